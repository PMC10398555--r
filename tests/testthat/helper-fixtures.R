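# Shared fixtures: cohort builders and independent rule oracles.

# Independent per-respondent rule oracles (plain logical formulas, not
# the package's expression-tree evaluator).
oracle_rules <- list(
  rule1 = function(a) a[["q2"]] && a[["q4"]] && a[["q5"]],
  rule2 = function(a) a[["q2"]] && a[["q4"]] && a[["q6"]],
  rule3 = function(a) {
    (a[["q2"]] && (a[["q4"]] || (a[["q1"]] && a[["q3"]])) && a[["q6"]]) ||
      a[["q7"]]
  },
  rule4 = function(a, intercept = -4.483, cutoff = 0.849) {
    y <- intercept + 1.484 * a[["q1"]] + 2.415 * a[["q2"]] +
      1.367 * a[["q3"]] + 2.749 * a[["q4"]] + 1.448 * a[["q6"]]
    (1 / (1 + exp(-y)) > cutoff) || a[["q7"]]
  }
)

oracle_over_patterns <- function(f, pats = answer_patterns()) {
  vapply(seq_len(nrow(pats)), function(i) f(as.list(pats[i, ])), logical(1))
}

# Minimal well-formed cohort records around an answer matrix.
fixture_cohort <- function(answers, age = 10, sex = "male",
                           reference = NA, aware = NA) {
  answers <- as.data.frame(answers)
  n <- nrow(answers)
  df <- data.frame(id = sprintf("F%04d", seq_len(n)),
                   age_months = rep_len(age, n),
                   sex = rep_len(sex, n),
                   stringsAsFactors = FALSE)
  df <- cbind(df, answers)
  df$device_id <- sprintf("dev%04d", seq_len(n))
  df$ip_address <- sprintf("ip%04d", seq_len(n))
  df$repeat_first <- rep("a", n)
  df$repeat_second <- rep("a", n)
  df$quality <- rep("good", n)
  df$excluded_condition <- rep(FALSE, n)
  df$reference <- rep_len(reference, n)
  df$aware <- rep_len(aware, n)
  df
}

random_answers <- function(n, p = 0.5) {
  m <- matrix(runif(n * 7) < p, nrow = n, ncol = 7,
              dimnames = list(NULL, paste0("q", 1:7)))
  as.data.frame(m)
}

# Cohort realizing the published phase-2 awareness-cascade counts:
# identified 267 (54 previously diagnosed; 13 of the remaining 213
# aware; 152 of the 200 unaware with lesions within a week), plus
# non-identified filler up to n.
cascade_fixture <- function(n = 837, identified = 267, prev_diag = 54,
                            aware = 13, lesions = 152) {
  not_diag <- identified - prev_diag
  unaware <- not_diag - aware
  ans <- data.frame(q1 = FALSE, q2 = TRUE, q3 = FALSE, q4 = TRUE,
                    q5 = FALSE, q6 = TRUE, q7 = FALSE)[rep(1, n), ]
  rownames(ans) <- NULL
  ans$q7[seq_len(prev_diag)] <- TRUE
  ans$q5[prev_diag + not_diag - seq_len(lesions) + 1] <- TRUE
  neg <- (identified + 1):n          # rule-3 negative filler
  ans$q2[neg] <- FALSE
  ans$q4[neg] <- FALSE
  aware_flag <- rep(FALSE, n)
  aware_flag[prev_diag + seq_len(aware)] <- TRUE
  fixture_cohort(ans, aware = aware_flag)
}
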