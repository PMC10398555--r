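# Synthetic respondent cohorts: a latent disease state plus correlated
# boolean answers. The answer model is either conditional independence
# of the questions given the disease state (with the logical implication
# Q5 => Q6 enforced: a site affected within the last week was affected
# within the last 6 months), or an explicit probability table over the
# 128 answer patterns per state. Pattern tables support exact analytic
# operating characteristics and calibration to published rule-level
# sensitivity/specificity and answer marginals.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_prob_vec <- function(p, what) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    stop(what, " must be probabilities in [0, 1]")
  }
  invisible(p)
}

#' Specify a generative cohort model
#'
#' Either supply per-question conditional probabilities
#' `P(Q_i = yes | diseased)` and `P(Q_i = yes | healthy)` (named vectors
#' `q1`..`q7`; questions independent given the state, except that Q5 is
#' drawn only when Q6 is yes, so `p["q5"]` is conditional on Q6), or
#' explicit length-128 probability tables over the answer patterns of
#' [answer_patterns()] per disease state.
#'
#' @param n default cohort size for [generate_cohort()].
#' @param prevalence latent disease prevalence, in \[0, 1\].
#' @param p_diseased,p_healthy named conditional-probability vectors
#'   (model a).
#' @param pattern_diseased,pattern_healthy length-128 pattern
#'   probability tables summing to 1 (model b).
#' @param seed default RNG seed for generation.
#' @param awareness_rate P(caregiver aware of possible AD | diseased);
#'   healthy caregivers are never flagged aware.
#' @param age_range age range in months, sampled uniformly.
#' @return Object of class `cohort_model`.
#' @export
cohort_model <- function(n, prevalence, p_diseased = NULL, p_healthy = NULL,
                         pattern_diseased = NULL, pattern_healthy = NULL,
                         seed = NULL, awareness_rate = 0.061,
                         age_range = c(0, 24)) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == round(n))
  check_prob_vec(prevalence, "prevalence")
  check_prob_vec(awareness_rate, "awareness_rate")
  cond_mode <- !is.null(p_diseased) || !is.null(p_healthy)
  table_mode <- !is.null(pattern_diseased) || !is.null(pattern_healthy)
  if (cond_mode == table_mode) {
    stop("supply either conditional probabilities or pattern tables")
  }
  if (cond_mode) {
    for (p in list(p_diseased, p_healthy)) {
      check_prob_vec(p, "conditional probabilities")
      if (is.null(names(p)) || !setequal(names(p), eceq_questions())) {
        stop("conditional probabilities must be named q1..q7")
      }
    }
    p_diseased <- p_diseased[eceq_questions()]
    p_healthy <- p_healthy[eceq_questions()]
  } else {
    for (p in list(pattern_diseased, pattern_healthy)) {
      check_prob_vec(p, "pattern probabilities")
      if (length(p) != 128L) stop("pattern tables must have length 128")
      if (abs(sum(p) - 1) > 1e-8) stop("pattern table must sum to 1")
    }
  }
  structure(list(n = as.integer(n), prevalence = prevalence,
                 p_diseased = p_diseased, p_healthy = p_healthy,
                 pattern_diseased = pattern_diseased,
                 pattern_healthy = pattern_healthy,
                 seed = seed, awareness_rate = awareness_rate,
                 age_range = age_range),
            class = "cohort_model")
}

#' @export
print.cohort_model <- function(x, ...) {
  mode <- if (is.null(x$pattern_diseased)) "conditional-independence"
          else "pattern-table"
  cat(sprintf("Cohort model (%s): n = %d, prevalence = %.3f\n",
              mode, x$n, x$prevalence))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibrated: max residual %.4g (%s)\n",
                x$calibration$residual_max,
                if (x$calibration$feasible) "feasible" else "INFEASIBLE"))
  }
  invisible(x)
}

# conditional-independence pattern probability, Q5 drawn only when Q6 yes
cond_pattern_probs <- function(p) {
  pats <- answer_patterns()
  probs <- rep(1, nrow(pats))
  for (q in c("q1", "q2", "q3", "q4", "q6", "q7")) {
    probs <- probs * ifelse(pats[, q], p[[q]], 1 - p[[q]])
  }
  q5 <- pats[, "q5"]; q6 <- pats[, "q6"]
  probs <- probs * ifelse(q6, ifelse(q5, p[["q5"]], 1 - p[["q5"]]),
                          ifelse(q5, 0, 1))
  probs
}

#' Pattern probability tables of a cohort model
#'
#' @param model a [cohort_model()].
#' @return List with `diseased` and `healthy`, each a length-128
#'   probability vector aligned with [answer_patterns()].
#' @export
pattern_table <- function(model) {
  stopifnot(inherits(model, "cohort_model"))
  if (!is.null(model$pattern_diseased)) {
    list(diseased = model$pattern_diseased, healthy = model$pattern_healthy)
  } else {
    list(diseased = cond_pattern_probs(model$p_diseased),
         healthy = cond_pattern_probs(model$p_healthy))
  }
}

#' Analytic operating characteristics of a rule under a model
#'
#' Exact (not sampled) sensitivity and specificity: the pattern
#' probability mass on rule-positive patterns among the diseased, and on
#' rule-negative patterns among the healthy.
#'
#' @param model a [cohort_model()].
#' @param rule a `screening_rule` or built-in name.
#' @return List with `sensitivity` and `specificity`.
#' @export
model_accuracy <- function(model, rule) {
  if (is.character(rule)) rule <- eceq_rule(rule)
  pt <- pattern_table(model)
  pos <- evaluate_rule(rule, answer_patterns())
  list(sensitivity = sum(pt$diseased[pos]),
       specificity = sum(pt$healthy[!pos]))
}

#' Analytic answer marginals of a cohort model
#'
#' @param model a [cohort_model()].
#' @return List with `diseased`, `healthy` and `overall` per-question
#'   yes-probabilities (overall mixes by prevalence).
#' @export
model_marginals <- function(model) {
  pt <- pattern_table(model)
  pats <- answer_patterns() * 1
  md <- as.vector(crossprod(pats, pt$diseased))
  mh <- as.vector(crossprod(pats, pt$healthy))
  names(md) <- names(mh) <- eceq_questions()
  list(diseased = md, healthy = mh,
       overall = model$prevalence * md + (1 - model$prevalence) * mh)
}

#' Generate a synthetic cohort
#'
#' Draws the latent disease state, then an answer pattern per respondent
#' from the state's pattern table, and fills plausible demographics and
#' survey bookkeeping fields (unique ids, device ids and network
#' addresses; matching repeated-question pair; good self-evaluated
#' quality; no excluded conditions). The `reference` column carries the
#' latent disease state — it stands in for the doctor's diagnosis, which
#' the generator treats as error-free. Reproducible: the same seed gives
#' a byte-identical cohort.
#'
#' @param model a [cohort_model()].
#' @param n cohort size (defaults to `model$n`).
#' @param seed RNG seed (defaults to `model$seed`).
#' @return Cohort data frame with the canonical pipeline columns.
#' @export
generate_cohort <- function(model, n = model$n, seed = model$seed) {
  stopifnot(inherits(model, "cohort_model"))
  pt <- pattern_table(model)
  pats <- answer_patterns()
  with_seed(seed, {
    diseased <- stats::runif(n) < model$prevalence
    idx <- integer(n)
    if (any(diseased)) {
      idx[diseased] <- sample.int(128L, sum(diseased), replace = TRUE,
                                  prob = pt$diseased)
    }
    if (any(!diseased)) {
      idx[!diseased] <- sample.int(128L, sum(!diseased), replace = TRUE,
                                   prob = pt$healthy)
    }
    ans <- pats[idx, , drop = FALSE]
    rep_ans <- sample(c("a", "b", "c"), n, replace = TRUE)
    aware <- diseased & stats::runif(n) < model$awareness_rate
    df <- data.frame(
      id = sprintf("R%06d", seq_len(n)),
      # floor to 0.1 months so an age never lands on the exclusive bound
      age_months = floor(stats::runif(n, model$age_range[1],
                                      model$age_range[2]) * 10) / 10,
      sex = sample(c("male", "female"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(ans))
    df$device_id <- sprintf("dev%06d", seq_len(n))
    df$ip_address <- sprintf("10.%d.%d.%d",
                             seq_len(n) %/% 65536L,
                             (seq_len(n) %/% 256L) %% 256L,
                             seq_len(n) %% 256L)
    df$repeat_first <- rep_ans
    df$repeat_second <- rep_ans
    df$quality <- "good"
    df$excluded_condition <- FALSE
    df$reference <- diseased
    df$aware <- aware
    df[COHORT_COLUMNS]
  })
}

#' Inject survey-style noise into a cohort
#'
#' Emulates field losses: nonresponse drops records; unqualified
#' responses get corrupted reliability fields (repeated-question
#' mismatch); duplicates append clones sharing device id, network
#' address and demographics with an existing record. Deterministic per
#' seed.
#'
#' @param records cohort data frame.
#' @param unqualified_ratio,nonresponse_rate,duplicate_ratio per-record
#'   probabilities in \[0, 1).
#' @param seed RNG seed.
#' @return Noisy cohort data frame.
#' @export
inject_survey_noise <- function(records, unqualified_ratio = 0.05,
                                nonresponse_rate = 0.5,
                                duplicate_ratio = 0, seed = NULL) {
  for (r in c(unqualified_ratio, nonresponse_rate, duplicate_ratio)) {
    if (!is.numeric(r) || is.na(r) || r < 0 || r >= 1) {
      stop("noise ratios must lie in [0, 1)")
    }
  }
  with_seed(seed, {
    n <- nrow(records)
    keep <- stats::runif(n) >= nonresponse_rate
    out <- records[keep, , drop = FALSE]
    m <- nrow(out)
    if (m > 0 && unqualified_ratio > 0) {
      corrupt <- stats::runif(m) < unqualified_ratio
      out$repeat_second[corrupt] <- paste0(out$repeat_first[corrupt], "_x")
    }
    if (m > 0 && duplicate_ratio > 0) {
      clone <- which(stats::runif(m) < duplicate_ratio)
      if (length(clone)) {
        dup <- out[clone, , drop = FALSE]
        dup$id <- paste0(dup$id, "_dup")
        out <- rbind(out, dup)
      }
    }
    rownames(out) <- NULL
    out
  })
}

# ---- calibration ------------------------------------------------------

softmax <- function(theta) {
  e <- exp(theta - max(theta))
  e / sum(e)
}

#' Calibrate a pattern-table cohort model to published targets
#'
#' Finds pattern probability tables (per disease state) whose exact,
#' analytic rule operating characteristics match target sensitivities
#' and specificities — and, optionally, whose overall answer marginals
#' match target per-question yes-frequencies. Minimizes the summed
#' squared residuals over the two 128-pattern simplexes via a softmax
#' parameterization (L-BFGS-B with analytic gradient). By default the full
#' simplex is searched: real respondents answer Q5 and Q6 inconsistently
#' (the published rules 1 and 2 perform differently even though their
#' yes-marginals coincide, which would be impossible under a strict
#' Q5 => Q6 implication), so the calibrated table must be free to place
#' mass on Q5-yes/Q6-no patterns; set `enforce_q5_q6 = TRUE` to restrict
#' the support to logically consistent patterns. If the best residual
#' exceeds `tol` the model is flagged infeasible, with the achieved
#' values and residuals reported.
#'
#' @param rules list of `screening_rule`s or built-in rule names.
#' @param sensitivity,specificity numeric target vectors, one per rule.
#' @param marginals optional named vector (`q1`..`q7`) of target overall
#'   yes-frequencies.
#' @param prevalence disease prevalence (mixes the marginals and scales
#'   the cohort).
#' @param n default cohort size of the returned model.
#' @param seed default generation seed of the returned model.
#' @param tol maximum absolute residual per target for feasibility.
#' @param marginal_weight relative weight of marginal residuals in the
#'   objective.
#' @param maxit optimizer iteration budget.
#' @param enforce_q5_q6 restrict the support to patterns with Q5 <= Q6.
#' @param awareness_rate passed to [cohort_model()].
#' @return A calibrated [cohort_model()] with a `calibration` element:
#'   `targets`, `achieved` (per-rule Se/Sp and marginals),
#'   `residual_max`, `feasible`, `convergence`.
#' @export
calibrate_cohort_model <- function(rules, sensitivity, specificity,
                                   marginals = NULL, prevalence,
                                   n = 1000, seed = NULL, tol = 0.01,
                                   marginal_weight = 1, maxit = 1000,
                                   enforce_q5_q6 = FALSE,
                                   awareness_rate = 0.061) {
  rules <- lapply(rules, function(r) if (is.character(r)) eceq_rule(r)
                                     else r)
  stopifnot(length(rules) == length(sensitivity),
            length(rules) == length(specificity))
  check_prob_vec(sensitivity, "target sensitivities")
  check_prob_vec(specificity, "target specificities")
  check_prob_vec(prevalence, "prevalence")

  pats <- answer_patterns()
  keep <- if (enforce_q5_q6) !(pats[, "q5"] & !pats[, "q6"])
          else rep(TRUE, nrow(pats))
  P <- pats[keep, , drop = FALSE]
  K <- nrow(P)
  A <- vapply(rules, function(r) evaluate_rule(r, P), logical(K))
  A <- matrix(as.numeric(A), nrow = K)       # K x R rule-positive indicator
  Aneg <- 1 - A
  M <- P * 1                                 # K x 7 question indicator
  has_m <- !is.null(marginals)
  if (has_m) {
    if (is.null(names(marginals)) ||
        !all(names(marginals) %in% eceq_questions())) {
      stop("marginals must be named with question ids q1..q7")
    }
    check_prob_vec(marginals, "target marginals")
    Mq <- M[, names(marginals), drop = FALSE]
  }

  unpack <- function(theta) {
    list(pD = softmax(theta[seq_len(K)]),
         pH = softmax(theta[K + seq_len(K)]))
  }
  resids <- function(p) {
    r_se <- as.vector(crossprod(A, p$pD)) - sensitivity
    r_sp <- as.vector(crossprod(Aneg, p$pH)) - specificity
    r_m <- if (has_m) {
      prevalence * as.vector(crossprod(Mq, p$pD)) +
        (1 - prevalence) * as.vector(crossprod(Mq, p$pH)) - marginals
    } else numeric(0)
    list(se = r_se, sp = r_sp, m = r_m)
  }
  fn <- function(theta) {
    r <- resids(unpack(theta))
    sum(r$se^2) + sum(r$sp^2) + marginal_weight * sum(r$m^2)
  }
  gr <- function(theta) {
    p <- unpack(theta)
    r <- resids(p)
    gD <- 2 * as.vector(A %*% r$se)
    gH <- 2 * as.vector(Aneg %*% r$sp)
    if (has_m) {
      gm <- as.vector(Mq %*% r$m)
      gD <- gD + 2 * marginal_weight * prevalence * gm
      gH <- gH + 2 * marginal_weight * (1 - prevalence) * gm
    }
    c(p$pD * (gD - sum(p$pD * gD)), p$pH * (gH - sum(p$pH * gH)))
  }
  opt <- stats::optim(rep(0, 2 * K), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 10))
  p <- unpack(opt$par)
  full_d <- full_h <- numeric(128)
  full_d[keep] <- p$pD
  full_h[keep] <- p$pH
  model <- cohort_model(n = n, prevalence = prevalence,
                        pattern_diseased = full_d / sum(full_d),
                        pattern_healthy = full_h / sum(full_h),
                        seed = seed, awareness_rate = awareness_rate)
  r <- resids(p)
  achieved <- data.frame(
    rule = vapply(rules, function(x) x$name, ""),
    target_sensitivity = sensitivity, target_specificity = specificity,
    sensitivity = sensitivity + r$se, specificity = specificity + r$sp)
  residual_max <- max(abs(c(r$se, r$sp, r$m)))
  feasible <- residual_max <= tol
  model$calibration <- list(
    targets = list(sensitivity = sensitivity, specificity = specificity,
                   marginals = marginals),
    achieved = achieved,
    achieved_marginals = if (has_m) marginals + r$m else NULL,
    residual_max = residual_max, feasible = feasible,
    convergence = opt$convergence)
  if (!feasible) {
    warning(sprintf(
      "calibration infeasible: max residual %.4f exceeds tolerance %.4f",
      residual_max, tol), call. = FALSE)
  }
  model
}

#' Published phase-1 calibration targets
#'
#' The rule-level sensitivities/specificities of the three boolean rules
#' and the per-question answer frequencies observed in the 195-child
#' validation cohort (148 diseased), as calibration inputs.
#'
#' @return List with `rules`, `sensitivity`, `specificity`, `marginals`,
#'   `prevalence`, `n`, `n_diseased`.
#' @export
eceq_phase1_targets <- function() {
  list(rules = c("rule1", "rule2", "rule3"),
       sensitivity = c(0.804, 0.811, 0.892),
       specificity = c(0.851, 0.915, 0.915),
       marginals = c(q1 = 116, q2 = 169, q3 = 112, q4 = 153, q5 = 162,
                     q6 = 162, q7 = 71) / 195,
       prevalence = 148 / 195,
       n = 195L, n_diseased = 148L)
}

#' Phase-1-style calibrated cohort model
#'
#' Convenience wrapper: calibrates a pattern-table model to the
#' published phase-1 rule targets and answer marginals at the phase-1
#' prevalence.
#'
#' @param n cohort size.
#' @param seed generation seed.
#' @param ... passed to [calibrate_cohort_model()].
#' @return A calibrated [cohort_model()].
#' @export
phase1_cohort_model <- function(n = 195, seed = NULL, ...) {
  t1 <- eceq_phase1_targets()
  calibrate_cohort_model(as.list(t1$rules), t1$sensitivity,
                         t1$specificity, marginals = t1$marginals,
                         prevalence = t1$prevalence, n = n, seed = seed,
                         ...)
}
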