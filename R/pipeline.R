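# Survey-export pipeline: read raw questionnaire exports, clean them
# through the staged exclusion flow (duplicates -> reliability -> age ->
# disease conditions), classify respondents with a screening rule, and
# derive prevalence, validation and awareness-cascade reports.

COHORT_COLUMNS <- c("id", "age_months", "sex", paste0("q", 1:7),
                    "device_id", "ip_address", "repeat_first",
                    "repeat_second", "quality", "excluded_condition",
                    "reference", "aware")

LOW_QUALITY_CODES <- c("poor", "low", "bad", "unreliable")

ensure_column <- function(df, col, default = NA) {
  if (!col %in% names(df)) df[[col]] <- rep(default, nrow(df))
  df
}

#' Read a cohort CSV export
#'
#' Expects one row per respondent with at least `id`, `age_months`, `sex`
#' and the answers `q1`..`q7` (coded yes/no, 1/0 or TRUE/FALSE). Optional
#' columns: `device_id`, `ip_address`, `repeat_first`, `repeat_second`
#' (the repeated reliability question), `quality` (self-evaluated
#' response quality), `excluded_condition` (autoimmune disease,
#' immunodeficiency, severe malnutrition, ...), `reference` (doctor's
#' diagnosis) and `aware` (caregiver awareness of possible AD). Missing
#' optional columns are filled with `NA`.
#'
#' @param path CSV file path.
#' @return data frame with the canonical cohort columns.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  required <- c("id", "age_months", "sex", paste0("q", 1:7))
  miss <- setdiff(required, names(df))
  if (length(miss)) stop("cohort file lacks columns: ",
                         paste(miss, collapse = ", "))
  for (col in COHORT_COLUMNS) df <- ensure_column(df, col)
  for (q in paste0("q", 1:7)) df[[q]] <- parse_yesno(df[[q]])
  for (col in c("excluded_condition", "reference", "aware")) {
    df[[col]] <- parse_yesno(df[[col]])
  }
  df[COHORT_COLUMNS]
}

#' Write a cohort CSV
#'
#' @param records cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

cleaning_report <- function(received, unparseable, duplicates, reliability,
                            overage, condition, retained,
                            partial_duplicates = 0L) {
  counts <- c(received = received, unparseable = unparseable,
              duplicates = duplicates, reliability = reliability,
              overage = overage, condition = condition,
              retained = retained)
  if (any(counts < 0)) stop("negative cleaning counts")
  removed <- unparseable + duplicates + reliability + overage + condition
  if (received - removed != retained) {
    stop("cleaning report does not balance: received ", received,
         ", removed ", removed, ", retained ", retained)
  }
  counts <- as.list(as.integer(counts))
  names(counts) <- c("received", "unparseable", "duplicates", "reliability",
                     "overage", "condition", "retained")
  structure(c(counts,
              list(partial_duplicates = as.integer(partial_duplicates))),
            class = "cleaning_report")
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  received    %d\n", x$received))
  cat(sprintf("  removed     unparseable %d, duplicates %d, reliability %d, over-age %d, condition %d\n",
              x$unparseable, x$duplicates, x$reliability, x$overage,
              x$condition))
  if (x$partial_duplicates > 0) {
    cat(sprintf("  flagged     %d partial duplicate(s) retained\n",
                x$partial_duplicates))
  }
  cat(sprintf("  retained    %d\n", x$retained))
  invisible(x)
}

#' Clean a raw survey export
#'
#' Applies the staged exclusion flow, in a fixed order so that each
#' record lands in exactly one removal bucket:
#' \enumerate{
#'   \item unparseable records (missing/invalid id or age) — counted
#'     explicitly, never silently dropped;
#'   \item duplicates: device id, network address AND basic demographics
#'     (age, sex) all equal to an earlier record — the first occurrence
#'     is kept. Partial matches (device + address only) are flagged in
#'     the report but retained;
#'   \item reliability failures: repeated-question mismatch,
#'     self-evaluated low quality, or any missing eCEQ answer;
#'   \item age at response `>= max_age_months` (exactly 24.0 months is
#'     excluded: the instrument targets children younger than 2 years);
#'   \item excluded disease conditions (autoimmune disease,
#'     immunodeficiency, severe malnutrition, ...).
#' }
#' Cleaning is idempotent: re-cleaning the retained records removes
#' nothing.
#'
#' @param records cohort data frame (see [read_cohort()]).
#' @param max_age_months exclusive upper age bound in months.
#' @return List with `records` (retained rows) and `report`
#'   (a `cleaning_report`).
#' @export
clean_cohort <- function(records, max_age_months = 24) {
  stopifnot(is.data.frame(records))
  for (col in COHORT_COLUMNS) records <- ensure_column(records, col)
  n <- nrow(records)
  if (n == 0L) {
    return(list(records = records,
                report = cleaning_report(0L, 0L, 0L, 0L, 0L, 0L, 0L)))
  }
  age <- suppressWarnings(as.numeric(records$age_months))

  unparseable <- is.na(records$id) | records$id == "" | is.na(age)
  pool <- !unparseable

  # duplicates: device + address + demographics all equal; NA keys never match
  full_key <- paste(records$device_id, records$ip_address, age,
                    records$sex, sep = "\r")
  keyable <- pool & !is.na(records$device_id) & !is.na(records$ip_address)
  dup <- rep(FALSE, n)
  dup[keyable] <- duplicated(full_key[keyable])
  pool <- pool & !dup

  partial_key <- paste(records$device_id, records$ip_address, sep = "\r")
  partial <- rep(FALSE, n)
  partial[keyable & pool] <- duplicated(partial_key[keyable & pool])

  ans <- as_answer_matrix(records, allow_na = TRUE)
  rep_mismatch <- !is.na(records$repeat_first) &
    !is.na(records$repeat_second) &
    as.character(records$repeat_first) != as.character(records$repeat_second)
  low_q <- !is.na(records$quality) &
    tolower(as.character(records$quality)) %in% LOW_QUALITY_CODES
  unreliable <- pool & (rep_mismatch | low_q | rowSums(is.na(ans)) > 0)
  pool <- pool & !unreliable

  overage <- pool & age >= max_age_months
  pool <- pool & !overage

  cond <- pool & !is.na(records$excluded_condition) &
    records$excluded_condition
  pool <- pool & !cond

  report <- cleaning_report(received = n, unparseable = sum(unparseable),
                            duplicates = sum(dup),
                            reliability = sum(unreliable),
                            overage = sum(overage), condition = sum(cond),
                            retained = sum(pool),
                            partial_duplicates = sum(partial))
  list(records = records[pool, , drop = FALSE], report = report)
}

#' Classify a cleaned cohort with a screening rule
#'
#' @param records cleaned cohort data frame with complete answers; an
#'   incomplete answer vector is an error naming the offending record(s).
#' @param rule a `screening_rule` or built-in rule name (see
#'   [eceq_rule()]).
#' @return Object of class `cohort_classification`: `positive` (logical
#'   per record, in input order), `n`, `n_positive`, `prevalence`,
#'   `rule`.
#' @export
classify_cohort <- function(records, rule) {
  if (is.character(rule)) rule <- eceq_rule(rule)
  stopifnot(inherits(rule, "screening_rule"), is.data.frame(records))
  n <- nrow(records)
  if (n > 0L) {
    ans <- as_answer_matrix(records, allow_na = TRUE)
    bad <- rowSums(is.na(ans)) > 0
    if (any(bad)) {
      ids <- if (!is.null(records$id)) records$id[bad] else which(bad)
      stop("incomplete eCEQ answers for record(s): ",
           paste(utils::head(ids, 10), collapse = ", "))
    }
  }
  positive <- if (n > 0L) evaluate_rule(rule, records) else logical(0)
  structure(list(positive = positive, n = n,
                 n_positive = sum(positive),
                 prevalence = if (n > 0L) mean(positive) else NA_real_,
                 rule = rule$name),
            class = "cohort_classification")
}

#' @export
print.cohort_classification <- function(x, ...) {
  cat(sprintf("Cohort classification by %s: %d/%d positive", x$rule,
              x$n_positive, x$n))
  if (!is.na(x$prevalence)) cat(sprintf(" (prevalence %.1f%%)",
                                        100 * x$prevalence))
  cat("\n")
  invisible(x)
}

#' Validate a rule against the reference diagnosis
#'
#' Classifies the cohort and compares against the `reference` column
#' (doctor's diagnosis); every record must carry one.
#'
#' @inheritParams classify_cohort
#' @return A [diagnostic_report()].
#' @export
validate_against_reference <- function(records, rule) {
  if (is.character(rule)) rule <- eceq_rule(rule)
  if (is.null(records$reference) || anyNA(parse_yesno(records$reference))) {
    stop("every record needs a reference diagnosis for validation")
  }
  cls <- classify_cohort(records, rule)
  diagnostic_report(confusion_from_labels(cls$positive,
                                          parse_yesno(records$reference)),
                    name = rule$name)
}

pct_of <- function(num, den) {
  if (is.na(num) || is.na(den) || den == 0) NA_real_ else 100 * num / den
}

#' Awareness cascade of identified cases
#'
#' Splits the rule-identified respondents into previously diagnosed
#' (Q7 yes) versus not; the not-previously-diagnosed into caregivers
#' aware of possible AD (the `aware` flag) versus unaware; and counts
#' the unaware with reported skin lesions within the last week (Q5).
#' Counts at each level sum to the level above. If the awareness flag is
#' missing for any relevant record, the cascade is truncated at that
#' level with an explicit marker.
#'
#' @param records cohort data frame with complete answers.
#' @param classifications a `cohort_classification` (or logical vector)
#'   aligned with `records`.
#' @return Object of class `awareness_cascade` with the counts,
#'   the derived percentages, and `truncated_at` (`NA` or
#'   `"awareness"`).
#' @export
awareness_cascade <- function(records, classifications) {
  pos <- if (inherits(classifications, "cohort_classification")) {
    classifications$positive
  } else {
    as.logical(classifications)
  }
  if (length(pos) != nrow(records)) {
    stop("classifications do not align with records")
  }
  ans <- as_answer_matrix(records)
  identified <- sum(pos)
  prev_diag <- sum(pos & ans[, "q7"])
  not_diag <- identified - prev_diag
  sub <- pos & !ans[, "q7"]
  aware_flag <- if ("aware" %in% names(records)) {
    parse_yesno(records$aware)
  } else {
    rep(NA, nrow(records))
  }
  truncated_at <- NA_character_
  if (any(sub) && anyNA(aware_flag[sub])) {
    truncated_at <- "awareness"
    aware <- unaware <- lesions_week <- NA_integer_
  } else {
    aware <- sum(sub & aware_flag)
    unaware <- not_diag - aware
    lesions_week <- sum(sub & !aware_flag & ans[, "q5"])
  }
  structure(list(identified = identified,
                 previously_diagnosed = prev_diag,
                 not_previously_diagnosed = not_diag,
                 aware = aware, unaware = unaware,
                 unaware_lesions_week = lesions_week,
                 pct_previously_diagnosed = pct_of(prev_diag, identified),
                 pct_aware = pct_of(aware, not_diag),
                 pct_lesions_week = pct_of(lesions_week, unaware),
                 truncated_at = truncated_at),
            class = "awareness_cascade")
}

#' @export
print.awareness_cascade <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", v)
  cat("Awareness cascade\n")
  cat(sprintf("  identified by rule:            %d\n", x$identified))
  cat(sprintf("  previously diagnosed (Q7):     %d (%s%%)\n",
              x$previously_diagnosed, fmt(x$pct_previously_diagnosed)))
  cat(sprintf("  not previously diagnosed:      %d\n",
              x$not_previously_diagnosed))
  if (!is.na(x$truncated_at)) {
    cat("  [cascade truncated: awareness flag missing]\n")
  } else {
    cat(sprintf("  caregiver aware of possible AD: %d (%s%%)\n",
                x$aware, fmt(x$pct_aware)))
    cat(sprintf("  unaware:                        %d\n", x$unaware))
    cat(sprintf("  unaware, lesions within 1 week: %d (%s%%)\n",
                x$unaware_lesions_week, fmt(x$pct_lesions_week)))
  }
  invisible(x)
}
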