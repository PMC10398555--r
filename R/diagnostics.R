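# Diagnostic-accuracy statistics for screening rules against a reference
# diagnosis, and reconstruction of 2x2 tables from published summary
# metrics (the raw respondent data are not deposited; printed Se/Sp and
# cohort counts pin the cells).

round_half_up <- function(x) floor(x + 0.5)

#' Confusion matrix of a binary rule against a reference diagnosis
#'
#' @param tp,fp,fn,tn non-negative integer cell counts (true/false
#'   positives/negatives).
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(cells) || any(cells < 0) || any(cells != round(cells))) {
    stop("confusion-matrix cells must be non-negative integers")
  }
  cells <- as.integer(cells)
  structure(list(tp = cells[1L], fp = cells[2L], fn = cells[3L],
                 tn = cells[4L]),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fp, x$fn, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("rule +", "rule -"),
                              c("disease +", "disease -")))
  print(m)
  invisible(x)
}

#' Tally a confusion matrix from predicted and reference labels
#'
#' @param predictions logical vector of rule classifications.
#' @param reference logical vector of reference diagnoses, same length.
#' @return A [confusion_matrix()]; cells always tally to the input length.
#' @export
confusion_from_labels <- function(predictions, reference) {
  predictions <- as.logical(predictions)
  reference <- as.logical(reference)
  if (length(predictions) != length(reference)) {
    stop("predictions and reference differ in length")
  }
  if (length(predictions) == 0L) stop("empty label vectors")
  if (anyNA(predictions) || anyNA(reference)) stop("labels contain NA")
  confusion_matrix(tp = sum(predictions & reference),
                   fp = sum(predictions & !reference),
                   fn = sum(!predictions & reference),
                   tn = sum(!predictions & !reference))
}

#' Reconstruct a confusion matrix from published summary metrics
#'
#' Given the cohort size, the number of diseased subjects, and a rule's
#' published sensitivity and specificity, recovers the integer 2x2 cells:
#' `tp = round(Se * n_diseased)` and `tn = round(Sp * (n_total -
#' n_diseased))`, rounding half up, with `fn`/`fp` by complement. The
#' recomputed Se/Sp agree with the inputs within the 0.5/n rounding
#' tolerance.
#'
#' @param n_total cohort size.
#' @param n_diseased number with the reference diagnosis; must satisfy
#'   `0 < n_diseased < n_total`.
#' @param sensitivity,specificity published proportions in \[0, 1\].
#' @return A [confusion_matrix()].
#' @export
reconstruct_confusion <- function(n_total, n_diseased, sensitivity,
                                  specificity) {
  stopifnot(length(n_total) == 1L, length(n_diseased) == 1L)
  if (!(n_diseased > 0 && n_diseased < n_total)) {
    stop("need 0 < n_diseased < n_total")
  }
  if (sensitivity < 0 || sensitivity > 1 || specificity < 0 ||
      specificity > 1) {
    stop("sensitivity and specificity must lie in [0, 1]")
  }
  d <- n_diseased
  h <- n_total - n_diseased
  tp <- round_half_up(sensitivity * d)
  tn <- round_half_up(specificity * h)
  confusion_matrix(tp = tp, fp = h - tn, fn = d - tp, tn = tn)
}

kappa_from_cells <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (pe >= 1) {
    if (po == 1) return(1)
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Diagnostic-accuracy report for one rule
#'
#' Computes sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV
#' `tp/(tp+fp)`, NPV `tn/(tn+fn)`, Cohen's kappa from the table margins,
#' and — for a binary rule — AUC as `(Se+Sp)/2`. A degenerate margin
#' yields an explicit `NA` for that metric with a warning, never a silent
#' 0/0.
#'
#' @param cm a [confusion_matrix()].
#' @param name rule label carried into the report.
#' @return Object of class `diagnostic_report`: the cells plus `n`,
#'   `prevalence`, `sensitivity`, `specificity`, `ppv`, `npv`, `kappa`,
#'   `auc`.
#' @export
diagnostic_report <- function(cm, name = NULL) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty confusion matrix")
  metric <- function(num, den, label) {
    if (den > 0) num / den
    else {
      warning(label, " undefined: empty margin", call. = FALSE)
      NA_real_
    }
  }
  se <- metric(tp, tp + fn, "sensitivity")
  sp <- metric(tn, tn + fp, "specificity")
  ppv <- metric(tp, tp + fp, "PPV")
  npv <- metric(tn, tn + fn, "NPV")
  structure(list(name = name, tp = tp, fp = fp, fn = fn, tn = tn, n = n,
                 prevalence = (tp + fn) / n,
                 sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
                 kappa = kappa_from_cells(tp, fp, fn, tn),
                 auc = if (is.na(se) || is.na(sp)) NA_real_
                       else (se + sp) / 2),
            class = "diagnostic_report")
}

#' @export
print.diagnostic_report <- function(x, ...) {
  pct <- function(v) if (is.na(v)) "NA" else sprintf("%.1f", 100 * v)
  two <- function(v) if (is.na(v)) "NA" else sprintf("%.2f", v)
  if (!is.null(x$name)) cat("Rule:", x$name, "\n")
  cat(sprintf("n = %d (diseased %d, prevalence %s%%)\n",
              x$n, x$tp + x$fn, pct(x$prevalence)))
  cat(sprintf("  sensitivity %s%%  specificity %s%%  PPV %s%%  NPV %s%%\n",
              pct(x$sensitivity), pct(x$specificity), pct(x$ppv),
              pct(x$npv)))
  cat(sprintf("  kappa %s  AUC %s\n", two(x$kappa), two(x$auc)))
  invisible(x)
}

#' Tabulate diagnostic reports in the published column order
#'
#' @param reports list of [diagnostic_report()] objects.
#' @return data frame with one row per rule: `rule`, `sensitivity_pct`,
#'   `specificity_pct`, `ppv_pct`, `npv_pct`, `kappa`, `auc`.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "diagnostic_report")) reports <- list(reports)
  rows <- lapply(seq_along(reports), function(i) {
    r <- reports[[i]]
    data.frame(rule = r$name %||% paste0("rule", i),
               sensitivity_pct = 100 * r$sensitivity,
               specificity_pct = 100 * r$specificity,
               ppv_pct = 100 * r$ppv, npv_pct = 100 * r$npv,
               kappa = r$kappa, auc = r$auc, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohen's kappa between two binary classifications
#'
#' Chance-corrected agreement between two raters or rules; no disease
#' labels needed. Two-category, unweighted.
#'
#' @param a,b logical vectors of equal, non-zero length.
#' @return kappa in \[-1, 1\]; exactly 1 for identical vectors. `NA` when
#'   chance agreement is 1 but observed agreement is not (cannot occur
#'   with both categories present).
#' @export
cohen_kappa <- function(a, b) {
  a <- as.logical(a); b <- as.logical(b)
  if (length(a) != length(b)) stop("vectors differ in length")
  if (length(a) == 0L) stop("empty vectors")
  if (anyNA(a) || anyNA(b)) stop("vectors contain NA")
  kappa_from_cells(tp = sum(a & b), fp = sum(a & !b),
                   fn = sum(!a & b), tn = sum(!a & !b))
}

#' ROC curve, Youden-optimal cutoff and trapezoidal AUC
#'
#' Enumerates candidate cutoffs (midpoints between consecutive distinct
#' scores, plus one below the minimum and one above the maximum),
#' classifying positive when `score > cutoff`. The reported cutoff
#' maximizes the Youden index Se + Sp - 1; ties break toward the lowest
#' qualifying cutoff, favoring sensitivity. AUC is the trapezoid area
#' over the resulting ROC points.
#'
#' @param scores numeric scores (e.g. predictive probabilities).
#' @param reference logical reference diagnoses; both classes must be
#'   present.
#' @return Object of class `roc_analysis`: `roc` (data frame of `cutoff`,
#'   `sensitivity`, `specificity`, `youden`), `cutoff`, `auc`.
#' @export
roc_cutoff <- function(scores, reference) {
  reference <- as.logical(reference)
  if (length(scores) != length(reference)) stop("lengths differ")
  if (anyNA(scores) || anyNA(reference)) stop("inputs contain NA")
  if (!any(reference) || all(reference)) {
    stop("reference must contain both classes")
  }
  s <- sort(unique(scores))
  mids <- if (length(s) > 1L) (s[-length(s)] + s[-1L]) / 2 else numeric(0)
  cand <- c(s[1L] - 1, mids, s[length(s)] + 1)
  sens <- vapply(cand, function(cc) mean(scores[reference] > cc), 0)
  spec <- vapply(cand, function(cc) mean(scores[!reference] <= cc), 0)
  youden <- sens + spec - 1
  best <- which.max(youden)  # candidates ascend, so first max = lowest cutoff
  fpr <- 1 - spec
  o <- order(fpr, sens)
  x <- fpr[o]; y <- sens[o]
  auc <- sum(diff(x) * (y[-1L] + y[-length(y)]) / 2)
  structure(list(roc = data.frame(cutoff = cand, sensitivity = sens,
                                  specificity = spec, youden = youden),
                 cutoff = cand[best], auc = auc),
            class = "roc_analysis")
}

#' @export
print.roc_analysis <- function(x, ...) {
  cat(sprintf("ROC over %d cutoffs: AUC %.3f, Youden-optimal cutoff %.4g\n",
              nrow(x$roc), x$auc, x$cutoff))
  invisible(x)
}

#' Odds ratio with Wald confidence interval
#'
#' `OR = exp(b)` with bounds `exp(b +/- z * se)`, `z` the two-sided
#' normal quantile for the confidence level.
#'
#' @param beta log-odds coefficient(s).
#' @param se standard error(s), strictly positive.
#' @param conf confidence level (default 0.95).
#' @return data frame with columns `or`, `lower`, `upper` (one row per
#'   coefficient).
#' @export
wald_or_ci <- function(beta, se, conf = 0.95) {
  if (any(se <= 0)) stop("standard errors must be positive")
  stopifnot(conf > 0, conf < 1, length(beta) == length(se))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  data.frame(or = exp(beta), lower = exp(beta - z * se),
             upper = exp(beta + z * se))
}
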