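# Screening rules: boolean AND/OR expressions over the seven questions
# (rules 1-3) and a logistic risk score with a probability cutoff and a
# Q7 override disjunct (rule 4). Rules are data, not hard-coded branches:
# user-defined variants are first-class and round-trip through JSON.

# ---- expression nodes -------------------------------------------------
# A node is a one-element named list:
#   list(q = i)            question atom, i in 1..7
#   list(and = list(...))  conjunction of child nodes
#   list(or  = list(...))  disjunction of child nodes
# This shape is identical to the JSON rule-file format.

validate_node <- function(node) {
  if (!is.list(node) || length(node) != 1L || is.null(names(node))) {
    stop("malformed rule node: each node is a one-element named list")
  }
  key <- names(node)
  if (key == "q") {
    i <- node$q
    if (!is.numeric(i) || length(i) != 1L || is.na(i) || i != as.integer(i) ||
        i < 1 || i > 7) {
      stop("question atom must reference an index in 1..7, got: ",
           deparse(node$q))
    }
  } else if (key %in% c("and", "or")) {
    if (!is.list(node[[1L]]) || length(node[[1L]]) < 1L) {
      stop("'", key, "' node needs at least one child")
    }
    lapply(node[[1L]], validate_node)
  } else {
    stop("unknown rule node type: '", key, "'")
  }
  invisible(node)
}

eval_node <- function(node, m) {
  key <- names(node)
  switch(key,
    q   = m[, paste0("q", node$q)],
    and = Reduce(`&`, lapply(node$and, eval_node, m = m)),
    or  = Reduce(`|`, lapply(node$or, eval_node, m = m))
  )
}

node_to_text <- function(node, top = TRUE) {
  key <- names(node)
  if (key == "q") return(paste0("Q", node$q))
  sep <- if (key == "and") "&" else "|"
  body <- paste(vapply(node[[1L]], node_to_text, "", top = FALSE),
                collapse = sep)
  if (top) body else paste0("(", body, ")")
}

# ---- constructors -----------------------------------------------------

#' Define a boolean screening rule
#'
#' @param expr expression tree: nested one-element named lists with keys
#'   `q` (atom, question index 1..7), `and`, `or`. Structural errors are
#'   raised here, at construction time, never during evaluation.
#' @param name label for reports.
#' @return Object of class `c("boolean_rule", "screening_rule")`.
#' @seealso [parse_rule()] to build the tree from `"Q2&Q4&Q6"` notation.
#' @export
boolean_rule <- function(expr, name = "custom") {
  validate_node(expr)
  structure(list(name = name, expr = expr),
            class = c("boolean_rule", "screening_rule"))
}

#' Parse a rule from the instrument's formula notation
#'
#' Accepts expressions such as `"(Q2&(Q4|(Q1&Q3))&Q6)|Q7"`: atoms `Q1`..
#' `Q7` (case-insensitive), `&`, `|` and parentheses. `Qn` means "the
#' answer to question n is yes".
#'
#' @param text rule formula.
#' @param name label for reports; defaults to the formula itself.
#' @return A [boolean_rule()].
#' @export
parse_rule <- function(text, name = text) {
  stopifnot(is.character(text), length(text) == 1L)
  lang <- tryCatch(str2lang(text),
                   error = function(e) stop("cannot parse rule: ", text))
  boolean_rule(lang_to_node(lang), name = name)
}

lang_to_node <- function(e) {
  if (is.symbol(e)) {
    s <- toupper(as.character(e))
    if (!grepl("^Q[1-7]$", s)) stop("unknown rule symbol: ", as.character(e))
    return(list(q = as.integer(substring(s, 2))))
  }
  if (is.call(e)) {
    op <- as.character(e[[1L]])
    if (op == "(") return(lang_to_node(e[[2L]]))
    if (op %in% c("&", "&&")) {
      return(list(and = list(lang_to_node(e[[2L]]), lang_to_node(e[[3L]]))))
    }
    if (op %in% c("|", "||")) {
      return(list(or = list(lang_to_node(e[[2L]]), lang_to_node(e[[3L]]))))
    }
    stop("unsupported operator in rule: ", op)
  }
  stop("unsupported rule element: ", deparse(e))
}

#' Define a logistic screening rule
#'
#' Classifies positive when the predictive probability
#' \eqn{1/(1+\exp(-(b_0 + \sum_n B_n Q_n)))} exceeds `cutoff`
#' (strictly, by default), or — with `q7_override` — when Q7 is yes
#' regardless of the score.
#'
#' @param coefficients named numeric vector of per-question log-odds
#'   weights; names among `q1`..`q7`.
#' @param intercept model intercept (log-odds at all-no).
#' @param cutoff probability cutoff, strictly inside (0, 1).
#' @param strict classify positive when probability `> cutoff` (`TRUE`,
#'   the default) or `>= cutoff`.
#' @param q7_override a yes on Q7 (previous doctor's diagnosis) forces a
#'   positive classification.
#' @param name label for reports.
#' @return Object of class `c("logistic_rule", "screening_rule")`.
#' @export
logistic_rule <- function(coefficients, intercept, cutoff = 0.849,
                          strict = TRUE, q7_override = TRUE,
                          name = "logistic") {
  stopifnot(is.numeric(coefficients), length(coefficients) >= 1L,
            is.numeric(intercept), length(intercept) == 1L,
            is.numeric(cutoff), length(cutoff) == 1L)
  if (is.null(names(coefficients)) ||
      !all(tolower(names(coefficients)) %in% eceq_questions())) {
    stop("coefficients must be named with question ids among q1..q7")
  }
  names(coefficients) <- tolower(names(coefficients))
  if (anyDuplicated(names(coefficients))) stop("duplicated coefficient names")
  if (!(cutoff > 0 && cutoff < 1)) stop("cutoff must lie strictly in (0, 1)")
  structure(list(name = name, coefficients = coefficients,
                 intercept = intercept, cutoff = cutoff, strict = strict,
                 q7_override = q7_override),
            class = c("logistic_rule", "screening_rule"))
}

# Printed coefficients of the rule-4 multivariate logistic model.
# Q5 is not in the model (its NPV was lower than Q6's); Q7 enters rule 4
# only through the override disjunct, never through the score.
ECEQ_COEF <- c(q1 = 1.484, q2 = 2.415, q3 = 1.367, q4 = 2.749, q6 = 1.448)
ECEQ_SE <- c(q1 = 0.61, q2 = 0.71, q3 = 0.52, q4 = 0.54, q6 = 0.59)
ECEQ_INTERCEPT <- -4.483       # full-precision published equation
ECEQ_INTERCEPT_ALT <- -4.84    # coefficient-table variant
ECEQ_INTERCEPT_SE <- 0.91

#' Built-in eCEQ identification rules
#'
#' The four published identification rules:
#' \describe{
#'   \item{rule1}{`Q2&Q4&Q5` — the original paper-questionnaire rule.}
#'   \item{rule2}{`Q2&Q4&Q6` — the 6-month-recall modification.}
#'   \item{rule3}{`(Q2&(Q4|(Q1&Q3))&Q6)|Q7` — Q1 and Q3 substitute for
#'     Q4, and a previous diagnosis (Q7) forces a positive.}
#'   \item{rule4}{logistic score over Q1-Q4 and Q6 with cutoff 0.849 and
#'     Q7 override. The default intercept is -4.483, the full-precision
#'     published equation; `"rule4_alt"` uses the -4.84 variant printed
#'     in the coefficient table (the two published values disagree, and
#'     the answer pattern {Q2,Q3,Q4} is classified differently by the
#'     two).}
#' }
#'
#' @param name one of `"rule1"`, `"rule2"`, `"rule3"`, `"rule4"`,
#'   `"rule4_alt"`.
#' @return A `screening_rule`.
#' @export
eceq_rule <- function(name = c("rule1", "rule2", "rule3", "rule4",
                               "rule4_alt")) {
  name <- match.arg(name)
  switch(name,
    rule1 = parse_rule("Q2&Q4&Q5", name = "rule1"),
    rule2 = parse_rule("Q2&Q4&Q6", name = "rule2"),
    rule3 = parse_rule("(Q2&(Q4|(Q1&Q3))&Q6)|Q7", name = "rule3"),
    rule4 = logistic_rule(ECEQ_COEF, ECEQ_INTERCEPT, cutoff = 0.849,
                          name = "rule4"),
    rule4_alt = logistic_rule(ECEQ_COEF, ECEQ_INTERCEPT_ALT, cutoff = 0.849,
                              name = "rule4_alt")
  )
}

#' Published logistic-model coefficient table
#'
#' The per-question log-odds coefficients and Wald standard errors of the
#' rule-4 model, plus the intercept, as inputs for odds-ratio and CI
#' computation.
#'
#' @param intercept which published intercept variant to carry.
#' @return data frame with columns `term`, `b`, `se`.
#' @export
eceq_logistic_table <- function(intercept = c("equation", "table")) {
  intercept <- match.arg(intercept)
  b0 <- if (intercept == "equation") ECEQ_INTERCEPT else ECEQ_INTERCEPT_ALT
  data.frame(term = c(names(ECEQ_COEF), "intercept"),
             b = c(unname(ECEQ_COEF), b0),
             se = c(unname(ECEQ_SE), ECEQ_INTERCEPT_SE),
             stringsAsFactors = FALSE)
}

# ---- evaluation -------------------------------------------------------

#' Evaluate a screening rule on answer vectors
#'
#' @param rule a `screening_rule`.
#' @param answers data frame or matrix with columns `q1`..`q7`.
#' @return Logical vector, one classification per row. Evaluation is
#'   deterministic and total: every well-formed rule classifies every
#'   complete answer vector.
#' @export
evaluate_rule <- function(rule, answers) UseMethod("evaluate_rule")

#' @export
evaluate_rule.boolean_rule <- function(rule, answers) {
  m <- as_answer_matrix(answers)
  as.logical(eval_node(rule$expr, m))
}

#' @export
evaluate_rule.logistic_rule <- function(rule, answers) {
  m <- as_answer_matrix(answers)
  p <- logistic_probability(rule, m)
  pos <- if (rule$strict) p > rule$cutoff else p >= rule$cutoff
  if (rule$q7_override) pos <- pos | m[, "q7"]
  as.logical(pos)
}

#' Predictive probability of a logistic rule
#'
#' The logistic transform of the linear score
#' \eqn{y = b_0 + \sum_n B_n Q_n} with \eqn{Q_n \in \{0,1\}}.
#'
#' @inheritParams evaluate_rule
#' @return Numeric vector of probabilities in (0, 1).
#' @export
logistic_probability <- function(rule, answers) {
  stopifnot(inherits(rule, "logistic_rule"))
  m <- as_answer_matrix(answers)
  y <- rule$intercept +
    as.vector(m[, names(rule$coefficients), drop = FALSE] %*%
                rule$coefficients)
  stats::plogis(y)
}

#' Exhaustive truth table of a rule
#'
#' Evaluates the rule on all 128 answer patterns. Serves as the oracle
#' surface for equivalence testing and for analytic operating
#' characteristics of pattern-table cohort models.
#'
#' @param rule a `screening_rule`.
#' @return data frame: `q1`..`q7` plus logical `positive`; 128 rows.
#' @export
rule_truth_table <- function(rule) {
  pats <- answer_patterns()
  data.frame(pats, positive = evaluate_rule(rule, pats))
}

# ---- JSON rule files --------------------------------------------------

rule_to_list <- function(rule) {
  if (inherits(rule, "boolean_rule")) {
    list(type = "boolean", name = rule$name, expr = rule$expr)
  } else {
    list(type = "logistic", name = rule$name,
         coef = as.list(rule$coefficients), intercept = rule$intercept,
         cutoff = rule$cutoff, strict = rule$strict,
         q7_override = rule$q7_override)
  }
}

rule_from_list <- function(x) {
  if (is.null(x$type)) stop("rule definition lacks a 'type' field")
  if (x$type == "boolean") {
    boolean_rule(x$expr, name = x$name %||% "custom")
  } else if (x$type == "logistic") {
    logistic_rule(unlist(x$coef), intercept = x$intercept,
                  cutoff = x$cutoff %||% 0.849,
                  strict = x$strict %||% TRUE,
                  q7_override = x$q7_override %||% TRUE,
                  name = x$name %||% "logistic")
  } else {
    stop("unknown rule type: ", x$type)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a rule definition file
#'
#' Rules serialize to JSON: boolean expressions as nested
#' `{"and":[...]}`/`{"or":[...]}`/`{"q":n}` nodes, logistic rules as
#' coefficient maps with `intercept`, `cutoff`, `strict`, `q7_override`.
#'
#' @param path file path.
#' @return `read_rule()` returns a `screening_rule`; `write_rule()`
#'   returns `path` invisibly.
#' @export
read_rule <- function(path) {
  rule_from_list(jsonlite::fromJSON(path, simplifyVector = FALSE))
}

#' @rdname read_rule
#' @param rule a `screening_rule`.
#' @export
write_rule <- function(rule, path) {
  stopifnot(inherits(rule, "screening_rule"))
  jsonlite::write_json(rule_to_list(rule), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.boolean_rule <- function(x, ...) {
  cat("eCEQ boolean rule '", x$name, "': ", node_to_text(x$expr), "\n",
      sep = "")
  invisible(x)
}

#' @export
print.logistic_rule <- function(x, ...) {
  terms <- paste0(sprintf("%.3f", x$coefficients), "*",
                  toupper(names(x$coefficients)), collapse = " + ")
  cat("eCEQ logistic rule '", x$name, "':\n", sep = "")
  cat("  score y =", terms, sprintf("%+.3f", x$intercept), "\n")
  cat("  positive when plogis(y) ", if (x$strict) ">" else ">=", " ",
      x$cutoff, if (x$q7_override) ", or Q7 yes", "\n", sep = "")
  invisible(x)
}
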