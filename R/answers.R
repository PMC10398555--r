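# Answer vectors: the seven boolean eCEQ responses per respondent.
# Q1 allergic family history, Q2 recurrent red rash/eczema, Q3 dry skin,
# Q4 itching, Q5 sites affected within 1 week, Q6 sites affected within
# 6 months, Q7 previous doctor's diagnosis of AD.

#' Question identifiers of the eCEQ
#'
#' The seven item identifiers, in instrument order.
#'
#' @return Character vector `c("q1", ..., "q7")`.
#' @export
eceq_questions <- function() paste0("q", 1:7)

#' Coerce yes/no style input to logical
#'
#' Accepts logical, 0/1 numeric, or character codings (`"yes"/"no"`,
#' `"y"/"n"`, `"true"/"false"`, `"1"/"0"`, case-insensitive). Anything
#' else becomes `NA`.
#'
#' @param x vector to coerce.
#' @return Logical vector of the same length.
#' @export
parse_yesno <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    bad <- !is.na(x) & !(x %in% c(0, 1))
    if (any(bad)) {
      stop("numeric answers must be coded 0/1; found: ",
           paste(unique(x[bad]), collapse = ", "))
    }
    return(x == 1)
  }
  v <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("yes", "y", "true", "t", "1")] <- TRUE
  out[v %in% c("no", "n", "false", "f", "0")] <- FALSE
  out
}

#' Validate and extract an answer matrix
#'
#' Extracts the columns `q1`..`q7` (case-insensitive) from a data frame or
#' matrix and returns an n x 7 logical matrix. Each answer must be strictly
#' yes or no; missing answers are rejected unless `allow_na = TRUE`
#' (cleaning and classification handle incomplete records explicitly).
#'
#' @param x data frame or matrix with columns `q1`..`q7`.
#' @param allow_na keep `NA` answers instead of erroring.
#' @return Logical matrix with columns `q1`..`q7`.
#' @export
as_answer_matrix <- function(x, allow_na = FALSE) {
  if (is.matrix(x)) x <- as.data.frame(x)
  if (!is.data.frame(x)) stop("answers must be a data frame or matrix")
  names(x) <- tolower(names(x))
  qs <- eceq_questions()
  missing_cols <- setdiff(qs, names(x))
  if (length(missing_cols)) {
    stop("missing answer columns: ", paste(missing_cols, collapse = ", "))
  }
  cols <- lapply(qs, function(q) parse_yesno(x[[q]]))
  m <- matrix(unlist(cols, use.names = FALSE), nrow = nrow(x), ncol = 7L,
              dimnames = list(NULL, qs))
  storage.mode(m) <- "logical"
  if (!allow_na && anyNA(m)) {
    stop("answers contain missing values in rows: ",
         paste(utils::head(which(rowSums(is.na(m)) > 0), 10), collapse = ", "))
  }
  m
}

#' Enumerate all 128 answer patterns
#'
#' Every combination of the seven yes/no answers, in a fixed order (q1
#' varies fastest). Used for truth tables, analytic operating
#' characteristics and calibration.
#'
#' @return 128 x 7 logical matrix with columns `q1`..`q7`.
#' @export
answer_patterns <- function() {
  g <- expand.grid(rep(list(c(FALSE, TRUE)), 7), KEEP.OUT.ATTRS = FALSE)
  names(g) <- eceq_questions()
  as.matrix(g)
}
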