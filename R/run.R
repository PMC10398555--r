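# End-to-end runner: one config drives clean -> classify ->
# (validate | cascade) -> report writing, with full provenance (config
# hash + seed) so that two runs with the same config are identical.

#' Build a run configuration
#'
#' @param mode `"validate"` (cohort carries a reference diagnosis;
#'   produce a diagnostic report) or `"survey"` (prevalence and, when the
#'   awareness flag is present, the awareness cascade).
#' @param rule built-in rule name (see [eceq_rule()]) or path to a rule
#'   JSON file.
#' @param input path to a cohort CSV; `NULL` to simulate instead.
#' @param simulate_n cohort size when simulating (phase-1-style
#'   calibrated model).
#' @param max_age_months cleaning age bound.
#' @param seed seed for every source of randomness in the run.
#' @param out_dir directory for report files; `NULL` writes nothing.
#' @return Object of class `run_config`. Unknown rule names are rejected
#'   here, at load time. The config round-trips through JSON unchanged.
#' @export
run_config <- function(mode = c("validate", "survey"), rule = "rule3",
                       input = NULL, simulate_n = 195L,
                       max_age_months = 24, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.character(rule) && !file.exists(rule)) {
    builtin <- c("rule1", "rule2", "rule3", "rule4", "rule4_alt")
    if (!rule %in% builtin) {
      stop("unknown rule '", rule, "'; built-ins are: ",
           paste(builtin, collapse = ", "))
    }
  }
  structure(list(mode = mode, rule = rule, input = input,
                 simulate_n = as.integer(simulate_n),
                 max_age_months = as.numeric(max_age_months),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration as JSON
#'
#' @param path JSON file path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, x[!vapply(x, is.null, TRUE)])
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  write_run_config(config, tmp)
  unname(tools::md5sum(tmp))
}

resolve_rule <- function(rule) {
  if (inherits(rule, "screening_rule")) return(rule)
  if (file.exists(rule)) read_rule(rule) else eceq_rule(rule)
}

#' Run the full pipeline from a configuration
#'
#' Loads (or simulates) a cohort, cleans it, classifies it with the
#' configured rule, and — depending on the mode — validates against the
#' reference diagnosis or builds the prevalence/awareness report. All
#' randomness derives from `config$seed`; the returned bundle (and any
#' files written) embed the config hash and seed for provenance.
#'
#' @param config a [run_config()].
#' @return List (invisibly if `out_dir` is set): `config`, `hash`,
#'   `cleaning`, `classification`, and `validation` or `cascade` as
#'   applicable.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  rule <- resolve_rule(config$rule)
  records <- if (!is.null(config$input)) {
    if (!file.exists(config$input)) {
      stop("input file not found: ", config$input)
    }
    read_cohort(config$input)
  } else {
    generate_cohort(phase1_cohort_model(n = config$simulate_n,
                                        seed = config$seed))
  }
  cleaned <- clean_cohort(records, max_age_months = config$max_age_months)
  if (nrow(cleaned$records) == 0L) {
    warning("no records retained after cleaning; reports will be empty",
            call. = FALSE)
  }
  cls <- classify_cohort(cleaned$records, rule)
  bundle <- list(config = config, hash = config_hash(config),
                 cleaning = cleaned$report, classification = cls)
  refs <- parse_yesno(cleaned$records$reference)
  if (config$mode == "validate") {
    if (nrow(cleaned$records) > 0L && !anyNA(refs)) {
      bundle$validation <- validate_against_reference(cleaned$records, rule)
    } else {
      warning("validation skipped: reference diagnosis missing",
              call. = FALSE)
    }
  } else {
    bundle$cascade <- awareness_cascade(cleaned$records, cls)
  }
  if (!is.null(config$out_dir)) {
    write_bundle(bundle, cleaned$records, config$out_dir)
    return(invisible(bundle))
  }
  bundle
}

write_bundle <- function(bundle, records, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  write_cohort(records, pth("cleaned.csv"))
  cls_df <- data.frame(id = records$id,
                       positive = bundle$classification$positive)
  utils::write.csv(cls_df, pth("classification.csv"), row.names = FALSE)
  provenance <- list(hash = bundle$hash, seed = bundle$config$seed,
                     config = unclass(bundle$config))
  out <- list(provenance = provenance,
              cleaning = unclass(bundle$cleaning),
              classification = unclass(bundle$classification))
  if (!is.null(bundle$validation)) {
    out$validation <- unclass(bundle$validation)
  }
  if (!is.null(bundle$cascade)) out$cascade <- unclass(bundle$cascade)
  jsonlite::write_json(out, pth("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null",
                       force = TRUE)
  invisible(out_dir)
}
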