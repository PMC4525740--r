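# Study drivers tying the stages together: forms -> screen -> group model
# -> report.  Each returns a small integer status (0 = success,
# 2 = validation failure, 3 = no consistent respondents), the contract the
# analysis scripts rely on.

#' Run configuration for the study pipeline
#'
#' @param forms Path to the forms CSV.
#' @param out Path for the report.
#' @param hierarchy Optional path to a hierarchy config; the packaged
#'   five-criterion hierarchy by default.
#' @param threshold CR acceptance threshold, in (0, 1].
#' @param method Prioritization method for the group weights.
#' @param format Report format: `"json"`, `"tsv"` or `"md"`.
#' @param strict Abort on malformed form rows (`TRUE`) or skip them with a
#'   warning (`FALSE`).
#' @param quiet Suppress progress messages.
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(forms, out, hierarchy = NULL, threshold = NULL,
                       method = NULL, format = "json", strict = TRUE,
                       quiet = FALSE) {
  structure(list(forms = forms, out = out, hierarchy = hierarchy,
                 threshold = threshold, method = method, format = format,
                 strict = strict, quiet = quiet),
            class = "run_config")
}

#' Execute the full study pipeline
#'
#' Reads the forms, screens respondents at the CR threshold, builds the
#' median group model and writes the report.  Logs the cohort size, the
#' number of consistent respondents, the group CR and the top criterion.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `status` (0 success, 2 validation
#'   failure, 3 no consistent respondents) and, on success, the
#'   `"cohort_result"`.
#' @export
cmd_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  say <- if (isTRUE(config$quiet)) function(...) invisible() else message
  res <- tryCatch({
    hier <- if (is.null(config$hierarchy)) default_hierarchy()
            else read_hierarchy(config$hierarchy)
    threshold <- if (is.null(config$threshold)) hier$threshold
                 else config$threshold
    if (threshold <= 0 || threshold > 1) {
      stop("invalid threshold: must lie in (0, 1]")
    }
    method <- if (is.null(config$method)) hier$method else config$method
    records <- read_forms(config$forms, hierarchy = hier,
                          strict = config$strict)
    if (length(records) == 0) stop("no usable respondent rows in ", config$forms)
    study <- withCallingHandlers(
      run_study(records, threshold = threshold, method = method),
      warning = function(w) invokeRestart("muffleWarning"))
    write_report(study, config$out, format = config$format)
    study
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(list(status = 2L, result = NULL)))
  }
  say(sprintf("respondents: %d, consistent: %d (%.1f%%)",
              res$n_total, res$n_consistent, 100 * res$fraction_consistent))
  if (res$no_consistent) {
    message("warning: no respondent passed the consistency screen")
    return(invisible(list(status = 3L, result = res)))
  }
  say(sprintf("group CR = %.4f; top criterion: %s (%.3f)",
              res$group_report$cr, res$ranking$label[1], res$ranking$weight[1]))
  say(sprintf("report written to %s", config$out))
  invisible(list(status = 0L, result = res))
}

#' Consistency check of a single matrix file
#'
#' Reads a comparison-matrix CSV and prints its consistency report
#' (lambda_max, CI, RI, CR at 4 decimals, and the verdict).
#'
#' @param path Path to the matrix CSV.
#' @param hierarchy Optional path to a hierarchy config the labels must
#'   match.
#' @param threshold CR acceptance threshold.
#' @return Invisibly, a list with `status` (0 or 2) and the
#'   `"consistency_report"` on success.
#' @export
cmd_consistency <- function(path, hierarchy = NULL, threshold = 0.10) {
  res <- tryCatch({
    hier <- if (is.null(hierarchy)) NULL else read_hierarchy(hierarchy)
    consistency(read_matrix(path, hierarchy = hier), threshold = threshold)
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(list(status = 2L, report = NULL)))
  }
  print(res)
  invisible(list(status = 0L, report = res))
}

#' Simulate a survey forms file
#'
#' Writes a forms CSV in the schema [read_forms()] expects, either from a
#' freshly generated cohort ([generate_cohort()]) or, with
#' `preset = "reference"`, from the packaged deterministic 96-respondent
#' cohort ([fp_cohort_fixture()]).
#'
#' @param out Output CSV path.
#' @param n Cohort size.
#' @param true_weights Weight vector the cohort judges around; defaults to
#'   the eigenvector weights of [fp_group_matrix()].
#' @param mixture Noise mixture; [default_mixture()] by default.
#' @param sigma Optional shortcut: a single noise sigma replacing the
#'   mixture.
#' @param seed Integer seed; identical seeds give byte-identical files.
#' @param preset `NULL` or `"reference"`.
#' @return Invisibly, a list with `status` (0 or 2) and the records
#'   written.
#' @export
cmd_simulate <- function(out, n = 96, true_weights = NULL,
                         mixture = default_mixture(), sigma = NULL,
                         seed = 1L, preset = NULL) {
  res <- tryCatch({
    if (!is.null(preset)) {
      if (!identical(preset, "reference")) stop("unknown preset: ", preset)
      records <- fp_cohort_fixture()
    } else {
      if (length(n) != 1L || is.na(n) || n < 1) {
        stop("invalid cohort size: n must be a positive integer")
      }
      if (is.null(true_weights)) true_weights <- priorities(fp_group_matrix())
      if (!is.null(sigma)) mixture <- list(list(prop = 1,
                                                model = noise_model(sigma)))
      records <- generate_cohort(n, true_weights, mixture = mixture,
                                 seed = seed)
    }
    write_forms(records, out)
    records
  }, error = function(e) e)
  if (inherits(res, "error")) {
    message("error: ", conditionMessage(res))
    return(invisible(list(status = 2L, records = NULL)))
  }
  invisible(list(status = 0L, records = res))
}
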