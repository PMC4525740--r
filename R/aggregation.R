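# Cohort-level pipeline: CR screening and the median group model.

#' Create a respondent record
#'
#' Bundles one respondent's comparison matrix with its consistency report
#' and optional demographics.
#'
#' @param id Respondent identifier, unique within a cohort.
#' @param a Comparison matrix.
#' @param threshold CR acceptance threshold used for the report.
#' @param demographics Optional named list of demographic values.
#' @return Object of class `"respondent_record"`.
#' @export
respondent_record <- function(id, a, threshold = 0.10, demographics = NULL) {
  structure(list(id = as.character(id),
                 matrix = a,
                 report = consistency(a, threshold = threshold),
                 demographics = demographics),
            class = "respondent_record")
}

#' Screen respondents by consistency ratio
#'
#' Partitions a cohort into the respondents whose CR is strictly below the
#' threshold and the rest, preserving input order within each part.
#'
#' @param records List of [respondent_record()] objects.
#' @param threshold CR acceptance threshold.
#' @return List with elements `consistent` and `inconsistent`.
#' @export
screen <- function(records, threshold = 0.10) {
  if (length(records) == 0) stop("empty cohort: no respondent records")
  ok <- vapply(records, function(r) r$report$cr < threshold, logical(1))
  list(consistent = records[ok], inconsistent = records[!ok])
}

#' Aggregate comparison matrices by the element-wise log median
#'
#' For each unordered criterion pair the group entry is
#' `exp(median(log a_ij))` across respondents; the lower triangle is filled
#' by reciprocity and the diagonal is 1.  Taking the median on the log
#' scale makes aggregation direction-invariant (aggregating the a_ji
#' entries gives exactly the reciprocal matrix): for an odd number of
#' matrices it coincides with the plain median of the judgments, and for
#' an even number the midpoint of the two central logs is the geometric
#' mean of the two central judgments.
#'
#' @param matrices Non-empty list of comparison matrices over the same
#'   criteria, in the same order.
#' @return The group comparison matrix.
#' @export
median_aggregate <- function(matrices) {
  if (length(matrices) == 0) stop("empty cohort: no matrices to aggregate")
  ref <- matrices[[1]]
  validate_comparison_matrix(ref)
  n <- nrow(ref)
  for (m in matrices[-1]) {
    validate_comparison_matrix(m)
    if (nrow(m) != n || !identical(dimnames(m), dimnames(ref))) {
      stop("heterogeneous cohort: matrices must share one criterion set")
    }
  }
  g <- diag(n)
  dimnames(g) <- dimnames(ref)
  k <- length(matrices)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      # median on the log scale; for odd k this is an observed judgment and
      # is returned bit-exactly, for even k the geometric mean of the two
      # central judgments
      vals <- sort(vapply(matrices, function(m) m[i, j], numeric(1)))
      v <- if (k %% 2 == 1) vals[(k + 1) / 2]
           else sqrt(vals[k / 2] * vals[k / 2 + 1])
      g[i, j] <- v
      g[j, i] <- 1 / v
    }
  }
  g
}

#' Run the cohort study pipeline
#'
#' Screens the cohort at the CR threshold, aggregates the consistent
#' respondents' matrices into the median group model, and derives the
#' group priority vector (principal eigenvector), its consistency report
#' and the criterion ranking.  If no respondent is consistent the group
#' fields are absent and the result carries a warning flag.
#'
#' @param records List of [respondent_record()] objects.
#' @param threshold CR acceptance threshold.
#' @param method Prioritization method for the group weights
#'   (`"eigenvector"` default; the group consistency report is always the
#'   eigenvector chain).
#' @return Object of class `"cohort_result"`: a list with `records`,
#'   `n_total`, `n_consistent`, `fraction_consistent`, `group_matrix`,
#'   `group_weights`, `group_report`, `ranking` and `no_consistent`
#'   (logical warning flag).
#' @export
run_study <- function(records, threshold = 0.10,
                      method = c("eigenvector", "geometric_mean")) {
  method <- match.arg(method)
  parts <- screen(records, threshold = threshold)
  n_total <- length(records)
  n_cons <- length(parts$consistent)
  res <- list(records = records,
              n_total = n_total,
              n_consistent = n_cons,
              fraction_consistent = n_cons / n_total,
              group_matrix = NULL, group_weights = NULL,
              group_report = NULL, ranking = NULL,
              no_consistent = n_cons == 0,
              threshold = threshold)
  if (n_cons == 0) {
    warning("no respondent passed the consistency screen; no group model computed")
  } else {
    g <- median_aggregate(lapply(parts$consistent, `[[`, "matrix"))
    res$group_matrix <- g
    res$group_report <- consistency(g, threshold = threshold)
    res$group_weights <- if (method == "eigenvector") res$group_report$weights
                         else priorities(g, method = method)
    res$ranking <- rank_criteria(res$group_weights)
  }
  structure(res, class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(sprintf("AHP cohort study: %d respondents, %d consistent (%.1f%%) at CR < %.2f\n",
              x$n_total, x$n_consistent, 100 * x$fraction_consistent,
              x$threshold))
  if (x$no_consistent) {
    cat("  WARNING: no consistent respondents; no group model\n")
  } else {
    cat(sprintf("  group model: lambda_max = %.4f, CR = %.4f (%s)\n",
                x$group_report$lambda_max, x$group_report$cr,
                if (x$group_report$consistent) "consistent" else "inconsistent"))
    cat("  ranking:\n")
    r <- x$ranking
    for (k in seq_len(nrow(r))) {
      cat(sprintf("    %d. %s  %.3f\n", r$rank[k], r$label[k], r$weight[k]))
    }
  }
  invisible(x)
}

#' Demographic frequency table for a cohort
#'
#' Counts and percentages per demographic characteristic, over the
#' respondents with a non-missing value for that characteristic.
#'
#' @param records List of [respondent_record()] objects.
#' @return Data frame with columns `characteristic`, `category`, `n`,
#'   `percent`.  Empty (with a warning) when no record carries
#'   demographics.
#' @export
demographic_summary <- function(records) {
  if (length(records) == 0) stop("empty cohort: no respondent records")
  demo <- lapply(records, `[[`, "demographics")
  keys <- unique(unlist(lapply(demo, names)))
  out <- data.frame(characteristic = character(0), category = character(0),
                    n = integer(0), percent = numeric(0),
                    stringsAsFactors = FALSE)
  if (length(keys) == 0) {
    warning("no demographics present in cohort")
    return(out)
  }
  for (k in keys) {
    vals <- unlist(lapply(demo, function(d) {
      v <- d[[k]]
      if (is.null(v) || is.na(v)) NULL else as.character(v)
    }))
    if (length(vals) == 0) next
    tab <- table(vals)
    out <- rbind(out, data.frame(characteristic = k,
                                 category = names(tab),
                                 n = as.integer(tab),
                                 percent = 100 * as.integer(tab) / length(vals),
                                 stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}
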