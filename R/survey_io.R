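# Readers and writers: hierarchy configs, survey forms, comparison
# matrices (with exact fraction round-trips) and study reports.

#' Read a hierarchy configuration
#'
#' Loads a goal + ordered criterion list from JSON (`.json`) or YAML
#' (`.yml`/`.yaml`), applying defaults for the CR threshold (0.10) and
#' prioritization method (`"eigenvector"`).
#'
#' @param path Path to the config file.
#' @return Object of class `"hierarchy_config"`: a list with `goal`,
#'   `criteria`, optional `descriptions`, `threshold`, `method`.
#' @export
read_hierarchy <- function(path) {
  if (!file.exists(path)) stop("hierarchy config not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  crit <- as.character(cfg$criteria)
  if (length(crit) < 2) stop("invalid hierarchy: field 'criteria' needs at least 2 entries")
  if (anyDuplicated(crit)) stop("invalid hierarchy: field 'criteria' has duplicate labels")
  if (any(!nzchar(crit))) stop("invalid hierarchy: field 'criteria' has empty labels")
  threshold <- if (is.null(cfg$threshold)) 0.10 else as.numeric(cfg$threshold)
  if (length(threshold) != 1L || is.na(threshold) || threshold <= 0 || threshold > 1) {
    stop("invalid hierarchy: field 'threshold' must lie in (0, 1]")
  }
  method <- if (is.null(cfg$method)) "eigenvector" else as.character(cfg$method)
  if (!method %in% c("eigenvector", "geometric_mean")) {
    stop("invalid hierarchy: field 'method' must be 'eigenvector' or 'geometric_mean'")
  }
  structure(list(goal = if (is.null(cfg$goal)) "" else as.character(cfg$goal),
                 criteria = crit,
                 descriptions = cfg$descriptions,
                 threshold = threshold,
                 method = method),
            class = "hierarchy_config")
}

#' The packaged default hierarchy
#'
#' The five-criterion family-physician selection hierarchy shipped with
#' the package.
#'
#' @return A `"hierarchy_config"` (see [read_hierarchy()]).
#' @export
default_hierarchy <- function() {
  read_hierarchy(system.file("extdata", "fp_hierarchy.json",
                             package = "ahpcohort", mustWork = TRUE))
}

# Column-name convention of the forms CSV: one winner + one intensity
# column per unordered pair, in hierarchy order.
pair_columns <- function(labels) {
  n <- length(labels)
  pairs <- utils::combn(n, 2)
  data.frame(i = pairs[1, ], j = pairs[2, ],
             winner = paste0(labels[pairs[1, ]], "_vs_", labels[pairs[2, ]],
                             "_winner"),
             intensity = paste0(labels[pairs[1, ]], "_vs_", labels[pairs[2, ]],
                                "_intensity"),
             stringsAsFactors = FALSE)
}

#' Read survey forms into respondent records
#'
#' Parses a forms CSV (UTF-8, comma separated) with one row per
#' respondent.  For every unordered criterion pair, in hierarchy order,
#' the file must carry the columns `<A>_vs_<B>_winner` (one of the two
#' labels or `"equal"`) and `<A>_vs_<B>_intensity` (integer 1..9; 1 when
#' the winner is `"equal"`).  An optional `respondent_id` column names the
#' respondents (row numbers otherwise); any remaining columns are kept as
#' demographics.
#'
#' @param path Path to the CSV file.
#' @param hierarchy A `"hierarchy_config"`; defaults to the packaged one.
#' @param strict If `TRUE` (default) any malformed row aborts with all
#'   collected row errors; if `FALSE` malformed rows are skipped with a
#'   warning.
#' @return List of [respondent_record()] objects.
#' @export
read_forms <- function(path, hierarchy = default_hierarchy(), strict = TRUE) {
  if (!file.exists(path)) stop("forms file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        encoding = "UTF-8")
  labels <- hierarchy$criteria
  pc <- pair_columns(labels)
  miss <- setdiff(c(pc$winner, pc$intensity), names(df))
  if (length(miss) > 0) {
    stop("forms file is missing pair column(s): ", paste(miss, collapse = ", "))
  }
  has_id <- "respondent_id" %in% names(df)
  demo_cols <- setdiff(names(df), c("respondent_id", pc$winner, pc$intensity))
  records <- list()
  errors <- character(0)
  for (r in seq_len(nrow(df))) {
    id <- if (has_id) as.character(df$respondent_id[r]) else sprintf("row_%d", r)
    row_err <- character(0)
    jd <- data.frame(i = pc$i, j = pc$j,
                     preferred = NA_character_, intensity = NA_integer_,
                     stringsAsFactors = FALSE)
    for (k in seq_len(nrow(pc))) {
      win <- as.character(df[[pc$winner[k]]][r])
      s <- suppressWarnings(as.numeric(df[[pc$intensity[k]]][r]))
      a_lab <- labels[pc$i[k]]
      b_lab <- labels[pc$j[k]]
      if (is.na(win) || !win %in% c(a_lab, b_lab, "equal")) {
        row_err <- c(row_err, sprintf(
          "row %d (%s): unknown winner '%s' for pair (%s, %s)",
          r, id, win, a_lab, b_lab))
        next
      }
      if (is.na(s) || s != as.integer(s) || s < 1 || s > 9) {
        row_err <- c(row_err, sprintf(
          "row %d (%s): invalid scale value '%s' for pair (%s, %s); intensity must be an integer in 1..9",
          r, id, df[[pc$intensity[k]]][r], a_lab, b_lab))
        next
      }
      if (win == "equal" && s != 1) {
        row_err <- c(row_err, sprintf(
          "row %d (%s): equal implies intensity 1 for pair (%s, %s), got %d",
          r, id, a_lab, b_lab, as.integer(s)))
        next
      }
      jd$preferred[k] <- if (win == "equal") "equal"
                         else if (win == a_lab) "first" else "second"
      jd$intensity[k] <- as.integer(s)
    }
    if (length(row_err) > 0) {
      errors <- c(errors, row_err)
      next
    }
    demo <- if (length(demo_cols) > 0) as.list(df[r, demo_cols, drop = FALSE])
            else NULL
    records[[length(records) + 1L]] <-
      respondent_record(id, matrix_from_judgments(jd, labels),
                        threshold = hierarchy$threshold,
                        demographics = demo)
  }
  if (length(errors) > 0) {
    msg <- paste(errors, collapse = "\n  ")
    if (strict) stop("malformed form rows:\n  ", msg)
    warning(sprintf("skipped %d malformed row(s):\n  %s",
                    length(unique(sub(":.*", "", errors))), msg))
  }
  records
}

#' Write respondent records as a forms CSV
#'
#' The inverse of [read_forms()]: serializes each record's matrix as
#' winner/intensity pair columns (plus `respondent_id` and any demographic
#' columns).  Every upper-triangle entry must be a Saaty scale value, as
#' on a real form.
#'
#' @param records List of [respondent_record()] objects over one criterion
#'   set.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_forms <- function(records, path) {
  stopifnot(length(records) >= 1)
  labels <- rownames(records[[1]]$matrix)
  pc <- pair_columns(labels)
  demo_keys <- unique(unlist(lapply(records, function(r) names(r$demographics))))
  rows <- lapply(records, function(rec) {
    a <- rec$matrix
    out <- list(respondent_id = rec$id)
    for (k in seq_len(nrow(pc))) {
      v <- a[pc$i[k], pc$j[k]]
      s <- if (v >= 1) v else 1 / v
      if (abs(s - round(s)) > 1e-9 || round(s) > 9) {
        stop(sprintf(
          "matrix of respondent '%s' is not representable on the Saaty form scale at pair (%s, %s): %g",
          rec$id, labels[pc$i[k]], labels[pc$j[k]], v))
      }
      out[[pc$winner[k]]] <- if (abs(v - 1) < 1e-12) "equal"
                             else if (v > 1) labels[pc$i[k]] else labels[pc$j[k]]
      out[[pc$intensity[k]]] <- as.integer(round(s))
    }
    for (d in demo_keys) {
      val <- rec$demographics[[d]]
      out[[d]] <- if (is.null(val)) NA else val
    }
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Exact serialization of ratio values: Saaty fractions as "1/3" etc.,
# integers bare, everything else at full double precision.
format_ratio <- function(x) {
  vapply(x, function(v) {
    if (abs(v - round(v)) < 1e-12) return(as.character(as.integer(round(v))))
    inv <- 1 / v
    if (abs(inv - round(inv)) < 1e-12) {
      return(paste0("1/", as.integer(round(inv))))
    }
    format(v, digits = 17)
  }, character(1))
}

parse_ratio <- function(s) {
  s <- trimws(s)
  frac <- grepl("^[0-9]+\\s*/\\s*[0-9]+$", s)
  out <- suppressWarnings(as.numeric(s))
  for (k in which(frac)) {
    parts <- as.numeric(strsplit(s[k], "/")[[1]])
    out[k] <- parts[1] / parts[2]
  }
  if (any(is.na(out))) {
    stop("not a valid comparison matrix: unparseable cell value '",
         s[which(is.na(out))[1]], "'")
  }
  out
}

#' Write a comparison matrix to CSV
#'
#' Writes the matrix with criterion labels as both header row and first
#' column.  Saaty fractions are serialized as exact fraction strings
#' (`"1/3"`), so reading the file back reproduces the matrix bit for bit.
#'
#' @param a Comparison matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(a, path) {
  validate_comparison_matrix(a)
  labels <- rownames(a)
  lines <- c(paste(c("criterion", labels), collapse = ","),
             vapply(seq_len(nrow(a)), function(i) {
               paste(c(labels[i], format_ratio(a[i, ])), collapse = ",")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a comparison matrix from CSV
#'
#' Parses a matrix CSV as written by [write_matrix()].  Cells may be
#' fraction strings (parsed exactly) or decimals; a decimal within
#' relative 1e-6 of a Saaty scale value is normalized to the exact
#' fraction (accommodating hand-entered approximations like
#' `0.3333333333`), other decimals are kept as given.  The file must
#' describe a positive reciprocal matrix with unit diagonal; after
#' validation the lower triangle is rebuilt as exact reciprocals of the
#' upper.
#'
#' @param path Path to the matrix CSV.
#' @param hierarchy Optional `"hierarchy_config"`; when given, the file's
#'   labels must match `hierarchy$criteria` in order.
#' @return A comparison matrix.
#' @export
read_matrix <- function(path, hierarchy = NULL) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character", encoding = "UTF-8")
  labels <- as.character(df[[1]])
  if (!identical(names(df)[-1], labels)) {
    stop("not a valid comparison matrix: header labels and row labels disagree")
  }
  if (!is.null(hierarchy) && !identical(labels, hierarchy$criteria)) {
    stop("matrix labels do not match the hierarchy criteria")
  }
  n <- length(labels)
  a <- matrix(NA_real_, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) a[i, ] <- parse_ratio(as.character(df[i, -1]))
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("not a valid comparison matrix: entries must be finite and positive")
  }
  # normalize near-scale decimals to the exact fraction
  ladder <- saaty_scale()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      d <- abs(a[i, j] - ladder) / ladder
      if (min(d) < 1e-6) a[i, j] <- ladder[which.min(d)]
    }
  }
  if (any(diag(a) != 1)) {
    stop("not a valid comparison matrix: diagonal entries must equal 1")
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(a[i, j] * a[j, i] - 1) > 1e-6) {
        stop(sprintf(
          "not a valid comparison matrix: reciprocity fails at cell (%s, %s): %s vs %s",
          labels[i], labels[j], format(a[i, j]), format(a[j, i])))
      }
      a[j, i] <- 1 / a[i, j]
    }
  }
  a
}

# Group block of a serialized report, shared by the three formats.
report_group_block <- function(result) {
  if (result$no_consistent) return(NULL)
  g <- result$group_matrix
  list(matrix = lapply(seq_len(nrow(g)),
                       function(i) as.list(stats::setNames(format_ratio(g[i, ]),
                                                           colnames(g)))),
       weights = as.list(round(stats::setNames(as.numeric(result$group_weights),
                                               names(result$group_weights)), 6)),
       lambda_max = round(result$group_report$lambda_max, 6),
       ci = round(result$group_report$ci, 6),
       ri = result$group_report$ri,
       cr = round(result$group_report$cr, 6),
       consistent = result$group_report$consistent,
       ranking = lapply(seq_len(nrow(result$ranking)), function(k) {
         list(label = result$ranking$label[k],
              weight = round(result$ranking$weight[k], 6),
              rank = result$ranking$rank[k])
       }))
}

#' Write a cohort study report
#'
#' Serializes a [run_study()] result deterministically (fixed field order
#' and decimal places, so repeated runs are byte-identical) as JSON, TSV
#' or Markdown.
#'
#' @param result A `"cohort_result"`.
#' @param path Output path.
#' @param format One of `"json"`, `"tsv"`, `"md"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("json", "tsv", "md")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "cohort_result"))
  resp <- lapply(result$records, function(r) {
    list(id = r$id, cr = round(r$report$cr, 6), consistent = r$report$consistent)
  })
  if (format == "json") {
    obj <- list(cohort = list(n_total = result$n_total,
                              n_consistent = result$n_consistent,
                              fraction_consistent =
                                round(result$fraction_consistent, 6),
                              threshold = result$threshold),
                respondents = resp)
    if (result$no_consistent) {
      obj$warning <- "no respondent passed the consistency screen; no group model"
    } else {
      obj$group <- report_group_block(result)
    }
    jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  } else if (format == "tsv") {
    lines <- c(sprintf("# n_total\t%d", result$n_total),
               sprintf("# n_consistent\t%d", result$n_consistent),
               sprintf("# fraction_consistent\t%.6f", result$fraction_consistent))
    if (result$no_consistent) {
      lines <- c(lines, "# warning\tno consistent respondents; no group model",
                 "label\tweight\trank")
    } else {
      lines <- c(lines,
                 sprintf("# group_cr\t%.6f", result$group_report$cr),
                 "label\tweight\trank",
                 sprintf("%s\t%.6f\t%d", result$ranking$label,
                         result$ranking$weight, result$ranking$rank))
    }
    writeLines(lines, path, useBytes = TRUE)
  } else {
    lines <- c("# AHP cohort study report", "",
               sprintf("- respondents: %d", result$n_total),
               sprintf("- consistent (CR < %.2f): %d (%.1f%%)",
                       result$threshold, result$n_consistent,
                       100 * result$fraction_consistent))
    if (result$no_consistent) {
      lines <- c(lines, "",
                 "**Warning: no respondent passed the consistency screen; no group model.**")
    } else {
      lines <- c(lines,
                 sprintf("- group model: lambda_max = %.4f, CI = %.4f, RI = %.2f, CR = %.4f (%s)",
                         result$group_report$lambda_max, result$group_report$ci,
                         result$group_report$ri, result$group_report$cr,
                         if (result$group_report$consistent) "consistent"
                         else "inconsistent"),
                 "", "| rank | criterion | weight |", "|---|---|---|",
                 sprintf("| %d | %s | %.3f |", result$ranking$rank,
                         result$ranking$label, result$ranking$weight))
    }
    writeLines(lines, path, useBytes = TRUE)
  }
  invisible(path)
}
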