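# Core AHP mathematics: comparison matrices, priority vectors, consistency.

#' The Saaty judgment scale
#'
#' The admissible values of a pairwise-comparison matrix entry: the integer
#' intensities 1..9 (1 = equal importance, 3 = moderate, 5 = strong,
#' 7 = very strong, 9 = extreme, with 2, 4, 6, 8 as intermediate values)
#' and their reciprocals for the reverse direction.
#'
#' @return Numeric vector of the 17 scale values, increasing from 1/9 to 9.
#' @export
saaty_scale <- function() {
  c(1 / (9:2), 1:9)
}

#' Saaty's random index
#'
#' The expected consistency index of random positive reciprocal matrices of
#' order `n`, used as the denominator of the consistency ratio.  Values for
#' n = 1..10 are Saaty's (1980) table; n = 11..15 come from the extended
#' table.
#'
#' @param n Matrix order, an integer between 1 and 15.
#' @return The random index RI(n).
#' @export
random_index <- function(n) {
  ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49,
          1.51, 1.48, 1.56, 1.57, 1.59)
  if (length(n) != 1L || is.na(n) || n != as.integer(n) || n < 1 || n > 15) {
    stop("unsupported matrix order: n must be an integer in 1..15, got ",
         deparse(substitute(n)), " = ", paste(n, collapse = ", "))
  }
  ri[as.integer(n)]
}

# Internal: validate a positive reciprocal matrix.  Scale bounds (1/9..9)
# are enforced only where judgments enter the system (forms, matrix files),
# not here: consistent matrices w_i/w_j and aggregated matrices may
# legitimately fall outside the discrete scale.
validate_comparison_matrix <- function(a, rtol = 1e-12) {
  if (!is.matrix(a) || !is.numeric(a) || nrow(a) != ncol(a)) {
    stop("not a valid comparison matrix: expected a square numeric matrix")
  }
  n <- nrow(a)
  if (n < 2) stop("not a valid comparison matrix: need at least 2 criteria")
  if (any(!is.finite(a)) || any(a <= 0)) {
    stop("not a valid comparison matrix: entries must be finite and positive")
  }
  if (any(diag(a) != 1)) {
    stop("not a valid comparison matrix: diagonal entries must equal 1")
  }
  rec <- abs(a * t(a) - 1)
  if (any(rec > rtol)) {
    bad <- which(rec == max(rec), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "not a valid comparison matrix: reciprocity fails at cell (%d, %d): a_ij * a_ji = %.15g",
      bad[1], bad[2], a[bad[1], bad[2]] * a[bad[2], bad[1]]))
  }
  invisible(a)
}

#' Build a comparison matrix from pairwise judgments
#'
#' Assembles the n x n positive reciprocal matrix from one directed
#' judgment per unordered pair of criteria.  A judgment names the pair
#' (indices `i < j` into `labels`), which side is preferred (`"first"`,
#' `"second"` or `"equal"`) and the Saaty intensity 1..9.  The matrix entry
#' is the intensity if the row criterion is preferred, its reciprocal if
#' the column criterion is preferred, and 1 for equal preference.
#'
#' @param judgments Data frame with columns `i`, `j` (integer criterion
#'   indices, `i < j`), `preferred` (one of `"first"`, `"second"`,
#'   `"equal"`) and `intensity` (integer 1..9; must be 1 when
#'   `preferred = "equal"`).
#' @param labels Character vector of criterion names fixing row/column
#'   order.
#' @return The comparison matrix with `labels` as dimnames.
#' @export
matrix_from_judgments <- function(judgments, labels) {
  stopifnot(is.data.frame(judgments),
            all(c("i", "j", "preferred", "intensity") %in% names(judgments)))
  n <- length(labels)
  if (n < 2 || n > 15) stop("number of criteria must be in 2..15")
  if (anyDuplicated(labels) || any(!nzchar(labels))) {
    stop("criterion labels must be unique and non-empty")
  }
  i <- as.integer(judgments$i)
  j <- as.integer(judgments$j)
  if (any(is.na(i)) || any(is.na(j)) ||
      any(i < 1) || any(j < 1) || any(i > n) || any(j > n) || any(i >= j)) {
    stop("invalid pair indices: need 1 <= i < j <= ", n)
  }
  key <- paste(i, j)
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1]
    ij <- as.integer(strsplit(d, " ")[[1]])
    stop(sprintf("conflicting judgment: pair (%s, %s) appears more than once",
                 labels[ij[1]], labels[ij[2]]))
  }
  all_pairs <- apply(utils::combn(n, 2), 2, paste, collapse = " ")
  missing <- setdiff(all_pairs, key)
  if (length(missing) > 0) {
    ij <- as.integer(strsplit(missing[1], " ")[[1]])
    stop(sprintf("incomplete form: missing judgment for pair (%s, %s)",
                 labels[ij[1]], labels[ij[2]]))
  }
  s <- judgments$intensity
  if (any(is.na(s)) || any(s != as.integer(s)) || any(s < 1) || any(s > 9)) {
    stop("invalid scale value: intensity must be an integer in 1..9")
  }
  pref <- as.character(judgments$preferred)
  if (!all(pref %in% c("first", "second", "equal"))) {
    stop("preferred must be one of 'first', 'second', 'equal'")
  }
  if (any(pref == "equal" & s != 1)) {
    stop("invalid scale value: equal preference implies intensity 1")
  }
  a <- diag(n)
  dimnames(a) <- list(labels, labels)
  for (k in seq_along(i)) {
    v <- switch(pref[k],
                first  = s[k],
                second = 1 / s[k],
                equal  = 1)
    a[i[k], j[k]] <- v
    a[j[k], i[k]] <- 1 / v
  }
  a
}

#' Priority vector of a comparison matrix
#'
#' Derives normalized criterion weights from a positive reciprocal matrix.
#' The default is the classical principal right eigenvector, computed by
#' power iteration started from the uniform vector, renormalized to sum 1
#' at every step, and stopped when the L1 change between successive
#' iterates falls below `tol`.  The alternative is the row geometric mean
#' (the logarithmic least-squares solution), `w_i` proportional to
#' `prod_j(a_ij)^(1/n)`.  Both agree exactly on consistent matrices.
#'
#' @param a Comparison matrix (square, positive, reciprocal).
#' @param method `"eigenvector"` (default) or `"geometric_mean"`.
#' @param tol Convergence tolerance on the L1 change per power-iteration
#'   step.
#' @param max_iter Iteration cap; positive matrices converge long before
#'   this, so hitting it indicates corrupted input.
#' @return Named numeric vector of weights summing to 1, with the method
#'   recorded in attribute `"method"`.
#' @export
priorities <- function(a, method = c("eigenvector", "geometric_mean"),
                       tol = 1e-12, max_iter = 500) {
  method <- match.arg(method)
  validate_comparison_matrix(a)
  stopifnot(tol > 0, max_iter >= 1)
  n <- nrow(a)
  if (method == "geometric_mean") {
    w <- exp(rowMeans(log(a)))
    w <- w / sum(w)
  } else {
    w <- rep(1 / n, n)
    for (it in seq_len(max_iter)) {
      w_new <- as.vector(a %*% w)
      w_new <- w_new / sum(w_new)
      delta <- sum(abs(w_new - w))
      w <- w_new
      if (delta < tol) break
    }
    if (delta >= tol) {
      stop(sprintf(
        "power iteration failed to converge in %d iterations (last L1 change %.3g)",
        max_iter, delta))
    }
  }
  names(w) <- rownames(a)
  attr(w, "method") <- method
  w
}

#' Principal eigenvalue estimate from a priority vector
#'
#' The mean Rayleigh ratio `mean_i (A w)_i / w_i`.  At the eigenvector
#' fixed point this is exactly the Perron eigenvalue lambda_max; it equals
#' `n` if and only if the matrix is perfectly consistent, and is never
#' below `n` for a reciprocal matrix.
#'
#' @param a Comparison matrix.
#' @param w Strictly positive priority vector for `a`.
#' @return The lambda_max estimate.
#' @export
lambda_max <- function(a, w) {
  validate_comparison_matrix(a)
  w <- as.numeric(w)
  stopifnot(length(w) == nrow(a))
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("degenerate priority vector: all weights must be strictly positive")
  }
  mean(as.vector(a %*% w) / w)
}

#' Consistency report for a comparison matrix
#'
#' Computes the standard AHP consistency chain: eigenvector priorities,
#' lambda_max, consistency index CI = (lambda_max - n)/(n - 1), Saaty's
#' random index RI(n), and the consistency ratio CR = CI/RI.  Judgments are
#' accepted when CR is strictly below the threshold (default 0.10).  For
#' n <= 2 every reciprocal matrix is consistent; RI = 0 and CR is defined
#' as 0.
#'
#' @param a Comparison matrix.
#' @param threshold Acceptance threshold on CR, in (0, 1].
#' @param ... Passed on to [priorities()] (e.g. `tol`, `max_iter`).
#' @return An object of class `"consistency_report"`: a list with
#'   `lambda_max`, `ci`, `ri`, `cr`, `threshold`, `consistent`, the
#'   eigenvector `weights` and the order `n`.
#' @export
consistency <- function(a, threshold = 0.10, ...) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold <= 1)
  w <- priorities(a, method = "eigenvector", ...)
  n <- nrow(a)
  lm <- lambda_max(a, w)
  ci <- (lm - n) / (n - 1)
  ri <- random_index(n)
  cr <- if (ri > 0) ci / ri else 0
  structure(list(lambda_max = lm, ci = ci, ri = ri, cr = cr,
                 threshold = threshold, consistent = cr < threshold,
                 weights = w, n = n),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("AHP consistency report (n = %d)\n", x$n))
  cat(sprintf("  lambda_max = %.4f\n  CI = %.4f\n  RI = %.4f\n  CR = %.4f\n",
              x$lambda_max, x$ci, x$ri, x$cr))
  cat(sprintf("  %s (threshold %.2f)\n",
              if (x$consistent) "CONSISTENT" else "INCONSISTENT", x$threshold))
  invisible(x)
}

#' Rank criteria by priority weight
#'
#' Orders criteria by descending weight.  Tied weights share the smaller
#' rank and are listed alphabetically by label, so output is deterministic.
#'
#' @param w Named priority vector (weights summing to 1).
#' @return Data frame with columns `label`, `weight`, `rank`, in display
#'   order.
#' @export
rank_criteria <- function(w) {
  stopifnot(is.numeric(w), !is.null(names(w)), all(is.finite(w)))
  r <- rank(-as.numeric(w), ties.method = "min")
  ord <- order(-as.numeric(w), names(w))
  data.frame(label = names(w)[ord],
             weight = as.numeric(w)[ord],
             rank = r[ord],
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Synthesize global alternative priorities
#'
#' The second AHP step: combines criterion weights with per-criterion local
#' priorities of `m` alternatives into global priorities, global(k) =
#' sum_c weight(c) * local(c, k).
#'
#' @param criterion_weights Named priority vector over the criteria.
#' @param local_priorities Named list, one element per criterion, each a
#'   named numeric vector of local priorities over the same alternatives,
#'   summing to 1.
#' @return Named numeric vector of global alternative priorities, summing
#'   to 1.
#' @export
synthesize_alternatives <- function(criterion_weights, local_priorities) {
  stopifnot(is.numeric(criterion_weights), !is.null(names(criterion_weights)),
            is.list(local_priorities))
  crit <- names(criterion_weights)
  if (!setequal(names(local_priorities), crit)) {
    stop("inconsistent hierarchy: local priorities must cover exactly the weighted criteria")
  }
  alts <- names(local_priorities[[1]])
  if (is.null(alts)) stop("inconsistent hierarchy: local priorities must be named by alternative")
  global <- numeric(length(alts))
  names(global) <- alts
  for (c_lab in crit) {
    loc <- local_priorities[[c_lab]]
    if (!setequal(names(loc), alts)) {
      stop("inconsistent hierarchy: criterion '", c_lab,
           "' scores a different alternative set")
    }
    if (abs(sum(loc) - 1) > 1e-9) {
      stop("inconsistent hierarchy: local priorities for '", c_lab,
           "' do not sum to 1")
    }
    global <- global + criterion_weights[[c_lab]] * loc[alts]
  }
  global
}
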