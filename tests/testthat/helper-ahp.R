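# Shared test helpers.
#
# eigen_oracle() is the independent route to the priority vector: a dense
# eigendecomposition via base R eigen(), against which the package's power
# iteration is checked.  It must stay independent of the code under test.

eigen_oracle <- function(a) {
  e <- eigen(a)
  k <- which.max(Re(e$values))
  w <- Re(e$vectors[, k])
  w <- w / sum(w)
  list(weights = w, lambda = Re(e$values[k]))
}

# Random positive reciprocal matrix with upper-triangle entries drawn from
# the Saaty scale.
random_reciprocal <- function(n) {
  ladder <- saaty_scale()
  a <- diag(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- sample(ladder, 1)
      a[i, j] <- v
      a[j, i] <- 1 / v
    }
  }
  dimnames(a) <- list(paste0("C", 1:n), paste0("C", 1:n))
  a
}

# Consistent rank-one matrix a_ij = w_i / w_j.
consistent_matrix <- function(w) {
  n <- length(w)
  a <- outer(w, w, "/")
  diag(a) <- 1
  dimnames(a) <- list(paste0("C", 1:n), paste0("C", 1:n))
  a
}

# Judgments data frame encoding the upper triangle of a Saaty-scale matrix.
judgments_from_matrix <- function(a) {
  n <- nrow(a)
  pairs <- combn(n, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    v <- a[i, j]
    if (abs(v - 1) < 1e-12) {
      data.frame(i = i, j = j, preferred = "equal", intensity = 1L)
    } else if (v > 1) {
      data.frame(i = i, j = j, preferred = "first", intensity = as.integer(round(v)))
    } else {
      data.frame(i = i, j = j, preferred = "second", intensity = as.integer(round(1 / v)))
    }
  }))
}

# Frozen oracle values for the reference group matrix (computed once with
# eigen_oracle / the row-geometric-mean closed form).
REF_EIG_WEIGHTS <- c(0.132457, 0.237168, 0.466854, 0.068175, 0.095346)
REF_GEO_WEIGHTS <- c(0.131075, 0.238630, 0.465097, 0.069419, 0.095779)
REF_LAMBDA <- 5.28548890
REF_CR <- 0.063725

# A maximally intransitive 5-criterion judgment cycle (every criterion
# extremely preferred to the next); far beyond any consistency threshold.
cyclic_matrix <- function(labels) {
  n <- length(labels)
  a <- diag(n)
  dimnames(a) <- list(labels, labels)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- if (j == i + 1) 9 else 1 / 9
      a[i, j] <- v
      a[j, i] <- 1 / v
    }
  }
  a
}
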