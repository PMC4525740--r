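test_that("matrices are assembled correctly from pairwise judgments", {
  labels <- fp_criteria()
  jd <- judgments_from_matrix(fp_group_matrix())
  expect_identical(matrix_from_judgments(jd, labels), fp_group_matrix())

  # indifference on every pair gives the all-ones matrix
  eq <- data.frame(i = jd$i, j = jd$j, preferred = "equal", intensity = 1L)
  ones <- matrix_from_judgments(eq, labels)
  expect_true(all(ones == 1))
})

test_that("malformed judgment sets are rejected with specific errors", {
  labels <- fp_criteria()
  jd <- judgments_from_matrix(fp_group_matrix())
  expect_error(matrix_from_judgments(jd[-1, ], labels), "incomplete form")
  expect_error(matrix_from_judgments(rbind(jd, jd[1, ]), labels),
               "conflicting judgment")
  bad <- jd; bad$intensity[3] <- 0L
  expect_error(matrix_from_judgments(bad, labels), "invalid scale value")
  bad <- jd; bad$intensity[3] <- 10L
  expect_error(matrix_from_judgments(bad, labels), "invalid scale value")
  bad <- jd; bad$preferred[1] <- "equal"; bad$intensity[1] <- 5L
  expect_error(matrix_from_judgments(bad, labels), "intensity 1")
})

test_that("both priority methods match their frozen oracle values on the reference matrix", {
  m <- fp_group_matrix()
  w_eig <- priorities(m, method = "eigenvector")
  w_geo <- priorities(m, method = "geometric_mean")
  expect_equal(as.numeric(w_eig), REF_EIG_WEIGHTS, tolerance = 1e-5)
  expect_equal(as.numeric(w_geo), REF_GEO_WEIGHTS, tolerance = 1e-5)
  expect_equal(sum(w_eig), 1, tolerance = 1e-9)
  expect_equal(sum(w_geo), 1, tolerance = 1e-9)
  # live dual-route check against the dense eigendecomposition
  expect_lt(max(abs(w_eig - eigen_oracle(m)$weights)), 1e-8)
})

test_that("priorities recover the generating weights of a consistent matrix", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  a <- consistent_matrix(w)
  for (meth in c("eigenvector", "geometric_mean")) {
    expect_equal(as.numeric(priorities(a, method = meth)), w, tolerance = 1e-12)
  }
})

test_that("priorities validates its inputs", {
  bad <- matrix(c(1, 2, 3, 1), 2, 2)  # reciprocity broken
  expect_error(priorities(bad), "reciprocity")
  neg <- matrix(c(1, -2, -1 / 2, 1), 2, 2)
  expect_error(priorities(neg), "positive")
})

test_that("lambda_max is the mean Rayleigh ratio with the consistent floor", {
  a4 <- consistent_matrix(c(0.4, 0.3, 0.2, 0.1))
  expect_equal(lambda_max(a4, priorities(a4)), 4, tolerance = 1e-9)
  ones <- matrix(1, 3, 3)
  expect_identical(lambda_max(ones, rep(1 / 3, 3)), 3)
  m <- fp_group_matrix()
  expect_equal(lambda_max(m, priorities(m)), REF_LAMBDA, tolerance = 1e-6)
  expect_error(lambda_max(ones, c(1, 1, 0)), "degenerate priority vector")
})

test_that("the random index table matches Saaty's published values", {
  expect_identical(random_index(2), 0)
  expect_identical(random_index(3), 0.58)
  expect_identical(random_index(5), 1.12)
  expect_identical(random_index(10), 1.49)
  expect_identical(random_index(15), 1.59)
  expect_error(random_index(16), "unsupported matrix order")
  expect_error(random_index(0), "unsupported matrix order")
})

test_that("consistency reports CR with the strict acceptance rule", {
  rep <- consistency(fp_group_matrix())
  expect_equal(rep$cr, REF_CR, tolerance = 1e-5)
  expect_identical(round(rep$cr, 2), 0.06)
  expect_true(rep$consistent)
  expect_equal(rep$ci, (rep$lambda_max - 5) / 4, tolerance = 1e-12)
  expect_identical(rep$ri, 1.12)

  # perfectly consistent matrices have CR = 0
  expect_lt(consistency(consistent_matrix(c(0.5, 0.3, 0.2)))$cr, 1e-9)

  # the maximally intransitive triad is far past the threshold:
  # lambda_max = 1 + 9 + 1/9 (circulant), CR = ((91/9 - 3)/2) / 0.58
  triad <- matrix(c(1, 9, 1 / 9, 1 / 9, 1, 9, 9, 1 / 9, 1), 3, 3, byrow = TRUE)
  rep3 <- consistency(triad)
  expect_equal(rep3$lambda_max, 91 / 9, tolerance = 1e-9)
  expect_equal(rep3$cr, ((91 / 9 - 3) / 2) / 0.58, tolerance = 1e-9)
  expect_false(rep3$consistent)

  # n = 2 is always consistent by convention (RI = 0 -> CR = 0)
  two <- matrix(c(1, 7, 1 / 7, 1), 2, 2)
  rep2 <- consistency(two)
  expect_identical(rep2$cr, 0)
  expect_true(rep2$consistent)
})

test_that("ranking is descending with alphabetical shared-rank ties", {
  r <- rank_criteria(priorities(fp_group_matrix()))
  expect_identical(r$label,
                   c("Professional Characteristics",
                     "Patient-Doctor relationship",
                     "Individual Characteristics",
                     "Ethical Characteristics",
                     "The Setting"))
  expect_identical(r$rank, 1:5)

  u <- setNames(rep(1 / 3, 3), c("b", "a", "c"))
  ru <- rank_criteria(u)
  expect_identical(ru$rank, rep(1L, 3))
  expect_identical(ru$label, c("a", "b", "c"))

  rw <- rank_criteria(setNames(c(0.5, 0.3, 0.2), c("x", "y", "z")))
  expect_identical(rw$rank, 1:3)
})

test_that("alternative synthesis is the weighted sum of local priorities", {
  w1 <- setNames(1, "only")
  loc1 <- list(only = c(a = 0.7, b = 0.3))
  expect_equal(synthesize_alternatives(w1, loc1), c(a = 0.7, b = 0.3))

  w2 <- setNames(c(0.5, 0.5), c("c1", "c2"))
  loc2 <- list(c1 = c(a = 1, b = 0), c2 = c(a = 0, b = 1))
  expect_equal(synthesize_alternatives(w2, loc2), c(a = 0.5, b = 0.5))

  w3 <- setNames(c(0.7, 0.3), c("c1", "c2"))
  loc3 <- list(c1 = c(a = 0.6, b = 0.4), c2 = c(a = 0.2, b = 0.8))
  g <- synthesize_alternatives(w3, loc3)
  expect_equal(unname(g), c(0.48, 0.52), tolerance = 1e-12)
  expect_equal(sum(g), 1, tolerance = 1e-12)

  bad <- list(c1 = c(a = 0.6, b = 0.4), c2 = c(a = 0.2, zz = 0.8))
  expect_error(synthesize_alternatives(w3, bad), "inconsistent hierarchy")
})
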