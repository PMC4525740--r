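test_that("the packaged hierarchy loads with defaults applied", {
  h <- default_hierarchy()
  expect_s3_class(h, "hierarchy_config")
  expect_identical(h$criteria, fp_criteria())
  expect_identical(h$threshold, 0.10)
  expect_identical(h$method, "eigenvector")
})

test_that("hierarchy validation names the offending field", {
  one <- tempfile(fileext = ".json")
  jsonlite::write_json(list(goal = "g", criteria = list("only")), one,
                       auto_unbox = TRUE)
  expect_error(read_hierarchy(one), "criteria")

  dup <- tempfile(fileext = ".json")
  jsonlite::write_json(list(criteria = c("a", "a", "b")), dup)
  expect_error(read_hierarchy(dup), "duplicate")

  bad_t <- tempfile(fileext = ".json")
  jsonlite::write_json(list(criteria = c("a", "b"), threshold = 1.5), bad_t,
                       auto_unbox = TRUE)
  expect_error(read_hierarchy(bad_t), "threshold")
})

test_that("a custom YAML hierarchy threshold is honoured downstream", {
  y <- tempfile(fileext = ".yaml")
  writeLines(c("goal: demo", "criteria:", "  - A", "  - B", "  - C",
               "threshold: 0.2"), y)
  h <- read_hierarchy(y)
  expect_identical(h$threshold, 0.2)

  # a mildly inconsistent triad passes at 0.2 but not at 0.10
  a <- matrix(c(1, 2, 1, 1 / 2, 1, 2, 1, 1 / 2, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cr <- consistency(a)$cr
  expect_true(cr > 0.10 && cr < 0.2)
  rec <- respondent_record("r1", a, threshold = h$threshold)
  expect_true(rec$report$consistent)
})

test_that("forms round-trip through CSV, one record per row", {
  coh <- fp_cohort_fixture()[c(8, 23, 41)]
  f <- tempfile(fileext = ".csv")
  write_forms(coh, f)
  back <- read_forms(f)
  expect_length(back, 3)
  for (k in 1:3) {
    expect_identical(back[[k]]$matrix, coh[[k]]$matrix)
    expect_identical(back[[k]]$id, coh[[k]]$id)
    expect_identical(unlist(back[[k]]$demographics[names(coh[[k]]$demographics)]),
                     unlist(coh[[k]]$demographics))
  }
})

test_that("a single-row form encoding the reference judgments rebuilds the reference matrix", {
  rec <- respondent_record("t5", fp_group_matrix())
  f <- tempfile(fileext = ".csv")
  write_forms(list(rec), f)
  back <- read_forms(f)
  expect_identical(back[[1]]$matrix, fp_group_matrix())
})

test_that("malformed form rows abort in strict mode and are skipped when lenient", {
  rec <- respondent_record("ok", fp_group_matrix())
  f <- tempfile(fileext = ".csv")
  write_forms(list(rec, rec), f)
  lines <- readLines(f)

  corrupt <- function(pattern, replacement, row = 2) {
    bad <- lines
    bad[1 + row] <- sub(pattern, replacement, bad[1 + row])
    out <- tempfile(fileext = ".csv")
    writeLines(bad, out)
    out
  }

  # intensity 0 (the scale has no zero)
  zero <- corrupt(",3,", ",0,")
  expect_error(read_forms(zero), "invalid scale value")
  expect_warning(ok <- read_forms(zero, strict = FALSE), "skipped")
  expect_length(ok, 1)

  # "equal" paired with an intensity other than 1
  eq5 <- corrupt('"Patient-Doctor relationship",3', '"equal",5')
  expect_error(read_forms(eq5), "equal implies intensity 1")

  # winner label outside the pair
  unk <- corrupt('"Patient-Doctor relationship"', '"Nobody"')
  expect_error(read_forms(unk), "unknown winner")

  # structurally missing pair column is an error in either mode
  broken <- tempfile(fileext = ".csv")
  writeLines(sub("_winner", "_w", lines), broken)
  expect_error(read_forms(broken, strict = FALSE), "missing pair column")
})

test_that("matrix CSV round-trips are exact for scale entries", {
  f <- tempfile(fileext = ".csv")
  write_matrix(fp_group_matrix(), f)
  expect_identical(read_matrix(f), fp_group_matrix())

  set.seed(31)
  for (rep in 1:5) {
    a <- random_reciprocal(sample(3:7, 1))
    write_matrix(a, f)
    expect_identical(read_matrix(f), a)
  }
})

test_that("matrix files with broken reciprocity or stray decimals are handled", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("criterion,A,B", "A,1,3", "B,2,1"), f)
  expect_error(read_matrix(f), "not a valid comparison matrix")

  # hand-entered decimal near 1/3 is normalized to the exact fraction
  g <- tempfile(fileext = ".csv")
  writeLines(c("criterion,A,B", "A,1,0.3333333333", "B,3,1"), g)
  a <- read_matrix(g)
  expect_identical(a["A", "B"], 1 / 3)

  h <- tempfile(fileext = ".csv")
  writeLines(c("criterion,A,B", "A,1,-3", "B,-0.3333,1"), h)
  expect_error(read_matrix(h), "positive")
})

test_that("reports serialize deterministically in all three formats", {
  res <- run_study(fp_cohort_fixture())
  for (fmt in c("json", "tsv", "md")) {
    p1 <- tempfile(); p2 <- tempfile()
    write_report(res, p1, format = fmt)
    write_report(res, p2, format = fmt)
    expect_identical(readLines(p1), readLines(p2))
  }

  j <- jsonlite::fromJSON(write_report(res, tempfile(), format = "json"))
  expect_identical(j$cohort$n_consistent, 5L)
  expect_equal(j$group$cr, 0.063725)
  expect_equal(j$group$weights[["Professional Characteristics"]], 0.466854)
  raw <- jsonlite::fromJSON(write_report(res, tempfile(), format = "json"),
                            simplifyVector = FALSE)
  expect_identical(raw$group$matrix[[1]][["Patient-Doctor relationship"]], "1/3")

  md <- readLines(write_report(res, tempfile(), format = "md"))
  ranked <- grep("^\\| \\d", md, value = TRUE)
  expect_match(ranked[1], "Professional Characteristics")
  expect_match(ranked[5], "The Setting")
})

test_that("a cohort with no consistent respondents reports a warning block", {
  cyc <- cyclic_matrix(fp_criteria())
  coh <- lapply(1:2, function(k) respondent_record(paste0("r", k), cyc))
  res <- suppressWarnings(run_study(coh))
  j <- jsonlite::fromJSON(write_report(res, tempfile(), format = "json"))
  expect_match(j$warning, "no respondent")
  expect_null(j$group)
})
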