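test_that("reading an exposure CSV builds masks and separates columns", {
  path <- write_exposure_fixture(c(
    "y,age,A,B",
    "1.0,30,2.5,0.5",
    "2.0,41,,3.7",
    "3.0,28,1.2,<LOD"))
  res <- read_exposure_csv(path, outcome_col = "y",
                           confounder_cols = "age",
                           lod_map = c(A = 1.0, B = 1.0))
  expect_equal(res$outcome, c(1, 2, 3))
  expect_equal(names(res$confounders), "age")
  expect_equal(colnames(res$table$values), c("A", "B"))
  # exactly one structurally missing cell
  expect_equal(sum(res$table$missing_mask), 1L)
  expect_true(res$table$missing_mask[2, "A"])
  # 0.5 < LOD 1.0 -> censored; sentinel also censored
  expect_true(res$table$below_lod_mask[1, "B"])
  expect_true(res$table$below_lod_mask[3, "B"])
  expect_equal(sum(res$table$below_lod_mask), 2L)
})

test_that("reader rejects absent outcome and malformed cells", {
  path <- write_exposure_fixture(c("y,A", "1,2", "2,3"))
  expect_error(read_exposure_csv(path, outcome_col = "nope"),
               "outcome column")
  path2 <- write_exposure_fixture(c("y,A", "1,2", "2,oops"))
  expect_error(read_exposure_csv(path2, outcome_col = "y"),
               "row 2, column 'A'")
})

test_that("LOD imputation replaces censored cells by LOD/sqrt(2) only", {
  tab <- exposure_table(
    matrix(c(0.4, 3.7, 2.2, 5.0), 2, 2,
           dimnames = list(NULL, c("A", "B"))),
    lod = c(A = 2.0),
    below_lod_mask = matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  out <- impute_lod(tab)
  expect_equal(unname(out$values[1, "A"]), 2.0 / sqrt(2))
  expect_equal(unname(out$values[2, "A"]), 3.7)    # above-LOD untouched
  expect_equal(unname(out$values[, "B"]), c(2.2, 5.0))  # other col untouched
  expect_true(out$below_lod_mask[1, "A"])          # audit mask preserved

  # identity when nothing is censored
  tab2 <- exposure_table(matrix(1:4, 2, 2))
  expect_identical(impute_lod(tab2)$values, tab2$values)

  # censored cell without LOD metadata is a configuration error
  tab3 <- exposure_table(matrix(c(0.1, 1, 1, 1), 2, 2),
                         below_lod_mask = matrix(c(TRUE, FALSE, FALSE,
                                                   FALSE), 2, 2))
  expect_error(impute_lod(tab3), "no LOD metadata")
})

test_that("missingness filter uses a strict 40% rule over both masks", {
  vals <- matrix(runif(100 * 3, 1, 5), 100, 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  miss <- matrix(FALSE, 100, 3); blod <- matrix(FALSE, 100, 3)
  miss[1:21, 1] <- TRUE; blod[22:41, 1] <- TRUE   # A: 41% combined
  miss[1:20, 2] <- TRUE; blod[21:40, 2] <- TRUE   # B: exactly 40%
  vals[miss | blod] <- NA
  tab <- exposure_table(vals, missing_mask = miss, below_lod_mask = blod)

  res <- filter_missing(tab, max_missing_frac = 0.40)
  expect_equal(res$dropped$variable, "A")
  expect_equal(res$dropped$fraction, 0.41)
  expect_equal(colnames(res$table$values), c("B", "C"))  # 40% retained
  # retained values untouched (pure column selection)
  expect_identical(res$table$values[, "C"], vals[, "C"])

  # fully observed table drops nothing
  clean <- exposure_table(matrix(runif(20, 1, 2), 10, 2))
  expect_equal(nrow(filter_missing(clean)$dropped), 0L)

  # below-LOD can be excluded from the count
  res2 <- filter_missing(tab, count_below_lod = FALSE)
  expect_equal(nrow(res2$dropped), 0L)

  # everything dropped is an error
  allbad <- exposure_table(matrix(NA_real_, 10, 2),
                           missing_mask = matrix(TRUE, 10, 2))
  expect_error(filter_missing(allbad), "exceed")
})

test_that("log z-scoring matches hand computation and round-trips", {
  tab <- exposure_table(matrix(c(1, exp(1), exp(2)), 3, 1,
                               dimnames = list(NULL, "A")))
  sm <- log_zscore(tab)
  expect_equal(unname(sm$values[, 1]), c(-1, 0, 1))
  expect_equal(unname(sm$column_means["A"]), 1)

  withr::with_seed(8, {
    vals <- matrix(exp(rnorm(60)), 20, 3,
                   dimnames = list(NULL, c("A", "B", "C")))
  })
  sm2 <- log_zscore(exposure_table(vals))
  expect_lt(max(abs(colMeans(sm2$values))), 1e-10)
  expect_lt(max(abs(apply(sm2$values, 2, sd) - 1)), 1e-10)
  # round trip back to concentrations
  expect_lt(max(abs(unstandardize(sm2) / vals - 1)), 1e-9)
  # stored parameters reproduce the fit on the training data
  expect_equal(apply_standardization(sm2, vals), sm2$values,
               ignore_attr = TRUE)

  # degenerate and domain errors
  expect_error(log_zscore(exposure_table(matrix(5, 3, 1))),
               "zero-variance")
  expect_error(log_zscore(exposure_table(matrix(c(-1, 1, 2), 3, 1))),
               "non-positive")
  # structurally missing cells must be resolved first
  tabm <- exposure_table(matrix(c(NA, 1, 2, 3), 2, 2))
  expect_error(log_zscore(tabm), "handle_missing")
})

test_that("missing-cell handling offers complete-case and mean imputation", {
  vals <- matrix(c(NA, 2, 4, 1, 3, 5), 3, 2,
                 dimnames = list(NULL, c("A", "B")))
  tab <- exposure_table(vals)
  cc <- handle_missing(tab)
  expect_equal(cc$kept_rows, c(FALSE, TRUE, TRUE))
  expect_equal(nrow(cc$table$values), 2L)
  mi <- handle_missing(tab, "mean_impute")
  expect_equal(unname(mi$table$values[1, "A"]), 3)  # mean of 2, 4
  expect_false(any(mi$table$missing_mask))
})

test_that("the preprocessing chain is deterministic", {
  lines <- c("y,A,B", "1,0.4,2.0", "2,3.1,2.5", "3,1.2,4.0", "4,2.2,3.3",
             "5,0.9,2.8")
  p1 <- write_exposure_fixture(lines)
  run <- function(path) {
    r <- read_exposure_csv(path, "y", lod_map = c(A = 1.0))
    log_zscore(handle_missing(filter_missing(impute_lod(r$table))$table)$table)
  }
  expect_identical(run(p1)$values, run(p1)$values)
})

test_that("creatinine correction divides only the requested columns", {
  vals <- matrix(c(2, 4, 10, 20), 2, 2,
                 dimnames = list(NULL, c("U1", "B1")))
  out <- correct_creatinine(exposure_table(vals), "U1", c(2, 4))
  expect_equal(unname(out$values[, "U1"]), c(1, 1))
  expect_equal(unname(out$values[, "B1"]), c(10, 20))
})
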