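test_that("soft-thresholding and the objective match their definitions", {
  expect_equal(soft_threshold(3, 1), 2)
  expect_equal(soft_threshold(-0.5, 1), 0)
  expect_equal(soft_threshold(c(-2, 0, 2), 0), c(-2, 0, 2))

  # hand-computed: y = (1,2), x = (1,1), beta = 1, lambda = 1, w = 1
  X <- matrix(c(1, 1), 2, 1)
  expect_equal(alasso_objective(1, X, c(1, 2), lambda = 1, weights = 1), 2)
  # beta = 0 leaves only ||y||^2
  y <- c(0.3, -1.2, 2)
  expect_equal(alasso_objective(0, matrix(rnorm(3)), y, 5), sum(y^2))
})

test_that("lambda = 0 reproduces OLS and orthonormal designs the closed form", {
  withr::with_seed(11, {
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- drop(X %*% c(1, -2, 0, 0.5, 0)) + rnorm(200)
  })
  expect_lt(max(abs(fit_weighted_lasso(X, y, lambda = 0) -
                      qr.coef(qr(X), y))), 1e-8)

  Q <- orthonormal_design(100, 4)
  yo <- withr::with_seed(12, rnorm(100))
  w <- c(1, 2, 0.5, 1)
  for (lam in c(0.05, 0.3, 1)) {
    closed <- soft_threshold(drop(crossprod(Q, yo)), lam * w / 2)
    expect_lt(max(abs(fit_weighted_lasso(Q, yo, lam, w) - closed)), 1e-8)
  }
})

test_that("solver agrees with the brute-force grid oracle on small problems", {
  for (fx in make_fixture_set()) {
    b_cd <- fit_weighted_lasso(fx$X, fx$y, fx$lambda, fx$w)
    b_bf <- brute_force_wlasso(fx$X, fx$y, fx$lambda, fx$w)
    expect_lt(max(abs(b_cd - b_bf)), 2e-3)
  }
})

test_that("KKT stationarity holds at every returned solution", {
  for (fx in make_fixture_set()) {
    for (lam in c(fx$lambda, 0.1, 10)) {
      b <- fit_weighted_lasso(fx$X, fx$y, lam, fx$w, tol = 1e-9)
      expect_lt(kkt_violation(b, fx$X, fx$y, lam, fx$w), 1e-8)
    }
  }
})

test_that("objective is non-increasing across coordinate-descent sweeps", {
  fx <- make_fixture_set()[[2]]
  vals <- sapply(1:12, function(k) {
    b <- suppressWarnings(fit_weighted_lasso(fx$X, fx$y, fx$lambda, fx$w,
                                             max_sweeps = k))
    alasso_objective(b, fx$X, fx$y, fx$lambda, fx$w)
  })
  expect_true(all(diff(vals) <= 1e-12))
})

test_that("lambda at or above lambda_max gives the all-zero penalized fit", {
  withr::with_seed(3, {
    X <- scale(matrix(rnorm(80 * 4), 80, 4))
    y <- rnorm(80)
  })
  w <- c(1, 0.5, 2, 1)
  lmax <- lambda_max(X, y, w)
  expect_identical(unname(fit_weighted_lasso(X, y, lmax, w))[1:4],
                   rep(0, 4))
  expect_identical(unname(fit_weighted_lasso(X, y, lmax * 1.5, w))[1:4],
                   rep(0, 4))
  # just below lambda_max at least one coefficient activates
  expect_gt(sum(fit_weighted_lasso(X, y, lmax * 0.99, w) != 0), 0)

  # with an unpenalized column, that column stays at its LS value
  w0 <- c(0, 1, 1, 1)
  b <- fit_weighted_lasso(X, y, lambda_max(X, y, w0) * 2, w0)
  expect_equal(unname(b[2:4]), rep(0, 3))
  expect_equal(unname(b[1]), unname(qr.coef(qr(X[, 1, drop = FALSE]), y)),
               tolerance = 1e-8)
})

test_that("support is monotone along the path for orthonormal designs", {
  Q <- orthonormal_design(60, 5, seed = 21)
  y <- withr::with_seed(22, rnorm(60, sd = 2))
  lams <- seq(0.01, 2 * lambda_max(Q, y, 1), length.out = 40)
  sizes <- sapply(lams, function(l)
    sum(fit_weighted_lasso(Q, y, l, 1) != 0))
  expect_true(all(diff(sizes) <= 0))
})

test_that("unit weights reduce the adaptive lasso to the plain lasso", {
  fx <- make_fixture_set()[[3]]
  w_unit <- adaptive_weights(rep(1, 3), gamma = 2)  # |1|^-gamma = 1
  expect_identical(w_unit, rep(1, 3))
  for (lam in c(0.2, 2, 8)) {
    expect_identical(
      as.numeric(fit_weighted_lasso(fx$X, fx$y, lam, w_unit)),
      as.numeric(fit_weighted_lasso(fx$X, fx$y, lam, rep(1, 3))))
  }
})

test_that("solver cross-checks against glmnet on the same objective", {
  skip_if_not_installed("glmnet")
  withr::with_seed(5, {
    n <- 100
    X <- scale(matrix(rnorm(n * 6), n, 6)) * sqrt((n - 1) / n)  # 1/n scale
    y <- drop(X %*% c(1.5, -1, 0, 0, 0.5, 0)) + rnorm(n)
  })
  yc <- y - mean(y)
  w <- c(0.5, 1, 4, 4, 1, 2)
  lam <- 30
  b_cd <- fit_weighted_lasso(X, yc, lam, w)
  # glmnet rescales penalty.factor to sum to p, so its lambda must carry
  # the factor sum(w)/p to leave each w_j * lambda product unchanged
  g <- glmnet::glmnet(X, yc, lambda = lambda_to_glmnet(lam, n) * sum(w) / 6,
                      penalty.factor = w, standardize = FALSE,
                      intercept = FALSE, thresh = 1e-14)
  expect_lt(max(abs(b_cd - as.numeric(g$beta))), 1e-4)
})

test_that("initial estimates behave at their limits", {
  Q <- orthonormal_design(50, 3, seed = 31)
  y <- withr::with_seed(32, rnorm(50))
  expect_equal(unname(initial_beta(Q, y, "ols")),
               unname(drop(crossprod(Q, y))))

  withr::with_seed(33, {
    X <- matrix(rnorm(60 * 4), 60, 4)
    y2 <- rnorm(60)
  })
  ols <- initial_beta(X, y2, "ols")
  expect_equal(unname(initial_beta(X, y2, "ridge", ridge_lambda = 1e-8)),
               unname(ols), tolerance = 1e-6, ignore_attr = TRUE)
  expect_lt(max(abs(initial_beta(X, y2, "ridge", ridge_lambda = 1e12))),
            1e-6)
  # p >= n must refuse OLS
  expect_error(initial_beta(matrix(rnorm(20), 4, 5), rnorm(4), "ols"),
               "ridge")
})

test_that("adaptive weights follow |beta|^-gamma with cap and exemptions", {
  expect_equal(unname(adaptive_weights(c(2, 0.5), gamma = 1)), c(0.5, 2))
  expect_equal(unname(adaptive_weights(c(1, 1, 1), gamma = 0.5)),
               rep(1, 3))
  expect_equal(unname(adaptive_weights(c(0, 2), gamma = 1, cap = 1e6)),
               c(1e6, 0.5))
  expect_equal(unname(adaptive_weights(c(0.5, 0.5), gamma = 1,
                                       unpenalized = 2)), c(2, 0))
})

test_that("two-dimensional CV returns the degenerate single candidate", {
  withr::with_seed(41, {
    X <- matrix(rnorm(60 * 3), 60, 3)
    y <- drop(X %*% c(1, 0, 0)) + rnorm(60)
  })
  f <- tune_2d_cv(X, y, gamma_grid = 1, lambda_grid_size = 1, K = 3,
                  seed = 2)
  expect_equal(f$chosen_gamma, 1)
  expect_equal(dim(f$cv_surface), c(1L, 1L))
  expect_equal(unname(f$chosen_lambda), f$lambda_paths[1, 1])
})

test_that("two-dimensional CV is deterministic and recovers strong signals", {
  withr::with_seed(43, {
    X <- matrix(rnorm(200 * 8), 200, 8)
    colnames(X) <- paste0("V", 1:8)
    y <- drop(X %*% c(2, -1.5, 0, 0, 0, 1, 0, 0)) + rnorm(200, sd = 0.5)
  })
  f1 <- tune_2d_cv(X, y, seed = 9)
  f2 <- tune_2d_cv(X, y, seed = 9)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$chosen_lambda, f2$chosen_lambda)
  expect_setequal(f1$support, c("V1", "V2", "V6"))
  # coefficients near truth on this high-signal design
  expect_equal(unname(f1$beta[c("V1", "V2", "V6")]), c(2, -1.5, 1),
               tolerance = 0.1)
})

test_that("null data give sparse fits with the penalty chosen high", {
  sizes <- idx <- numeric(10)
  for (s in 1:10) {
    X <- withr::with_seed(s, matrix(rnorm(300 * 10), 300, 10))
    y <- withr::with_seed(100 + s, rnorm(300))
    f <- tune_2d_cv(X, y, seed = s)
    sizes[s] <- length(f$support)
    idx[s] <- f$chosen_index["lambda"]
  }
  expect_lte(median(sizes), 2)
  # chosen lambda sits in the top quartile of the path for most null runs
  expect_gte(mean(idx <= 25), 0.8)
})

test_that("unpenalized confounders always stay in the model", {
  withr::with_seed(51, {
    X <- matrix(rnorm(150 * 5), 150, 5)
    colnames(X) <- c(paste0("V", 1:4), "conf")
    y <- 0.4 * X[, "conf"] + rnorm(150)
  })
  f <- tune_2d_cv(X, y, seed = 1, unpenalized = "conf")
  expect_true("conf" %in% f$support)
  expect_equal(unname(f$weights["conf"]), 0)
})

test_that("OLS refit intervals behave on degenerate and aliased inputs", {
  withr::with_seed(61, {
    X <- matrix(rnorm(50 * 3), 50, 3,
                dimnames = list(NULL, c("X1", "X2", "X3")))
  })
  # empty support: intercept-only table
  tab0 <- refit_ols_ci(X, rnorm(50), support = character())
  expect_equal(tab0$term, "(Intercept)")

  # noiseless outcome: interval collapses onto the truth
  tab1 <- refit_ols_ci(X, X[, 1], support = "X1")
  est <- tab1[tab1$term == "X1", ]
  expect_equal(est$estimate, 1, tolerance = 1e-10)
  expect_lt(est$ci_high - est$ci_low, 1e-8)

  # aliased column is dropped with a warning
  Xa <- cbind(X, X4 = X[, 1])
  expect_warning(taba <- refit_ols_ci(Xa, X[, 1] + rnorm(50),
                                      support = c("X1", "X4")),
                 "aliased")
  expect_false("X4" %in% taba$term)
})

test_that("refit intervals achieve nominal coverage for a fixed support", {
  hits <- 0L
  n_rep <- 400L
  for (r in seq_len(n_rep)) {
    withr::with_seed(1000 + r, {
      X <- matrix(rnorm(60 * 2), 60, 2,
                  dimnames = list(NULL, c("X1", "X2")))
      y <- X[, 1] * 0.5 + rnorm(60)
    })
    tab <- refit_ols_ci(X, y, support = c("X1", "X2"))
    ci <- tab[tab$term == "X1", ]
    hits <- hits + (ci$ci_low <= 0.5 && 0.5 <= ci$ci_high)
  }
  expect_equal(hits / n_rep, 0.95, tolerance = 0.025)
})
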