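#' Soft-thresholding operator
#'
#' The shrinkage operator `sign(z) * max(|z| - t, 0)`, the coordinate-wise
#' minimizer of an L1-penalized quadratic.
#'
#' @param z Numeric vector.
#' @param t Non-negative threshold.
#' @return Numeric vector of the same length as `z`.
#' @export
#' @examples
#' soft_threshold(3, 1)    # 2
#' soft_threshold(-0.5, 1) # 0
soft_threshold <- function(z, t) {
  stopifnot(is.numeric(z), is.numeric(t), all(t >= 0))
  sign(z) * pmax(abs(z) - t, 0)
}

#' Weighted-L1 (adaptive lasso) objective
#'
#' Evaluates `||y - X beta||^2 + lambda * sum_j w_j |beta_j|`. Note the
#' residual sum of squares is not divided by `2n`: lambda values are on a
#' different scale from conventions that use the `1/(2n)` factor (see
#' [lambda_to_glmnet()]).
#'
#' @param beta Coefficient vector (length `ncol(X)`).
#' @param X Design matrix.
#' @param y Response vector.
#' @param lambda Non-negative penalty level.
#' @param weights Per-coefficient penalty weights `w_j >= 0`; `w_j = 0`
#'   leaves coefficient `j` unpenalized (used for confounders). Recycled to
#'   `ncol(X)`.
#' @return The scalar objective value.
#' @export
alasso_objective <- function(beta, X, y, lambda, weights = 1) {
  stopifnot(length(beta) == ncol(X), length(y) == nrow(X), lambda >= 0)
  w <- rep_len(weights, ncol(X))
  sum((y - drop(X %*% beta))^2) + lambda * sum(w * abs(beta))
}

#' Convert lambda between penalty scalings
#'
#' The objective used here is `||y - X beta||^2 + lambda * sum w_j |beta_j|`.
#' Software that minimizes `(1/(2n)) ||y - X beta||^2 + lambda' * sum w_j
#' |beta_j|` (e.g. glmnet) uses `lambda' = lambda / (2n)`.
#'
#' @param lambda Penalty on this package's scale.
#' @param n Sample size.
#' @return The equivalent penalty on the `1/(2n)` scale.
#' @export
lambda_to_glmnet <- function(lambda, n) lambda / (2 * n)

#' @rdname lambda_to_glmnet
#' @param lambda_glmnet Penalty on the `1/(2n)` scale.
#' @export
lambda_from_glmnet <- function(lambda_glmnet, n) lambda_glmnet * 2 * n

#' Fit a weighted lasso at fixed lambda by coordinate descent
#'
#' Minimizes `||y - X beta||^2 + lambda * sum_j w_j |beta_j|` by cyclic
#' coordinate descent with exact soft-threshold updates. Columns with
#' `weights = 0` receive plain least-squares coordinate updates. No
#' intercept is fit: center `y` (and the columns of `X`) beforehand, or use
#' [tune_2d_cv()] which handles centering.
#'
#' @inheritParams alasso_objective
#' @param tol Gradient-scale convergence tolerance: iteration stops when the
#'   maximum violation of the stationarity (KKT) conditions is below `tol`.
#' @param max_sweeps Maximum number of full coordinate sweeps.
#' @param beta_init Optional warm-start coefficients.
#' @return Numeric coefficient vector with attributes `converged` (logical)
#'   and `n_iter` (sweeps used). A warning is emitted if `max_sweeps` was
#'   exhausted; the best iterate found is returned.
#' @export
fit_weighted_lasso <- function(X, y, lambda, weights = 1, tol = 1e-9,
                               max_sweeps = 100000L, beta_init = NULL) {
  X <- as.matrix(X)
  stopifnot(is.numeric(y), length(y) == nrow(X), lambda >= 0, tol > 0)
  w <- rep_len(weights, ncol(X))
  stopifnot(all(w >= 0), all(is.finite(w)))
  fit <- cd_path(X, as.numeric(y), lambda, w, tol, as.integer(max_sweeps),
                 beta_init)
  beta <- drop(fit$beta[, 1L])
  names(beta) <- colnames(X)
  if (!fit$converged[1L])
    warning("coordinate descent did not converge in ", max_sweeps,
            " sweeps; returning best iterate")
  attr(beta, "converged") <- fit$converged[1L]
  attr(beta, "n_iter") <- fit$n_iter[1L]
  beta
}

#' KKT stationarity certificate for a weighted-lasso solution
#'
#' Returns the maximum violation of the first-order optimality conditions of
#' the weighted-L1 objective at `beta`: for active coefficients
#' `|2 x_j'r - lambda w_j sign(beta_j)|`, for zero coefficients
#' `max(0, |2 x_j'r| - lambda w_j)`, with residual `y - X beta`.
#'
#' @inheritParams fit_weighted_lasso
#' @param beta Coefficient vector to certify.
#' @return The maximum violation (0 means exact stationarity).
#' @export
kkt_violation <- function(beta, X, y, lambda, weights = 1) {
  X <- as.matrix(X)
  w <- rep_len(weights, ncol(X))
  r <- y - drop(X %*% beta)
  g <- 2 * drop(crossprod(X, r))
  v <- ifelse(beta != 0, abs(g - lambda * w * sign(beta)),
              pmax(0, abs(g) - lambda * w))
  max(v)
}

#' Initial coefficient estimates for adaptive weights
#'
#' OLS or ridge estimates used to build the adaptive-lasso weights. Ridge is
#' recommended when multicollinearity is a concern (e.g. designs with
#' interaction columns); its penalty can be chosen by internal K-fold
#' cross-validation.
#'
#' @param X Design matrix (columns should be standardized; no intercept
#'   column -- center `y` instead).
#' @param y Centered response vector.
#' @param method `"ols"` or `"ridge"`.
#' @param ridge_lambda Ridge penalty (on the `||y - X beta||^2 +
#'   ridge_lambda ||beta||^2` scale). `NULL` selects it by cross-validation.
#' @param K Folds for the internal ridge cross-validation.
#' @param seed Seed for the internal cross-validation fold assignment.
#' @return Coefficient vector; for ridge, the chosen penalty is attached as
#'   attribute `ridge_lambda`.
#' @export
initial_beta <- function(X, y, method = c("ols", "ridge"),
                         ridge_lambda = NULL, K = 5L, seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (method == "ols") {
    if (p >= n)
      stop("OLS initial estimates require p < n; use method = \"ridge\"")
    qx <- qr(X)
    if (qx$rank < p)
      stop("singular design for OLS initial estimates; use method = \"ridge\"")
    beta <- qr.coef(qx, y)
    names(beta) <- colnames(X)
    return(beta)
  }
  sv <- svd(X)
  if (is.null(ridge_lambda)) {
    grid <- 10^seq(-2, 5, length.out = 30)
    folds <- cv_plan(n, K = K, seed = seed)$assignments
    sse <- numeric(length(grid))
    for (k in seq_len(K)) {
      te <- folds == k
      svk <- svd(X[!te, , drop = FALSE])
      uy <- drop(crossprod(svk$u, y[!te]))
      for (g in seq_along(grid)) {
        bk <- drop(svk$v %*% (uy * svk$d / (svk$d^2 + grid[g])))
        sse[g] <- sse[g] + sum((y[te] - drop(X[te, , drop = FALSE] %*% bk))^2)
      }
    }
    ridge_lambda <- grid[which.min(sse)]
  }
  uy <- drop(crossprod(sv$u, y))
  beta <- drop(sv$v %*% (uy * sv$d / (sv$d^2 + ridge_lambda)))
  names(beta) <- colnames(X)
  attr(beta, "ridge_lambda") <- ridge_lambda
  beta
}

#' Adaptive-lasso penalty weights
#'
#' Builds `w_j = |beta_j|^(-gamma)`, capped at `cap` so that variables with
#' an initial estimate of exactly zero remain representable in finite
#' arithmetic (the cap makes them effectively unselectable). Positions
#' listed in `unpenalized` are forced to weight 0 (used for confounders).
#'
#' @param beta_initial Initial coefficient estimates (OLS or ridge).
#' @param gamma Positive exponent.
#' @param cap Upper bound on weights.
#' @param unpenalized Integer or logical index of unpenalized positions.
#' @return Weight vector of the same length as `beta_initial`.
#' @export
adaptive_weights <- function(beta_initial, gamma, cap = 1e6,
                             unpenalized = NULL) {
  stopifnot(gamma > 0, cap > 0)
  w <- pmin(abs(beta_initial)^(-gamma), cap)
  w[!is.finite(w)] <- cap
  if (!is.null(unpenalized)) w[unpenalized] <- 0
  names(w) <- names(beta_initial)
  w
}

#' Smallest lambda that zeroes all penalized coefficients
#'
#' For the objective `||y - X beta||^2 + lambda * sum w_j |beta_j|`,
#' `lambda_max = max_j 2 |x_j' y0| / w_j` over penalized columns, where `y0`
#' is `y` after projecting out any unpenalized columns (for which the
#' all-zero penalized solution still fits least squares).
#'
#' @inheritParams fit_weighted_lasso
#' @return The scalar `lambda_max`.
#' @export
lambda_max <- function(X, y, weights = 1) {
  X <- as.matrix(X)
  w <- rep_len(weights, ncol(X))
  pen <- w > 0
  y0 <- y
  if (any(!pen)) {
    Xu <- X[, !pen, drop = FALSE]
    y0 <- y - drop(Xu %*% qr.coef(qr(Xu), y))
  }
  if (!any(pen)) return(0)
  # tiny upward rounding so beta(lambda_max) is exactly zero in floating
  # point, not within one ulp of the activation boundary
  max(2 * abs(drop(crossprod(X[, pen, drop = FALSE], y0))) / w[pen]) *
    (1 + 1e-10)
}

.lambda_path <- function(lmax, length_out = 100L, eps = 1e-4) {
  if (lmax <= 0) return(0)
  exp(seq(log(lmax), log(eps * lmax), length.out = length_out))
}

# Column standardization helpers: sample sd (denominator n - 1), matching
# the z-score convention used in preprocessing. Zero-variance columns get
# scale 1 so they standardize to an all-zero column.
.std_fit <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  list(center = ctr, scale = scl)
}

.std_apply <- function(X, std) {
  scale(X, center = std$center, scale = std$scale)[, , drop = FALSE]
}

#' Adaptive lasso with two-dimensional (gamma, lambda) cross-validation
#'
#' Fits the adaptive lasso `||y - X beta||^2 + lambda * sum_j w_j |beta_j|`
#' with weights `w_j = |beta_j^initial|^(-gamma)`, tuning the pair
#' `(gamma, lambda)` jointly by K-fold cross-validation: for each gamma a
#' log-spaced lambda path is built from `lambda_max(gamma)` down to
#' `1e-4 * lambda_max`, the CV mean squared error is evaluated on the whole
#' grid with one shared fold assignment, and the model is refit on all data
#' at the CV-minimizing pair. Ties are broken toward the larger lambda,
#' then the smaller gamma (favoring sparsity).
#'
#' Standardization of the design is recomputed inside each training fold and
#' applied to its held-out fold; the final refit standardizes on all data.
#' By default (`cv_weights = "full"`) the adaptive weights are built once
#' from initial estimates on the full data and shared across folds -- the
#' convention of a fixed `penalty.factor` in cross-validated penalized
#' regression, where only lambda (and here gamma) is cross-validated;
#' `cv_weights = "per_fold"` instead recomputes the initial estimates and
#' weights inside each training fold (fully nested, at the cost of a
#' noisier CV surface). The lambda paths always come from the full-data
#' weights so the surface lies on one grid.
#'
#' @param X Predictor matrix (need not be standardized; standardization is
#'   handled internally).
#' @param y Response vector.
#' @param gamma_grid Candidate gamma exponents.
#' @param lambda_grid_size Points on each lambda path.
#' @param K Number of cross-validation folds.
#' @param seed Integer seed controlling the fold assignment (and the
#'   internal ridge cross-validation, when used).
#' @param init Initial estimator for the adaptive weights: `"ols"`,
#'   `"ridge"`, or `"auto"` (ridge when `p >= 0.5 n` or the standardized
#'   design's condition number exceeds 1e3, otherwise OLS).
#' @param unpenalized Names or indices of columns never penalized
#'   (confounders); they are also excluded from the weight construction.
#' @param weight_cap Cap on adaptive weights (see [adaptive_weights()]).
#' @param tol,max_sweeps Solver controls; `tol` is the KKT tolerance of the
#'   final fit.
#' @param cv_tol Looser KKT tolerance used for the path solves inside
#'   cross-validation, where only the CV curve matters.
#' @param cv_weights `"full"` (default) shares full-data adaptive weights
#'   across CV folds; `"per_fold"` recomputes them inside each training
#'   fold. See Details.
#' @return An object of class `"alasso_fit"`: list with elements `beta`
#'   (coefficients on the original scale of `X`), `beta_std` (standardized
#'   scale), `intercept`, `support` (names of nonzero coefficients),
#'   `chosen_gamma`, `chosen_lambda`, `beta_initial`, `weights`,
#'   `cv_surface` (gamma x lambda CV-MSE matrix), `lambda_paths`,
#'   `n_iter`, `converged`, `folds`.
#' @export
tune_2d_cv <- function(X, y, gamma_grid = c(0.5, 1, 2),
                       lambda_grid_size = 100L, K = 10L, seed = 1L,
                       init = c("auto", "ols", "ridge"), unpenalized = NULL,
                       weight_cap = 1e6, tol = 1e-9, cv_tol = 1e-3,
                       max_sweeps = 100000L,
                       cv_weights = c("full", "per_fold")) {
  init <- match.arg(init)
  cv_weights <- match.arg(cv_weights)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, K >= 2, length(gamma_grid) >= 1)
  upen_idx <- if (is.character(unpenalized)) {
    match(unpenalized, colnames(X))
  } else unpenalized
  if (anyNA(upen_idx)) stop("unknown unpenalized column name")

  std_all <- .std_fit(X)
  Xs <- .std_apply(X, std_all)
  yc <- y - mean(y)
  if (init == "auto") {
    init <- if (p >= 0.5 * n || kappa(Xs, exact = FALSE) > 1e3) "ridge"
            else "ols"
  }
  get_init <- function(Xtr, ytr) {
    initial_beta(Xtr, ytr, method = init, K = 5L, seed = seed)
  }

  # lambda paths from full-data weights so the CV surface is on one grid
  b0_full <- get_init(Xs, yc)
  paths <- matrix(NA_real_, length(gamma_grid), lambda_grid_size)
  w_full <- vector("list", length(gamma_grid))
  for (g in seq_along(gamma_grid)) {
    w_full[[g]] <- adaptive_weights(b0_full, gamma_grid[g], cap = weight_cap,
                                    unpenalized = upen_idx)
    paths[g, ] <- .lambda_path(lambda_max(Xs, yc, w_full[[g]]),
                               lambda_grid_size)
  }

  plan <- cv_plan(n, K = K, seed = seed)
  folds <- plan$assignments
  sse <- matrix(0, length(gamma_grid), lambda_grid_size)
  for (k in seq_len(K)) {
    te <- folds == k
    std_k <- .std_fit(X[!te, , drop = FALSE])
    Xtr <- .std_apply(X[!te, , drop = FALSE], std_k)
    Xte <- .std_apply(X[te, , drop = FALSE], std_k)
    ybar <- mean(y[!te])
    ytr <- y[!te] - ybar
    b0_k <- if (cv_weights == "per_fold") get_init(Xtr, ytr) else NULL
    for (g in seq_along(gamma_grid)) {
      if (is.null(b0_k)) {
        wk <- w_full[[g]]
        # the objective carries no 1/n factor, so a lambda tuned for n
        # samples corresponds to lambda * n_train/n on the training fold
        lam_scale <- sum(!te) / n
      } else {
        wk <- adaptive_weights(b0_k, gamma_grid[g], cap = weight_cap,
                               unpenalized = upen_idx)
        # fold weights have their own scale; evaluate the fold at the same
        # relative depths of its own lambda_max so grid points correspond
        lam_scale <- lambda_max(Xtr, ytr, wk) / paths[g, 1L]
      }
      sol <- cd_path(Xtr, ytr, paths[g, ] * lam_scale, wk, cv_tol,
                     as.integer(max_sweeps), NULL)
      pred <- ybar + Xte %*% sol$beta
      sse[g, ] <- sse[g, ] + colSums((y[te] - pred)^2)
    }
  }
  cv_mse <- sse / n

  # CV-minimizing pair; ties -> larger lambda (earlier path index), then
  # smaller gamma
  best <- min(cv_mse)
  cand <- which(cv_mse == best, arr.ind = TRUE)
  cand <- cand[order(cand[, "col"], gamma_grid[cand[, "row"]]), ,
               drop = FALSE]
  g_star <- cand[1L, "row"]; l_star <- cand[1L, "col"]
  chosen_gamma <- gamma_grid[g_star]
  chosen_lambda <- paths[g_star, l_star]

  # final refit on all data at the chosen pair, warm-started along the path
  sol <- cd_path(Xs, yc, paths[g_star, seq_len(l_star)], w_full[[g_star]],
                 tol, as.integer(max_sweeps), NULL)
  beta_std <- drop(sol$beta[, l_star])
  names(beta_std) <- colnames(X)
  beta <- beta_std / std_all$scale
  intercept <- mean(y) - sum(beta * std_all$center)
  dimnames(cv_mse) <- list(gamma = gamma_grid, lambda = NULL)

  structure(list(
    beta = beta, beta_std = beta_std, intercept = intercept,
    support = names(beta_std)[beta_std != 0],
    chosen_gamma = chosen_gamma, chosen_lambda = chosen_lambda,
    gamma_grid = gamma_grid, lambda_paths = paths, cv_surface = cv_mse,
    chosen_index = c(gamma = unname(g_star), lambda = unname(l_star)),
    beta_initial = b0_full, weights = w_full[[g_star]],
    init_method = init, unpenalized = upen_idx,
    standardization = std_all, y_mean = mean(y),
    n_iter = sol$n_iter[l_star], converged = sol$converged[l_star],
    folds = folds, n = n
  ), class = "alasso_fit")
}

#' @export
print.alasso_fit <- function(x, ...) {
  cat("Adaptive lasso fit (two-dimensional CV)\n")
  cat(sprintf("  n = %d, p = %d; chosen gamma = %g, lambda = %.4g\n",
              x$n, length(x$beta), x$chosen_gamma, x$chosen_lambda))
  cat(sprintf("  support (%d): %s\n", length(x$support),
              paste(x$support, collapse = ", ")))
  invisible(x)
}

#' Predict from an adaptive lasso fit
#'
#' @param object An `"alasso_fit"` from [tune_2d_cv()].
#' @param newdata Matrix with the same columns as the training design.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.alasso_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  drop(newdata %*% object$beta) + object$intercept
}

#' OLS refit on a selected support with Wald confidence intervals
#'
#' Refits ordinary least squares on the selected columns (plus any forced
#' confounders) and reports Wald t-intervals. These are naive post-selection
#' intervals: the selection event is ignored, so nominal coverage is only
#' guaranteed when the support is fixed a priori.
#'
#' @param X Predictor matrix (original scale).
#' @param y Response vector.
#' @param support Character vector of selected column names (may be empty).
#' @param confounders Character vector of columns always included.
#' @param level Confidence level.
#' @return Data frame with columns `term`, `estimate`, `se`, `ci_low`,
#'   `ci_high` (first row is the intercept). Aliased (collinear) columns are
#'   dropped with a warning.
#' @export
refit_ols_ci <- function(X, y, support, confounders = character(),
                         level = 0.95) {
  X <- as.matrix(X)
  keep <- unique(c(confounders, support))
  stopifnot(all(keep %in% colnames(X)), length(keep) < length(y))
  df <- data.frame(.y = y, check.names = FALSE)
  if (length(keep)) df <- cbind(df, as.data.frame(X[, keep, drop = FALSE]))
  fit <- stats::lm(.y ~ ., data = df)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    warning("aliased columns dropped from refit: ",
            paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  ci <- suppressWarnings(stats::confint(fit, level = level))
  sm <- suppressWarnings(summary(fit))$coefficients
  ok <- names(cf)[!is.na(cf)]
  data.frame(
    term = sub("^`(.*)`$", "\\1", ok),
    estimate = cf[ok],
    se = sm[ok, "Std. Error"],
    ci_low = ci[ok, 1L],
    ci_high = ci[ok, 2L],
    row.names = NULL
  )
}
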