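#' Balanced K-fold cross-validation plan
#'
#' Randomly partitions `n` samples into `K` folds whose sizes differ by at
#' most one.
#'
#' @param n Number of samples.
#' @param K Number of folds.
#' @param seed Integer seed for the random assignment.
#' @return List with `K`, `assignments` (integer fold id per sample),
#'   `fold_sizes`, and `seed`.
#' @export
cv_plan <- function(n, K = 10L, seed = 1L) {
  stopifnot(K >= 2, K <= n)
  assignments <- withr::with_seed(seed, sample(rep_len(seq_len(K), n)))
  list(K = as.integer(K), assignments = assignments,
       fold_sizes = tabulate(assignments, K), seed = seed)
}

#' Goodness-of-fit metrics: R-squared, adjusted R-squared, MSE
#'
#' `r2 = 1 - SSE/SST`, `adj_r2 = 1 - (1 - r2)(n - 1)/(n - p_effective - 1)`,
#' `mse = SSE/n` (divisor `n`, not `n - p`).
#'
#' @param y Observed outcomes.
#' @param yhat Fitted values.
#' @param p_effective Number of estimated coefficients excluding the
#'   intercept (selected terms plus forced confounders).
#' @return List with `r2`, `adj_r2`, `mse`.
#' @export
r2_metrics <- function(y, yhat, p_effective) {
  stopifnot(length(y) == length(yhat), p_effective >= 0)
  n <- length(y)
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("outcome has zero variance; R-squared undefined")
  if (n <= p_effective + 1)
    stop("adjusted R-squared requires n > p_effective + 1")
  sse <- sum((y - yhat)^2)
  r2 <- 1 - sse / sst
  list(r2 = r2,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - p_effective - 1),
       mse = sse / n)
}

#' Fold-weighted cross-validated prediction error
#'
#' K-fold cross-validation of an arbitrary self-contained fitting procedure.
#' For each fold `k` the procedure is fit on the complement and evaluated on
#' the held-out part `C_k`; the prediction error is combined across folds
#' with fold-size weights:
#' `MSPE = sum_k (n_k/n) * sum_{i in C_k} (y_i - yhat_i)^2 / n_k`,
#' which equals the pooled mean of all held-out squared errors for any fold
#' sizes. `mse_cv` is the fold-size-weighted mean of the training MSEs of
#' the per-fold fits.
#'
#' @param fit_fn Function `(X_train, y_train) -> function(X_new) -> yhat`.
#'   It must be self-contained (any tuning happens inside the training data
#'   it receives).
#' @param X Predictor matrix.
#' @param y Outcome vector.
#' @param K Number of folds (default 10).
#' @param seed Seed for the fold assignment (ignored when `plan` is given).
#' @param plan Optional [cv_plan()] to reuse across methods.
#' @return List with `mspe_cv`, `mse_cv`, `fold_mspe`, `fold_mse`, `plan`.
#' @export
mspe_kfold <- function(fit_fn, X, y, K = 10L, seed = 1L, plan = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(plan)) {
    if (K > n) stop("K must not exceed the number of samples")
    plan <- cv_plan(n, K = K, seed = seed)
  }
  K <- plan$K
  fold_mspe <- fold_mse <- numeric(K)
  for (k in seq_len(K)) {
    te <- plan$assignments == k
    predictor <- fit_fn(X[!te, , drop = FALSE], y[!te])
    fold_mspe[k] <- mean((y[te] - predictor(X[te, , drop = FALSE]))^2)
    fold_mse[k] <- mean((y[!te] - predictor(X[!te, , drop = FALSE]))^2)
  }
  wts <- plan$fold_sizes / n
  list(mspe_cv = sum(wts * fold_mspe), mse_cv = sum(wts * fold_mse),
       fold_mspe = fold_mspe, fold_mse = fold_mse, plan = plan)
}

#' Compare analysis methods on one dataset
#'
#' Runs each requested workflow -- single-step adaptive lasso
#' (`"alasso"`), CART screening + adaptive lasso (`"cart_alasso"`), and
#' random-forest screening + adaptive lasso (`"rf_alasso"`) -- on the same
#' data with a shared cross-validation plan, and tabulates the five
#' performance metrics plus the selected support size.
#'
#' @param X Standardized predictor matrix.
#' @param y Outcome vector.
#' @param methods Subset of `c("alasso", "cart_alasso", "rf_alasso")`.
#' @param with_interactions Logical; may be a vector to request both model
#'   families (e.g. `c(FALSE, TRUE)` mirrors a 3 x 2 comparison grid).
#' @param confounders Names of columns forced into every model, unpenalized.
#' @param K Folds for the shared performance CV plan.
#' @param seed Integer seed.
#' @param ... Further arguments passed to [run_analysis()].
#' @return Data frame with one row per method x interaction setting and
#'   columns `method`, `with_interactions`, `r2`, `adj_r2`, `mse`, `mse_cv`,
#'   `mspe_cv`, `support_size`.
#' @export
compare_methods <- function(X, y,
                            methods = c("alasso", "cart_alasso", "rf_alasso"),
                            with_interactions = c(FALSE, TRUE),
                            confounders = character(), K = 10L, seed = 1L,
                            ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  plan <- cv_plan(nrow(as.matrix(X)), K = K, seed = seed)
  grid <- expand.grid(method = methods, wi = with_interactions,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- run_analysis(X, y, method = grid$method[i],
                        with_interactions = grid$wi[i],
                        confounders = confounders, K = K, seed = seed,
                        cv_plan = plan, ...)
    pf <- res$performance
    data.frame(method = grid$method[i], with_interactions = grid$wi[i],
               r2 = pf$r2, adj_r2 = pf$adj_r2, mse = pf$mse,
               mse_cv = pf$mse_cv, mspe_cv = pf$mspe_cv,
               support_size = length(setdiff(res$fit$support, confounders)))
  })
  do.call(rbind, rows)
}
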