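#' Expand pairwise interaction columns
#'
#' Appends all `C(q, 2)` pairwise products of the listed columns to the
#' design. Products are computed from the standardized main effects and
#' each product column is then re-standardized; no quadratic (self) terms
#' are created. Term names are `"A:B"` with `A` before `B` in input column
#' order. Confounders should not be listed in `variables`.
#'
#' @param X Predictor matrix.
#' @param variables Columns to interact (default: all columns of `X`).
#' @return List of class `"expanded_design"` with `design` (`X` plus
#'   product columns), `terms` (data frame `term`, `var_a`, `var_b`), and
#'   the standardization parameters needed by [expand_apply()]. With fewer
#'   than two `variables`, `design` is `X` and `terms` has zero rows.
#' @export
expand_interactions <- function(X, variables = colnames(X)) {
  X <- as.matrix(X)
  stopifnot(all(variables %in% colnames(X)))
  q <- length(variables)
  if (q < 2) {
    return(structure(list(design = X,
                          terms = data.frame(term = character(),
                                             var_a = character(),
                                             var_b = character()),
                          main_std = NULL, prod_std = NULL),
                     class = "expanded_design"))
  }
  main_std <- .std_fit(X[, variables, drop = FALSE])
  Xs <- .std_apply(X[, variables, drop = FALSE], main_std)
  pairs <- utils::combn(variables, 2L)
  P <- Xs[, pairs[1L, ], drop = FALSE] * Xs[, pairs[2L, ], drop = FALSE]
  colnames(P) <- paste0(pairs[1L, ], ":", pairs[2L, ])
  prod_std <- .std_fit(P)
  P <- .std_apply(P, prod_std)
  structure(list(design = cbind(X, P),
                 terms = data.frame(term = colnames(P),
                                    var_a = pairs[1L, ], var_b = pairs[2L, ]),
                 main_std = main_std, prod_std = prod_std),
            class = "expanded_design")
}

#' Rebuild an expanded design for new data
#'
#' Applies the interaction construction fitted by [expand_interactions()]
#' (training standardization of mains, product, training re-standardization
#' of products) to held-out rows.
#'
#' @param expansion An `"expanded_design"`.
#' @param newX New predictor matrix with the original main-effect columns.
#' @return Matrix with the same columns as `expansion$design`.
#' @export
expand_apply <- function(expansion, newX) {
  stopifnot(inherits(expansion, "expanded_design"))
  newX <- as.matrix(newX)
  if (nrow(expansion$terms) == 0) return(newX)
  vars <- names(expansion$main_std$center)
  Xs <- .std_apply(newX[, vars, drop = FALSE], expansion$main_std)
  P <- Xs[, expansion$terms$var_a, drop = FALSE] *
    Xs[, expansion$terms$var_b, drop = FALSE]
  colnames(P) <- expansion$terms$term
  cbind(newX, .std_apply(P, expansion$prod_std))
}

# One full modeling pass (screen -> expand -> tune) on a training set.
# Returns the fitted pieces plus a prediction closure for new rows.
.fit_procedure <- function(X, y, method, with_interactions, confounders,
                           screen_rule, screen_k, screen_frac, n_trees,
                           cart_folds, gamma_grid, lambda_grid_size,
                           tune_K, seed, init, interaction_scope,
                           cv_weights, verbose) {
  candidates <- setdiff(colnames(X), confounders)
  Xc <- X[, candidates, drop = FALSE]

  screen <- switch(method,
    alasso = new_screen_result(method = "none", kept = candidates,
                               forced = confounders),
    rf_alasso = {
      s <- select_by_vimp(rf_vimp(Xc, y, n_trees = n_trees, seed = seed),
                          rule = screen_rule, k = screen_k,
                          frac = screen_frac)
      s$forced <- confounders
      s
    },
    cart_alasso = {
      s <- cart_screen(Xc, y, cv_folds = cart_folds, seed = seed)
      s$forced <- confounders
      s
    })

  # canonicalize to input column order so interaction terms are always
  # named "A:B" with A before B in the design's column order
  kept <- intersect(candidates, screen$kept)
  if (screen$empty && method != "alasso") {
    if (verbose)
      warning("empty screen (", method, "); falling back to the unscreened ",
              "single-step analysis", call. = FALSE)
    kept <- candidates
  }

  inter_vars <- if (method == "alasso" || interaction_scope == "all")
    candidates else kept
  base <- X[, unique(c(kept, confounders)), drop = FALSE]
  expansion <- if (with_interactions && length(inter_vars) >= 2) {
    ex <- expand_interactions(X[, unique(c(kept, confounders)),
                                drop = FALSE],
                              variables = intersect(colnames(base),
                                                    inter_vars))
    ex
  } else expand_interactions(base, variables = character())

  fit <- tune_2d_cv(expansion$design, y, gamma_grid = gamma_grid,
                    lambda_grid_size = lambda_grid_size, K = tune_K,
                    seed = seed, init = init, unpenalized = confounders,
                    cv_weights = cv_weights)
  predictor <- function(newX) {
    predict(fit, expand_apply(expansion, newX[, colnames(base),
                                              drop = FALSE]))
  }
  list(screen = screen, expansion = expansion, fit = fit,
       predictor = predictor)
}

#' Run one mixture-analysis workflow end to end
#'
#' Executes one of the three workflows on a standardized design: single-step
#' adaptive lasso (`"alasso"`), CART screening followed by adaptive lasso
#' (`"cart_alasso"`), or the proposed random-forest screening followed by
#' adaptive lasso (`"rf_alasso"`). For the two-step methods, pairwise
#' interaction terms (when requested) are formed among the *retained*
#' variables only -- variables eliminated by the screen contribute no
#' interactions -- while the single-step method expands over all
#' candidates. Confounders bypass screening, enter every model, and are
#' never penalized (weight 0) nor crossed into products.
#'
#' An empty screen falls back, with a warning, to the unscreened single-step
#' analysis.
#'
#' @param X Standardized predictor matrix (exposures plus confounder
#'   columns).
#' @param y Outcome vector.
#' @param method One of `"alasso"`, `"cart_alasso"`, `"rf_alasso"`.
#' @param with_interactions Include pairwise interaction terms?
#' @param confounders Column names forced into the model, unpenalized.
#' @param screen_rule,screen_k,screen_frac Importance selection rule for
#'   `"rf_alasso"` (see [select_by_vimp()]).
#' @param n_trees Random-forest size.
#' @param cart_folds Folds for CART pruning cross-validation.
#' @param gamma_grid,lambda_grid_size,tune_K Adaptive-lasso tuning controls
#'   (see [tune_2d_cv()]).
#' @param K Folds for the performance cross-validation.
#' @param seed Integer seed threaded through every stochastic component.
#' @param init Initial estimator for adaptive weights (see [tune_2d_cv()]).
#' @param cv_weights How adaptive weights are handled inside the tuning
#'   cross-validation (see [tune_2d_cv()]).
#' @param cv_mode `"nested"` re-runs the complete procedure (screening
#'   included) inside each performance-CV training fold, avoiding selection
#'   leakage; `"fixed-screen"` screens once on the full data and only
#'   re-tunes the adaptive lasso per fold.
#' @param interaction_scope `"screened"` (default) or `"all"`, overriding
#'   the screen-then-expand order for sensitivity analysis.
#' @param hierarchy `"none"` (default) keeps interaction selections as the
#'   penalized fit returns them -- interaction-only detections are allowed;
#'   `"strong"` drops any selected interaction whose two main effects were
#'   not both selected.
#' @param performance Compute the performance report (in-sample and
#'   cross-validated metrics)? Disable for pure selection studies.
#' @param cv_plan Optional shared [cv_plan()] for the performance CV.
#' @param ci_level Confidence level of the OLS refit intervals.
#' @param verbose Emit workflow warnings (empty screens, dimension and
#'   collinearity advisories)?
#' @return An object of class `"run_result"`: list with `method`,
#'   `with_interactions`, `screen`, `fit` (an `"alasso_fit"`), `ci_table`
#'   (naive OLS refit on the selected support), `performance` (list `r2`,
#'   `adj_r2`, `mse`, `mse_cv`, `mspe_cv`, `K`, `cv_mode`, or `NULL`),
#'   `expansion`, `predictor`, and `seed`.
#' @export
run_analysis <- function(X, y,
                         method = c("rf_alasso", "alasso", "cart_alasso"),
                         with_interactions = FALSE,
                         confounders = character(),
                         screen_rule = "positive", screen_k = NULL,
                         screen_frac = NULL, n_trees = 1000L,
                         cart_folds = 10L, gamma_grid = c(0.5, 1, 2),
                         lambda_grid_size = 100L, tune_K = 10L, K = 10L,
                         seed = 1L, init = "auto",
                         cv_mode = c("nested", "fixed-screen"),
                         interaction_scope = c("screened", "all"),
                         hierarchy = c("none", "strong"),
                         cv_weights = c("full", "per_fold"),
                         performance = TRUE, cv_plan = NULL,
                         ci_level = 0.95, verbose = TRUE) {
  method <- match.arg(method)
  cv_mode <- match.arg(cv_mode)
  interaction_scope <- match.arg(interaction_scope)
  hierarchy <- match.arg(hierarchy)
  cv_weights <- match.arg(cv_weights)
  # ridge initial estimates whenever interaction columns enter the design
  # (multicollinearity by construction); otherwise the condition-number
  # based default of tune_2d_cv applies
  if (init == "auto" && with_interactions) init <- "ridge"
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(length(y) == nrow(X), all(confounders %in% colnames(X)))
  n <- nrow(X)

  if (verbose) {
    cr <- stats::cor(X[, setdiff(colnames(X), confounders), drop = FALSE])
    cr[upper.tri(cr, diag = TRUE)] <- 0
    hi <- which(abs(cr) > 0.8, arr.ind = TRUE)
    if (nrow(hi))
      warning("highly correlated exposure pair(s) (|r| > 0.8), e.g. ",
              rownames(cr)[hi[1L, 1L]], "/", colnames(cr)[hi[1L, 2L]],
              "; consider removing one variable from each highly ",
              "correlated pair before analysis", call. = FALSE)
  }

  main <- .fit_procedure(X, y, method, with_interactions, confounders,
                         screen_rule, screen_k, screen_frac, n_trees,
                         cart_folds, gamma_grid, lambda_grid_size, tune_K,
                         seed, init, interaction_scope, cv_weights,
                         verbose)
  p_design <- ncol(main$expansion$design)
  if (verbose && p_design > 0.8 * n)
    warning("design has ", p_design, " columns for ", n, " samples after ",
            "expansion; this workflow is intended for datasets of roughly ",
            "10-50 predictor variables", call. = FALSE)

  if (hierarchy == "strong" && nrow(main$expansion$terms)) {
    tm <- main$expansion$terms
    bad <- tm$term[!(tm$var_a %in% main$fit$support &
                       tm$var_b %in% main$fit$support)]
    drop_terms <- intersect(main$fit$support, bad)
    if (length(drop_terms)) {
      main$fit$support <- setdiff(main$fit$support, drop_terms)
      main$fit$beta[drop_terms] <- 0
      main$fit$beta_std[drop_terms] <- 0
    }
  }

  ci_table <- refit_ols_ci(main$expansion$design, y,
                           support = setdiff(main$fit$support, confounders),
                           confounders = confounders, level = ci_level)

  perf <- NULL
  if (performance) {
    yhat <- predict(main$fit, main$expansion$design)
    base_metrics <- r2_metrics(y, yhat,
                               p_effective = length(main$fit$support))
    fit_fn <- if (cv_mode == "nested") {
      function(Xtr, ytr) {
        .fit_procedure(Xtr, ytr, method, with_interactions, confounders,
                       screen_rule, screen_k, screen_frac, n_trees,
                       cart_folds, gamma_grid, lambda_grid_size, tune_K,
                       seed, init, interaction_scope, cv_weights,
                       verbose = FALSE)$predictor
      }
    } else {
      kept_cols <- colnames(main$expansion$design)
      base_cols <- setdiff(kept_cols, main$expansion$terms$term)
      function(Xtr, ytr) {
        ex <- if (nrow(main$expansion$terms)) {
          expand_interactions(Xtr[, base_cols, drop = FALSE],
                              variables = unique(c(
                                main$expansion$terms$var_a,
                                main$expansion$terms$var_b)))
        } else expand_interactions(Xtr[, base_cols, drop = FALSE],
                                   variables = character())
        f <- tune_2d_cv(ex$design, ytr, gamma_grid = gamma_grid,
                        lambda_grid_size = lambda_grid_size, K = tune_K,
                        seed = seed, init = init, unpenalized = confounders,
                        cv_weights = cv_weights)
        function(newX) predict(f, expand_apply(ex, newX[, base_cols,
                                                        drop = FALSE]))
      }
    }
    cv <- mspe_kfold(fit_fn, X, y, K = K, seed = seed, plan = cv_plan)
    perf <- list(r2 = base_metrics$r2, adj_r2 = base_metrics$adj_r2,
                 mse = base_metrics$mse, mse_cv = cv$mse_cv,
                 mspe_cv = cv$mspe_cv, K = cv$plan$K, cv_mode = cv_mode,
                 p_effective = length(main$fit$support), seed = seed)
  }

  structure(list(method = method, with_interactions = with_interactions,
                 screen = main$screen, fit = main$fit, ci_table = ci_table,
                 performance = perf, expansion = main$expansion,
                 predictor = main$predictor, confounders = confounders,
                 seed = seed),
            class = "run_result")
}

#' @rdname run_analysis
#' @export
run_two_step <- function(X, y, method = c("rf_alasso", "cart_alasso"), ...) {
  run_analysis(X, y, method = match.arg(method), ...)
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("Workflow: %s%s\n", x$method,
              if (x$with_interactions) " + pairwise interactions" else ""))
  print(x$screen)
  print(x$fit)
  if (!is.null(x$performance)) {
    p <- x$performance
    cat(sprintf(
      "  R2 = %.3f, adj R2 = %.3f, MSE = %.4g, MSE.CV = %.4g, MSPE.CV = %.4g (K = %d, %s)\n",
      p$r2, p$adj_r2, p$mse, p$mse_cv, p$mspe_cv, p$K, p$cv_mode))
  }
  invisible(x)
}
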