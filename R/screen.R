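#' Random-forest permutation variable importance
#'
#' Grows a regression forest (bootstrap-sampled trees, random candidate
#' subsets at each split) and measures each variable's importance as the
#' mean increase in out-of-bag mean squared error when that variable's
#' values are permuted -- larger values indicate better predictability.
#' Backed by \pkg{ranger} with unscaled permutation importance and a single
#' thread, so results are deterministic given the seed.
#'
#' @param X Predictor matrix (standardized exposures).
#' @param y Continuous outcome vector.
#' @param n_trees Number of trees (default 1000).
#' @param mtry Candidate variables per split; default
#'   `max(floor(m/3), 1)`, the regression-forest convention.
#' @param min_node Minimum node size (default 5).
#' @param seed Integer seed.
#' @return Data frame of class `"vimp_table"` with columns `variable`,
#'   `vimp` (outcome-variance units), and `rank` (1 = largest), ordered by
#'   rank. Ties keep input column order.
#' @export
rf_vimp <- function(X, y, n_trees = 1000L, mtry = NULL, min_node = 5L,
                    seed = 1L) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(nrow(X) >= 20, ncol(X) >= 1, length(y) == nrow(X))
  if (stats::sd(y) == 0) stop("outcome is constant; importance undefined")
  if (is.null(mtry)) mtry <- max(floor(ncol(X) / 3), 1L)
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = df,
    num.trees = n_trees, mtry = mtry, min.node.size = min_node,
    importance = "permutation", scale.permutation.importance = FALSE,
    replace = TRUE, num.threads = 1L, seed = seed)
  vimp <- fit$variable.importance[colnames(X)]
  out <- data.frame(variable = colnames(X), vimp = unname(vimp))
  out$rank <- rank(-out$vimp, ties.method = "first")
  out <- out[order(out$rank), ]
  rownames(out) <- NULL
  attr(out, "oob_error") <- fit$prediction.error
  attr(out, "n_trees") <- n_trees
  class(out) <- c("vimp_table", "data.frame")
  out
}

#' Select variables from an importance table
#'
#' @param vimp A `"vimp_table"` from [rf_vimp()].
#' @param rule Selection rule: `"positive"` keeps variables with importance
#'   strictly above zero (better than noise, the default); `"top_k"` keeps
#'   the `k` largest; `"frac_of_max"` keeps those with importance at least
#'   `c * max(vimp)`.
#' @param k Number kept under `"top_k"` (capped at `m` with a warning).
#' @param frac Fraction `c` for `"frac_of_max"`.
#' @return A screen result (see [cart_screen()] for the structure); when
#'   nothing is kept, `empty` is `TRUE` and downstream workflows fall back
#'   to no screening.
#' @export
select_by_vimp <- function(vimp, rule = c("positive", "top_k", "frac_of_max"),
                           k = NULL, frac = NULL) {
  rule <- match.arg(rule)
  stopifnot(inherits(vimp, "vimp_table"))
  kept <- switch(rule,
    positive = vimp$variable[vimp$vimp > 0],
    top_k = {
      stopifnot(!is.null(k), k >= 1)
      if (k > nrow(vimp)) {
        warning("top_k k = ", k, " exceeds the ", nrow(vimp),
                " candidates; keeping all")
        k <- nrow(vimp)
      }
      vimp$variable[vimp$rank <= k]
    },
    frac_of_max = {
      stopifnot(!is.null(frac))
      vimp$variable[vimp$vimp >= frac * max(vimp$vimp)]
    })
  new_screen_result(method = "rf", kept = kept,
                    diagnostics = list(rule = rule, k = k, frac = frac,
                                       n_trees = attr(vimp, "n_trees"),
                                       oob_error = attr(vimp, "oob_error")),
                    vimp = vimp)
}

new_screen_result <- function(method, kept, forced = character(),
                              diagnostics = list(), vimp = NULL) {
  structure(list(method = method, kept = kept, forced = forced,
                 empty = length(kept) == 0, diagnostics = diagnostics,
                 vimp = vimp),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("Screen (%s): %d variable(s) kept%s\n", x$method,
              length(x$kept),
              if (x$empty) " [empty screen: fallback to no screening]"
              else ""))
  if (length(x$kept)) cat(" ", paste(x$kept, collapse = ", "), "\n")
  invisible(x)
}

#' CART screening with cost-complexity pruning and the 1-SE rule
#'
#' Grows a regression tree by recursive binary partitioning minimizing
#' squared error, prunes it by cost-complexity with the penalty chosen by
#' K-fold cross-validation under the one-standard-error rule, and keeps the
#' distinct variables appearing in any split of the pruned tree. A
#' root-only pruned tree (typical when the outcome is independent of all
#' predictors) yields an empty screen.
#'
#' @param X Predictor matrix.
#' @param y Continuous outcome vector.
#' @param cv_folds Folds for the internal pruning cross-validation.
#' @param seed Integer seed (controls the pruning CV partition).
#' @param cp Complexity parameter used when growing the initial tree.
#' @return A `"screen_result"`: list with `method`, `kept` (split
#'   variables), `forced`, `empty` flag, and `diagnostics` (chosen pruning
#'   alpha and the CV error table).
#' @export
cart_screen <- function(X, y, cv_folds = 10L, seed = 1L, cp = 0.001) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  stopifnot(nrow(X) >= 20, length(y) == nrow(X))
  if (stats::sd(y) == 0) stop("outcome is constant; cannot grow a tree")
  df <- data.frame(.y = y, X, check.names = FALSE)
  fit <- withr::with_seed(seed,
    rpart::rpart(.y ~ ., data = df, method = "anova",
                 control = rpart::rpart.control(cp = cp, xval = cv_folds)))
  tab <- fit$cptable
  i_min <- which.min(tab[, "xerror"])
  thresh <- tab[i_min, "xerror"] + tab[i_min, "xstd"]
  i_1se <- which(tab[, "xerror"] <= thresh)[1L]
  pruned <- rpart::prune(fit, cp = tab[i_1se, "CP"])
  used <- pruned$frame$var
  kept_all <- unique(as.character(used[used != "<leaf>"]))
  kept <- colnames(X)[colnames(X) %in% kept_all]  # input column order
  new_screen_result(method = "cart", kept = kept,
                    diagnostics = list(alpha = unname(tab[i_1se, "CP"]),
                                       cptable = tab, cv_folds = cv_folds))
}
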