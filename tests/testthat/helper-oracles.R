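# Independent brute-force minimizer of the weighted-L1 objective
#   ||y - X beta||^2 + lambda * sum_j w_j |beta_j|
# by grid search over a box, refined iteratively (the objective is convex,
# so shrinking the window around the current grid argmin is safe as long as
# the window stays several grid steps wide). Shares no code with the
# coordinate-descent solver.
brute_force_wlasso <- function(X, y, lambda, w, lower = -3, upper = 3,
                               n_grid = 41L, rounds = 6L) {
  p <- ncol(X)
  w <- rep_len(w, p)
  lo <- rep(lower, p); hi <- rep(upper, p)
  best <- NULL
  for (r in seq_len(rounds)) {
    grids <- lapply(seq_len(p), function(j)
      seq(lo[j], hi[j], length.out = n_grid))
    cand <- as.matrix(expand.grid(grids))
    fitted <- cand %*% t(X)   # candidates x n
    sse <- rowSums((matrix(y, nrow(cand), length(y),
                           byrow = TRUE) - fitted)^2)
    pen <- lambda * drop(abs(cand) %*% w)
    vals <- sse + pen
    i <- which.min(vals)
    best <- cand[i, ]
    step <- (hi - lo) / (n_grid - 1)
    lo <- best - 4 * step
    hi <- best + 4 * step
  }
  best
}

# Fixed small test problems (p <= 3) with varied correlation structure and
# weights, including an unpenalized (w = 0) column.
make_fixture_set <- function() {
  fx <- list()
  withr::with_seed(42, {
    X1 <- matrix(rnorm(20), 20, 1)
    fx[[1]] <- list(X = X1, y = drop(X1) * 0.8 + rnorm(20), lambda = 2,
                    w = 1)
    X2 <- matrix(rnorm(40), 20, 2)
    X2[, 2] <- 0.7 * X2[, 1] + 0.5 * X2[, 2]  # correlated pair
    fx[[2]] <- list(X = X2, y = X2[, 1] - 0.5 * X2[, 2] + rnorm(20),
                    lambda = 4, w = c(1, 2))
    X3 <- matrix(rnorm(60), 20, 3)
    fx[[3]] <- list(X = X3, y = drop(X3 %*% c(1, 0, -0.6)) + rnorm(20),
                    lambda = 6, w = c(0.5, 3, 1))
    X4 <- matrix(rnorm(60), 20, 3)
    X4[, 3] <- 0.6 * X4[, 1] - 0.6 * X4[, 2] + 0.4 * X4[, 3]
    fx[[4]] <- list(X = X4, y = drop(X4 %*% c(0.5, 0.5, 0)) + rnorm(20),
                    lambda = 3, w = c(1, 1, 0))  # one unpenalized column
    fx[[5]] <- list(X = X3, y = fx[[3]]$y, lambda = 0.5, w = c(1, 1, 1))
  })
  fx
}

# Orthonormal design helper (columns of Q from a QR decomposition)
orthonormal_design <- function(n, p, seed = 7) {
  withr::with_seed(seed, qr.Q(qr(matrix(rnorm(n * p), n, p))))
}

# Write a small exposure CSV fixture; returns the path
write_exposure_fixture <- function(lines, dir = withr::local_tempdir(
                                     .local_envir = parent.frame())) {
  path <- file.path(dir, "exposures.csv")
  writeLines(lines, path)
  path
}
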