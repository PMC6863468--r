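# Independent oracles used to cross-check the package's own fitting paths.

# Brute-force grid search minimising the log-scale SSE of the
# exponential-quadratic curve over an (a, b, c) lattice, iteratively
# refined until the grid spacing falls below `resolution`. Deliberately
# independent of the closed-form least-squares path it checks.
grid_search_fit <- function(tt, y,
                            a_range = c(-12, 2), b_range = c(-0.3, 0.5),
                            c_range = c(-0.02, 0.02),
                            n_grid = 13, resolution = 1e-4) {
  ly <- log(y)
  X <- cbind(1, tt, tt^2)
  ranges <- list(a = a_range, b = b_range, c = c_range)
  repeat {
    grids <- lapply(ranges, function(r) seq(r[1], r[2], length.out = n_grid))
    lattice <- expand.grid(a = grids$a, b = grids$b, c = grids$c)
    resid <- ly - X %*% t(as.matrix(lattice))
    sse <- colSums(resid^2)
    best <- lattice[which.min(sse), ]
    spacing <- vapply(grids, function(g) g[2] - g[1], numeric(1))
    if (all(spacing < resolution)) {
      return(list(a = best$a, b = best$b, c = best$c, sse = min(sse)))
    }
    # shrink each range to +/- 1.5 grid steps around the current best point
    ranges <- Map(function(centre, step) c(centre - 1.5 * step,
                                           centre + 1.5 * step),
                  as.list(unlist(best)), as.list(spacing))
  }
}

# Log-scale SSE of a fitted (a, b, c) triple -- shared metric for the
# oracle comparison.
log_sse <- function(fit, tt, y) {
  sum((log(y) - (fit$a + fit$b * tt + fit$c * tt^2))^2)
}

# Random small temperature series from a known curve with lognormal noise.
random_series <- function(truth_abc = c(a = -6, b = 0.1, c = -0.001),
                          noise_sd = 0.2,
                          tt = c(14, 23, 32, 41, 45)) {
  y <- exp(truth_abc[["a"]] + truth_abc[["b"]] * tt +
             truth_abc[["c"]] * tt^2 + rnorm(length(tt), 0, noise_sd))
  data.frame(T_tissue_C = tt, flux = y)
}
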