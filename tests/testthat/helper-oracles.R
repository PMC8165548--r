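# independent oracles used across the suite; deliberately naive
# implementations kept separate from the package's code paths

# brute-force Gaussian-kernel weighted mean at a single point
oracle_kernel_point <- function(t, a, at, window_sd) {
  w <- exp(-(t - at)^2 / (2 * window_sd^2))
  sum(a * w) / sum(w)
}

# ordinary least squares by the normal equations on raw sums
oracle_ols <- function(t, a) {
  n <- length(t)
  slope <- (n * sum(t * a) - sum(t) * sum(a)) /
    (n * sum(t^2) - sum(t)^2)
  intercept <- mean(a) - slope * mean(t)
  resid <- a - intercept - slope * t
  list(slope = slope, intercept = intercept, resid = resid)
}

# exhaustive enumeration of all 2^k replicate outcomes
oracle_n_of_k <- function(p, n, k) {
  outcomes <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  prob <- apply(outcomes, 1, function(o) prod(ifelse(o, p, 1 - p)))
  sum(prob[rowSums(outcomes) >= n])
}

# trajectory constructed directly from values on the default grid
make_traj <- function(values, grid = grid_spec()) {
  tibble::tibble(
    grid_time = seq(grid$range[1], grid$range[2],
                    length.out = grid$n_points),
    value = rep_len(values, grid$n_points))
}
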