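#' Pseudotime grid and kernel settings for trajectory interpolation
#'
#' @param n_points Number of equally spaced grid points (default 200).
#' @param window_sd Gaussian kernel bandwidth in pseudotime units
#'   (default 0.1).
#' @param range Closed pseudotime interval the grid spans, default
#'   `c(0, 1)`.
#'
#' @return An object of class `grid_spec`.
#' @export
#' @examples
#' grid_spec()
grid_spec <- function(n_points = 200, window_sd = 0.1, range = c(0, 1)) {
  n_points <- check_count(n_points, "n_points", lower = 2L)
  check_number(window_sd, "window_sd")
  if (window_sd <= 0) stop_param("window_sd", "must be > 0")
  range <- check_range(range, "range")
  structure(list(n_points = n_points, window_sd = window_sd, range = range),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d points on [%g, %g], window_sd = %g\n",
              x$n_points, x$range[1], x$range[2], x$window_sd))
  invisible(x)
}

grid_times <- function(grid) {
  seq(grid$range[1], grid$range[2], length.out = grid$n_points)
}

# Nadaraya-Watson kernel-weighted mean of (t, a) evaluated at `at`;
# the numerical core shared by interpolate_trajectory() and the MC engine.
kernel_interp <- function(t, a, at, window_sd) {
  w <- exp(-outer(at, t, "-")^2 / (2 * window_sd^2))
  as.vector(w %*% a) / rowSums(w)
}

new_trajectory <- function(times, values, grid, provenance) {
  out <- tibble(grid_time = times, value = values)
  attr(out, "grid") <- grid
  attr(out, "provenance") <- provenance
  class(out) <- c("trajectory", class(out))
  out
}

#' Interpolate a sparse single-cell sample onto a pseudotime grid
#'
#' Gaussian-kernel weighted averaging (Nadaraya-Watson): the value at grid
#' point `t_k` is `sum(a_i * w_i) / sum(w_i)` with
#' `w_i = exp(-(t_i - t_k)^2 / (2 * window_sd^2))`, weights taken over the
#' sample's own points only. The result is bounded by the sample's
#' abundance range and is exact for constant data.
#'
#' @param sample A data frame with `time` and `abundance` columns (e.g.
#'   from [subsample()]); at least one row.
#' @param grid A [grid_spec()].
#'
#' @return A `trajectory` tibble with columns `grid_time`, `value`.
#' @export
#' @examples
#' s <- tibble::tibble(time = c(0, 0.5, 1), abundance = c(1, 1.5, 2))
#' interpolate_trajectory(s, grid_spec())
interpolate_trajectory <- function(sample, grid = grid_spec()) {
  if (!is.data.frame(sample) ||
      !all(c("time", "abundance") %in% names(sample))) {
    stop_param("sample", "must have `time` and `abundance` columns")
  }
  if (nrow(sample) < 1L) stop_param("sample", "must contain at least one cell")
  if (!inherits(grid, "grid_spec")) stop_param("grid", "must be a grid_spec")
  gt <- grid_times(grid)
  t <- pmin(pmax(sample$time, grid$range[1]), grid$range[2])
  vals <- kernel_interp(t, sample$abundance, gt, grid$window_sd)
  new_trajectory(gt, vals, grid, "interpolated")
}

#' Reference line evaluated on a pseudotime grid
#'
#' Builds the comparison curves used by the area-between-curves decision
#' rule: the known generative line of a simulated population, a flat null
#' line, or a sloped comparator for false-positive runs.
#'
#' @param slope Line slope; 0 gives a constant line.
#' @param anchor Anchor level. With `anchor_mode = "intercept_at_zero"` the
#'   line is `slope * t + anchor`; with `"center_at_mean"` it is
#'   `anchor + slope * (t - midpoint(range))`, i.e. it passes through the
#'   grid midpoint at height `anchor`.
#' @param grid A [grid_spec()].
#' @param anchor_mode `"intercept_at_zero"` or `"center_at_mean"`.
#'
#' @return A `trajectory` tibble.
#' @export
#' @examples
#' reference_line(1, 1, grid_spec(), "intercept_at_zero")
reference_line <- function(slope, anchor, grid = grid_spec(),
                           anchor_mode = c("intercept_at_zero",
                                           "center_at_mean")) {
  anchor_mode <- match.arg(anchor_mode)
  check_number(slope, "slope")
  check_number(anchor, "anchor")
  if (!inherits(grid, "grid_spec")) stop_param("grid", "must be a grid_spec")
  gt <- grid_times(grid)
  vals <- switch(anchor_mode,
    intercept_at_zero = slope * gt + anchor,
    center_at_mean = anchor + slope * (gt - mean(grid$range)))
  new_trajectory(gt, vals, grid,
                 if (slope == 0) "reference_constant" else "reference_line")
}

same_grid <- function(a, b) {
  nrow(a) == nrow(b) && isTRUE(all.equal(a$grid_time, b$grid_time))
}

#' Area between two trajectories
#'
#' Mean absolute difference between two trajectories over their shared
#' grid — a Riemann approximation of the area between the curves divided
#' by the grid's span, so values are comparable across grid resolutions.
#' Symmetric, non-negative, and zero only for identical curves; the
#' classification rules in [classify_subsample()] compare these distances.
#'
#' @param a,b `trajectory` tibbles on identical grids.
#' @return A single non-negative number.
#' @export
#' @examples
#' g <- grid_spec()
#' area_between(reference_line(1, 0, g), reference_line(0, 0, g))
area_between <- function(a, b) {
  for (x in list(a, b)) {
    if (!is.data.frame(x) || !all(c("grid_time", "value") %in% names(x))) {
      stop_param("a", "trajectories must have `grid_time` and `value` columns")
    }
  }
  if (!same_grid(a, b)) {
    stop_param("b", "trajectories must share the same grid")
  }
  mean(abs(a$value - b$value))
}

#' Read or write a trajectory as CSV
#'
#' Columns `grid_time,value`.
#'
#' @param x A `trajectory` tibble.
#' @param path File path.
#' @return `write_trajectory()` returns `x` invisibly; `read_trajectory()`
#'   a tibble.
#' @export
write_trajectory <- function(x, path) {
  out <- as_tibble(x)[c("grid_time", "value")]
  out$grid_time <- sprintf("%.17g", out$grid_time)
  out$value <- sprintf("%.17g", out$value)
  readr::write_csv(out, path)
  invisible(x)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  tibble(grid_time = as.numeric(raw$grid_time),
         value = as.numeric(raw$value))
}
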