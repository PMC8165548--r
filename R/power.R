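#' Classify one subsample as changing or non-changing
#'
#' Interpolates the sample onto the references' grid and compares two
#' area-between-curves distances. In a true-positive run the references
#' are the population's generative line (`truth`) and a flat null line
#' (`alternative`); the subsample is called *changing* when its trajectory
#' is strictly closer to the truth than to the null. In a false-positive
#' run the truth is the flat line of a non-changing population and the
#' alternative a sloped comparator; the subsample is called *changing*
#' (a false positive) when its trajectory is strictly closer to the sloped
#' line. Ties are classified non-changing.
#'
#' @param sample A data frame with `time` and `abundance` columns.
#' @param truth A `trajectory`: the population's true curve.
#' @param alternative A `trajectory`: the flat null line (`tp_run`) or the
#'   sloped comparator (`fp_run`).
#' @param mode `"tp_run"` or `"fp_run"`.
#' @param grid A [grid_spec()] matching the reference trajectories.
#'
#' @return A one-row tibble with columns `abc_true`, `abc_alternative`,
#'   `verdict` (`"changing"`/`"nonchanging"`) and `mode`.
#' @export
#' @examples
#' g <- grid_spec()
#' s <- tibble::tibble(time = c(0, 0.5, 1), abundance = c(1, 1.5, 2))
#' classify_subsample(s, reference_line(1, 1, g),
#'                    reference_line(0, 1.5, g), "tp_run", g)
classify_subsample <- function(sample, truth, alternative,
                               mode = c("tp_run", "fp_run"),
                               grid = grid_spec()) {
  mode <- match.arg(mode)
  if (!same_grid(truth, alternative)) {
    stop_param("alternative", "references must share the same grid")
  }
  traj <- interpolate_trajectory(sample, grid)
  if (!same_grid(traj, truth)) {
    stop_param("grid", "must match the reference trajectories' grid")
  }
  abc_true <- area_between(traj, truth)
  abc_alt <- area_between(traj, alternative)
  verdict <- classify_abc(abc_true, abc_alt, mode)
  tibble(abc_true = abc_true, abc_alternative = abc_alt,
         verdict = verdict, mode = mode)
}

# decision rule shared with the MC engine; strict inequalities, so exact
# ties fall to "nonchanging" (conservative toward the null)
classify_abc <- function(abc_true, abc_alt, mode) {
  changing <- if (mode == "tp_run") abc_true < abc_alt else abc_alt < abc_true
  ifelse(changing, "changing", "nonchanging")
}

# One Monte-Carlo repeat: simulate a population, draw `n_subsamples`
# subsamples of size n_sample, classify each, return the fraction called
# changing. Runs in the ambient RNG stream (callers seed it).
mc_repeat_rate <- function(spec, n_sample, grid, n_subsamples,
                           mode, comparator_slope = NULL,
                           anchor = "population") {
  gt <- grid_times(grid)
  time <- runif(spec$n_cells, spec$time_range[1], spec$time_range[2])
  abundance <- spec$slope * time + spec$intercept +
    rnorm(spec$n_cells, 0, spec$noise_sd)
  mid <- mean(spec$time_range)
  level <- spec_mean_level(spec)
  if (mode == "tp_run") {
    truth_vals <- spec$slope * gt + spec$intercept
  } else {
    truth_vals <- rep(spec$intercept, length(gt))
  }
  hits <- vapply(seq_len(n_subsamples), function(i) {
    idx <- sample.int(spec$n_cells, n_sample)
    tr <- kernel_interp(time[idx], abundance[idx], gt, grid$window_sd)
    anchor_level <- if (anchor == "population") level else
      mean(abundance[idx])
    alt_vals <- if (mode == "tp_run") {
      rep(anchor_level, length(gt))
    } else {
      anchor_level + comparator_slope * (gt - mid)
    }
    abc_true <- mean(abs(tr - truth_vals))
    abc_alt <- mean(abs(tr - alt_vals))
    classify_abc(abc_true, abc_alt, mode) == "changing"
  }, logical(1))
  mean(hits)
}

new_power_estimate <- function(rates, rate_kind, params, n_subsamples,
                               n_repeats, seed) {
  structure(
    list(rate = mean(rates), spread = if (length(rates) > 1) sd(rates) else 0,
         rate_kind = rate_kind,
         repeats = tibble(repeat_id = seq_along(rates), rate = rates),
         params = params, n_subsamples = n_subsamples,
         n_repeats = n_repeats, seed = seed),
    class = "power_estimate")
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> %s = %.3f (sd %.3f across %d repeats of %d subsamples)\n",
              x$rate_kind, x$rate, x$spread, x$n_repeats, x$n_subsamples))
  print(x$params)
  invisible(x)
}

#' @rdname estimate_accuracy
#' @param x A `power_estimate`.
#' @param ... Unused.
#' @export
tidy.power_estimate <- function(x, ...) {
  dplyr::bind_cols(x$repeats,
                   x$params[rep(1L, nrow(x$repeats)), , drop = FALSE])
}

#' @rdname estimate_accuracy
#' @export
glance.power_estimate <- function(x, ...) {
  dplyr::bind_cols(
    tibble(rate_kind = x$rate_kind, rate = x$rate, spread = x$spread,
           n_subsamples = x$n_subsamples, n_repeats = x$n_repeats),
    x$params)
}

#' Monte-Carlo accuracy of detecting a changing protein
#'
#' Estimates the true-positive rate for one `(slope, noise_sd, n_sample)`
#' cell: in each of `n_repeats` repeats a fresh population is simulated,
#' `n_subsamples` subsamples of `n_sample` cells are drawn, interpolated,
#' and classified against the population's generative line versus a flat
#' null line; the accuracy is the fraction classified changing, averaged
#' over repeats, with the across-repeat standard deviation as spread.
#'
#' By default the flat null is anchored at the population's mean abundance
#' level (the generative line's value at the midpoint of the time range);
#' `null_anchor = "subsample"` instead anchors it at each subsample's own
#' mean.
#'
#' @param spec A [population_spec()] with non-zero slope.
#' @param n_sample Cells per subsample.
#' @param grid A [grid_spec()].
#' @param n_subsamples Subsamples per repeat (default 1000).
#' @param n_repeats Independent repeats, each with a fresh population
#'   (default 10).
#' @param seed Integer master seed.
#' @param null_anchor `"population"` (default) or `"subsample"`.
#'
#' @return A `power_estimate`; see [tidy.power_estimate()] and
#'   [glance.power_estimate()].
#' @export
#' @examples
#' est <- estimate_accuracy(population_spec(1, 0.25), n_sample = 16,
#'                          n_subsamples = 50, n_repeats = 2, seed = 1)
#' glance(est)
estimate_accuracy <- function(spec, n_sample, grid = grid_spec(),
                              n_subsamples = 1000, n_repeats = 10,
                              seed = NULL,
                              null_anchor = c("population", "subsample")) {
  null_anchor <- match.arg(null_anchor)
  if (!inherits(spec, "population_spec")) {
    stop_param("spec", "must be a population_spec")
  }
  if (spec$slope == 0) {
    stop_param("spec$slope",
               "must be non-zero for an accuracy run; use estimate_fp_rate() for non-changing populations")
  }
  n_sample <- check_count(n_sample, "n_sample")
  if (n_sample > spec$n_cells) stop_param("n_sample", "exceeds n_cells")
  n_subsamples <- check_count(n_subsamples, "n_subsamples")
  n_repeats <- check_count(n_repeats, "n_repeats")
  rates <- with_seed_(seed, {
    vapply(seq_len(n_repeats), function(r) {
      mc_repeat_rate(spec, n_sample, grid, n_subsamples, "tp_run",
                     anchor = null_anchor)
    }, numeric(1))
  })
  params <- tibble(slope = spec$slope, noise_sd = spec$noise_sd,
                   sv = if (spec$noise_sd > 0) spec$slope / spec$noise_sd else Inf,
                   n_sample = n_sample)
  new_power_estimate(rates, "accuracy", params, n_subsamples, n_repeats, seed)
}

#' Monte-Carlo false-positive rate for a non-changing protein
#'
#' Simulates populations with slope 0 and noise `noise_sd`, classifies
#' subsamples against the flat truth versus a sloped comparator line of
#' slope `comparator_slope`, and reports the fraction wrongly called
#' changing. The comparator is centered: it passes through the population
#' mean level (default) or the subsample mean at the midpoint of the time
#' range, so the comparison is about shape rather than offset.
#'
#' @param noise_sd Cell-to-cell noise standard deviation (>= 0).
#' @param comparator_slope Slope of the false-positive comparator line
#'   (> 0). `comparator_slope / noise_sd` is the S/V ratio of the cell.
#' @param intercept Population abundance level (default 1).
#' @param n_cells Population size (default 10000).
#' @param comparator_anchor `"population"` (default) or `"subsample"`.
#' @inheritParams estimate_accuracy
#'
#' @return A `power_estimate` with `rate_kind = "fp_rate"`.
#' @export
#' @examples
#' est <- estimate_fp_rate(noise_sd = 0.5, comparator_slope = 1,
#'                         n_sample = 16, n_subsamples = 50,
#'                         n_repeats = 2, seed = 1)
#' glance(est)
estimate_fp_rate <- function(noise_sd, comparator_slope, n_sample,
                             grid = grid_spec(), n_subsamples = 1000,
                             n_repeats = 10, seed = NULL, intercept = 1,
                             n_cells = 10000,
                             comparator_anchor = c("population",
                                                   "subsample")) {
  comparator_anchor <- match.arg(comparator_anchor)
  check_number(noise_sd, "noise_sd", lower = 0)
  check_number(comparator_slope, "comparator_slope")
  if (comparator_slope <= 0) stop_param("comparator_slope", "must be > 0")
  spec <- population_spec(slope = 0, noise_sd = noise_sd, n_cells = n_cells,
                          intercept = intercept)
  n_sample <- check_count(n_sample, "n_sample")
  n_subsamples <- check_count(n_subsamples, "n_subsamples")
  n_repeats <- check_count(n_repeats, "n_repeats")
  rates <- with_seed_(seed, {
    vapply(seq_len(n_repeats), function(r) {
      mc_repeat_rate(spec, n_sample, grid, n_subsamples, "fp_run",
                     comparator_slope = comparator_slope,
                     anchor = comparator_anchor)
    }, numeric(1))
  })
  params <- tibble(slope = comparator_slope, noise_sd = noise_sd,
                   sv = if (noise_sd > 0) comparator_slope / noise_sd else Inf,
                   n_sample = n_sample)
  new_power_estimate(rates, "fp_rate", params, n_subsamples, n_repeats, seed)
}

#' Realisations of an S/V ratio
#'
#' Expands one S/V ratio into several concrete `(slope, noise_sd)` pairs
#' with `slope / noise_sd == ratio`, used to demonstrate that detection
#' rates depend on the parameters only through their ratio. The default
#' slopes follow the simulation design: `(0.5, 0.75, 1, 1.5, 2, 3)`.
#'
#' @param ratio Positive S/V ratio.
#' @param slopes Slopes to realise the ratio with; `noise_sd = slope /
#'   ratio`.
#' @return A tibble with columns `sv`, `slope`, `noise_sd`.
#' @export
#' @examples
#' sv_realizations(0.5)
sv_realizations <- function(ratio, slopes = c(0.5, 0.75, 1, 1.5, 2, 3)) {
  check_number(ratio, "ratio")
  if (ratio <= 0) stop_param("ratio", "must be > 0")
  if (!is.numeric(slopes) || length(slopes) < 1L || any(slopes <= 0)) {
    stop_param("slopes", "must be positive numbers")
  }
  tibble(sv = ratio, slope = slopes, noise_sd = slopes / ratio)
}

#' Sweep true-positive and false-positive rates over S/V ratios
#'
#' Runs [estimate_accuracy()] and/or [estimate_fp_rate()] for every
#' `(realisation, n_sample)` combination. Accuracy runs use the
#' realisation's `(slope, noise_sd)` as the generative parameters;
#' false-positive runs use a zero-slope population with the realisation's
#' `noise_sd` and its `slope` as the comparator slope. Per-realisation
#' rows are kept so scale invariance across realisations of one ratio is
#' directly testable; [sv_summary()] pools them.
#'
#' @param realizations A tibble with columns `sv`, `slope`, `noise_sd`
#'   (rows from [sv_realizations()], possibly several ratios bound
#'   together).
#' @param n_samples Integer vector of subsample sizes.
#' @param rate_kinds Any of `"accuracy"`, `"fp_rate"`.
#' @inheritParams estimate_accuracy
#'
#' @return A tibble of class `power_table` with columns `rate_kind`, `sv`,
#'   `slope`, `noise_sd`, `n_sample`, `rate`, `spread`.
#' @export
#' @examples
#' tab <- sv_sweep(sv_realizations(2, slopes = c(1, 2)), n_samples = 16,
#'                 n_subsamples = 50, n_repeats = 2, seed = 1)
#' sv_summary(tab)
sv_sweep <- function(realizations, n_samples,
                     rate_kinds = c("accuracy", "fp_rate"),
                     grid = grid_spec(), n_subsamples = 1000,
                     n_repeats = 10, seed = NULL) {
  rate_kinds <- match.arg(rate_kinds, several.ok = TRUE)
  if (!is.data.frame(realizations) || nrow(realizations) == 0L ||
      !all(c("sv", "slope", "noise_sd") %in% names(realizations))) {
    stop_param("realizations",
               "must be a non-empty tibble with columns sv, slope, noise_sd")
  }
  if (any(realizations$noise_sd <= 0)) {
    stop_param("realizations$noise_sd", "must be > 0")
  }
  cells <- tidyr::expand_grid(
    rate_kind = rate_kinds,
    realizations[c("sv", "slope", "noise_sd")],
    n_sample = as.integer(n_samples))
  seeds <- with_seed_(seed, child_seeds(nrow(cells)))
  rows <- purrr::pmap(
    c(cells, list(cell_seed = seeds)),
    function(rate_kind, sv, slope, noise_sd, n_sample, cell_seed) {
      est <- if (rate_kind == "accuracy") {
        estimate_accuracy(population_spec(slope, noise_sd), n_sample,
                          grid = grid, n_subsamples = n_subsamples,
                          n_repeats = n_repeats, seed = cell_seed)
      } else {
        estimate_fp_rate(noise_sd, comparator_slope = slope,
                         n_sample = n_sample, grid = grid,
                         n_subsamples = n_subsamples,
                         n_repeats = n_repeats, seed = cell_seed)
      }
      tibble(rate_kind = rate_kind, sv = sv, slope = slope,
             noise_sd = noise_sd, n_sample = n_sample,
             rate = est$rate, spread = est$spread)
    })
  out <- dplyr::bind_rows(rows)
  attr(out, "n_subsamples") <- n_subsamples
  attr(out, "n_repeats") <- n_repeats
  class(out) <- c("power_table", class(out))
  out
}

#' Pool a power table over realisations of each S/V ratio
#'
#' @param table A `power_table` from [sv_sweep()].
#' @return A tibble with one row per `(rate_kind, sv, n_sample)`: the mean
#'   `rate` over realisations, the root-mean-square of the per-realisation
#'   spreads (`spread`), the across-realisation standard deviation of the
#'   rates (`realization_sd`), and `n_realizations`.
#' @export
sv_summary <- function(table) {
  if (!is.data.frame(table) ||
      !all(c("rate_kind", "sv", "n_sample", "rate") %in% names(table))) {
    stop_param("table", "must be a power_table")
  }
  dplyr::summarise(
    dplyr::group_by(as_tibble(table), .data$rate_kind, .data$sv,
                    .data$n_sample),
    realization_sd = if (dplyr::n() > 1) sd(.data$rate) else 0,
    spread = sqrt(mean(.data$spread^2)),
    rate = mean(.data$rate),
    n_realizations = dplyr::n(),
    .groups = "drop")
}

#' Plot a power table
#'
#' Detection rate against the number of sampled cells, one line per S/V
#' ratio, faceted by rate kind, with error bars of one across-repeat
#' standard deviation.
#'
#' @param object A `power_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.power_table <- function(object, ...) {
  pooled <- sv_summary(object)
  ggplot2::ggplot(pooled,
                  ggplot2::aes(x = .data$n_sample, y = .data$rate,
                               colour = factor(.data$sv),
                               group = factor(.data$sv))) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$rate - .data$spread,
                                          ymax = .data$rate + .data$spread)) +
    ggplot2::facet_wrap(~rate_kind) +
    ggplot2::labs(x = "cells sampled per time course", y = "rate",
                  colour = "S/V") +
    ggplot2::ylim(0, 1)
}
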