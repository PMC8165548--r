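#' Estimate the S/V ratio of a sample by linear regression
#'
#' Fits ordinary least squares of abundance on time; the fitted slope is
#' the slope estimate and the standard deviation of the residuals the
#' variation estimate. The reported ratio uses the slope magnitude,
#' `|slope_est| / variation_est`, since S/V is an effect-size-to-noise
#' magnitude; it is `Inf` when the residuals are exactly zero.
#'
#' @param sample A data frame with `time` and `abundance` columns, at
#'   least 3 rows and at least two distinct times.
#' @param residual_denominator `"n-1"` (sample standard deviation of the
#'   residuals, default) or `"n-2"` (regression residual standard error).
#'
#' @return An object of class `sv_estimate` with fields `slope_est`,
#'   `variation_est`, `ratio_est`, `n`; see [tidy.sv_estimate()] and
#'   [glance.sv_estimate()].
#' @export
#' @examples
#' s <- tibble::tibble(time = c(0, 0.5, 1), abundance = c(1, 2, 1))
#' estimate_sv(s)
estimate_sv <- function(sample, residual_denominator = c("n-1", "n-2")) {
  residual_denominator <- match.arg(residual_denominator)
  if (!is.data.frame(sample) ||
      !all(c("time", "abundance") %in% names(sample))) {
    stop_param("sample", "must have `time` and `abundance` columns")
  }
  n <- nrow(sample)
  if (n < 3L) {
    abort("S/V estimation needs at least 3 cells",
          class = "svpower_estimation_error")
  }
  if (length(unique(sample$time)) < 2L) {
    abort("S/V estimation needs at least two distinct time values",
          class = "svpower_estimation_error")
  }
  fit <- stats::lm.fit(cbind(intercept = 1, time = sample$time),
                       sample$abundance)
  slope_est <- unname(fit$coefficients["time"])
  denom <- if (residual_denominator == "n-1") n - 1 else n - 2
  variation_est <- sqrt(sum(fit$residuals^2) / denom)
  # residuals at the level of float rounding mean an exact fit
  if (variation_est <= zero_resid_tol(sample$abundance)) variation_est <- 0
  ratio_est <- if (variation_est > 0) abs(slope_est) / variation_est else Inf
  structure(list(slope_est = slope_est, variation_est = variation_est,
                 ratio_est = ratio_est, n = n,
                 residual_denominator = residual_denominator),
            class = "sv_estimate")
}

#' @export
print.sv_estimate <- function(x, ...) {
  cat(sprintf("<sv_estimate> slope %.4g, variation %.4g, S/V %.4g (n = %d)\n",
              x$slope_est, x$variation_est, x$ratio_est, x$n))
  invisible(x)
}

#' @rdname estimate_sv
#' @param x An `sv_estimate`.
#' @param ... Unused.
#' @export
tidy.sv_estimate <- function(x, ...) {
  tibble(term = c("slope", "variation", "sv_ratio"),
         estimate = c(x$slope_est, x$variation_est, x$ratio_est))
}

#' @rdname estimate_sv
#' @export
glance.sv_estimate <- function(x, ...) {
  tibble(slope_est = x$slope_est, variation_est = x$variation_est,
         ratio_est = x$ratio_est, n = x$n)
}

# threshold below which a residual spread is float noise from an exact fit
zero_resid_tol <- function(abundance) {
  1e-12 * max(diff(range(abundance)), abs(abundance), 1)
}

# simulate one population at a given true S/V and return n_events ratio
# estimates from subsamples of n_sample cells (ambient RNG stream)
sv_estimate_events <- function(true_sv, n_sample, n_events, n_cells,
                               noise_sd, intercept,
                               residual_denominator = "n-1") {
  time <- runif(n_cells)
  abundance <- true_sv * noise_sd * time + intercept +
    rnorm(n_cells, 0, noise_sd)
  denom_nm1 <- residual_denominator == "n-1"
  vapply(seq_len(n_events), function(i) {
    idx <- sample.int(n_cells, n_sample)
    fit <- stats::.lm.fit(cbind(1, time[idx]), abundance[idx])
    v <- sqrt(sum(fit$residuals^2) /
                (if (denom_nm1) n_sample - 1 else n_sample - 2))
    if (v > zero_resid_tol(abundance[idx])) {
      abs(fit$coefficients[2]) / v
    } else {
      Inf
    }
  }, numeric(1))
}

#' Error distribution of the S/V estimator
#'
#' Simulates a population with a known S/V ratio, repeatedly subsamples it
#' and estimates S/V by [estimate_sv()]'s regression recipe, and returns
#' the distribution of `true_sv - ratio_est` — the error a practitioner
#' makes when estimating S/V from a finite destructive sample.
#'
#' @param true_sv True S/V ratio of the simulated population (> 0; the
#'   realisation uses `slope = true_sv * noise_sd`, and by the estimator's
#'   scale-freeness the realisation does not matter).
#' @param n_sample Cells per subsampling event (vectorised; >= 3).
#' @param n_events Subsampling events per sample size (default 1000).
#' @param n_cells Population size (default 10000).
#' @param noise_sd Noise standard deviation of the realisation (default 1).
#' @param intercept Population intercept (default 1).
#' @param seed Integer master seed.
#'
#' @return A tibble of class `sv_error_dist` with columns `n_sample`,
#'   `event`, `error`; `glance()` summarises mean, sd and quantiles per
#'   sample size.
#' @export
#' @examples
#' d <- sv_error_distribution(1, n_sample = 30, n_events = 100, seed = 1)
#' glance(d)
sv_error_distribution <- function(true_sv, n_sample, n_events = 1000,
                                  n_cells = 10000, noise_sd = 1,
                                  intercept = 1, seed = NULL) {
  check_number(true_sv, "true_sv", lower = 0)
  check_number(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop_param("noise_sd", "must be > 0")
  n_events <- check_count(n_events, "n_events")
  n_cells <- check_count(n_cells, "n_cells")
  if (any(n_sample < 3)) stop_param("n_sample", "must be >= 3")
  out <- with_seed_(seed, {
    purrr::map(as.integer(n_sample), function(n) {
      est <- sv_estimate_events(true_sv, n, n_events, n_cells, noise_sd,
                                intercept)
      tibble(n_sample = n, event = seq_len(n_events),
             error = true_sv - est)
    })
  })
  out <- dplyr::bind_rows(out)
  attr(out, "true_sv") <- true_sv
  class(out) <- c("sv_error_dist", class(out))
  out
}

#' @rdname sv_error_distribution
#' @param x An `sv_error_dist`.
#' @param ... Unused.
#' @export
glance.sv_error_dist <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(as_tibble(x), .data$n_sample),
    mean_error = mean(.data$error),
    sd_error = sd(.data$error),
    q025 = quantile(.data$error, 0.025),
    q50 = quantile(.data$error, 0.5),
    q975 = quantile(.data$error, 0.975),
    n_events = dplyr::n(),
    .groups = "drop")
}

#' @rdname sv_error_distribution
#' @param object An `sv_error_dist`.
#' @export
autoplot.sv_error_dist <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$error,
                               colour = factor(.data$n_sample))) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "true S/V - estimated S/V", colour = "cells sampled")
}

#' Retention under an estimated-S/V cutoff
#'
#' Simulates one population per true S/V value, repeatedly subsamples it,
#' estimates S/V per event, and reports the fraction of events whose
#' estimate clears the cutoff — i.e. how many proteins of each true
#' quality survive filtering on the estimated ratio.
#'
#' @param true_svs Numeric vector of true S/V ratios (>= 0; 0 is a
#'   non-changing protein).
#' @param cutoff Retention threshold on the estimated ratio (default 1);
#'   events with `ratio_est >= cutoff` are retained.
#' @param n_sample Cells per subsampling event (default 30).
#' @param n_events Events per population (default 1000).
#' @param n_cells Population size (default 1000).
#' @inheritParams sv_error_distribution
#'
#' @return A tibble of class `retention_table` with columns `true_sv`,
#'   `cutoff`, `n_sample`, `n_events`, `fraction_retained`.
#' @export
#' @examples
#' filter_retention(c(0, 2), n_events = 100, seed = 1)
filter_retention <- function(true_svs, cutoff = 1, n_sample = 30,
                             n_events = 1000, n_cells = 1000,
                             noise_sd = 1, intercept = 1, seed = NULL) {
  if (!is.numeric(true_svs) || length(true_svs) < 1L || any(true_svs < 0)) {
    stop_param("true_svs", "must be a non-empty vector of non-negative ratios")
  }
  check_number(cutoff, "cutoff", allow_inf = TRUE)
  n_sample <- check_count(n_sample, "n_sample", lower = 3L)
  n_events <- check_count(n_events, "n_events")
  n_cells <- check_count(n_cells, "n_cells")
  rows <- with_seed_(seed, {
    purrr::map(true_svs, function(sv) {
      est <- sv_estimate_events(sv, n_sample, n_events, n_cells, noise_sd,
                                intercept)
      tibble(true_sv = sv, cutoff = cutoff, n_sample = n_sample,
             n_events = n_events, fraction_retained = mean(est >= cutoff))
    })
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("retention_table", class(out))
  out
}

#' @rdname filter_retention
#' @param object A `retention_table`.
#' @param ... Unused.
#' @export
autoplot.retention_table <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = factor(.data$true_sv),
                               y = 100 * .data$fraction_retained)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "true S/V", y = "% of sampling events retained")
}
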