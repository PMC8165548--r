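#' Detection rate across independent replicate time courses
#'
#' With per-time-course detection probability `p` and `x` independent
#' replicates, the probability of detecting in *every* replicate is
#' `p^x`. Applied to a true-positive rate it gives the replicated TP
#' rate; applied to a false-positive rate it gives the (much smaller)
#' replicated FP rate.
#'
#' @param p Per-time-course probability, in \[0, 1\] (vectorised).
#' @param x Number of independent replicates (>= 1).
#' @return `p^x`.
#' @export
#' @examples
#' replicate_rate(0.9, 2)   # 0.81
#' replicate_rate(0.05, 2)  # 0.0025
replicate_rate <- function(p, x) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_param("p", "must be probabilities in [0, 1]")
  }
  x <- check_count(x, "x")
  p^x
}

#' Detection rate requiring n of k replicates
#'
#' Probability that at least `n` of `k` independent replicate time courses
#' detect, when each detects with probability `p`: the binomial upper tail
#' `sum_{j=n..k} C(k, j) p^j (1-p)^(k-j)`.
#'
#' @inheritParams replicate_rate
#' @param n Minimum number of detecting replicates (1 <= n <= k).
#' @param k Number of replicates.
#' @return A probability (vectorised over `p`).
#' @export
#' @examples
#' n_of_k_rate(0.5, 1, 3)        # 0.875
#' n_of_k_rate(0.9, 2, 2)        # same as replicate_rate(0.9, 2)
n_of_k_rate <- function(p, n, k) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_param("p", "must be probabilities in [0, 1]")
  }
  n <- check_count(n, "n")
  k <- check_count(k, "k")
  if (n > k) stop_param("n", "must be <= k")
  pbinom(n - 1, k, p, lower.tail = FALSE)
}

# exact lookup of a pooled (rate_kind, sv, n_sample) cell in a power table
lookup_rate <- function(pooled, kind, sv, n_sample) {
  hit <- pooled[pooled$rate_kind == kind & pooled$sv == sv &
                  pooled$n_sample == n_sample, ]
  if (nrow(hit) != 1L) {
    abort(sprintf(
      "no %s entry for S/V = %g, n_sample = %d in the rate table (exact lookup, no interpolation)",
      kind, sv, n_sample), class = "svpower_lookup_error")
  }
  hit$rate
}

#' Evaluate cell-budget allocation scenarios
#'
#' Compares ways to split a fixed total number of cells between density
#' within a time course and number of replicate time courses. Per-course
#' TP and FP rates are looked up (exactly, no interpolation) from a rate
#' table produced by [sv_sweep()], then combined across replicates with
#' [replicate_rate()] (`all_of_k`) or [n_of_k_rate()]
#' (`at_least_n_of_k`).
#'
#' @param total_cells Total cell budget.
#' @param options A list of `c(cells_per_course, n_replicates)` pairs, or
#'   a two-column data frame with those columns.
#' @param rate_source A `power_table` from [sv_sweep()] (or its
#'   [sv_summary()]), containing `accuracy` and `fp_rate` rows for the
#'   requested S/V and sample sizes.
#' @param sv S/V ratio the scenarios are evaluated at.
#' @param detection_rule `"all_of_k"` (default) or `"at_least_n_of_k"`.
#' @param n_required Minimum detecting replicates for
#'   `"at_least_n_of_k"`.
#'
#' @return A tibble with one row per option: `option`,
#'   `cells_per_course`, `n_replicates`, `cells_used`, `per_course_tp`,
#'   `per_course_fp`, `overall_tp`, `overall_fp`.
#' @export
#' @examples
#' rates <- tibble::tibble(
#'   rate_kind = rep(c("accuracy", "fp_rate"), each = 2),
#'   sv = 2, n_sample = c(16, 25, 16, 25),
#'   rate = c(0.80, 0.87, 0.15, 0.09), spread = 0)
#' evaluate_budget(50, list(c(25, 2), c(16, 3)), rates, sv = 2)
evaluate_budget <- function(total_cells, options, rate_source, sv,
                            detection_rule = c("all_of_k",
                                               "at_least_n_of_k"),
                            n_required = NULL) {
  detection_rule <- match.arg(detection_rule)
  total_cells <- check_count(total_cells, "total_cells")
  if (is.data.frame(options)) {
    options <- purrr::pmap(options[c("cells_per_course", "n_replicates")], c)
  }
  if (!is.list(options) || length(options) == 0L) {
    stop_param("options", "must be a non-empty list of (cells_per_course, n_replicates) pairs")
  }
  pooled <- if (all(c("realization_sd", "n_realizations") %in%
                    names(rate_source))) {
    rate_source
  } else {
    sv_summary(rate_source)
  }
  rows <- purrr::imap(options, function(opt, i) {
    cells <- check_count(opt[[1]], "cells_per_course")
    reps <- check_count(opt[[2]], "n_replicates")
    used <- cells * reps
    if (used > total_cells) {
      stop_param("options", sprintf(
        "option %d uses %d cells, exceeding the budget of %d",
        i, used, total_cells))
    }
    tp <- lookup_rate(pooled, "accuracy", sv, cells)
    fp <- lookup_rate(pooled, "fp_rate", sv, cells)
    combine <- function(p) {
      if (detection_rule == "all_of_k") {
        replicate_rate(p, reps)
      } else {
        n_req <- n_required %||%
          stop_param("n_required", "must be given for at_least_n_of_k")
        n_of_k_rate(p, n_req, reps)
      }
    }
    tibble(option = sprintf("%dx%d", cells, reps),
           cells_per_course = cells, n_replicates = reps,
           cells_used = used, per_course_tp = tp, per_course_fp = fp,
           overall_tp = combine(tp), overall_fp = combine(fp))
  })
  dplyr::bind_rows(rows)
}
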