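#' Describe a simulated single-cell population
#'
#' A population spec holds the generative parameters for a simulated
#' protein: each cell gets a pseudotime drawn uniformly on `time_range`
#' and an abundance `slope * time + intercept + e`, with `e` zero-mean
#' Gaussian noise of standard deviation `noise_sd`. The slope-to-noise
#' ratio `slope / noise_sd` is the S/V ratio the rest of the package is
#' organised around.
#'
#' @param slope Abundance change per unit pseudotime (may be 0 for a
#'   non-changing protein).
#' @param noise_sd Standard deviation of the cell-to-cell noise term;
#'   must be non-negative. Covers biological and technical variability
#'   jointly.
#' @param n_cells Number of cells in the population (default 10000).
#' @param intercept Abundance at pseudotime 0 (default 1).
#' @param time_range Closed pseudotime interval, default `c(0, 1)`.
#'
#' @return An object of class `population_spec`.
#' @seealso [simulate_population()]
#' @export
#' @examples
#' population_spec(slope = 1, noise_sd = 0.25)
population_spec <- function(slope, noise_sd, n_cells = 10000,
                            intercept = 1, time_range = c(0, 1)) {
  check_number(slope, "slope")
  check_number(noise_sd, "noise_sd", lower = 0)
  n_cells <- check_count(n_cells, "n_cells")
  check_number(intercept, "intercept")
  time_range <- check_range(time_range, "time_range")
  structure(
    list(slope = slope, intercept = intercept, noise_sd = noise_sd,
         n_cells = n_cells, time_range = time_range),
    class = "population_spec"
  )
}

#' @export
print.population_spec <- function(x, ...) {
  cat(sprintf(
    "<population_spec> abundance = %g * time + %g + N(0, %g), %d cells, time in [%g, %g]\n",
    x$slope, x$intercept, x$noise_sd, x$n_cells,
    x$time_range[1], x$time_range[2]))
  invisible(x)
}

# population mean abundance level implied by a spec (line evaluated at the
# midpoint of the time range); the anchoring level for population-level
# reference curves
spec_mean_level <- function(spec) {
  spec$slope * mean(spec$time_range) + spec$intercept
}

#' Simulate a single-cell population
#'
#' Realises a [population_spec()]: times are independent uniform draws on
#' the spec's time range and abundances follow the linear-plus-noise model.
#' Each row is one cell; measuring a cell is destructive, so downstream
#' subsampling never reuses a cell.
#'
#' @param spec A [population_spec()].
#' @param seed Integer seed; the same `(spec, seed)` pair reproduces the
#'   population exactly. `NULL` uses the current RNG stream.
#'
#' @return A tibble of class `sc_population` with columns `cell_id`,
#'   `time`, `abundance`; the spec and seed are kept as attributes.
#' @export
#' @examples
#' pop <- simulate_population(population_spec(1, 0.25), seed = 1)
#' head(pop)
simulate_population <- function(spec, seed = NULL) {
  if (!inherits(spec, "population_spec")) {
    stop_param("spec", "must be a population_spec")
  }
  out <- with_seed_(seed, {
    time <- runif(spec$n_cells, spec$time_range[1], spec$time_range[2])
    abundance <- spec$slope * time + spec$intercept +
      rnorm(spec$n_cells, 0, spec$noise_sd)
    tibble(cell_id = seq_len(spec$n_cells), time = time,
           abundance = abundance)
  })
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  class(out) <- c("sc_population", class(out))
  out
}

#' Draw a destructive subsample from a simulated population
#'
#' Draws `n` distinct cells uniformly without replacement, standing for one
#' single-cell time-course experiment in which each measured cell is
#' destroyed.
#'
#' @param population An `sc_population` tibble from [simulate_population()],
#'   or any data frame with `time` and `abundance` columns.
#' @param n Number of cells to draw (between 1 and the population size).
#' @param seed Integer seed for reproducibility; `NULL` uses the current
#'   RNG stream.
#'
#' @return A tibble of class `sc_sample` with the same columns as the
#'   population.
#' @export
#' @examples
#' pop <- simulate_population(population_spec(1, 0.25), seed = 1)
#' subsample(pop, 16, seed = 2)
subsample <- function(population, n, seed = NULL) {
  if (!is.data.frame(population) ||
      !all(c("time", "abundance") %in% names(population))) {
    stop_param("population", "must have `time` and `abundance` columns")
  }
  n <- check_count(n, "n")
  if (n > nrow(population)) {
    stop_param("n", sprintf("cannot exceed the population size (%d)",
                            nrow(population)))
  }
  idx <- with_seed_(seed, sample.int(nrow(population), n))
  out <- as_tibble(population[idx, , drop = FALSE])
  attr(out, "spec") <- attr(population, "spec")
  attr(out, "source_seed") <- seed
  class(out) <- c("sc_sample", class(out))
  out
}

#' Read or write populations and samples as CSV
#'
#' Plain-text serialisation with columns `cell_id,time,abundance`. Values
#' round-trip exactly ([readr::write_csv()] writes shortest
#' exactly-representable decimals).
#'
#' @param x A population or sample tibble.
#' @param path File path.
#' @return `write_population()` returns `x` invisibly; `read_population()`
#'   returns a tibble with columns `cell_id`, `time`, `abundance`.
#' @export
write_population <- function(x, path) {
  cols <- intersect(c("cell_id", "time", "abundance"), names(x))
  if (!all(c("time", "abundance") %in% cols)) {
    stop_param("x", "must have `time` and `abundance` columns")
  }
  out <- as_tibble(x)[cols]
  # 17 significant digits round-trips a double bit-exactly
  out$time <- sprintf("%.17g", out$time)
  out$abundance <- sprintf("%.17g", out$abundance)
  readr::write_csv(out, path)
  invisible(x)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  # parse numbers through base strtod (correctly rounded) so serialised
  # doubles come back bit-exact
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           .default = readr::col_character()))
  tibble(cell_id = as.integer(raw$cell_id),
         time = as.numeric(raw$time),
         abundance = as.numeric(raw$abundance))
}
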