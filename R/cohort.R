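#' Synthesise a two-group protein-by-cell abundance matrix
#'
#' Generates a log-scale abundance table for two cell groups: per protein
#' a baseline, a between-group effect and a within-group standard
#' deviation are drawn (or recycled from numeric vectors), values are
#' Gaussian around the group means, and entries are masked missing
#' completely at random at `missing_rate`. The true per-protein
#' parameters are kept in the `truth` attribute so recovery is testable.
#'
#' @param n_proteins Number of proteins (rows).
#' @param n_cells_per_group Cells per group (columns per group).
#' @param effect_size Between-group abundance difference per protein: a
#'   single number, a vector recycled across proteins, or a `function(n)`
#'   returning `n` draws.
#' @param sd Within-group standard deviation per protein: number, vector
#'   or `function(n)`.
#' @param missing_rate Probability an entry is missing, in \[0, 1).
#' @param group_labels Two distinct labels, default `c("A", "B")`; the
#'   effect is added to the second group.
#' @param baseline Baseline log-abundance (default 0).
#' @param seed Integer seed.
#'
#' @return A list of class `abundance_matrix` with elements `abundance`
#'   (tibble, `protein_id` plus one column per cell) and `groups` (tibble
#'   `cell_id`, `group`); attribute `truth` holds the generating
#'   parameters.
#' @export
#' @examples
#' m <- synth_two_group_matrix(5, 4, effect_size = 1, sd = 0.5, seed = 1)
#' m$abundance
synth_two_group_matrix <- function(n_proteins, n_cells_per_group,
                                   effect_size, sd, missing_rate = 0,
                                   group_labels = c("A", "B"),
                                   baseline = 0, seed = NULL) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_cells_per_group <- check_count(n_cells_per_group, "n_cells_per_group")
  check_number(missing_rate, "missing_rate", lower = 0)
  if (missing_rate >= 1) stop_param("missing_rate", "must be < 1")
  if (length(group_labels) != 2L ||
      group_labels[1] == group_labels[2]) {
    stop_param("group_labels", "must be two distinct labels")
  }
  draw <- function(x, field) {
    if (is.function(x)) {
      out <- x(n_proteins)
    } else if (is.numeric(x)) {
      out <- rep_len(x, n_proteins)
    } else {
      stop_param(field, "must be numeric or a function(n)")
    }
    out
  }
  with_seed_(seed, {
    effects <- draw(effect_size, "effect_size")
    sds <- draw(sd, "sd")
    if (any(sds < 0)) stop_param("sd", "must be non-negative")
    n_cells <- 2L * n_cells_per_group
    cell_id <- sprintf("cell%03d", seq_len(n_cells))
    group <- rep(group_labels, each = n_cells_per_group)
    vals <- matrix(rnorm(n_proteins * n_cells,
                         mean = baseline +
                           outer(effects, as.numeric(group == group_labels[2])),
                         sd = rep(sds, times = n_cells)),
                   nrow = n_proteins)
    if (missing_rate > 0) {
      vals[runif(length(vals)) < missing_rate] <- NA_real_
    }
    colnames(vals) <- cell_id
    abundance <- dplyr::bind_cols(
      tibble(protein_id = sprintf("prot%04d", seq_len(n_proteins))),
      as_tibble(vals))
    out <- structure(
      list(abundance = abundance,
           groups = tibble(cell_id = cell_id, group = group)),
      class = "abundance_matrix")
    attr(out, "truth") <- tibble(
      protein_id = abundance$protein_id,
      true_effect = effects, true_sd = sds)
    out
  })
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("<abundance_matrix> %d proteins x %d cells (%s)\n",
              nrow(x$abundance), nrow(x$groups),
              paste(sprintf("%s: %d", unique(x$groups$group),
                            table(x$groups$group)[unique(x$groups$group)]),
                    collapse = ", ")))
  invisible(x)
}

#' Read a protein-by-cell abundance matrix and its group map
#'
#' The matrix file is CSV or TSV (by extension) with a `protein_id` first
#' column and one column per cell; the group file has columns
#' `cell_id,group`. Values are assumed already log-transformed.
#'
#' @param path Matrix file path.
#' @param groups_path Group-map file path.
#' @return An `abundance_matrix` list (see [synth_two_group_matrix()]).
#' @export
read_abundance_matrix <- function(path, groups_path) {
  reader <- function(p) {
    if (grepl("\\.tsv$", p, ignore.case = TRUE)) {
      readr::read_tsv(p, show_col_types = FALSE)
    } else {
      readr::read_csv(p, show_col_types = FALSE)
    }
  }
  abundance <- reader(path)
  if (names(abundance)[1] != "protein_id") {
    stop_param("path", "first column must be `protein_id`")
  }
  groups <- reader(groups_path)
  if (!all(c("cell_id", "group") %in% names(groups))) {
    stop_param("groups_path", "must have columns `cell_id` and `group`")
  }
  missing_cells <- setdiff(setdiff(names(abundance), "protein_id"),
                           groups$cell_id)
  if (length(missing_cells) > 0) {
    stop_param("groups_path",
               sprintf("no group label for cells: %s",
                       paste(utils::head(missing_cells, 5), collapse = ", ")))
  }
  structure(list(abundance = abundance,
                 groups = groups[groups$cell_id %in% names(abundance), ]),
            class = "abundance_matrix")
}

#' Per-protein fold change and within-group variation
#'
#' For a two-group abundance table, computes each protein's fold change —
#' the absolute difference between the two group means on the (log)
#' abundance scale — and its within-group variation, the sample standard
#' deviation of the *reference* group's cells. Their ratio `sv_proxy`
#' approximates the S/V ratio when the transition between the groups is
#' scaled to a unit time interval, connecting observed two-state data to
#' the simulation grids. Missing values are ignored per protein; proteins
#' with fewer than `min_obs` observed values in either group are dropped
#' (with a message).
#'
#' @param x An `abundance_matrix`, or a wide tibble with `protein_id`
#'   plus one column per cell (then `groups` is required).
#' @param reference_group Label of the group whose standard deviation is
#'   reported (the documented asymmetry: swapping groups changes only
#'   `within_group_sd`).
#' @param groups A tibble `cell_id,group` when `x` is a plain tibble.
#' @param min_obs Minimum non-missing values per group (default 3).
#'
#' @return A tibble of class `effect_table`: `protein_id`, `fold_change`,
#'   `within_group_sd`, `sv_proxy` (`Inf` when the reference group is
#'   constant), `n_obs_ref`, `n_obs_other`. Attribute `n_dropped` counts
#'   proteins removed by the `min_obs` filter.
#' @export
#' @examples
#' m <- synth_two_group_matrix(5, 10, effect_size = 1, sd = 0.5, seed = 1)
#' effect_table(m, reference_group = "A")
effect_table <- function(x, reference_group, groups = NULL, min_obs = 3) {
  if (inherits(x, "abundance_matrix")) {
    groups <- x$groups
    x <- x$abundance
  }
  if (is.null(groups)) {
    stop_param("groups", "must be supplied when `x` is not an abundance_matrix")
  }
  min_obs <- check_count(min_obs, "min_obs")
  lvls <- unique(groups$group)
  if (length(lvls) != 2L) {
    stop_param("groups", sprintf("exactly two groups required, found %d",
                                 length(lvls)))
  }
  if (!reference_group %in% lvls) {
    stop_param("reference_group",
               sprintf("'%s' is not one of the group labels (%s)",
                       reference_group, paste(lvls, collapse = ", ")))
  }
  other_group <- setdiff(lvls, reference_group)
  long <- tidyr::pivot_longer(x, -"protein_id", names_to = "cell_id",
                              values_to = "abundance")
  long <- dplyr::inner_join(long, groups, by = "cell_id")
  long <- dplyr::filter(long, !is.na(.data$abundance))
  per <- dplyr::summarise(
    dplyr::group_by(long, .data$protein_id),
    mean_ref = mean(.data$abundance[.data$group == reference_group]),
    mean_other = mean(.data$abundance[.data$group == other_group]),
    within_group_sd = sd(.data$abundance[.data$group == reference_group]),
    n_obs_ref = sum(.data$group == reference_group),
    n_obs_other = sum(.data$group == other_group),
    .groups = "drop")
  keep <- per$n_obs_ref >= min_obs & per$n_obs_other >= min_obs
  n_dropped <- sum(!keep) + (nrow(x) - nrow(per))
  if (n_dropped > 0) {
    message(sprintf(
      "effect_table: dropped %d protein(s) with fewer than %d observed values in a group",
      n_dropped, min_obs))
  }
  per <- per[keep, ]
  out <- dplyr::transmute(
    per,
    protein_id = .data$protein_id,
    fold_change = abs(.data$mean_ref - .data$mean_other),
    within_group_sd = .data$within_group_sd,
    sv_proxy = dplyr::if_else(.data$within_group_sd > 0,
                              .data$fold_change / .data$within_group_sd,
                              Inf),
    n_obs_ref = .data$n_obs_ref,
    n_obs_other = .data$n_obs_other)
  # preserve the input protein order
  out <- out[order(match(out$protein_id, x$protein_id)), ]
  attr(out, "n_dropped") <- n_dropped
  attr(out, "reference_group") <- reference_group
  class(out) <- c("effect_table", class(out))
  out
}

#' @rdname effect_table
#' @param object An `effect_table`.
#' @param ... Unused.
#' @export
autoplot.effect_table <- function(object, ...) {
  dat <- dplyr::filter(as_tibble(object), is.finite(.data$sv_proxy))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$within_group_sd,
                                    y = .data$fold_change)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = c(1, 2, 4), intercept = 0,
                         linetype = "dashed", colour = "grey50") +
    ggplot2::labs(x = "within-group standard deviation",
                  y = "|fold change| (log scale units)")
}
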