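# ggplot2 figures for the main result types.

#' Plot an ERA training loss trace
#'
#' @param object An `era_fit`.
#' @param ... Unused.
#' @return A ggplot: loss per epoch on a log scale.
#' @export
autoplot.era_fit <- function(object, ...) {
  ggplot2::ggplot(object$loss_trace,
                  ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "mean pair divergence",
                  title = sprintf("%s training loss", object$objective)) +
    ggplot2::theme_minimal()
}

#' Plot campaign progress
#'
#' Best scaled fitness found so far, per round and replicate.
#'
#' @param object A `campaign_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.campaign_result <- function(object, ...) {
  prog <- object$records |>
    dplyr::group_by(.data$replicate, .data$round) |>
    dplyr::summarise(round_best = max(.data$scaled_fitness),
                     .groups = "drop_last") |>
    dplyr::arrange(.data$round, .by_group = TRUE) |>
    dplyr::mutate(best_so_far = cummax(.data$round_best)) |>
    dplyr::ungroup()
  ggplot2::ggplot(prog, ggplot2::aes(x = .data$round, y = .data$best_so_far,
                                     group = .data$replicate)) +
    ggplot2::geom_step(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "round", y = "best scaled fitness so far",
                  title = object$landscape_name) +
    ggplot2::theme_minimal()
}

#' Plot a position frequency matrix
#'
#' Stacked per-position residue frequencies of the likelihood-weighted MSA;
#' residues below `min_frequency` are lumped for legibility.
#'
#' @param object An `era_pfm`.
#' @param min_frequency Residues below this frequency at every position are
#'   dropped from the legend (still plotted as grey).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.era_pfm <- function(object, min_frequency = 0.01, ...) {
  keep <- tibble::as_tibble(object) |>
    dplyr::group_by(.data$residue) |>
    dplyr::summarise(mx = max(.data$frequency), .groups = "drop")
  shown <- keep$residue[keep$mx >= min_frequency]
  dat <- tibble::as_tibble(object) |>
    dplyr::mutate(residue_shown = ifelse(.data$residue %in% shown,
                                         .data$residue, "other"))
  ggplot2::ggplot(dat, ggplot2::aes(x = factor(.data$position),
                                    y = .data$frequency,
                                    fill = .data$residue_shown)) +
    ggplot2::geom_col(color = "grey30", linewidth = 0.1) +
    ggplot2::labs(x = "mutated position", y = "weighted frequency",
                  fill = "residue") +
    ggplot2::theme_minimal()
}

#' Plot probability-mass fold changes
#'
#' @param fold_change Tibble from [probability_mass_fold_change()].
#' @return A ggplot of fold change against activity threshold, log scale.
#' @export
plot_mass_fold_change <- function(fold_change) {
  ggplot2::ggplot(fold_change,
                  ggplot2::aes(x = .data$threshold, y = .data$fold_change)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "activity threshold",
                  y = "fold change in probability mass") +
    ggplot2::theme_minimal()
}
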