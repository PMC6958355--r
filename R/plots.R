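#' Plot the sliding-window propensity profile of one sequence
#'
#' Shows the per-window mean propensity with the decision threshold and
#' shades the called antimicrobial stretches.
#'
#' @param sequence Protein sequence.
#' @param scale A [propensity_scale()].
#' @return A ggplot object.
#' @export
plot_propensity_profile <- function(sequence, scale = propensity_scale()) {
  prof <- window_profile(sequence, scale)
  stretches <- call_stretches(sequence, scale)
  p <- ggplot2::ggplot(prof, ggplot2::aes(x = .data$start,
                                          y = .data$mean_pv)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::geom_hline(yintercept = scale$threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "window start (residue)",
                  y = "mean window propensity",
                  title = "Antimicrobial propensity profile",
                  subtitle = sprintf("window %d, threshold %g (lower = more antimicrobial)",
                                     scale$window, scale$threshold)) +
    ggplot2::theme_minimal()
  if (nrow(stretches) > 0) {
    p <- p + ggplot2::geom_rect(
      data = stretches,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
      inherit.aes = FALSE
    )
  }
  p
}

#' @describeIn rank_amps Dot-and-box plot of CAS per proteome (peptides
#'   counted in every proteome they trace to).
#' @param object An `amp_ranking`.
#' @param ... Unused.
#' @export
autoplot.amp_ranking <- function(object, ...) {
  if (!"proteomes" %in% names(object)) {
    abort("Ranking has no `proteomes` membership column to plot.")
  }
  long <- object |>
    tidyr::unnest("proteomes") |>
    dplyr::rename(proteome = "proteomes")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$proteome, y = .data$cas)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_jitter(width = 0.18, alpha = 0.4, size = 0.8,
                         colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "combined antimicrobial score (CAS)",
                  title = "CAS distribution per proteome") +
    ggplot2::theme_minimal()
}

#' Heatmap of pairwise common-peptide counts between proteomes
#'
#' @param summary An `amp_proteome_summary` from [proteome_summary()],
#'   or the `pairwise` tibble itself.
#' @return A ggplot object.
#' @export
plot_proteome_overlap <- function(summary) {
  pw <- if (inherits(summary, "amp_proteome_summary")) {
    summary$pairwise
  } else {
    summary
  }
  ggplot2::ggplot(pw, ggplot2::aes(x = .data$proteome_a,
                                   y = .data$proteome_b,
                                   fill = .data$n_common)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_common),
                       colour = "white", size = 3) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "common\npeptides",
                  title = "Shared peptides across proteomes") +
    ggplot2::theme_minimal()
}
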