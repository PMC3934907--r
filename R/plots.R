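#' Plot a nearest-TSS distance profile
#'
#' Bar chart of the fraction of peaks per distance bin, the standard
#' view of how TSS-proximal a binding profile is.
#'
#' @param profile Tibble from [distance_profile()].
#' @return A ggplot object.
#' @export
plot_distance_profile <- function(profile) {
  assert_columns(profile, c("label", "fraction"), "profile")
  profile |>
    dplyr::mutate(label = factor(.data$label, levels = .data$label)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col(fill = "#3B6E8F") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", 100 * .data$fraction)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x),
                                expand = ggplot2::expansion(mult = c(0, 0.1))) +
    ggplot2::labs(x = "Distance to nearest TSS (bp)",
                  y = "Fraction of peaks") +
    ggplot2::theme_minimal()
}

#' Plot motif occurrence fractions against the shuffled background
#'
#' Dodged bars of the observed and background fraction of peaks with
#' at least one motif occurrence.
#'
#' @param summary Tibble from [peak_hit_fraction()] or
#'   [shuffle_enrichment()].
#' @return A ggplot object.
#' @export
plot_motif_enrichment <- function(summary) {
  assert_columns(summary, c("name", "fraction"), "summary")
  long <- tibble(
    name = rep(summary$name, 2),
    what = rep(c("peaks", "shuffled background"), each = nrow(summary)),
    fraction = c(summary$fraction,
                 summary[["background_fraction"]] %||%
                   rep(NA_real_, nrow(summary)))
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$name, y = .data$fraction,
                                     fill = .data$what)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("#3B6E8F", "#C7CdD1"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "Fraction of peaks with a hit") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 35, hjust = 1))
}

#' Plot a regulatory classification summary
#'
#' @param object A `so_reg_summary` object.
#' @param ... Unused.
#' @return A ggplot bar chart of the POS/NEG/AMB counts.
#' @method autoplot so_reg_summary
#' @export
autoplot.so_reg_summary <- function(object, ...) {
  dat <- tibble(
    category = factor(c("POS", "NEG", "AMB"), levels = c("POS", "NEG", "AMB")),
    count = c(object$n_pos, object$n_neg, object$n_amb),
    pct = c(object$pct_pos, object$pct_neg, object$pct_amb)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$category, y = .data$count,
                                    fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%d (%.1f%%)",
                                                    .data$count, .data$pct)),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_fill_manual(values = c(POS = "#2E7D52", NEG = "#A84C4C",
                                          AMB = "#8A8A8A")) +
    ggplot2::labs(x = NULL, y = "Peak-bearing responsive genes") +
    ggplot2::theme_minimal()
}
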