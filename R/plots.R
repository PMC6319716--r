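#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-chromosome FISH aneuploidy rates
#'
#' Bar chart of disomy and nullisomy percentages per chromosomal unit, with
#' the specimen's total aneuploidy and the abnormality threshold overlaid.
#'
#' @param object A `fish_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fish_report
#' @export
autoplot.fish_report <- function(object, ...) {
  dat <- object$per_chromosome |>
    tidyr::pivot_longer(c("disomy_pct", "nullisomy_pct"),
                        names_to = "event", values_to = "pct") |>
    dplyr::mutate(event = sub("_pct$", "", .data$event),
                  chrom = factor(.data$chrom,
                                 levels = object$per_chromosome$chrom))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom, y = .data$pct,
                                    fill = .data$event)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$params$fish_abnormal_threshold_pct,
                        linetype = 2, linewidth = 0.3) +
    ggplot2::labs(
      x = "chromosome", y = "% of scorable cells", fill = NULL,
      title = sprintf("FISH aneuploidy: total %.2f%% over %d cells",
                      object$total_aneuploidy_pct, object$n_scorable)
    ) +
    ggplot2::theme_minimal()
}

#' Plot chromosome-level CNV aneuploidy
#'
#' Bar chart of the percentage of assessed genes called gained or lost on
#' each chromosome.
#'
#' @param object An `aneuploidy_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot aneuploidy_report
#' @export
autoplot.aneuploidy_report <- function(object, ...) {
  dat <- object$per_chromosome |>
    tidyr::pivot_longer(c("genes_gained", "genes_lost"),
                        names_to = "direction", values_to = "n") |>
    dplyr::mutate(
      pct = ifelse(.data$genes_assessed > 0,
                   100 * .data$n / .data$genes_assessed, 0),
      direction = sub("genes_", "", .data$direction),
      chrom = factor(.data$chrom, levels = object$per_chromosome$chrom)
    )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$chrom, y = .data$pct,
                                    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(gained = "#c23b22",
                                          lost = "#1f6fb5")) +
    ggplot2::labs(
      x = "chromosome", y = "% of assessed genes called", fill = NULL,
      title = sprintf("Molecular karyotype: %.2f%% of genes called",
                      object$total_aneuploidy_pct)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ICSI outcome rates
#'
#' Dot plot of clinical pregnancy, pregnancy-loss and term rates per group.
#'
#' @param rates Output of [outcome_rates()].
#' @return A ggplot object.
#' @export
plot_outcome_rates <- function(rates) {
  dat <- rates |>
    tidyr::pivot_longer(c("clinical_pregnancy_pct", "pregnancy_loss_pct",
                          "term_pct"),
                        names_to = "rate", values_to = "pct") |>
    dplyr::mutate(rate = sub("_pct$", "", .data$rate))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$group, y = .data$pct,
                                    colour = .data$rate)) +
    ggplot2::geom_point(size = 3, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "%", colour = NULL) +
    ggplot2::theme_minimal()
}
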