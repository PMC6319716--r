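#' Normalize a study/control depth pair into a log-ratio track
#'
#' Library sizes are equalized by scaling each table so its median exon
#' depth is 1 (median rather than total so the scaling is robust to the
#' copy-number events being sought). A pseudocount of raw reads is added to
#' every depth before scaling so log ratios stay finite at zero depth, and
#' exons with zero raw depth in both specimens are masked: they carry no
#' information and are excluded from every downstream fraction.
#'
#' @param study,control `depth_table` objects covering the same model.
#' @param model The `gene_model` both tables cover.
#' @param params A `karyo_params` (for the pseudocount), or NULL for
#'   defaults.
#' @return A `logratio_track` tibble with columns `chrom`, `start`, `end`,
#'   `gene_id`, `study_norm`, `control_norm`, `log2_ratio`, `masked`.
#'   `log2_ratio` is NA on masked exons.
#' @examples
#' sim <- simulate_depth_pair(toy_gene_model(), dispersion = 0, seed = 1)
#' track <- depth_logratio(sim$study, sim$control, toy_gene_model())
#' summary(track$log2_ratio)
#' @export
depth_logratio <- function(study, control, model, params = NULL) {
  params <- as_karyo_params(params)
  study <- as_depth_table(study, model)
  control <- as_depth_table(control, model)
  if (all(study$depth == 0)) stop("study depth table is all zeros", call. = FALSE)
  if (all(control$depth == 0)) stop("control depth table is all zeros", call. = FALSE)
  masked <- study$depth == 0 & control$depth == 0
  s <- study$depth + params$pseudocount
  ctl <- control$depth + params$pseudocount
  s_norm <- s / stats::median(s[!masked])
  c_norm <- ctl / stats::median(ctl[!masked])
  out <- tibble::tibble(
    chrom = model$chrom,
    start = model$start,
    end = model$end,
    gene_id = model$gene_id,
    study_norm = s_norm,
    control_norm = c_norm,
    log2_ratio = ifelse(masked, NA_real_, log2(s_norm / c_norm)),
    masked = masked
  )
  structure(out, class = c("logratio_track", class(tibble::tibble())))
}

#' Per-exon log-ratio plot
#'
#' Plots the exon-level log2 study:control ratios along each chromosome,
#' highlighting exons belonging to called genes when a call set is supplied.
#'
#' @param track A `logratio_track`.
#' @param calls Optional `cnv_calls` tibble; called genes are colored.
#' @return A ggplot object.
#' @export
plot_logratio <- function(track, calls = NULL) {
  dat <- dplyr::filter(tibble::as_tibble(track), !.data$masked)
  dat$call <- "none"
  if (!is.null(calls) && nrow(calls)) {
    keep <- dplyr::filter(tibble::as_tibble(calls), !.data$filtered)
    idx <- match(dat$gene_id, keep$gene_id)
    dat$call <- ifelse(is.na(idx), "none", keep$call[idx])
  }
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$start, y = .data$log2_ratio,
                                    colour = .data$call)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::scale_colour_manual(
      values = c(none = "grey55", gain = "#c23b22", loss = "#1f6fb5"),
      breaks = c("gain", "loss")
    ) +
    ggplot2::labs(x = "exon start (bp)", y = expression(log[2]~ratio),
                  colour = "call") +
    ggplot2::theme_minimal()
}
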