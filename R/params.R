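#' Shared analysis parameters
#'
#' Collects every threshold used across the FISH, TUNEL and read-depth
#' pipelines in a single validated object. Defaults are the screening
#' thresholds used throughout: a specimen is flagged abnormal by FISH when
#' total aneuploidy exceeds 1.6% of scorable cells (with a 2-3 percentage
#' point inter-replicate FISH error band and at least 1000 cells scored),
#' TUNEL chromatin fragmentation is normal at or below 15% of at least 500
#' cells, a gene is duplicated when more than 70% of its exons exceed 1.5x
#' the control median depth (deleted below 0.5x), and a specimen is called
#' homozygous when at most 5% of its called SNPs are heterozygous.
#'
#' @param fish_abnormal_threshold_pct Total-aneuploidy percentage above which
#'   a specimen is abnormal by FISH. Default 1.6.
#' @param fish_error_band_pct Length-2 numeric, the FISH scoring error band in
#'   percentage points; replicates whose totals differ by more than the upper
#'   bound are discordant. Default `c(2, 3)`.
#' @param fish_min_cells Minimum scorable cells for a sufficient FISH
#'   assessment. Default 1000.
#' @param tunel_normal_threshold_pct Fragmentation percentage at or below
#'   which chromatin is normal. Default 15.
#' @param tunel_min_cells Minimum cells for a sufficient TUNEL assessment.
#'   Default 500.
#' @param dup_ratio Multiple of the control reference depth above which an
#'   exon supports duplication. Default 1.5.
#' @param del_ratio Multiple of the control reference depth below which an
#'   exon supports deletion. Default 0.5.
#' @param exon_fraction Fraction of a gene's exons that must support a gain
#'   (or loss) before the gene is called; the comparison is strict. Default
#'   0.70.
#' @param het_homozygosity_cutoff_pct Heterozygous-SNP percentage at or below
#'   which homozygosity is assigned. Default 5.0.
#' @param probe_panel Character vector of chromosomes in the FISH probe
#'   panel. Default the nine clinically screened chromosomes
#'   X, Y, 13, 15, 16, 17, 18, 21, 22.
#' @param polymorphic_overlap Fraction of a gene's exonic bases that must
#'   fall inside polymorphic-CNV regions before a call is filtered as a
#'   common variant. Default 0.5.
#' @param pseudocount Raw reads added to every exon depth before
#'   normalization, to keep log ratios finite. Default 0.5.
#'
#' @return An object of class `karyo_params` (a named list).
#' @examples
#' karyo_params()
#' karyo_params(exon_fraction = 0.8)
#' @export
karyo_params <- function(fish_abnormal_threshold_pct = 1.6,
                         fish_error_band_pct = c(2, 3),
                         fish_min_cells = 1000,
                         tunel_normal_threshold_pct = 15,
                         tunel_min_cells = 500,
                         dup_ratio = 1.5,
                         del_ratio = 0.5,
                         exon_fraction = 0.70,
                         het_homozygosity_cutoff_pct = 5.0,
                         probe_panel = c("X", "Y", "13", "15", "16", "17",
                                         "18", "21", "22"),
                         polymorphic_overlap = 0.5,
                         pseudocount = 0.5) {
  params <- list(
    fish_abnormal_threshold_pct = as.numeric(fish_abnormal_threshold_pct),
    fish_error_band_pct = as.numeric(fish_error_band_pct),
    fish_min_cells = as.integer(fish_min_cells),
    tunel_normal_threshold_pct = as.numeric(tunel_normal_threshold_pct),
    tunel_min_cells = as.integer(tunel_min_cells),
    dup_ratio = as.numeric(dup_ratio),
    del_ratio = as.numeric(del_ratio),
    exon_fraction = as.numeric(exon_fraction),
    het_homozygosity_cutoff_pct = as.numeric(het_homozygosity_cutoff_pct),
    probe_panel = as.character(probe_panel),
    polymorphic_overlap = as.numeric(polymorphic_overlap),
    pseudocount = as.numeric(pseudocount)
  )
  validate_karyo_params(params)
  structure(params, class = "karyo_params")
}

validate_karyo_params <- function(p) {
  pct_fields <- c("fish_abnormal_threshold_pct", "tunel_normal_threshold_pct",
                  "het_homozygosity_cutoff_pct")
  for (f in pct_fields) {
    if (!is.finite(p[[f]]) || p[[f]] < 0 || p[[f]] > 100) {
      stop(sprintf("`%s` must be a percentage in [0, 100], got %s", f, p[[f]]),
           call. = FALSE)
    }
  }
  if (length(p$fish_error_band_pct) != 2 ||
      any(p$fish_error_band_pct < 0 | p$fish_error_band_pct > 100) ||
      diff(p$fish_error_band_pct) < 0) {
    stop("`fish_error_band_pct` must be an increasing interval within [0, 100]",
         call. = FALSE)
  }
  if (!(p$del_ratio > 0 && p$del_ratio < 1 && p$dup_ratio > 1)) {
    stop("require 0 < del_ratio < 1 < dup_ratio", call. = FALSE)
  }
  if (!(p$exon_fraction > 0 && p$exon_fraction <= 1)) {
    stop("`exon_fraction` must lie in (0, 1]", call. = FALSE)
  }
  if (anyDuplicated(p$probe_panel)) {
    stop("`probe_panel` must not contain duplicate chromosomes", call. = FALSE)
  }
  if (p$fish_min_cells < 1 || p$tunel_min_cells < 1) {
    stop("minimum cell counts must be positive", call. = FALSE)
  }
  if (!(p$polymorphic_overlap > 0 && p$polymorphic_overlap <= 1)) {
    stop("`polymorphic_overlap` must lie in (0, 1]", call. = FALSE)
  }
  if (p$pseudocount < 0) stop("`pseudocount` must be non-negative", call. = FALSE)
  invisible(p)
}

#' @export
print.karyo_params <- function(x, ...) {
  cat("<karyo_params>\n")
  cat(sprintf("  FISH : abnormal > %.2f%% of >= %d scorable cells; error band %g-%g pp\n",
              x$fish_abnormal_threshold_pct, x$fish_min_cells,
              x$fish_error_band_pct[1], x$fish_error_band_pct[2]))
  cat(sprintf("  TUNEL: normal <= %.1f%% of >= %d cells\n",
              x$tunel_normal_threshold_pct, x$tunel_min_cells))
  cat(sprintf("  CNV  : gain > %gx / loss < %gx control median over > %.0f%% of exons\n",
              x$dup_ratio, x$del_ratio, 100 * x$exon_fraction))
  cat(sprintf("  SNP  : homozygous when het fraction <= %.1f%%\n",
              x$het_homozygosity_cutoff_pct))
  cat(sprintf("  panel: %s\n", paste(x$probe_panel, collapse = ", ")))
  invisible(x)
}

as_karyo_params <- function(params) {
  if (is.null(params)) return(karyo_params())
  if (inherits(params, "karyo_params")) return(params)
  do.call(karyo_params, as.list(params))
}

# autosomes of a panel, and whether the panel carries the X/Y pair
panel_autosomes <- function(panel) setdiff(panel, c("X", "Y"))
panel_has_sex <- function(panel) all(c("X", "Y") %in% panel)
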