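#' Call gene-level copy-number gains and losses
#'
#' Applies the duplication/deletion depth rule to a normalized log-ratio
#' track. For each gene the control-side reference is the median normalized
#' control depth over the gene's unmasked exons. An exon supports a gain
#' when its normalized study depth exceeds `dup_ratio` times the reference
#' (strict), and a loss when it falls below `del_ratio` times the reference
#' (strict). A gene is called when its supporting exon fraction over
#' unmasked exons strictly exceeds `exon_fraction` (default 0.70). If both
#' directions somehow exceed the threshold the larger fraction wins and a
#' tie gives no call. Genes whose exons are all masked are not assessed and
#' are reported in the `unassessed` attribute. Calls come back ranked by
#' [rank_cnvs()].
#'
#' @param track A `logratio_track` from [depth_logratio()].
#' @param model The `gene_model` the track covers.
#' @param params A `karyo_params` or NULL for defaults.
#' @return A `cnv_calls` tibble with columns `gene_id`, `chrom`, `call`
#'   (`"gain"`/`"loss"`), `supporting_exon_fraction`, `mean_log2_ratio`,
#'   `rank`, `filtered`, `filter_reason`; attributes `unassessed`
#'   (gene_ids never assessed) and `genes_assessed` (per-chromosome counts).
#' @examples
#' model <- toy_gene_model()
#' sim <- simulate_depth_pair(model, seed = 7,
#'   spiked_events = data.frame(target = "21_G05", multiplier = 2))
#' call_gene_cnv(depth_logratio(sim$study, sim$control, model), model)
#' @export
call_gene_cnv <- function(track, model, params = NULL) {
  params <- as_karyo_params(params)
  stopifnot(inherits(track, "logratio_track"))
  if (!identical(exon_key(track), exon_key(model))) {
    stop("log-ratio track does not cover the model's exons", call. = FALSE)
  }
  per_gene <- tibble::as_tibble(track) |>
    dplyr::filter(!.data$masked) |>
    dplyr::group_by(.data$gene_id, .data$chrom) |>
    dplyr::summarise(
      n_exons = dplyr::n(),
      reference = stats::median(.data$control_norm),
      frac_gain = mean(.data$study_norm > params$dup_ratio * reference),
      frac_loss = mean(.data$study_norm < params$del_ratio * reference),
      mean_log2_ratio = mean(.data$log2_ratio),
      .groups = "drop"
    )
  unassessed <- setdiff(unique(model$gene_id), per_gene$gene_id)
  calls <- per_gene |>
    dplyr::mutate(
      gain_hit = .data$frac_gain > params$exon_fraction,
      loss_hit = .data$frac_loss > params$exon_fraction,
      call = dplyr::case_when(
        .data$gain_hit & .data$loss_hit & .data$frac_gain > .data$frac_loss ~ "gain",
        .data$gain_hit & .data$loss_hit & .data$frac_loss > .data$frac_gain ~ "loss",
        .data$gain_hit & .data$loss_hit ~ NA_character_,  # exact tie: no call
        .data$gain_hit ~ "gain",
        .data$loss_hit ~ "loss",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$call)) |>
    dplyr::mutate(
      supporting_exon_fraction = ifelse(.data$call == "gain",
                                        .data$frac_gain, .data$frac_loss),
      filtered = FALSE,
      filter_reason = NA_character_
    ) |>
    dplyr::select("gene_id", "chrom", "call", "supporting_exon_fraction",
                  "mean_log2_ratio", "filtered", "filter_reason")
  assessed <- per_gene |>
    dplyr::count(.data$chrom, name = "genes_assessed")
  out <- rank_cnvs(new_cnv_calls(calls, unassessed = unassessed,
                                 genes_assessed = assessed))
  out
}

new_cnv_calls <- function(calls, unassessed = character(),
                          genes_assessed = NULL) {
  if (!"rank" %in% names(calls)) calls$rank <- NA_integer_
  cols <- c("gene_id", "chrom", "call", "supporting_exon_fraction",
            "mean_log2_ratio", "rank", "filtered", "filter_reason")
  structure(tibble::as_tibble(calls)[cols],
            unassessed = unassessed,
            genes_assessed = genes_assessed,
            class = c("cnv_calls", class(tibble::tibble())))
}

#' Rank CNV calls by log-ratio magnitude
#'
#' Sorts calls by decreasing `|mean_log2_ratio|`, breaking ties by gene_id
#' (ascending), and assigns ranks 1..K without gaps. Filtered calls are kept
#' in the table after the unfiltered ones but carry rank NA; ranking is
#' computed over unfiltered calls only.
#'
#' @param calls A `cnv_calls` tibble.
#' @return The same tibble, sorted and ranked.
#' @export
rank_cnvs <- function(calls) {
  calls <- tibble::as_tibble(calls)
  if (!"filtered" %in% names(calls)) calls$filtered <- FALSE
  active <- calls[!calls$filtered, , drop = FALSE]
  dropped <- calls[calls$filtered, , drop = FALSE]
  ord <- order(-abs(active$mean_log2_ratio), active$gene_id)
  active <- active[ord, , drop = FALSE]
  active$rank <- seq_len(nrow(active))
  if (nrow(dropped)) {
    dropped <- dropped[order(-abs(dropped$mean_log2_ratio),
                             dropped$gene_id), , drop = FALSE]
    dropped$rank <- NA_integer_
  }
  new_cnv_calls(dplyr::bind_rows(active, dropped),
                unassessed = attr(calls, "unassessed") %||% character(),
                genes_assessed = attr(calls, "genes_assessed"))
}

#' Filter calls overlapping polymorphic CNV regions
#'
#' Marks a call as a common variant when at least `polymorphic_overlap`
#' (default 50%) of the gene's total exonic bases fall inside the supplied
#' polymorphic regions. Filtered calls remain in the output with
#' `filtered = TRUE` and reason `"polymorphic"`; ranks are recomputed over
#' the unfiltered calls only. Applying the filter twice is the same as
#' applying it once.
#'
#' @param calls A `cnv_calls` tibble.
#' @param polymorphic_regions Data frame of BED intervals (`chrom`, `start`,
#'   `end`) or a path to a BED file; NULL or empty means no filtering.
#' @param model The `gene_model` the calls refer to.
#' @param params A `karyo_params` or NULL for defaults.
#' @return The `cnv_calls` tibble with `filtered`/`filter_reason` set and
#'   ranks recomputed.
#' @export
filter_common <- function(calls, polymorphic_regions, model, params = NULL) {
  params <- as_karyo_params(params)
  regions <- read_regions(polymorphic_regions)
  if (is.null(regions) || nrow(regions) == 0 || nrow(calls) == 0) {
    return(rank_cnvs(calls))
  }
  frac <- polymorphic_fraction(model, regions)
  calls <- tibble::as_tibble(calls)
  hit <- frac[calls$gene_id] >= params$polymorphic_overlap
  hit[is.na(hit)] <- FALSE
  calls$filtered <- unname(hit)
  calls$filter_reason <- unname(ifelse(hit, "polymorphic", NA_character_))
  rank_cnvs(new_cnv_calls(calls,
                          unassessed = attr(calls, "unassessed") %||% character(),
                          genes_assessed = attr(calls, "genes_assessed")))
}

read_regions <- function(x) {
  if (is.null(x)) return(NULL)
  if (is.character(x) && length(x) == 1) {
    lines <- readLines(x)
    lines <- lines[nzchar(trimws(lines)) & !grepl("^(track|browser|#)", lines)]
    if (!length(lines)) return(tibble::tibble(chrom = character(),
                                              start = integer(),
                                              end = integer()))
    fields <- strsplit(lines, "\t", fixed = TRUE)
    x <- tibble::tibble(chrom = vapply(fields, `[[`, "", 1),
                        start = as.integer(vapply(fields, `[[`, "", 2)),
                        end = as.integer(vapply(fields, `[[`, "", 3)))
  }
  tibble::as_tibble(x)[c("chrom", "start", "end")]
}

# fraction of each gene's exonic bases covered by the regions
polymorphic_fraction <- function(model, regions) {
  totals <- tapply(model$end - model$start, model$gene_id, sum)
  overlap <- stats::setNames(numeric(length(totals)), names(totals))
  for (chr in unique(model$chrom)) {
    ex <- model[model$chrom == chr, , drop = FALSE]
    rg <- regions[regions$chrom == chr, , drop = FALSE]
    if (nrow(rg) == 0) next
    exon_ir <- IRanges::IRanges(start = ex$start + 1L, end = ex$end)
    region_ir <- IRanges::reduce(IRanges::IRanges(start = rg$start + 1L,
                                                  end = rg$end))
    hits <- IRanges::findOverlaps(exon_ir, region_ir)
    if (length(hits) == 0) next
    inter_w <- IRanges::width(IRanges::pintersect(
      exon_ir[S4Vectors_queryHits(hits)], region_ir[S4Vectors_subjectHits(hits)]))
    per_exon <- tapply(inter_w, S4Vectors_queryHits(hits), sum)
    idx <- as.integer(names(per_exon))
    ov <- tapply(as.numeric(per_exon), ex$gene_id[idx], sum)
    overlap[names(ov)] <- overlap[names(ov)] + ov
  }
  overlap / as.numeric(totals)
}

# thin indirection so the IRanges accessors resolve without attaching S4Vectors
S4Vectors_queryHits <- function(h) IRanges::from(h)
S4Vectors_subjectHits <- function(h) IRanges::to(h)

#' Assign specimen homozygosity from the heterozygous SNP fraction
#'
#' Computes the percentage of called SNPs that are heterozygous and assigns
#' homozygosity when it is at or below the cutoff (default 5.0%). Missing
#' genotypes were already excluded at read time and enter neither numerator
#' nor denominator.
#'
#' @param variants A `variant_table`.
#' @param params A `karyo_params` or NULL for defaults.
#' @return A `zygosity_report`: list with `n_sites`, `het_fraction_pct`,
#'   `homozygous`.
#' @examples
#' assign_zygosity(simulate_variants(1000, 0.03, seed = 1))
#' @export
assign_zygosity <- function(variants, params = NULL) {
  params <- as_karyo_params(params)
  gt <- variants$genotype
  if (length(gt) == 0) stop("no called sites: zygosity is undefined", call. = FALSE)
  het_pct <- 100 * sum(gt == "het") / length(gt)
  structure(
    list(n_sites = length(gt),
         het_fraction_pct = het_pct,
         homozygous = het_pct <= params$het_homozygosity_cutoff_pct),
    class = "zygosity_report"
  )
}

#' @export
print.zygosity_report <- function(x, ...) {
  cat(sprintf("<zygosity_report> %d sites, %.2f%% heterozygous -> %s\n",
              x$n_sites, x$het_fraction_pct,
              if (x$homozygous) "homozygous" else "not homozygous"))
  invisible(x)
}

#' Summarize CNV calls into chromosome-level aneuploidy
#'
#' Aggregates unfiltered gene-level calls into per-chromosome and total
#' aneuploidy percentages: the fraction of assessed genes (genes with at
#' least one unmasked exon) called gained or lost.
#'
#' @param calls A `cnv_calls` tibble (filtered calls are excluded).
#' @param model The `gene_model`.
#' @return An `aneuploidy_report`: list with `per_chromosome` tibble
#'   (`chrom`, `genes_assessed`, `genes_gained`, `genes_lost`,
#'   `aneuploidy_pct`) and scalars `total_aneuploidy_pct`,
#'   `genes_assessed`, `genes_called`.
#' @export
summarize_aneuploidy <- function(calls, model) {
  calls <- tibble::as_tibble(calls)
  active <- calls[!calls$filtered, , drop = FALSE]
  unassessed <- attr(calls, "unassessed") %||% character()
  chroms <- model_chromosomes(model)
  assessed <- tibble::as_tibble(model) |>
    dplyr::distinct(.data$chrom, .data$gene_id) |>
    dplyr::filter(!.data$gene_id %in% unassessed) |>
    dplyr::count(.data$chrom, name = "genes_assessed")
  per_chrom <- tibble::tibble(chrom = chroms) |>
    dplyr::left_join(assessed, by = "chrom") |>
    dplyr::left_join(
      active |> dplyr::count(.data$chrom, .data$call) |>
        tidyr::pivot_wider(names_from = "call", values_from = "n",
                           values_fill = 0L),
      by = "chrom"
    )
  for (col in c("genes_assessed", "gain", "loss")) {
    if (!col %in% names(per_chrom)) per_chrom[[col]] <- 0L
    per_chrom[[col]][is.na(per_chrom[[col]])] <- 0L
  }
  per_chrom <- per_chrom |>
    dplyr::transmute(
      chrom = .data$chrom,
      genes_assessed = as.integer(.data$genes_assessed),
      genes_gained = as.integer(.data$gain),
      genes_lost = as.integer(.data$loss),
      aneuploidy_pct = ifelse(.data$genes_assessed > 0,
                              100 * (.data$genes_gained + .data$genes_lost) /
                                .data$genes_assessed, NA_real_)
    )
  total_assessed <- sum(per_chrom$genes_assessed)
  total_called <- sum(per_chrom$genes_gained + per_chrom$genes_lost)
  structure(
    list(per_chromosome = per_chrom,
         genes_assessed = total_assessed,
         genes_called = total_called,
         total_aneuploidy_pct = if (total_assessed > 0) {
           100 * total_called / total_assessed
         } else NA_real_),
    class = "aneuploidy_report"
  )
}

#' @export
print.aneuploidy_report <- function(x, ...) {
  cat(sprintf("<aneuploidy_report> %d/%d genes called (%.2f%% total aneuploidy)\n",
              x$genes_called, x$genes_assessed, x$total_aneuploidy_pct))
  print(x$per_chromosome)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
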