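#' Read a gene/exon model from BED
#'
#' Parses a BED file (at least four columns: chrom, start, end, name) into a
#' gene model: one row per exon, grouped by gene, sorted by position, with
#' overlapping or book-ended records of the same gene merged. Coordinates are
#' BED convention, 0-based half-open, and are kept that way in all outputs.
#'
#' @param path Path to a BED file with columns chrom, start, end, gene_id.
#' @return A `gene_model` tibble with columns `chrom`, `start`, `end`,
#'   `gene_id`, one row per exon, carrying the ordered chromosome list in
#'   attribute `chromosomes`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines(c("chr21\t0\t100\tG1", "chr21\t200\t300\tG1"), bed)
#' read_gene_model(bed)
#' @export
read_gene_model <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines)]
  if (length(lines) == 0 || all(!nzchar(trimws(lines)))) {
    warning("empty BED file: returning an empty gene model", call. = FALSE)
    return(new_gene_model(tibble::tibble(
      chrom = character(), start = integer(), end = integer(),
      gene_id = character()
    )))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 4)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: expected >= 4 tab-separated fields",
                 bad[1]), call. = FALSE)
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3)))
  bad <- which(is.na(starts) | is.na(ends))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-integer coordinates", bad[1]),
         call. = FALSE)
  }
  exons <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1),
    start = starts,
    end = ends,
    gene_id = vapply(fields, `[[`, "", 4)
  )
  bad <- which(exons$end <= exons$start)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: end must exceed start", bad[1]),
         call. = FALSE)
  }
  as_gene_model(exons)
}

#' Build a gene model from an exon table
#'
#' @param exons Data frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (BED coordinates, 0-based half-open). Exons of a gene are sorted and
#'   merged when they overlap or are book-ended.
#' @return A `gene_model` tibble; see [read_gene_model()].
#' @export
as_gene_model <- function(exons) {
  exons <- tibble::as_tibble(exons)[c("chrom", "start", "end", "gene_id")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (any(exons$end <= exons$start)) {
    stop("every exon interval must satisfy end > start", call. = FALSE)
  }
  multi <- exons |>
    dplyr::distinct(.data$gene_id, .data$chrom) |>
    dplyr::count(.data$gene_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(multi)) {
    stop(sprintf("gene_id spanning multiple chromosomes: %s",
                 paste(multi$gene_id, collapse = ", ")), call. = FALSE)
  }
  chrom_order <- unique(exons$chrom)
  # merge overlapping/book-ended exon records within a gene
  merged <- exons |>
    dplyr::arrange(match(.data$chrom, chrom_order), .data$start, .data$end) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      new_block = .data$start > dplyr::lag(cummax(as.numeric(.data$end)),
                                           default = -Inf),
      block = cumsum(.data$new_block)
    ) |>
    dplyr::group_by(.data$gene_id, .data$chrom, .data$block) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$chrom, chrom_order), .data$start,
                   .data$gene_id) |>
    dplyr::select("chrom", "start", "end", "gene_id")
  new_gene_model(merged, chromosomes = chrom_order)
}

new_gene_model <- function(exons, chromosomes = unique(exons$chrom)) {
  structure(exons,
            chromosomes = chromosomes,
            class = c("gene_model", class(tibble::tibble())))
}

is_gene_model <- function(x) inherits(x, "gene_model")

#' Write a gene model to BED
#'
#' @param model A `gene_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  stopifnot(is_gene_model(model))
  readr::write_tsv(tibble::as_tibble(model)[c("chrom", "start", "end", "gene_id")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @export
print.gene_model <- function(x, ...) {
  genes <- length(unique(x$gene_id))
  cat(sprintf("<gene_model> %d exon(s), %d gene(s), %d chromosome(s)\n",
              nrow(x), genes, length(attr(x, "chromosomes"))))
  NextMethod()
}

model_chromosomes <- function(model) {
  chr <- attr(model, "chromosomes")
  if (is.null(chr)) unique(model$chrom) else chr
}

exon_key <- function(df) {
  paste(df$chrom, df$start, df$end, df$gene_id, sep = ":")
}
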