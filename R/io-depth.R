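#' Read a per-exon depth table
#'
#' Reads a tab-separated table with columns `chrom`, `start`, `end`, `gene`
#' (or `gene_id`) and `depth`, and checks it against a gene model: every exon
#' of the model must be present exactly once with identical coordinates, and
#' depths must be non-negative integers. Partial coverage is an error, not a
#' silent drop, because the per-gene exon-fraction rule downstream is
#' undefined over missing exons.
#'
#' @param path Path to a TSV file with a header row.
#' @param model A `gene_model` the table must cover.
#' @return A `depth_table` tibble with columns `chrom`, `start`, `end`,
#'   `gene_id`, `depth`, in model exon order.
#' @export
read_depth_table <- function(path, model) {
  stopifnot(is_gene_model(model))
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  names(tab)[names(tab) == "gene"] <- "gene_id"
  required <- c("chrom", "start", "end", "gene_id", "depth")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("depth table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  depth_num <- suppressWarnings(as.numeric(tab$depth))
  bad <- which(is.na(depth_num) | depth_num < 0 | depth_num != round(depth_num))
  if (length(bad)) {
    stop(sprintf("row %d: depth %s is not a non-negative integer",
                 bad[1], tab$depth[bad[1]]), call. = FALSE)
  }
  tab <- tibble::tibble(
    chrom = tab$chrom,
    start = as.integer(tab$start),
    end = as.integer(tab$end),
    gene_id = tab$gene_id,
    depth = as.integer(depth_num)
  )
  as_depth_table(tab, model)
}

#' Validate a depth table against a gene model
#'
#' @param depths Data frame with columns `chrom`, `start`, `end`, `gene_id`
#'   (or `gene`), `depth`.
#' @inheritParams read_depth_table
#' @return A `depth_table` tibble in model exon order.
#' @export
as_depth_table <- function(depths, model) {
  stopifnot(is_gene_model(model))
  depths <- tibble::as_tibble(depths)
  names(depths)[names(depths) == "gene"] <- "gene_id"
  if (any(depths$depth < 0) || any(depths$depth != round(depths$depth))) {
    stop("depths must be non-negative integers", call. = FALSE)
  }
  keys <- exon_key(depths)
  model_keys <- exon_key(model)
  absent <- setdiff(model_keys, keys)
  if (length(absent)) {
    pretty <- vapply(strsplit(absent, ":", fixed = TRUE), function(f) {
      sprintf("%s exon %s:%s-%s", f[4], f[1], f[2], f[3])
    }, "")
    stop(sprintf("depth table is missing %d model exon(s): %s",
                 length(absent),
                 paste(utils::head(pretty, 5), collapse = "; ")),
         call. = FALSE)
  }
  extra <- setdiff(keys, model_keys)
  if (length(extra)) {
    stop(sprintf("depth table contains %d exon(s) not in the model (first: %s)",
                 length(extra), extra[1]), call. = FALSE)
  }
  if (anyDuplicated(keys)) {
    stop("depth table lists the same exon more than once", call. = FALSE)
  }
  ord <- match(model_keys, keys)
  out <- tibble::tibble(
    chrom = as.character(depths$chrom[ord]),
    start = as.integer(depths$start[ord]),
    end = as.integer(depths$end[ord]),
    gene_id = as.character(depths$gene_id[ord]),
    depth = as.integer(depths$depth[ord])
  )
  structure(out, class = c("depth_table", class(tibble::tibble())))
}

#' Write a depth table to TSV
#'
#' @param depths A `depth_table` (or compatible data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_depth_table <- function(depths, path) {
  readr::write_tsv(tibble::as_tibble(depths)[c("chrom", "start", "end",
                                               "gene_id", "depth")], path)
  invisible(path)
}
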