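#' Read per-cell FISH signal counts
#'
#' Reads a tab-separated table with one row per scored cell and one column
#' per probe in the panel, each entry the number of fluorescent signals
#' counted for that probe in that cell. Cells are returned in file order.
#'
#' @param path Path to a TSV file whose header names every probe in `panel`.
#' @param panel Character vector of probe (chromosome) names; defaults to the
#'   nine-probe panel in [karyo_params()].
#' @return A `fish_cells` tibble with a `cell` index column and one integer
#'   column per probe.
#' @export
read_fish_cells <- function(path, panel = karyo_params()$probe_panel) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_probes <- setdiff(panel, names(tab))
  if (length(missing_probes)) {
    stop(sprintf("FISH table is missing probe column(s): %s",
                 paste(missing_probes, collapse = ", ")), call. = FALSE)
  }
  counts <- tab[panel]
  for (p in panel) {
    v <- suppressWarnings(as.numeric(counts[[p]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad)) {
      stop(sprintf("row %d, probe %s: signal count '%s' is not a non-negative integer",
                   bad[1], p, counts[[p]][bad[1]]), call. = FALSE)
    }
    counts[[p]] <- as.integer(v)
  }
  as_fish_cells(counts, panel)
}

#' Build a FISH cell table from counts
#'
#' @param counts Data frame with one non-negative integer column per probe.
#' @inheritParams read_fish_cells
#' @return A `fish_cells` tibble.
#' @export
as_fish_cells <- function(counts, panel = karyo_params()$probe_panel) {
  counts <- tibble::as_tibble(counts)
  missing_probes <- setdiff(panel, names(counts))
  if (length(missing_probes)) {
    stop(sprintf("missing probe column(s): %s",
                 paste(missing_probes, collapse = ", ")), call. = FALSE)
  }
  counts <- counts[panel]
  if (any(vapply(counts, function(v) any(v < 0 | v != round(v)), TRUE))) {
    stop("signal counts must be non-negative integers", call. = FALSE)
  }
  counts[] <- lapply(counts, as.integer)
  out <- dplyr::bind_cols(tibble::tibble(cell = seq_len(nrow(counts))), counts)
  structure(out,
            panel = panel,
            class = c("fish_cells", class(tibble::tibble())))
}

cells_panel <- function(cells) {
  p <- attr(cells, "panel")
  if (is.null(p)) setdiff(names(cells), "cell") else p
}

#' Write FISH cells to TSV
#'
#' @param cells A `fish_cells` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fish_cells <- function(cells, path) {
  panel <- cells_panel(cells)
  readr::write_tsv(tibble::as_tibble(cells)[panel], path)
  invisible(path)
}
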