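# Small programmatic fixtures shared across test files.

tiny_model <- function() {
  as_gene_model(data.frame(
    chrom = c("chr21", "chr21", "chr21", "chr22", "chr22"),
    start = c(0L, 200L, 400L, 0L, 300L),
    end = c(100L, 300L, 500L, 100L, 400L),
    gene_id = c("G1", "G1", "G1", "G2", "G2")
  ))
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

depth_tsv <- function(model, depths) {
  c("chrom\tstart\tend\tgene\tdepth",
    sprintf("%s\t%d\t%d\t%s\t%s", model$chrom, model$start, model$end,
            model$gene_id, depths))
}

# FISH cell with the given per-probe counts; defaults are a normal haploid
# X-bearing cell over the standard 9-probe panel.
make_cell <- function(..., panel = karyo_params()$probe_panel) {
  counts <- stats::setNames(as.list(rep(1L, length(panel))), panel)
  counts[["Y"]] <- 0L
  over <- list(...)
  counts[names(over)] <- lapply(over, as.integer)
  tibble::as_tibble(counts)
}

make_cells <- function(...) {
  as_fish_cells(dplyr::bind_rows(...))
}
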