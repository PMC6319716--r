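#' Read a variant table with zygosity calls
#'
#' Accepts either a VCF (zygosity taken from the first sample's GT field) or
#' a minimal TSV with columns `chrom`, `pos`, `genotype` where genotype is
#' `het` or `hom`. Phased and unphased genotypes are treated identically and
#' multi-allelic genotypes are classified by whether the two called alleles
#' differ. Missing genotypes (`./.`) are excluded from the table and counted
#' separately, so they enter neither the numerator nor the denominator of the
#' heterozygous fraction.
#'
#' @param path Path to a `.vcf` file or a TSV.
#' @return A `variant_table` tibble with columns `chrom`, `pos`, `genotype`
#'   (factor-free character, `"het"`/`"hom"`) and an attribute `n_missing`.
#' @export
read_variant_table <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    read_variant_vcf(path)
  } else {
    read_variant_tsv(path)
  }
}

read_variant_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@fix) == 0) {
    return(new_variant_table(tibble::tibble(chrom = character(),
                                            pos = integer(),
                                            genotype = character()),
                             n_missing = 0L))
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")[, 1]
  zyg <- classify_gt(gt)
  keep <- !is.na(zyg)
  new_variant_table(
    tibble::tibble(chrom = vcf@fix[keep, "CHROM"],
                   pos = as.integer(vcf@fix[keep, "POS"]),
                   genotype = zyg[keep]),
    n_missing = sum(!keep)
  )
}

# GT string -> "het"/"hom"/NA (missing). Handles phased separators and
# multi-allelic allele indices; haploid calls count as hom.
classify_gt <- function(gt) {
  alleles <- strsplit(gt, "[/|]")
  vapply(alleles, function(a) {
    if (length(a) == 0 || any(a == "." | a == "" | is.na(a))) return(NA_character_)
    if (length(unique(a)) > 1) "het" else "hom"
  }, "")
}

read_variant_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  required <- c("chrom", "pos", "genotype")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop(sprintf("variant table is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  gt <- tolower(tab$genotype)
  missing <- gt %in% c("./.", ".", "missing", "na")
  bad <- which(!missing & !gt %in% c("het", "hom"))
  if (length(bad)) {
    stop(sprintf("row %d: unknown genotype token '%s' (expected het/hom)",
                 bad[1], tab$genotype[bad[1]]), call. = FALSE)
  }
  new_variant_table(
    tibble::tibble(chrom = tab$chrom[!missing],
                   pos = as.integer(tab$pos[!missing]),
                   genotype = gt[!missing]),
    n_missing = sum(missing)
  )
}

new_variant_table <- function(tab, n_missing = 0L) {
  structure(tab,
            n_missing = as.integer(n_missing),
            class = c("variant_table", class(tibble::tibble())))
}

#' Write a variant table to TSV
#'
#' @param variants A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(variants, path) {
  readr::write_tsv(tibble::as_tibble(variants)[c("chrom", "pos", "genotype")],
                   path)
  invisible(path)
}
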