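#' @title Seeded synthetic inputs for every pipeline stage
#' @description Generators that emulate the statistical structure the
#'   analysis assumes — shared exon-level depth baselines with overdispersed
#'   count noise and spiked copy-number events, per-cell FISH signal counts
#'   under known disomy/nullisomy/diploidy rates, het/hom SNP tables, and
#'   Bernoulli TUNEL labels — so each stage can be validated by parameter
#'   recovery. All generators are deterministic given `seed`.
#' @name simulate
NULL

# run code under a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Overdispersed counts with linear mean-variance relation var = (1 + phi) mu
# (negative binomial with size mu/phi). phi = 0 is the noiseless limit:
# depths are exactly round(mu), so identity and boundary properties can be
# exercised without sampling noise.
rdepth <- function(mu, dispersion) {
  if (dispersion == 0) return(as.integer(round(mu)))
  out <- integer(length(mu))
  pos <- mu > 0  # a fully deleted target has mean 0 and draws 0 reads
  out[pos] <- as.integer(stats::rnbinom(sum(pos), size = mu[pos] / dispersion,
                                        mu = mu[pos]))
  out
}

#' Simulate a control/study exome depth pair with spiked CNVs
#'
#' Draws one latent per-exon baseline shared by both specimens,
#' `b_e = baseline_depth * exp(N(0, exon_effect_sd))` (emulating exon-level
#' capture efficiency), then samples overdispersed counts around `b_e` for
#' the control and around `m_g * b_e` for the study, where `m_g` is the
#' spiked multiplier of the gene owning the exon (1 when unspiked). Count
#' noise has linear mean-variance relation `var = (1 + dispersion) * mu`;
#' `dispersion = 0` is the deterministic noiseless limit. Spiking a
#' chromosome applies its multiplier to every gene on it, modelling a
#' cell-fraction whole-chromosome aneuploidy in bulk sperm DNA (e.g.
#' multiplier 1 + f for a chromosome gained in a fraction f of cells).
#'
#' @param model A `gene_model`.
#' @param baseline_depth Mean exon depth in reads. Default 100.
#' @param exon_effect_sd SD (log scale) of the per-exon multiplicative
#'   baseline effect. Default 0.05.
#' @param dispersion Overdispersion of the count noise (linear
#'   parameterization); 0 gives deterministic depths. Default 0.05.
#' @param spiked_events Data frame with columns `target` (a gene_id or a
#'   chromosome name from the model) and `multiplier` (>= 0), or NULL.
#' @param seed Integer seed; NULL uses the current RNG state.
#' @return A list with `depth_table` elements `control` and `study`, plus
#'   `truth`: a tibble of the per-gene multipliers actually applied.
#' @examples
#' sim <- simulate_depth_pair(toy_gene_model(), seed = 1,
#'   spiked_events = data.frame(target = "13_G01", multiplier = 2))
#' head(sim$study)
#' @export
simulate_depth_pair <- function(model,
                                baseline_depth = 100,
                                exon_effect_sd = 0.05,
                                dispersion = 0.05,
                                spiked_events = NULL,
                                seed = NULL) {
  stopifnot(is_gene_model(model), baseline_depth > 0, dispersion >= 0,
            exon_effect_sd >= 0)
  mult <- stats::setNames(rep(1, length(unique(model$gene_id))),
                          unique(model$gene_id))
  if (!is.null(spiked_events) && nrow(spiked_events)) {
    spiked_events <- tibble::as_tibble(spiked_events)
    if (any(spiked_events$multiplier < 0)) {
      stop("spiked multipliers must be >= 0", call. = FALSE)
    }
    chroms <- model_chromosomes(model)
    for (i in seq_len(nrow(spiked_events))) {
      target <- spiked_events$target[i]
      m <- spiked_events$multiplier[i]
      if (target %in% names(mult)) {
        mult[target] <- mult[target] * m
      } else if (target %in% chroms) {
        on_chrom <- unique(model$gene_id[model$chrom == target])
        mult[on_chrom] <- mult[on_chrom] * m
      } else {
        stop(sprintf("spiked target '%s' is neither a gene nor a chromosome of the model",
                     target), call. = FALSE)
      }
    }
  }
  exon_mult <- mult[model$gene_id]
  with_seed(seed, {
    b_e <- baseline_depth *
      exp(stats::rnorm(nrow(model), 0, exon_effect_sd))
    control <- rdepth(b_e, dispersion)
    study <- rdepth(exon_mult * b_e, dispersion)
    list(
      control = as_depth_table(dplyr::mutate(tibble::as_tibble(model),
                                             depth = control), model),
      study = as_depth_table(dplyr::mutate(tibble::as_tibble(model),
                                           depth = study), model),
      truth = tibble::tibble(gene_id = names(mult),
                             multiplier = unname(mult))
    )
  })
}

#' Simulate per-cell FISH signal counts
#'
#' Per cell, diploidy is drawn first with probability `diploidy_rate`: a
#' diploid cell shows 2 signals on every autosome probe and 2 sex-chromosome
#' signals in total (two independent haploid sex draws). Otherwise each
#' chromosomal unit (each autosome, and the X/Y pair jointly) independently
#' shows disomy (2 signals) with its disomy rate, nullisomy (0 signals) with
#' its nullisomy rate, and 1 signal otherwise; sex-probe signals are
#' allocated to X with probability `sex_ratio` per haploid draw.
#'
#' @param n_cells Number of cells.
#' @param panel Probe panel (chromosome names); default from
#'   [karyo_params()].
#' @param disomy_rate,nullisomy_rate Scalar rate applied to every chromosomal
#'   unit, or a named vector over units (autosome names and `"XY"` for the
#'   sex pair); unnamed units default to 0.
#' @param diploidy_rate Per-cell diploidy probability.
#' @param sex_ratio Probability a haploid draw carries X rather than Y.
#' @param seed Integer seed; NULL uses the current RNG state.
#' @return A `fish_cells` tibble.
#' @examples
#' simulate_fish_cells(5, disomy_rate = c("21" = 0.5), seed = 1)
#' @export
simulate_fish_cells <- function(n_cells,
                                panel = karyo_params()$probe_panel,
                                disomy_rate = 0,
                                nullisomy_rate = 0,
                                diploidy_rate = 0,
                                sex_ratio = 0.5,
                                seed = NULL) {
  stopifnot(n_cells >= 1, diploidy_rate >= 0, diploidy_rate <= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  autosomes <- panel_autosomes(panel)
  units <- c(autosomes, if (panel_has_sex(panel)) "XY")
  d <- unit_rates(disomy_rate, units, "disomy_rate")
  n <- unit_rates(nullisomy_rate, units, "nullisomy_rate")
  if (any(d + n > 1)) {
    stop("disomy_rate + nullisomy_rate must be <= 1 for every chromosome",
         call. = FALSE)
  }
  with_seed(seed, {
    counts <- matrix(1L, nrow = n_cells, ncol = length(panel),
                     dimnames = list(NULL, panel))
    diploid <- stats::runif(n_cells) < diploidy_rate
    for (a in autosomes) {
      u <- stats::runif(n_cells)
      counts[, a] <- ifelse(u < d[a], 2L, ifelse(u < d[a] + n[a], 0L, 1L))
      counts[diploid, a] <- 2L
    }
    if (panel_has_sex(panel)) {
      u <- stats::runif(n_cells)
      copies <- ifelse(u < d["XY"], 2L, ifelse(u < d["XY"] + n["XY"], 0L, 1L))
      copies[diploid] <- 2L
      x1 <- stats::runif(n_cells) < sex_ratio
      x2 <- stats::runif(n_cells) < sex_ratio
      nx <- ifelse(copies == 0L, 0L,
                   ifelse(copies == 1L, as.integer(x1),
                          as.integer(x1) + as.integer(x2)))
      counts[, "X"] <- nx
      counts[, "Y"] <- copies - nx
    }
    as_fish_cells(tibble::as_tibble(counts), panel)
  })
}

unit_rates <- function(rate, units, what) {
  if (is.null(names(rate))) {
    if (length(rate) != 1) {
      stop(sprintf("`%s` must be a scalar or a named vector", what),
           call. = FALSE)
    }
    r <- stats::setNames(rep(rate, length(units)), units)
  } else {
    unknown <- setdiff(names(rate), units)
    if (length(unknown)) {
      stop(sprintf("`%s` names not in the panel's chromosomal units: %s",
                   what, paste(unknown, collapse = ", ")), call. = FALSE)
    }
    r <- stats::setNames(rep(0, length(units)), units)
    r[names(rate)] <- rate
  }
  if (any(r < 0 | r > 1)) {
    stop(sprintf("`%s` values must lie in [0, 1]", what), call. = FALSE)
  }
  r
}

#' Simulate a het/hom SNP table
#'
#' Each site is independently heterozygous with probability `het_fraction`.
#'
#' @param n_sites Number of called sites.
#' @param het_fraction Probability a site is heterozygous.
#' @param seed Integer seed; NULL uses the current RNG state.
#' @return A `variant_table` tibble.
#' @export
simulate_variants <- function(n_sites, het_fraction, seed = NULL) {
  stopifnot(n_sites >= 0, het_fraction >= 0, het_fraction <= 1)
  with_seed(seed, {
    het <- stats::runif(n_sites) < het_fraction
    new_variant_table(tibble::tibble(
      chrom = rep("chr1", n_sites),
      pos = seq_len(n_sites),
      genotype = ifelse(het, "het", "hom")
    ))
  })
}

#' Simulate per-cell TUNEL fragmentation labels
#'
#' @param n_cells Number of cells.
#' @param frag_rate Probability a cell is TUNEL-positive.
#' @param seed Integer seed; NULL uses the current RNG state.
#' @return A tibble with columns `cell` and logical `fragmented`.
#' @export
simulate_tunel <- function(n_cells, frag_rate, seed = NULL) {
  stopifnot(n_cells >= 1, frag_rate >= 0, frag_rate <= 1)
  with_seed(seed, tibble::tibble(
    cell = seq_len(n_cells),
    fragmented = stats::runif(n_cells) < frag_rate
  ))
}

#' Desk-scale gene model for simulation
#'
#' A small genome whose chromosomes mirror the FISH probe panel: by default
#' 9 chromosomes, 20 genes per chromosome, 5 exons of 150 bp per gene, with
#' 50 bp introns and 10 kb between genes.
#'
#' @param chromosomes Chromosome names. Default the probe panel.
#' @param genes_per_chrom,exons_per_gene,exon_bp Model dimensions.
#' @return A `gene_model` tibble.
#' @examples
#' toy_gene_model(genes_per_chrom = 2, exons_per_gene = 3)
#' @export
toy_gene_model <- function(chromosomes = karyo_params()$probe_panel,
                           genes_per_chrom = 20,
                           exons_per_gene = 5,
                           exon_bp = 150) {
  grid <- tidyr::expand_grid(
    chrom = chromosomes,
    gene = seq_len(genes_per_chrom),
    exon = seq_len(exons_per_gene)
  )
  exons <- grid |>
    dplyr::mutate(
      gene_id = sprintf("%s_G%02d", .data$chrom, .data$gene),
      start = (.data$gene - 1L) * 10000L + (.data$exon - 1L) * (exon_bp + 50L),
      end = .data$start + exon_bp
    ) |>
    dplyr::select("chrom", "start", "end", "gene_id")
  as_gene_model(exons)
}
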