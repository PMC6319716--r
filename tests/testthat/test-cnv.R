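# build a logratio_track directly so thresholds can be pinned exactly
manual_track <- function(model, study_norm, control_norm = 1) {
  structure(tibble::tibble(
    chrom = model$chrom, start = model$start, end = model$end,
    gene_id = model$gene_id,
    study_norm = study_norm,
    control_norm = rep_len(control_norm, nrow(model)),
    log2_ratio = log2(study_norm / rep_len(control_norm, nrow(model))),
    masked = FALSE
  ), class = c("logratio_track", class(tibble::tibble())))
}

ten_exon_model <- function(n_genes = 3) {
  toy_gene_model(chromosomes = "chr1", genes_per_chrom = n_genes,
                 exons_per_gene = 10)
}

test_that("the 70%-exon rule calls gains and losses with strict boundaries", {
  model <- ten_exon_model()
  # gene 1: 8 exons at 2.0x, 2 at 1.0x -> gain, fraction 0.8
  sn <- rep(1, nrow(model))
  sn[model$gene_id == "chr1_G01"] <- c(rep(2, 8), 1, 1)
  calls <- call_gene_cnv(manual_track(model, sn), model)
  expect_equal(calls$gene_id, "chr1_G01")
  expect_equal(calls$call, "gain")
  expect_equal(calls$supporting_exon_fraction, 0.8)
  expect_equal(calls$rank, 1L)

  # 7/10 exons at 1.6x: fraction 0.7 is NOT > 0.70 -> no call
  sn <- rep(1, nrow(model))
  sn[model$gene_id == "chr1_G01"] <- c(rep(1.6, 7), 1, 1, 1)
  expect_equal(nrow(call_gene_cnv(manual_track(model, sn), model)), 0)

  # exactly 1.5x / 0.5x the reference does not support (strict inequality)
  sn <- rep(1, nrow(model))
  sn[model$gene_id == "chr1_G01"] <- 1.5
  sn[model$gene_id == "chr1_G02"] <- 0.5
  expect_equal(nrow(call_gene_cnv(manual_track(model, sn), model)), 0)

  # just past the thresholds both directions are called
  sn <- rep(1, nrow(model))
  sn[model$gene_id == "chr1_G01"] <- 1.5001
  sn[model$gene_id == "chr1_G02"] <- 0.4999
  calls <- call_gene_cnv(manual_track(model, sn), model)
  expect_setequal(paste(calls$gene_id, calls$call),
                  c("chr1_G01 gain", "chr1_G02 loss"))
})

test_that("identical specimens yield zero calls genome-wide", {
  model <- toy_gene_model()
  sim <- simulate_depth_pair(model, seed = 21)
  track <- depth_logratio(sim$control, sim$control, model)
  calls <- call_gene_cnv(track, model)
  expect_equal(nrow(calls), 0)
  rep <- summarize_aneuploidy(calls, model)
  expect_equal(rep$total_aneuploidy_pct, 0)
})

test_that("fully masked genes are unassessed, not called", {
  model <- tiny_model()
  study <- as_depth_table(dplyr::mutate(tibble::as_tibble(model),
                                        depth = c(100L, 100L, 100L, 0L, 0L)),
                          model)
  control <- as_depth_table(dplyr::mutate(tibble::as_tibble(model),
                                          depth = c(100L, 100L, 100L, 0L, 0L)),
                            model)
  track <- depth_logratio(study, control, model)
  calls <- call_gene_cnv(track, model)
  expect_equal(attr(calls, "unassessed"), "G2")
  rep <- summarize_aneuploidy(calls, model)
  g2row <- rep$per_chromosome[rep$per_chromosome$chrom == "chr22", ]
  expect_equal(g2row$genes_assessed, 0L)
})

test_that("ranking sorts by |log ratio| with lexicographic tie-break", {
  calls <- tibble::tibble(
    gene_id = c("B", "C", "A"), chrom = "chr1", call = "gain",
    supporting_exon_fraction = 1,
    mean_log2_ratio = c(1.0, 0.9, 2.0),
    filtered = FALSE, filter_reason = NA_character_
  )
  ranked <- rank_cnvs(calls)
  expect_equal(ranked$gene_id, c("A", "B", "C"))
  expect_equal(ranked$rank, 1:3)

  expect_equal(nrow(rank_cnvs(calls[0, ])), 0)

  tie <- dplyr::mutate(calls[1:2, ], gene_id = c("B", "A"),
                       mean_log2_ratio = 1.0)
  expect_equal(rank_cnvs(tie)$gene_id, c("A", "B"))
  # losses rank by magnitude
  mixed <- dplyr::mutate(calls, mean_log2_ratio = c(-3, 0.5, 1),
                         call = c("loss", "gain", "gain"))
  expect_equal(rank_cnvs(mixed)$gene_id[1], "B")
})

test_that("polymorphic-region filtering follows the 50% exonic-overlap rule", {
  model <- tiny_model()  # G1: chr21 exons 0-100,200-300,400-500; G2: chr22
  calls <- tibble::tibble(
    gene_id = c("G1", "G2"), chrom = c("chr21", "chr22"), call = "gain",
    supporting_exon_fraction = 1, mean_log2_ratio = c(1, 0.8),
    filtered = FALSE, filter_reason = NA_character_
  )
  # no regions: identity
  none <- filter_common(calls, NULL, model)
  expect_false(any(none$filtered))

  # G1 fully covered -> filtered; ranks recomputed over the survivors
  region <- data.frame(chrom = "chr21", start = 0, end = 600)
  filt <- filter_common(calls, region, model)
  expect_true(filt$filtered[filt$gene_id == "G1"])
  expect_equal(filt$filter_reason[filt$gene_id == "G1"], "polymorphic")
  expect_equal(filt$rank[filt$gene_id == "G2"], 1L)
  expect_true(is.na(filt$rank[filt$gene_id == "G1"]))

  # 1/3 of G1 exonic bases -> below 50%, not filtered
  partial <- data.frame(chrom = "chr21", start = 0, end = 100)
  expect_false(any(filter_common(calls, partial, model)$filtered))

  # exactly 50% of G2 (one of two 100 bp exons) -> filtered (>= rule)
  half <- data.frame(chrom = "chr22", start = 0, end = 100)
  expect_true(filter_common(calls, half, model)$filtered[2])

  # the filter is a projection: applying twice equals applying once
  once <- filter_common(calls, region, model)
  twice <- filter_common(once, region, model)
  expect_equal(tibble::as_tibble(twice), tibble::as_tibble(once))
})

test_that("zygosity assignment uses the 5% cutoff inclusively", {
  make_var <- function(het, hom) {
    as_variant <- tibble::tibble(
      chrom = "chr1", pos = seq_len(het + hom),
      genotype = c(rep("het", het), rep("hom", hom))
    )
    structure(as_variant, class = c("variant_table", class(tibble::tibble())))
  }
  z <- assign_zygosity(make_var(5, 95))
  expect_equal(z$het_fraction_pct, 5.0)
  expect_true(z$homozygous)
  z6 <- assign_zygosity(make_var(6, 94))
  expect_equal(z6$het_fraction_pct, 6.0)
  expect_false(z6$homozygous)
  expect_true(assign_zygosity(make_var(0, 10))$homozygous)
  expect_error(assign_zygosity(make_var(0, 0)), "no called sites")
})

test_that("aneuploidy summary is the fraction of assessed genes called", {
  model <- toy_gene_model(chromosomes = "chr21", genes_per_chrom = 180,
                          exons_per_gene = 1)
  genes <- unique(model$gene_id)
  calls <- tibble::tibble(
    gene_id = genes[1:9], chrom = "chr21",
    call = c(rep("gain", 5), rep("loss", 4)),
    supporting_exon_fraction = 1, mean_log2_ratio = 1,
    filtered = FALSE, filter_reason = NA_character_
  )
  rep <- summarize_aneuploidy(calls, model)
  expect_equal(rep$per_chromosome$aneuploidy_pct, 5.00)
  expect_equal(rep$per_chromosome$genes_gained, 5L)
  expect_equal(rep$per_chromosome$genes_lost, 4L)
  expect_equal(rep$total_aneuploidy_pct, 5.00)

  empty <- summarize_aneuploidy(calls[0, ], model)
  expect_equal(empty$total_aneuploidy_pct, 0)
  # filtered calls do not count
  rep2 <- summarize_aneuploidy(dplyr::mutate(calls, filtered = TRUE), model)
  expect_equal(rep2$total_aneuploidy_pct, 0)
})

test_that("caller matches a literal brute-force oracle on small instances", {
  model <- toy_gene_model(chromosomes = c("chrA", "chrB"),
                          genes_per_chrom = 10, exons_per_gene = 4)
  genes <- unique(model$gene_id)
  for (seed in 1:5) {
    set.seed(seed + 100)
    spikes <- data.frame(
      target = sample(genes, 6),
      multiplier = sample(c(0, 0.3, 1, 1.8, 2.5), 6, replace = TRUE)
    )
    sim <- simulate_depth_pair(model, seed = seed, spiked_events = spikes)
    track <- depth_logratio(sim$study, sim$control, model)
    calls <- call_gene_cnv(track, model)
    oracle <- brute_force_cnv(sim$study, sim$control, model)
    got <- tibble::as_tibble(calls)[order(calls$gene_id),
                                    c("gene_id", "call",
                                      "supporting_exon_fraction")]
    expect_equal(as.data.frame(got),
                 oracle[c("gene_id", "call", "supporting_exon_fraction")],
                 ignore_attr = TRUE)
  }
})

test_that("calls shrink monotonically as thresholds tighten and scale out", {
  model <- toy_gene_model(genes_per_chrom = 10)
  set.seed(77)
  spikes <- data.frame(target = sample(unique(model$gene_id), 12),
                       multiplier = rep(c(0, 1.7, 2.2, 0.4), 3))
  sim <- simulate_depth_pair(model, seed = 77, spiked_events = spikes)
  track <- depth_logratio(sim$study, sim$control, model)

  n_calls <- function(params) nrow(call_gene_cnv(track, model, params))
  base <- n_calls(karyo_params())
  # raising the exon fraction can only drop calls
  expect_lte(n_calls(karyo_params(exon_fraction = 0.9)), base)
  expect_lte(base, n_calls(karyo_params(exon_fraction = 0.5)))
  # widening the [del, dup] band can only drop calls
  expect_lte(n_calls(karyo_params(dup_ratio = 2.0, del_ratio = 0.3)), base)

  # scale invariance: multiplying study depths by c > 0 leaves calls unchanged
  scaled <- tibble::as_tibble(sim$study)
  scaled$depth <- scaled$depth * 3L
  track_scaled <- depth_logratio(as_depth_table(scaled, model), sim$control,
                                 model)
  a <- call_gene_cnv(track, model)
  b <- call_gene_cnv(track_scaled, model)
  expect_equal(b[c("gene_id", "call")], a[c("gene_id", "call")],
               ignore_attr = TRUE)
})

test_that("seeded gene and chromosome spikes are recovered exactly", {
  model <- toy_gene_model(chromosomes = c("chr1", "chr2"),
                          genes_per_chrom = 100, exons_per_gene = 5)
  sim <- simulate_depth_pair(
    model, baseline_depth = 100, dispersion = 0.05, seed = 2024,
    spiked_events = data.frame(target = c("chr1_G01", "chr1_G02"),
                               multiplier = c(2.0, 0.0)))
  calls <- call_gene_cnv(depth_logratio(sim$study, sim$control, model), model)
  expect_setequal(paste(calls$gene_id, calls$call),
                  c("chr1_G01 gain", "chr1_G02 loss"))

  # whole-chromosome gain at multiplier 2: nearly all chr genes called
  model9 <- toy_gene_model()
  sim21 <- simulate_depth_pair(model9, seed = 31,
                               spiked_events = data.frame(target = "21",
                                                          multiplier = 2.0))
  rep <- summarize_aneuploidy(
    call_gene_cnv(depth_logratio(sim21$study, sim21$control, model9), model9),
    model9)
  per <- rep$per_chromosome
  expect_gte(per$aneuploidy_pct[per$chrom == "21"], 95)
  expect_true(all(per$aneuploidy_pct[per$chrom != "21"] <= 2))
})
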