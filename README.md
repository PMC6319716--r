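# spermkaryo

Quantifying chromosomal abnormalities in sperm specimens from two
complementary assays, for reproductive-genetics labs comparing ejaculated
with surgically retrieved (epididymal or testicular) spermatozoa:

* **FISH aneuploidy scoring** — per-cell fluorescent signal counts over a
  nine-probe panel (chromosomes X, Y, 13, 15, 16, 17, 18, 21, 22) are
  classified into disomy, nullisomy, diploidy and euploidy, and aggregated
  into specimen-level rates with replicate-slide reconciliation.
* **Molecular karyotype by exome read depth** — per-exon depths of a study
  specimen are normalized against a control, converted to log2 ratios, and
  genes are called duplicated or deleted by the depth-threshold rule, with
  ranking, polymorphic-region filtering, homozygosity assignment from the
  heterozygous SNP fraction, and a chromosome-level aneuploidy summary.

TUNEL chromatin-fragmentation scoring, ICSI outcome-rate tables, and the
group comparisons used alongside these assays (Welch *t*, Mann–Whitney *U*,
Friedman χ²) are included, together with seeded synthetic-data generators
so every stage is verifiable by parameter recovery without external data.

## The rules implemented

A cell is scored from its probe signals: 2 signals on an autosome probe is
a disomy, 0 a nullisomy, 1 normal; sex probes are read jointly (one X or
one Y is normal, two sex signals a gonosomal disomy, none a nullisomy); a
cell with 2 signals on every autosome and two sex signals is diploid; 3 or
more signals anywhere makes the cell unscorable. A specimen's total
aneuploidy is the percentage of scorable cells that are not euploid, read
against an abnormality threshold of >1.6% over at least 1000 cells, with
replicate slides pooled and flagged discordant beyond a 3-point error band.

For the molecular karyotype, each depth table is scaled to unit median
(with a 0.5-read pseudocount), and for gene *g* with per-gene control
reference *r<sub>g</sub>* (median normalized control depth over its exons),
an exon supports duplication when its normalized study depth exceeds
1.5 × *r<sub>g</sub>* and deletion when it falls below 0.5 × *r<sub>g</sub>*;
the gene is called when more than 70% of its exons agree. Calls are ranked
by |mean log2 ratio|, common variants are filtered at ≥50% exonic overlap
with polymorphic regions, and homozygosity is assigned when the
heterozygous SNP fraction is ≤5.0%. TUNEL chromatin is normal at ≤15%
fragmented cells of at least 500 scored.

## Worked example

```r
library(spermkaryo)

# a desk-scale genome: 9 chromosomes matching the probe panel,
# 20 genes each, 5 exons per gene
model <- toy_gene_model()

# chromosome 21 gained (multiplier 2), one gene on 17 deleted
sim <- simulate_depth_pair(
  model, baseline_depth = 100, dispersion = 0.05, seed = 7,
  spiked_events = data.frame(target = c("21", "17_G04"),
                             multiplier = c(2.0, 0.0)))
track <- depth_logratio(sim$study, sim$control, model)
calls <- call_gene_cnv(track, model)
summarize_aneuploidy(calls, model)
#> <aneuploidy_report> 21/180 genes called (11.67% total aneuploidy)
#> # A tibble: 9 x 5
#>   chrom genes_assessed genes_gained genes_lost aneuploidy_pct
#> ...
#> 6 17                20            0          1              5
#> 8 21                20           20          0            100
```

Every gene on the spiked chromosome is recovered as a gain (100% on
chromosome 21) and the deleted gene as a loss; no other gene is called.

```r
cells <- simulate_fish_cells(10000, disomy_rate = c("21" = 0.02),
                             diploidy_rate = 0.003, seed = 7)
glance(score_fish(cells))
#> # A tibble: 1 x 8
#>   n_cells n_scorable n_unscorable diploidy_pct total_aneuploidy_pct abnormal
#> 1   10000      10000            0         0.28                 2.27 TRUE
```

The scorer recovers the simulated 2% chromosome-21 disomy plus 0.3%
diploidy as a 2.27% total, above the 1.6% threshold, so the specimen is
flagged abnormal.

```r
outcomes <- read_outcome_table(system.file("extdata", "icsi_outcomes.tsv",
                                           package = "spermkaryo"))
outcome_rates(outcomes)[, c("group", "clinical_pregnancy_pct",
                            "pregnancy_loss_pct", "term_pct")]
#> # A tibble: 5 x 4
#>   group               clinical_pregnancy_pct pregnancy_loss_pct term_pct
#> 1 fish_ejaculated                       22.1               62.5     37.5
#> 2 fish_surgical                         50                  0      100
#> 3 ngs_ejaculated                        47.2               29.4     70.6
#> 4 combined_ejaculated                    0                 NA       NA
#> 5 combined_testicular                  100                  0      100
```

The shipped table holds published ICSI outcome counts per sperm source:
clinical pregnancy rates are per embryo transfer (49/222 = 22.1% for
ejaculated specimens in the FISH cohort), and loss/term rates are per
pregnancy with a known outcome (30/48 = 62.5%).

Each result type has `tidy()`/`glance()` methods and plots:
`autoplot(score_fish(cells))`, `autoplot(summarize_aneuploidy(calls, model))`,
`plot_logratio(track, calls)`, `plot_outcome_rates(outcome_rates(outcomes))`.

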