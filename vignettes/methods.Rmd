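---
title: "Methods: sperm aneuploidy scoring by FISH and read-depth karyotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sperm aneuploidy scoring by FISH and read-depth karyotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spermkaryo)
```

# Scope and model

Spermatozoa are haploid, so the expected FISH signal count is one per
autosome probe and one sex-chromosome signal per cell; aneuploidy shows up
as an extra signal (disomy), a missing one (nullisomy), or a fully doubled
complement (diploidy). The package scores both the cytological assay
(per-cell probe counts) and its sequencing counterpart: a molecular
karyotype in which a study specimen's per-exon read depths are compared
with a control specimen's and genes are called gained or lost from the
depth ratio. Both assays end in a specimen-level percentage read against a
clinical threshold, and both are wrapped by the outcome and group-comparison
statistics used when such specimens are taken into ICSI cycles.

Everything downstream of signal counting and depth extraction is in scope;
image analysis, alignment, and depth counting conventions are not — depth
tables are taken as given, validated exon-by-exon against the gene model.

# FISH scoring

`classify_fish_cells()` applies the scoring rules per cell; `score_fish()`
aggregates. Decisions taken where scoring practice leaves room:

* **Signal counts of 3 or more make a cell unscorable**, as does a total of
  three sex signals (e.g. X=2, Y=1): only disomy, nullisomy and diploidy
  are screened, so higher-order patterns are set aside rather than guessed
  at. Unscorable cells leave both numerator and denominator.
* **Diploidy preempts per-chromosome events**: a cell with two signals
  everywhere is one diploid cell, not nine disomies. This matches how
  cytogeneticists tally such cells and keeps the event classes disjoint.
* **Total aneuploidy is cell-based**: the percentage of scorable cells that
  are not euploid, with diploid cells counted as abnormal. Per-chromosome
  disomy/nullisomy rates stay marginal (a cell with two events counts once
  per chromosome there, once in the total). A sum of per-chromosome event
  rates would double-count multi-event cells and could exceed 100%; the
  cell fraction is the only definition that yields a single coherent
  specimen percentage.
* **Sex probes are read jointly** as one chromosomal unit ("XY"): (1,0) and
  (0,1) are normal, any two sex signals are a gonosomal disomy, none a
  nullisomy. Reports therefore carry one XY row rather than separate X and
  Y rows.
* The abnormality threshold is **strictly greater than 1.6%** — a specimen
  at exactly 1.6% is on the euploid side, which the boundary test pins.
* **Replicates are pooled by raw cell counts**, not by averaging
  percentages, so a 1500-cell slide outweighs a 600-cell one. Replicates
  whose totals differ by more than the upper bound of the 2–3 percentage
  point FISH error band are flagged discordant for manual review; the
  pooled report is still produced.

Thresholds (abnormal > 1.6% of ≥ 1000 scorable cells) and the probe panel
live in `karyo_params()` and are validated there.

# Molecular karyotype from read depth

`depth_logratio()` normalizes both depth tables to unit median exon depth.
Median rather than total-read scaling keeps the normalization robust to the
very copy-number events being sought: a gained chromosome inflates the
total but barely moves the median of a desk-scale exome. A pseudocount of
0.5 reads is added to every exon before scaling so log ratios stay finite
at zero depth; at depth 100 it biases a true doubling to
log2(200.5/100.5) = 0.996, well inside calling tolerance. Exons with zero
raw depth in both specimens carry no information and are masked from every
downstream fraction; a gene whose exons are all masked is reported
unassessed rather than uncalled.

`call_gene_cnv()` implements the threshold rule. The control-side
"median depth" is read **per gene** — the median normalized control depth
over the gene's unmasked exons — because a genome-wide median would
misjudge genes with atypical capture efficiency; the exon-level baseline
effect in the simulator exists precisely to exercise this. An exon supports
a gain above 1.5 × reference and a loss below 0.5 × reference, and a gene
is called when **more than** 70% of its unmasked exons agree; all three
comparisons are strict, pinned by boundary tests (an exon at exactly 1.5×,
or 7 of 10 exons supporting, does not call). Log ratios are computed per
exon, the finest unit the input carries. If both directions ever exceeded
the threshold (impossible for disjoint support at fractions above 0.5) the
larger fraction would win, a tie giving no call.

Ranking is by |mean log2 ratio| descending with lexicographic gene-id
tie-break, ranks 1..K without gaps. Polymorphic filtering marks a call when
at least 50% of the gene's exonic bases fall inside the supplied regions —
the conventional CNV overlap criterion, exposed as
`polymorphic_overlap` — keeps the call in the output with its reason, and
recomputes ranks over the survivors; the operation is a projection
(applying it twice changes nothing). Homozygosity is assigned at a
heterozygous SNP fraction ≤ 5.0% (inclusive), with missing genotypes
excluded from both numerator and denominator.

The chromosome-level summary reports, per chromosome, the percentage of
assessed genes called gained or lost. A specimen-level CNV "aneuploidy
percentage" has no unique definition from gene calls; the assessed-gene
fraction is the one computable from the quantities this pipeline produces,
and the whole-chromosome recovery test (a chromosome spiked at multiplier
2 yields ≥ 95% of its genes called, others ≤ 2%) shows it behaves as a
chromosome-level readout.

# Synthetic data: what it emulates and what it does not

`simulate_depth_pair()` draws one latent exon baseline
*b<sub>e</sub>* = depth × exp(N(0, σ)) shared by study and control —
emulating exon-specific capture efficiency, which cancels in per-exon
ratios but not in the per-gene reference — then samples counts around
*b<sub>e</sub>* (control) and *m<sub>g</sub>·b<sub>e</sub>* (study).
Count noise is negative binomial in the **linear parameterization**,
var = (1 + φ)·μ, with `dispersion` = φ; this keeps the noise scale
proportional to depth in the way shallow technical replicates of capture
data behave, and makes φ = 0 a clean noiseless limit in which depths are
exactly round(μ) — used by the identity and boundary tests. Defaults
(depth 100, exon effect SD 0.05, dispersion 0.05) are chosen for
testability of the threshold rule at desk scale, not as a calibrated model
of any sequencer. Whole-chromosome spikes multiply every gene on the
chromosome, modelling a cell-fraction aneuploidy in bulk sperm DNA
(multiplier 1 + f for a chromosome gained in a fraction f of cells) — note
that a 40%-cell-fraction gain (multiplier 1.4) sits below the 1.5×
duplication threshold and is correctly not called; the rule detects
(near-)clonal events.

The generator does not model GC bias, mappability, batch effects,
segmental duplications, or realistic human exon coordinates, so passing
recovery tests demonstrate correctness of the calling logic under the
stated noise model, not performance on real exomes.

`simulate_fish_cells()` draws diploidy first (a diploid cell is not
additionally disomic), then per-chromosome events independently, with sex
signals allocated X or Y per haploid draw. It does not model probe
hybridization failure or signal colocalization, which in real slides
motivate the replicate protocol. TUNEL labels and het/hom sites are plain
Bernoulli draws. All generators are bit-reproducible given `seed`.

# Statistics

The two-group comparison is Welch's unequal-variance *t* (group sizes and
variances differ throughout this application; the pooled variant is never
assumed) alongside the Mann–Whitney *U* with midrank ties — exact two-sided
p by enumeration when the combined n is at most 12 with no ties, otherwise
the tie- and continuity-corrected normal approximation; the exact path is
verified against full enumeration for all group sizes up to 6. Friedman's
χ² uses within-block midranks with the standard tie correction; a matrix
whose blocks are each fully tied has statistic 0 by continuity. All
p-values are two-sided and no multiple-testing correction is applied —
comparisons are reported individually with their group summaries.

Outcome rates: clinical pregnancy per embryo transfer; pregnancy-loss and
term rates per pregnancy **with a known outcome** (miscarriages + term).
The known-outcome denominator is what published count pairs such as 30/48
losses against 49 pregnancies imply — one pregnancy without a recorded
endpoint drops out — and it equals the pregnancy count whenever all
endpoints are known. Rates are reported to one decimal with an integer
display column; serialized reports round percentages to two decimals for
determinism.

# Problem sizes and numerical choices

The test suite runs the CNV recovery at 20 simulations of 200 five-exon
genes (multipliers 0, 0.3, 1.8, 2.5; sensitivity ≥ 0.95, false-call rate
≤ 0.01 against generator truth), FISH recovery at 10,000 cells, and
TUNEL/zygosity recovery at 10,000 cells / 20,000 sites, each within 3
binomial standard errors at fixed seeds — sizes chosen so the whole suite
completes on a laptop in well under a minute while leaving the binomial
tolerances meaningfully tight. Degenerate inputs are contracts, not
silent paths: empty cell sets, all-zero depth tables, zero called SNP
sites and incomplete block matrices raise errors; insufficient cell counts
(FISH < 1000, TUNEL < 500) produce reports flagged `sufficient_cells =
FALSE` with a warning.

# Known limitations

* Gene-level calling only: no segmentation, breakpoint estimation, or
  sub-gene events; a gene straddling a real CNV boundary dilutes its own
  supporting fraction.
* The per-gene control reference assumes several exons per gene;
  single-exon genes make the reference the exon itself, so only the
  normalization separates signal from noise there.
* The FISH scorer trusts the counted signals; hybridization artifacts
  appear as (un)scorable patterns rather than being corrected.
* Specimen-level percentages from patient cohorts are properties of the
  specimens; the package reproduces the *procedures* and validates them by
  parameter recovery on synthetic data, not by reproducing cohort values.
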