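---
title: "Selecting and validating qPCR reference genes with refstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and validating qPCR reference genes with refstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(refstab)
```

## The problem

Relative quantification by qPCR expresses a target gene's abundance in
each sample as a ratio to one or more reference (housekeeping) genes.
The whole construction stands or falls with the references: a "reference"
whose expression responds to the experimental condition biases every
downstream fold change. Because no gene is stably expressed in every
tissue and condition, candidate references must be re-validated for each
new experimental design. `refstab` implements the complete validation
workflow for that task — technical QC of raw cycle-threshold (Ct) values,
amplification-efficiency screening, three complementary gene-stability
algorithms with a consensus report, and efficiency-corrected
normalization with nonparametric group testing — with a synthetic data
generator that emulates a songbird singing experiment so that every stage
can be exercised and tested end to end.

The package ships a pan-avian candidate panel as a fixture: 14 classical
housekeeping genes (18S, ABL, GAPDH, GUSB, HMBS, HPRT, PGK1, RPL13,
RPL19, RPS7, SDHA, TFRC, VIM, YWHAZ) with primer sequences and amplicon
sizes, and the per-species assay screen across nine bird species from
ostrich to zebra finch.

## Ct data model and triplicate QC

Reactions are run in technical triplicate and collapsed to a mean Ct per
sample and gene. The QC rule (`collapse_triplicate()`): if one of the
three Ct values deviates from each of the other two by more than 0.5
cycles while those two agree within 0.5, the outlier is excluded and the
concordant pair averaged; if no two values agree within the tolerance the
well set fails and must be repeated. The tolerance (0.5 cycles) and the
cycle ceiling (40) live in `qc_policy()`.

Missingness is two-valued. An entry can be *undetected* — the reaction
never crossed the threshold within 40 cycles ("ND") — or merely *failed
QC*. The distinction matters for gene exclusion:
`exclude_undetected_genes()` removes a gene when the fraction of
undetected samples exceeds `detection_exclusion_fraction` (default 0, so
one truly undetected sample excludes the gene, the behaviour appropriate
for an assay at its detection limit), while QC failures only drop that
sample from analyses that need it. Conflating the two would let a single
discordant triplicate delete an otherwise healthy gene.

## Amplification efficiency

Each assay's efficiency is fitted from a ten-fold dilution series over
five orders of magnitude: ordinary least squares of Ct on log10
concentration gives the slope, the per-cycle amplification factor is
E = 10^(-1/slope), and percent efficiency is 100(E - 1), so perfect
doubling is a slope of -3.32 and 100%. Assays are accepted when the
efficiency lies inside [90, 110]% — inclusive at both ends, which is how
the packaged nine-species screen reproduces its published per-species
established-assay counts (from six to 11). The fit is invariant to
rescaling all concentrations, and on noiseless series the round-trip
recovers the generating factor to well below 0.01%.

## Relative quantities

All stability and normalization computations work on efficiency-corrected
relative quantities, Q = E^(Ct_min − Ct), with each gene's lowest Ct (its
most concentrated sample) as calibrator. The calibrator choice only
rescales a gene's column; every statistic downstream is built from
ratios, so it cannot affect M values, V values, model-based stabilities
or fold changes. This is asserted by tests rather than assumed.

## The three stability algorithms

**geNorm** (`genorm()`). For genes j and k, the pairwise variation is the
standard deviation (n−1 denominator) over samples of log2(Q_j/Q_k); gene
j's stability M_j is the mean of its pairwise variations with all other
candidates. The gene with the highest M is removed and M recomputed until
two genes — the recommended pair, inseparable by construction — remain.
Normalization factors NF_n (per-sample geometric means over the n most
stable genes) give the pairwise variation V(n/n+1) = SD over samples of
log2(NF_n/NF_{n+1}); the recommended gene count is the smallest n with
V(n/n+1) < 0.15. Ties at the maximum M are broken by excluding the gene
later in input order; the final pair is ordered by M in the last
three-gene round. geNorm assumes the candidates are not co-regulated —
co-regulated genes hide behind their low mutual variation.

**Model-based inter/intra-group analysis** (`normfinder()`). Each
sample's log2 quantity vector is centred by its across-gene mean,
removing sample loading. Per gene and experimental group we estimate the
group mean deviation and residual variance of the centred values. The
inter-group component (the gene's group mean minus its across-group
average) is shrunk toward zero by τ²/(τ² + s²/n_g), with τ² the
across-gene variance of those deviations — genes only get charged for
group shifts that stand out from the panel-wide spread. The intra-group
variance is corrected for the shared centring term (the across-gene mean
variance divided by the gene count), clamping negative estimates at
zero. The stability value is the mean over groups of |shrunk shift| +
sqrt(corrected variance / n_g); lower is better. `normfinder_best_pair()`
scores every pair by the same formula applied to the pair average
(shifts averaged, variances averaged and quartered), so two genes with
opposite-sign group shifts can jointly beat any single gene — the
behaviour that makes group-aware pair selection genuinely different from
taking the two best singles. The algorithm is named after, and follows
the published variance-decomposition model of, the NormFinder tool;
published reimplementations differ in constants, so this package's
guarantees are the recovery properties its tests assert, not decimal
agreement with the original VBA add-in.

**BestKeeper** (`bestkeeper()`). Descriptive and deliberately simple: per
gene, the sample SD of raw Cts, the coefficient of variation (SD as a
percent of mean Ct), and the Pearson correlation with the BestKeeper
index (the per-sample geometric mean Ct over all candidates). Genes with
SD > 1.5 cycles are flagged but never removed — in input-limited material
such as microbiopsies, every gene can exceed the guideline and the flag
is information, not a filter. The original tool leaves weighing the three
measures to the user; `consensus_rank()` ranks genes on each measure
separately (SD and CV ascending, correlation descending, mid-ranks on
ties) and averages the three ranks. A tie in mean rank is broken in
favour of the gene whose three per-measure ranks have the smallest
spread — the gene "equally stable in all three values" — then by input
order. The correlation is ranked by signed value, not magnitude: a
reference should co-vary positively with the index, and a strongly
negative correlate is the worst possible reference. This choice is
configurable in spirit (the per-measure ranks are returned, so any other
weighting can be applied) and is stated here because the descriptive
literature is silent on it.

The three algorithms answer different questions (ratio stability, group
separation, raw-Ct dispersion) and genuinely disagree on real data; the
pipeline therefore reports them side by side and recommends one pair per
algorithm rather than forcing a global winner.

## Normalization and group testing

`normalize_expression()` divides the target's Q by the per-sample
geometric mean of the reference genes' Q. `compare_groups()` reports the
treatment/control fold change and a two-sided Mann-Whitney test. The
group summary for the fold change is the median by default — consistent
with the rank-based test — with the mean-based fold reported alongside;
which of the two a published figure used is often unstated, so both are
emitted. The U statistic's p-value is exact (full enumeration of
assignments of the pooled ranks, two-sided by distance of U from its null
mean) whenever both groups have at most 10 observations and the pooled
values are tie-free; otherwise a mid-rank normal approximation with tie
and continuity correction is used. With five versus seven samples,
complete separation gives the attainable minimum p = 2/792 ≈ 0.0025.
Significance labels follow the conventional thresholds (* p < 0.05,
** p < 0.01). No multiple-testing correction is applied across targets;
with three genes of interest examined against a directional prior
hypothesis this matches field practice, and a user needing familywise
control can apply `p.adjust` to the reported p-values.

## The synthetic generator and what it does (not) show

`simulate_ct_table()` draws Ct = baseline − effect/log2(E) + sample shift
+ per-sample gene noise + replicate noise. Group effects are specified in
log2 expression units and converted to cycles through each gene's own
amplification factor, so efficiency correction is genuinely exercised:
a +1 log2 effect moves a 95%-efficiency assay by more cycles than a
103% one. Replicate outliers (displaced by 0.6–3.0 cycles, guaranteed to
trip the 0.5-cycle rule) occur with configurable probability. Cts at or
beyond the cycle ceiling are reported as not detected, as an instrument
would.

`preset_song_dataset()` fixes the study conditions emulated throughout
the tests: 5 singing vs 7 silent birds; nine stable reference candidates
with the zebra-finch assay efficiencies from the packaged screen;
EGR1 and CFOS with a true +3 log2 (8-fold) singing effect; FOXP2 with
none. Noise is decomposed as the data of such experiments suggest:
per-sample RNA-input scaling of SD 1.6 cycles dominating (so every
gene's raw Ct SD exceeds the 1.5-cycle BestKeeper guideline, as observed
in microbiopsy material), residual per-gene biological/technical noise
of 0.15 cycles, triplicate repeatability of 0.08 cycles (typical
instrument-level well-to-well scatter; larger values would make the
0.5-cycle QC rule fire routinely on ordinary wells, which real protocols
do not show), and a 2% displaced-replicate rate. 18S is simulated at
baseline Ct 8, far more abundant than the mRNA candidates — which is why
its CV (computed on raw Cts) ranks poorly in BestKeeper even though it is
perfectly stable, a known artifact of CV on abundant transcripts.

What the generator does *not* emulate: co-regulation among candidates
(geNorm's known blind spot), inter-plate batch effects and calibrators,
RNA-quality covariates, or amplification-curve-level artifacts. Passing
tests on this preset therefore show that the algorithms recover the
structure they model — they do not certify behaviour on data violating
those assumptions.

## Numerical and design choices

* Sample SDs everywhere use the n−1 denominator.
* Log base 2 throughout; group sizes may be unequal.
* geNorm tie at maximum M: exclude the later gene in input order
  (deterministic, logged in the exclusion order).
* Model-based estimator: negative corrected variances clamp to zero
  (messaged); τ² = 0 shrinks inter-group components to exactly zero.
* BestKeeper: a zero-variance gene has an undefined index correlation and
  is reported as missing, never as 0, and is excluded from the consensus
  ranking with a message.
* Degenerate inputs error early with named conditions: non-negative
  dilution slopes, fewer than three distinct concentrations, fewer than
  three genes, groups below two samples, all genes undetected.
* The melting-temperature criterion (58 °C) of the primer panel is
  carried as metadata only; no Tm model is applied, and the panel
  validator checks only the computable rules (length, GC, amplicon
  size). The shipped panel itself contains honest rule violations
  (GAPDH's 269–270 bp amplicon; RPL19/SDHA GC content just outside
  40–70%) which the validator reports rather than resolves.
* Analysis drivers under `analysis/` use seed 1 and the preset's
  12 × 12 design; the test suite's stochastic properties run 100 seeded
  replicates of the same preset, sized so the whole suite stays fast.

## Limitations

The model-based estimator shares NormFinder's assumptions (additive
log-scale model, roughly symmetric noise) and its pair formula is one of
several in circulation; with a single group it degrades to ranking by
corrected variance. BestKeeper's descriptors are group-blind: a
condition-responsive gene can, by chance, show the lowest raw-Ct
dispersion in a small sample and rank well — one more reason the
pipeline keeps condition-responsive genes of interest out of the
candidate pool by design. The exact rank-sum enumeration is limited to
groups of ten (beyond that the corrected normal approximation is
excellent), and fold changes from five versus seven samples carry wide
sampling error even under a true 8-fold effect.
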