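---
title: "Methods: cistrome co-occupancy and cofactor-balance subgroups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cistrome co-occupancy and cofactor-balance subgroups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofbal)
```

`cofbal` analyses how a transcription factor's genome occupancy is shaped by
the balance of its cofactors, and how that balance stratifies tumours. The
motivating system is IRF4 in activated-B-cell-like diffuse large B-cell
lymphoma (ABC-DLBCL): IRF4's DNA binding is released by partner factors —
the ETS proteins SPIB and PU.1 at ETS/IRF composite elements (EICE), and
BATF at AP1/IRF composite elements (AICE) — so the relative abundance of
SPIB and BATF decides which regulatory elements IRF4 occupies, and tumours
with reciprocal SPIB/BATF expression behave differently. Every statistical
step of that argument is implemented here as a reusable, tested function;
a synthetic-data module generates all inputs with known planted structure
so the whole chain is verifiable without external data.

## Peak-centre overlap clustering

Peaks from any number of cistromes are pooled and merged into regulatory
elements by a greedy scan: in (chrom, centre, −score, label) order, a peak
whose centre lies strictly less than `radius` (default 250 bp) from the open
cluster's *index peak* centre joins that cluster; otherwise it founds a new
cluster and becomes its index. Two conventions deserve emphasis:

* **Strict inequality.** A centre exactly `radius` away starts a new
  cluster. The boundary is tested explicitly.
* **Index-peak definition.** Membership is measured from the founding
  peak's centre, not from the nearest member: centres 100, 300, 500 with a
  250 bp radius give clusters {100, 300} and {500}, because 500 is 400 bp
  from the index at 100. Processing order makes the result deterministic
  and independent of how the input cistromes are split across files; ties
  at identical centres are broken by higher score, then label. A
  brute-force reimplementation of the written rule is kept in the test
  suite and compared across hundreds of random instances with adversarial
  spacings (0, 249, 250, 251 bp gaps).

Each cluster's *occupancy signature* is the set of cistrome labels
contributing a member (e.g. `IRF4_SPIB_PU1`), the unit of every downstream
class comparison.

## Coordinates and peak centres

All intervals are BED-convention 0-based half-open. narrowPeak summit
offsets give absolute centres (`start + offset`); an offset of −1 falls back
to the interval midpoint, as does BED6 input (floored midpoint). Centres
must lie inside their intervals; violations are rejected at parse time with
the offending line number.

## Gene assignment and promoter fractions

Two geometries are used by the workflows and both are explicit modes:

* `upstream5kb_intragenic` — centre within 5 kb upstream of the TSS
  (strand-aware: upstream means lower coordinates for "+" genes, higher for
  "−" genes) or anywhere in the gene body. Used to call a gene
  "occupancy-associated" for enrichment tests.
* `tss_flank` — centre within TSS ± 2 kb, strand-ignorant. Used for
  promoter fractions and expression-by-occupancy summaries.

The promoter definition behind the reported promoter-bias fractions is not
uniquely fixed by convention; TSS ± 2 kb is the default and a parameter.
Assignments are validated against an exhaustive interval-membership scan.

## Consensus motif counting

Composite-element consensi are scanned as exact IUPAC matches within
`centre ± 100 bp` of each element, on both strands unless a pattern says
otherwise. Defaults: EICE `GGAARTGAAAC`, AICE-1 `TTTCNNNNTGASTCA`, AICE-2
`GAAATGASTCA`, AP1 `TGASTCA`, ETS `RGGAAR`; all editable. Position-weight
scoring is deliberately out of scope — the questions asked here ("is an
EICE present near the centre?") are consensus questions. Three numerical
choices: ambiguous bases in the scanned sequence never match; a consensus
that equals its own reverse complement (AP1) is counted once per interval,
not once per strand; and hits of a short pattern lying inside a hit of a
composite pattern (an ETS core inside an EICE) can be suppressed with
`suppress_within`, mirroring the practice of counting "ETS not overlapping
an adjacent EICE". The scanner is tested against a regex-expansion oracle
on random sequence.

## Binned occupancy correlation

Genome-wide similarity of cistromes is summarised by Pearson correlation of
100 bp-binned occupancy (binary peak presence by default; a signal mode sums
scores). The correlation domain is the union of bins occupied by at least
one track. Correlating over *all* genomic bins would inflate r through the
shared empty genome — with mostly-empty binary tracks the all-bins r
approaches the fraction-independent limit driven by the zeros — so the
union domain is the default and `all_bins` is provided for sensitivity
analysis. Zero-variance tracks produce `NA` with a warning, never a silent
zero. Tracks are ordered by average-linkage hierarchical clustering on
`1 − r`.

## Knockdown differential occupancy

Per-element log2 fold changes between knockdown and control are computed
from depth-normalised, pseudocounted counts:
`log2(((kd + 1) / N_kd) / ((ctl + 1) / N_ctl))`. Classes (occupancy
signatures) are summarised by median and IQR and contrasted pairwise with a
two-sided Mann–Whitney test — distribution-free, matching the box-plot
style presentation such data receive. The *stable subset* holds elements
with linear fold change below 1.4 in either direction
(`max(FC, 1/FC) < 1.4`); its enrichment for a focal signature (elements
bound by the factor without the depleted partner) is an exact
hypergeometric over-tail. When counts arrive through the TSV interface
without library sizes, column totals are used; note this absorbs part of a
genuinely global depletion into the normaliser, which is the standard
reads-per-million trade-off.

## Quadrant split and consensus meta-profiles

Within the selected cell-of-origin class (default ABC), samples are split
at the median of each marker gene (defaults SPIB and BATF): ranks above
`ceiling(n/2)` are "high", so with odd *n* the middle sample goes to "low"
and "high" is strictly the top half; ties are broken by stable sample
order. This makes the quadrant partition exhaustive, exclusive, and
deterministic — the original description ("top and bottom 50%") leaves the
tie policy open, so it is documented here and enforced by enumeration
tests.

Per cohort, differential expression between the two extreme quadrants
(SPIB^high/BATF^low vs SPIB^low/BATF^high) uses Welch's t-test on log2
values at unadjusted p < 0.05 (a rank-sum alternative is available). The
test is not named in the motivating analysis; Welch is the standard choice
for normalised array data and the cross-cohort consensus is the real
multiplicity control: a gene enters a *meta-profile* only when significant
with the same sign in ≥ 4 cohorts. No additional FDR layer is added at the
per-cohort step, matching that design. Genes qualifying in both directions
are excluded and reported as conflicts. Support is counted over the
intersection of the cohorts' gene universes so all genes share a
denominator; meta-profiles are monotone in the support threshold (tested).

Knockdown expression lists use Welch + Benjamini–Hochberg at two
stringencies: adjusted p < 0.05, and additionally linear fold change
≥ 1.5.

## Enrichment statistics

* **Hypergeometric tests** are exact (`phyper`, log-space internally) and
  verified against rational enumeration for every configuration with
  N ≤ 25.
* **BH FDR** is the unnamed "correction for false discovery" standard;
  the method is pluggable.
* **Bootstrap stage z-scores**: the null draws query-sized gene sets
  without replacement from the universe (default 1e7 draws, configurable —
  the bundled analyses use 1e5–1e6), giving `z = (obs − mean_null)/sd_null`
  per differentiation-stage category (B cell, activated B cell,
  plasmablast, plasma cell) and an empirical two-sided p with the
  `(r+1)/(n_iter+1)` correction so p is never 0. Sampling without
  replacement makes the null exactly hypergeometric, so the bootstrap
  moments are audited against `nK/N` and the hypergeometric variance in
  closed form; the z-score and the empirical p are reported side by side
  rather than choosing one derivation.
* **Signature collections** (GMT) are filtered to sets of fewer than 1000
  genes *before* testing (strict inequality: a 1000-gene set is excluded),
  then tested hypergeometrically with batch-wise BH.
* **Proportion comparisons** use Pearson's 2×2 chi-squared without
  continuity correction (df = 1), with a warning suggesting an exact test
  when an expected cell falls below 1.

## Survival and mutation association

Kaplan–Meier curves come from the product-limit estimator
(`survival::survfit`); groups are compared with the log-rank test — the
standard KM companion, as the comparison test is otherwise unspecified.
Ties between events and censorings at the same time are resolved events
first. Mutation enrichment per quadrant uses a one-sided Fisher's exact
test on the (in-quadrant vs rest) × (mutated vs not) table; mutations other
than the targeted lesion (MYD88-L265P) are collapsed into "wild type" by
default, reflecting a clinical scenario of targeted mutation detection, and
the collapse rule is a parameter.

## What the synthetic data does and does not emulate

The generators produce every input with the statistical structure the
analysis assumes, under the simplest distributional families that admit
closed-form checks:

* **Cistromes**: latent elements placed uniformly with a minimum spacing of
  4× the clustering radius (1 kb), so truth clusters are unambiguous;
  spacing is configurable to stress-test the clustering. Each factor joins
  another factor's elements with the pairwise design probability; centres
  jitter with Gaussian sd 20 bp (peak-summit uncertainty); scores are
  log-normal.
* **Element counts**: Poisson with log-normal element strengths; knockdown
  multiplies the mean by a per-signature retained fraction.
* **Expression cohorts**: nine cohorts of 50 all-ABC samples × 10 000 genes
  by default; Gaussian log2 noise (sd 0.7), planted quadrant effects of
  1.5 log2 units for 50 genes per direction — a moderate array-scale effect
  that per-cohort tests detect often but not always, which is what makes
  the ≥ 4-cohort consensus informative; exponential survival (baseline
  median 40 months, typical of an aggressive lymphoma cohort, administrative
  censoring at 120 months) with a hazard multiplier in the focal quadrant;
  Bernoulli mutation status with an odds multiplier there.
* **Sequences**: i.i.d. background at a set GC with literal IUPAC
  instantiations embedded at known positions and strands.

Not emulated: raw reads and alignment artefacts, platform/batch effects
across cohorts, probe-level structure (inputs are gene-level; a max-mean
probe collapse utility is provided), mixed cell-of-origin composition
within a sample, and correlated co-binding beyond pairwise sharing. Passing
tests therefore demonstrate that the statistical machinery recovers planted
structure of the assumed form — not that any particular biological dataset
satisfies those assumptions.

All generators take explicit seeds and restore the caller's RNG state;
identical spec + seed is byte-identical output, which the orchestration
layer extends to whole report bundles: `manifest.json` lists every stage's
files with md5 hashes and a parameter hash, and reruns reproduce it
byte-for-byte.

## Problem sizes in the bundled checks

The test suite and the acceptance script run entirely on synthetic data at
sizes chosen to make the planted effects statistically unambiguous while
keeping a full run inside a few minutes on one core: 100 clustering
instances of 200 peaks; exhaustive hypergeometric/Fisher enumeration to
N = 25 and margins 15; bootstrap moment checks at 1e6 draws (the 1e7
default remains available as a parameter); nine cohorts × 50 samples ×
10 000 genes for meta-profile recovery; 1000 elements per factor for
knockdown recovery; 100 survival simulations at 100 patients per arm.

## Known limitations

* Clustering is greedy and scan-ordered; a centre can be within the radius
  of two cluster indices and joins the earlier one. This matches the
  stated rule but is not a globally optimal partition.
* Consensus matching cannot rank degenerate motif quality; PWM scoring is
  out of scope by design.
* The per-cohort DE step assumes roughly Gaussian log2 values; heavy-tailed
  cohorts should use the rank-sum option.
* Fisher-based mutation association is conservative at small counts, as
  usual for discrete one-sided tests.
* No automated cohort-outlier rule is provided: cohort inclusion is an
  explicit user decision in the configuration.
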