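# cofbal — cistrome co-occupancy and cofactor-balance subgroups

`cofbal` is an R package for a recurring question in regulatory genomics:
a transcription factor whose DNA binding depends on partner factors will
occupy different regulatory elements — and drive different programmes — as
the balance of its cofactors shifts. The motivating system is IRF4 in
activated-B-cell-like diffuse large B-cell lymphoma (ABC-DLBCL). IRF4 binds
EICE elements with the ETS factors SPIB/PU.1 and AICE elements with BATF,
so tumours with reciprocal *SPIB*/*BATF* expression
(SPIB^high/BATF^low vs SPIB^low/BATF^high) form molecularly and clinically
distinct subgroups.

The package implements both halves of that analysis as tested, reusable
functions:

**Co-occupancy workflow** — peak I/O (BED6/narrowPeak); greedy peak-centre
overlap clustering (centres strictly < 250 bp from the cluster's index-peak
centre merge); occupancy signatures per merged regulatory element;
centre-distance profiles; promoter fractions; IUPAC consensus-motif
counting (EICE/AICE/AP1/ETS) around element centres; 100 bp binned
genome-wide occupancy correlation with hierarchical ordering; knockdown
differential occupancy per signature class, including the stable
(fold change < 1.4) subset and its hypergeometric enrichment.

**Subgroup workflow** — median-split quadrant assignment on two marker
genes within a cell-of-origin class; per-cohort differential expression
between the extreme quadrants (Welch, p < 0.05); consensus *meta-profiles*
(same-sign significance in ≥ 4 cohorts); hypergeometric and bootstrap
(sampling without replacement, z-scores) gene-set enrichment; GMT signature
collections filtered to < 1000 genes with BH FDR; Kaplan–Meier survival
with log-rank comparison; one-sided Fisher mutation association per
quadrant (e.g. MYD88-L265P).

A first-class synthetic-data module generates every input the pipeline
consumes — multi-factor cistromes with planted co-occupancy and summit
jitter, element counts with planted knockdown depletion, multi-cohort
expression with planted quadrant effects, survival hazards and mutation
odds, and sequence with embedded motifs — so the full chain is verifiable
offline against known truth.

## Worked example

Simulate three cistromes with a planted sharing design, cluster them, and
quantify co-occupancy:

```r
library(cofbal)

spec <- cistrome_sim_spec(factors = c("IRF4", "SPIB", "PU1"),
                          n_elements_per_factor = 1000,
                          shared_fraction = matrix(c(1.0, 0.8, 0.4,
                                                     0.8, 1.0, 0.5,
                                                     0.4, 0.5, 1.0), 3, 3),
                          seed = 42)
sim <- gen_cistromes(spec)
clusters <- cluster_peaks(sim$cistromes, radius = 250)
occupancy_signature_counts(clusters)
#>          IRF4      IRF4_PU1     IRF4_SPIB IRF4_SPIB_PU1           PU1
#>           120           268           868           950           303
#>          SPIB      SPIB_PU1
#>            93           398
```

Most IRF4 elements carry SPIB (sharing was planted at 0.8), and peak
centres co-localise tightly:

```r
prof <- centre_distance_profile(sim$cistromes$IRF4, sim$cistromes$SPIB)
prof$fraction_within
#> [1] 0.765    # IRF4 peaks with a SPIB centre within 50 bp
```

Knock down SPIB in silico (SPIB-bound classes retain 40% of signal) and
measure differential occupancy per signature class:

```r
counts <- gen_element_counts(sim$truth,
                             c(IRF4_SPIB = 0.4, IRF4_SPIB_PU1 = 0.4,
                               SPIB = 0.4, SPIB_PU1 = 0.4), seed = 43)
differential_occupancy(counts)$class_summary
#>       signature   n  median    q25    q75
#> 1          IRF4 120  0.0111 -0.051  0.067
#> 3     IRF4_SPIB 868 -1.3219 -1.397 -1.246
#> 4 IRF4_SPIB_PU1 950 -1.3159 -1.390 -1.245
#> ...
```

SPIB-dependent classes drop by log2(0.4) ≈ −1.32 while IRF4-only elements
are untouched, and the knockdown-stable subset is strongly enriched for
them:

```r
stable_subset_enrichment(counts, fc_threshold = 1.4, focus_signature = "IRF4")
#>     k   n   K    N  p_value direction stable_fraction focus_fraction_stable
#> 1 120 691 120 3000 5.74e-81  enriched            0.23                 0.174
```

Nine synthetic expression cohorts with planted quadrant structure feed the
subgroup workflow:

```r
co <- gen_expression_cohorts(cohort_sim_spec(seed = 7, hazard_ratio = 0.3,
                                             mutation_enrichment_odds = 6))
quads <- lapply(co$datasets, assign_quadrants)
ext <- attr(quads[[1]], "extremes")
de <- lapply(seq_along(co$datasets), function(i) {
  q <- quads[[i]]
  differential_expression(co$datasets[[i]],
                          group_x = q$sample[q$quadrant == ext[1]],
                          group_y = q$sample[q$quadrant == ext[2]])
})
meta <- consensus_meta_profile(de, min_support = 4)
nrow(meta$up_in_x); nrow(meta$up_in_y)
#> [1] 51
#> [1] 51    # all 50 planted genes per direction recovered
```

The planted clinical structure is detected in each cohort:

```r
d1 <- co$datasets[[1]]; q1 <- quads[[1]]
ann <- d1$annotations[match(q1$sample, d1$annotations$sample), ]
sel <- q1$quadrant %in% ext
logrank_test(ann$os_time[sel], ann$os_event[sel], q1$quadrant[sel])$p_value
#> [1] 0.0003217  # hazard ratio 0.3 planted in SPIBhigh_BATFlow

mutation_association(q1, setNames(ann$myd88, ann$sample))
#>            quadrant mutated_in n_in mutated_out n_out p_value odds_ratio
#> 2  SPIBhigh_BATFlow          7   13           5    37 0.00691      7.078
#> ...
```

## Configuration-driven runs

Both workflows run from a YAML config (inputs, parameter block, output
directory) and write TSV/GMT tables plus a `manifest.json` with md5 hashes
of every emitted file — reruns with the same config and seed are
byte-identical. A thin CLI wraps the same functions:

```sh
exec/cofbal simulate cistromes --config sim.yaml --out simdir/
exec/cofbal cooccupancy --config cooccupancy.yaml
exec/cofbal subgroups --config subgroups.yaml
```

## Further documentation

`vignettes/cofactor-balance-methods.Rmd` describes the statistical model of
every stage, the tie-break and boundary conventions, what the synthetic
generators do and do not emulate, and known limitations.
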