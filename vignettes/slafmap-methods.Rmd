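---
title: "Models and methods behind slafmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slafmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

slafmap reconstructs, as tested reusable code, the genetic analysis of a
biparental onion F2 population derived from two doubled-haploid (DH)
parents and genotyped by SLAF sequencing: marker quality control,
high-resolution linkage-map construction, QTL scanning for flower stalk
height (FSH) and male fertility, and a favorable-allelic-variant (FAV)
heterosis-scoring procedure.  This vignette explains the underlying
models, the parameters that matter, the numerical choices, and what the
synthetic-data validation does and does not demonstrate.

## The cross and the genotype model

Both parents are fully homozygous DH lines, so every informative marker
segregates as `aa × bb`: the F2 genotypes aa, ab, bb occur in the
Mendelian 1:2:1 ratio, and all marker pairs are in coupling phase by
construction.  Genotypes are stored as integers (0, 1, 2, `NA`) in a
markers × individuals matrix with per-marker metadata (parental alleles,
SNPs per SLAF tag, parental sequencing depths).

## Synthetic data: what it emulates

`simulate_f2_genotypes()` draws, per individual and linkage group, two
independent gametes under a **no-interference (Poisson) crossover
process**: between adjacent markers separated by *d* cM the
parental-origin allele flips with the Haldane probability
$r = \tfrac12(1 - e^{-2d/100})$.  Defaults are the study conditions:
321 individuals, 8 linkage groups with the published group lengths
(115.29–140.43 cM), and — as the one deliberately scaled-down choice —
100 markers per group rather than the study's ~1,300, which preserves
sub-2-cM marker spacing while keeping the all-pairs linkage computation
(O(m²) EM problems) tractable on one CPU.  Test and acceptance runs use
50–60 markers per group for the same reason; the problem sizes used are
stated with each run.

`apply_observation_model()` overlays missingness (default 4%, matching
the study's ~96% marker integrity), uniform genotype-call errors
(default 0.5%, a typical residual error for depth-filtered
reduced-representation calls; the study does not state its rate),
Poisson per-marker depths with means 319.07 (parents) and 29.12
(progeny), and SNP-per-tag counts on 1..8 with mean ≈ 2 (matching the
study's 21,250 SNPs over 10,584 tags).

`simulate_phenotype()` assigns each QTL the genetic values −a / +d / +a
for aa / ab / bb plus a Gaussian residual.  Under 1:2:1 frequencies a
locus contributes variance $a^2/2 + d^2/4$.  The study reports per-QTL
effects and PVE but no residual variance, so the generator solves the
residual SD from the target PVEs:
$V_P = \sum_q V_{g,q} / \sum_q (\mathrm{PVE}_q/100)$, residual variance
$V_P - \sum_q V_{g,q}$.  With the default four QTLs (ADD 2.80–3.00 cm,
DOM 0.83–2.98 cm, PVE 6.28–7.19%) this gives a residual SD of ≈ 7.7 cm
around a 117.4 cm mean (the bin-weighted mean of the published FSH
distribution), which reproduces the published 90–140 cm range.  QTLs are
anchored at the nearest simulated marker so the truth bookkeeping is
exact; two default QTLs sit 4.4 cM apart on one group and can share an
anchor at coarse marker spacing, in which case their effects add — scans
then legitimately find one merged locus.

`simulate_fertility()` makes the parent-2 allele dominant at the
restorer locus (aa sterile; ab, bb fertile), the classic 3:1 F2 ratio.

One global seed expands into per-stage child seeds through the affine
rule in `split_seed()` (modulus 2³¹−1), so stages are independently
reproducible and every output is bit-identical given seed and
configuration.

**What passing on synthetic data does not show:** the generator has no
crossover interference, no locus-specific error structure, no
segregation-distortion loading, and marker positions independent of any
physical genome, so recovery rates here bound idealized performance, not
performance on real SLAF data.

## Marker QC

Four rules run in a fixed order (SNP count, completeness, distortion,
depth) so failure attribution is reproducible; the thresholds are the
study's (more than 5 SNPs; non-missing fraction below 0.70; 1:2:1
Pearson χ², df 2, p < 0.05, per-marker with no multiplicity correction;
either parent below 10×).  The study's wording of the completeness and
distortion criteria is internally contradictory ("more than 70% missing"
versus "complete degree below 70%"; "significant separation distortion
(p > 0.05)"); we adopt the standard readings — require ≥ 70% non-missing
and discard p < 0.05.  Completeness is computed over all progeny.
Markers whose parental calls are not `aa × bb` are set aside first with
reason `pattern`; `classify_segregation_pattern()` implements the full
eight-pattern two-parent taxonomy, flagging loci with more than four
alleles as repetitive.  On clean simulated data the filter loses ≈ 5% of
markers — the distortion test's false positives at α = 0.05 — which is
inherent to the study's per-marker threshold.

## Linkage map

**Pairwise linkage.** For codominant F2 pairs the nine genotype classes
have probabilities determined by r; the double heterozygote mixes the
parental and double-recombinant configurations with conditional
recombinant expectation $2r^2/((1-r)^2 + r^2)$.  The EM iteration counts
expected recombinant gametes; it is vectorized over all pairs at once
(nine indicator cross-products, element-wise updates), so an 800-marker
map costs a few dense matrix products.  MLOD is the maximized log₁₀
likelihood ratio against r = 0.5.  Pairs with fewer than 20 jointly
genotyped individuals are forced unlinked (MLOD 0) to guard against
spurious linkage from sparse overlap.  Tests require the EM to match a
10⁻⁴-step grid search of the same likelihood written out independently.

**Grouping.** Single-linkage connected components of the MLOD > 5 graph,
reported largest first with deterministic tie-breaking.  The threshold,
not a requested count, defines the partition: if it does not yield the
expected 8 groups the map is returned as found with a warning.  At
~115,000 candidate pairs the expected number of chance MLOD > 5 edges is
below one but not zero, so an occasional run merges two chromosomes —
reported honestly rather than forced apart.

**Ordering.** A minimum spanning tree on the r̂-weighted complete graph
(a 10⁻⁹ offset keeps r = 0 edges present) is linearized by a depth-first
traversal from one endpoint of the weighted diameter, then refined by
2-opt segment reversals interleaved with single-marker reinsertion
sweeps, both accepting only moves that lower the sum of adjacent
recombination fractions (SARF).  The reversal window defaults to the
whole group: windowed reversals alone cannot unfold large blocks the
DFS seed occasionally folds, and at ≤ a few hundred markers per group
the full pass is cheap.  The orientation is canonicalized by marker id.
On error-free data with ~2 cM spacing the true order (or its exact
reversal) is recovered in ≥ 95% of runs; with markers closer than about
0.5 cM at n = 321 adjacent orders are statistically unidentifiable —
the optimizer then returns an order whose SARF is at least as good as
the truth's, which is the property the tests assert.

**Error correction and imputation.** A non-missing call whose nearest
non-missing neighbours within 5 markers on both sides agree with each
other but differ from it would require a double crossover in a short
interval; such singletons are set to missing (never rewritten to another
concrete call), iterating to stability.  Missing calls are then imputed
by majority vote among the 5 map-nearest markers of the same individual,
ties resolved toward the heterozygote (the F2 modal class).  Blanking
removes genuine close double crossovers too, so built maps shrink
systematically by roughly 5–9% relative to the simulated truth — the
price of removing ~90% of planted errors at a ≤ 0.05% false-blank rate.

**Distances.** Adjacent recombination fractions are re-estimated on the
corrected, completed data and accumulated through the Kosambi function
$d = 25\,\ln[(1+2r)/(1-2r)]$ (inverse $r = \tfrac12\tanh(d/50)$).
Kosambi is used for reported distances (the study's choice) even though
the generator is Haldane; the resulting map-function mismatch is small
at dense spacing and is covered by a dedicated ordering test
(Kosambi < Haldane for all r).  Map summaries follow the study's
convention of dividing total length by the marker *count* for the
average adjacent distance; the per-gap version (count − 1) is reported
alongside.

## QTL scanning

Conditional genotype probabilities at a grid position are computed from
the nearest non-missing flanking markers per individual through Haldane
transition matrices (degenerate at observed markers; Mendelian prior
¼, ½, ¼ for individuals with no information on the group).  The scan is
**Haley–Knott regression** of the phenotype on
$x_a = P(bb) - P(aa)$ and $x_d = P(ab)$, with forward-selected
background cofactor markers (additive + dominance coding, at most 5,
stopping when the RSS gain falls below 1% of total variance) included in
both null and full models except within a 10 cM exclusion window of the
tested position — conventional composite-interval-mapping defaults, on a
1 cM grid.  Full-mixture interval mapping would give nearly identical
LOD at these effect sizes at several times the cost of a
1000-permutation run.

Thresholds come from permuting the phenotype against whole-individual
genotype vectors (preserving marker correlation) and taking empirical
quantiles of the genome-wide maximum LOD at 0.99/0.95/0.90 confidence;
if no rung declares a QTL the manual ladder 3.0/2.5/2.0 is walked, and
the first declaring rung is recorded as provenance.  Permutation scans
are cofactor-free: re-selecting cofactors per permutation is
prohibitively expensive and permuted phenotypes carry no signal for
selection; calibration tests show the resulting genome-wide type-I error
at the 0.95 rung is ≈ 5%.

QTLs are maximal contiguous supra-threshold runs; ADD and DOM are
re-estimated at the peak *without* cofactors, since cofactors in linkage
with the peak absorb part of the effect and the quantities are defined
on the raw genotype contrast (ADD = half the homozygote mean difference
toward the parent-2 allele; DOM = heterozygote deviation from the
homozygote midpoint).  PVE uses the likelihood-R² identity
$(1 - 10^{-2\,\mathrm{LOD}/n}) \times 100$, which the study does not
state but which is the standard choice and is capped below 100% by
construction (the study's printed 110.31% for the fertility locus is
treated as non-reproducible).  Binary fertility is scanned as a 0/1
trait in the same linear framework; this reproduces the single dominant
locus with an overwhelming peak and effect magnitudes ≈ 0.5/0.5, the
binary-coding analogue of the published ±0.49.

## FAV analysis

The heterosis argument: if heterozygosity at a marker is advantageous
for FSH, the proportion of heterozygous carriers should rise across
phenotype bins.  Bins are half-open 10-cm intervals anchored at 90 cm
(a value of exactly 100 falls in (90, 100]).  Candidates are the mapped
markers inside declared FSH QTL intervals.  Per-bin heterozygote
proportions keep missing genotypes in the denominator by default
(matching fixed printed bin sizes; an option switches to
informative-only).  Bins holding fewer than 10 individuals are reported
`NA` and excluded from trends: a proportion over a handful of plants is
noise, and the reference procedure's own smallest bin held 11.  The
trend statistic is the plain Pearson correlation of bin midpoint versus
proportion; a marker is flagged *effective* when trend ≥ 0.5 and the top
bin exceeds the bottom bin, with both ranking measures (unweighted mean
of bin proportions; whole-population heterozygote fraction) always
reported so alternative rules can be applied downstream.  The exact rule
the study used to cut 20 effective from 49 candidate markers is not
recoverable from its text; the defaults here reproduce the shape of the
procedure and admit all 20 published rows.

**Known limitation.** A Pearson correlation over 4–5 bins is scale-free:
under the null P(r ≥ 0.5) is ≈ 0.20–0.25 regardless of sample size, so
the default shortlist rule admits roughly a quarter of null markers.
The flag is a *ranking heuristic for shortlisting within already
QTL-significant intervals*, not a hypothesis test; tests assert the
attainable calibration (agreement with the exact null distribution of
r, and < 10% at trend ≥ 0.9) and the ≥ 80% sensitivity to a strongly
overdominant planted locus.

## Pipeline, formats, determinism

`run_pipeline()` chains simulate → qc → map → scan (FSH, then
fertility) → fav, validating the configuration before any stage runs and
writing every artifact as tab-separated text (`--` missing genotype,
`.` missing numeric) plus a JSON manifest of configuration, derived
seeds, and stage row counts — sufficient to replay the run
byte-identically, which the tests verify.  Supplying genotypes and
phenotypes skips simulation (real-data mode).  VCF emission/ingest is
provided for interoperability (one record per SNP; parental-state
recoding; non-`aa×bb` records routed to the pattern classifier;
multi-allelic records skipped and counted).  The package's interface is
these functions; the pipeline entry point is `run_pipeline()` plus the
`scripts/acceptance.R` reproduction script.

## Numerical choices and degenerate inputs

EM convergence tolerance 10⁻¹², capped at 500 iterations, estimates
clamped to [0, 0.5]; likelihood terms with zero counts contribute
exactly zero; r ≥ 0.5 is rejected by the Kosambi forward transform
(infinite distance).  Adjacent distances use r capped at 0.4999.
Constant phenotypes give identically zero LOD; rank-deficient designs
fall back to pivoted least squares with absent coefficients treated as
zero effect.  Zero-length groups, all-missing individuals, empty bins,
empty QTL sets and empty VCFs all return well-defined empty results
rather than errors, with warnings where information is lost.
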