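---
title: "Mapping donor introgressions in backcross conversion lines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping donor introgressions in backcross conversion lines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Conversion breeding programs turn exotic, photoperiod-sensitive landraces
into temperate-adapted lines by repeated backcrossing to the landrace
(recurrent parent) while selecting, in each segregating generation, for
alleles contributed by an elite donor — dwarfing and photoperiod
insensitivity in the sorghum case that motivates this package. Decades
later, genotyping the converted line (SC), its exotic progenitor (EP) and
the donor reveals which chromosome segments of the donor were retained:
selection keeps donor segments around its targets at high frequency, while
the unselected background decays toward the neutral expectation. Mapping
introgression frequency across many independent conversions therefore maps
the loci required for temperate adaptation, without any phenotyping.

`introgmap` implements that retrospective analysis as a tested pipeline for
sparse, homozygous-dominated SNP matrices of the kind produced by
genotyping-by-sequencing (GBS), together with a meiosis-level simulator of
the crossing scheme so that every stage can be validated against a known
ground truth.

## The trio model

For a marker genotyped in all three members of a trio, with all calls
homozygous, there are four outcomes:

* all three genotypes equal — no polymorphism, **non-informative**;
* SC matches the donor and not the EP — introgression **present** (score 1);
* SC matches the EP and not the donor — introgression **absent** (score 0);
* the SC allele occurs in neither parent — **unexpected**.

Heterozygous or missing members make the trio call missing. Unexpected
genotypes cannot arise under the pedigree model, so their rate per marker
and per pair is a direct quality-control statistic: scattered unexpected
calls indicate drift between the genotyped EP seed lot and the recurrent
parent actually used; clustered runs indicate an introgression from a
different donor; very high rates indicate clerical swaps. QC removes
markers with more than 20% unexpected calls, then pairs with more than 10%
(both strict inequalities; the unexpected fraction is
unexpected / (informative + unexpected), a denominator that stays
well-defined when unexpected calls dominate).

### Donor consensus

The donor is genotyped as several replicate libraries. Libraries whose mean
pairwise non-missing concordance with the others falls below 0.8 are
dropped; the consensus call at a marker is the majority call provided it is
homozygous, untied and supported by at least 80% of the non-missing calls,
otherwise missing. The concordance metric and both fractions are exposed as
configuration because outlier libraries can equally be flagged by other
means (e.g. a PCA of libraries).

### Score imputation and frequency

After setting non-informative and unexpected calls to missing, missing
scores are filled per pair and chromosome by distance-weighted linear
interpolation between the nearest informative flanking markers,
`(sL (pR − p) + sR (p − pL)) / (pR − pL)`, with constant extension beyond
the first/last informative marker; chromosomes with no informative marker
for a pair remain undefined and drop out of downstream denominators.
Introgression frequency at a marker is the mean of defined scores across
pairs, in percent; fractional (interpolated) scores enter that mean.
Coordinates are 1-based bp internally; exported BED-like tracks are 0-based
half-open.

Imputation is deliberately simple: interpolation of a 0/1 step function is
unbiased on average but *underestimates narrow, sparsely covered sweeps*
and can miss very small introgressions entirely — the reason the
genome-wide mean frequency of an unselected panel sits slightly below the
analytic 3.125% when missingness is high.

### Marker pre-filters

SNPs called from the same short sequencing tag carry no independent
information: scanning left-to-right, a marker is removed when a retained
marker strictly less than 64 bp upstream has an identical genotype pattern
on shared non-missing samples and is in complete LD (r² = 1, which
requires at least two distinct shared genotypes); the leftmost of a
redundant run is kept, making the operation idempotent. A minor-allele
frequency filter (strictly above 10%, alleles counted over non-missing
calls with heterozygotes contributing one each) is applied **only** to the
marker set used for population structure; rare alleles are especially
informative for pairwise introgression calls and are never filtered there.

## Population structure

EP lines are assigned to subpopulations by thresholds on the first two
principal components of their alt-allele dosage matrix (missing dosages
filled with the marker mean). Because PC sign and scale are arbitrary,
each component is canonicalized (largest-magnitude loading made positive)
before the thresholds apply; the shipped defaults (PC2 < −20 → guinea/kafir,
else PC1 > 0 → caudatum, else durra) reproduce one historical dataset and
**must be recalibrated** on any new panel by inspecting the returned
coordinates.

Per-SNP differentiation between the SC and EP panels uses the Hudson
estimator,

$$F_{st} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) - p_2(1-p_2)/(n_2-1)}
               {p_1(1-p_2) + p_2(1-p_1)},$$

with allele counts in haploid units on pairwise-complete data. No estimator
was mandated by the analysis this package re-implements; Hudson's was
chosen for its closed form and stable ratio-of-averages behaviour. Because
Fst makes no pedigree assumption, its peaks cross-validate the
introgression-frequency peaks.

Subpopulation-specific targets are detected by a permutation test: the
observed statistic is, per marker, the range (max − min) of subpopulation
introgression frequencies; per chromosome, the maximum of that range. Pair
labels are permuted (group sizes fixed, 200 permutations, α = 0.05), each
chromosome's threshold is the empirical (1 − α) quantile of its null
maxima, and observed per-marker ranges above their chromosome's threshold
are flagged. Recording per-chromosome maxima controls for the number and
spacing of markers per chromosome; how the chromosome-level null maps to
marker-level calls was an open design point, resolved here by applying the
chromosome threshold to each marker's observed range.

## Anchoring unplaced contigs

Backcross-derived lines carry donor segments in long blocks, so raw 0/1
introgression calls are correlated over megabases — far beyond ordinary LD.
A SNP on an unanchored contig is eligible for placement when it has at
least 20 present/absent calls and a raw present fraction of at least 10%;
its squared Pearson correlation against every anchored SNP (on
pairwise-complete data with at least 20 shared calls) is computed, all
anchored SNPs tied for the maximum within 10⁻¹² are collected, and a
chromosome is assigned when the tied set is confined to one chromosome.
r² is computed on raw calls, not imputed scores, to avoid
interpolation-induced correlation. Two regimes are unanchorable in
principle: SNPs inside a fully swept core (their all-present pattern is
shared by every swept locus genome-wide) and SNPs whose overlap with every
anchored SNP contains only a handful of informative calls; both surface as
non-unique ties rather than confident misplacements.

## The simulator

`simulate_conversion()` emulates the conversion scheme at the level of
meioses. Haplotypes are run-length lists of parental-origin labels along a
genetic map (default 10 chromosomes × 1.6 Morgans — 16 Morgans total — at a
constant 40 Mb per Morgan, 500 markers per chromosome). A gamete receives
Poisson(length in Morgans) crossovers at uniform genetic positions with no
interference (Haldane model) and a fair starting haplotype, so the
recombination fraction between loci d Morgans apart is (1 − e^(−2d))/2.

Two crossing schemes are provided. The default `f2_backcross` follows the
historical program: each of the B = 4 cycles selfs the current plant to an
F2, selects an F2 individual homozygous for the donor allele at every
declared target (rejection sampling, bounded at 10⁴ draws), and backcrosses
it to the recurrent parent; a final selfing with selection yields the line.
`backcross` is the classical plain chain (F1 then B straight backcrosses,
then the final selfing) — the scheme under which the textbook moments of
the donor fraction in backcross-derived inbreds are stated. Selection on
the historical program's phenotypes is idealized as donor-homozygosity at
declared target loci — the genetic consequence the analysis measures.
Final inbreeding is modelled as one selfing followed by one further
meiosis that fixes each residually heterozygous segment at random; the
expectation (1/2)^(B+1) is exact under this shortcut, the variance very
slightly approximate compared with selfing to complete fixation.

Under the plain chain the donor fraction of an inbred line has mean 3.125%
and, on this map, a simulated standard deviation of ≈2.6% across lines —
3 percentage points to the nearest point; the interleaved-selfing scheme
gives ≈2.3% because its extra meioses average the transmitted fraction.
A panel of a few hundred lines therefore shows background frequencies of
roughly 2–4%, and regions above a 4% linkage threshold indicate selection.

EP lines are drawn as inbred genotypes from a progenitor pool: a fraction
`divergence` (default 0.8) of markers is polymorphic between donor and
pool, with the non-donor allele at pool frequency drawn from `ep_freq`
(default U(0.1, 1)); subpopulations displace those frequencies with a
Balding–Nichols model (default F = 0.15), which gives the PCA a real
structure to recover. Noise is applied per cell in the order unexpected →
heterozygous → missing, with defaults matching the emulated study: 66%
missing (raw GBS; partial imputation in the original workflow reduced this
to ~20–23%, so analysis-stage experiments may reasonably use rates in that
range), 0.3% heterozygous, and a low scattered unexpected rate (default
2%). Unexpected calls replace SC genotypes by a third allele at
donor/EP-polymorphic markers, in three modes that mimic the observed
signatures: `scattered` (drift), `segmental` (one contiguous foreign
block), `pair_swap` (clerical rewiring of EP identities).

What the generator does **not** emulate: coalescent EP diversity and
linkage disequilibrium within the progenitor pool (marker frequencies are
independent), allele-call error models beyond the three phenomenological
rates, non-constant recombination along chromosomes, and crossover
interference. Passing tests therefore demonstrate correctness of the
pipeline's logic under the stated model, not robustness to every artefact
of real GBS data.

## Validation experiments and problem sizes

The shipped test-suite experiments were sized for desk-scale runs while
keeping Monte-Carlo error small relative to the assertions: 10,000 plain
BC4 lines for the donor-fraction moments; a 390-pair unselected panel at
default noise for the genome-wide background band (2–4%); 200 replicate
permutation runs at n_perm = 100 on null data (uniform scores, 30/30/30
groups) for type-I calibration; a 100-pair panel with three global targets,
one group-specific target, missing = 0.5 and a mixture of 2% and 25%
unexpected rates for end-to-end parameter recovery and QC bookkeeping; and
100 synthetic contigs on a 100-line panel for anchoring. The anchoring
panel is a fully divergent, fully genotyped cross (divergence = 1,
`ep_freq = c(1, 1)`, no missingness) with near-target contigs drawn from a
0.02–0.2 Morgan annulus around the targets: the annulus excludes the
unanchorable swept core, and complete genotypes make the r² scan reflect
linkage rather than sampling noise of the shared-call subset — at sparser
call densities the 20-call overlap floor is only reachable with panels of
several hundred lines, which is how the original analysis (390 pairs) met
it. Robustness to missingness is exercised by the background-band and
parameter-recovery experiments instead.

## Numerical and degenerate-input conventions

* Strict inequalities throughout the QC and filters, matching their
  definitions (>20%, >10%, <64 bp, MAF >10%); eligibility thresholds for
  anchoring are inclusive (≥20 calls, ≥10%).
* Ties: donor-consensus ties are set missing; redundant-marker runs keep
  the lowest position; anchoring ties are exact to 10⁻¹² (configurable).
* Markers with zero informative-plus-unexpected calls are retained by
  marker QC and flagged uninformative; all-missing markers are dropped by
  the MAF filter with a logged count.
* Fst is undefined (NA) at markers monomorphic in both panels or with
  fewer than two non-missing genotypes in either panel.
* The permutation test warns below 20 permutations (unstable quantile);
  results carry their seed, and reruns with the same seed are identical.
* Multi-allelic input sites are dropped with a logged count; duplicated
  sample identifiers are errors, as are malformed rows (reported with
  their line number).

## Known limitations

* Interpolation-based imputation underestimates narrow sweeps on sparse
  data; frequencies near tightly selected loci are conservative.
* The pipeline analyzes homozygous trios only; heterozygous calls (0.3% in
  the emulated data) are treated as missing.
* PCA thresholds are dataset-specific by nature; the defaults are a
  starting point, not a universal rule.
* The per-chromosome permutation threshold applied to marker-level ranges
  is conservative for chromosomes with many independent peaks.
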