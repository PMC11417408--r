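---
title: "Methods: compartment, domain and mark-redistribution analysis of binned Hi-C data"
author: "EpiContact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: compartment, domain and mark-redistribution analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpiContact)
```

# Scope and scientific setting

EpiContact analyses the interplay between the epigenome and 3D genome
organization in plant-like genomes, where chromosomes typically carry
gene-rich euchromatic arms and a TE-rich pericentromeric core of
constitutive heterochromatin, with Polycomb (H3K27me3) facultative
heterochromatin interspersed in the arms.  Loss of the chromatin
remodeler DDM1 relocates H3K27me3 from gene-associated regions into the
TE-rich core, and this epigenomic reshuffling weakens the spatial
segregation of active (A) and inactive (B) chromatin.  The package
implements the full analysis chain used to quantify such a phenotype —
contact-matrix normalization, A/B compartment calling, compartment
strength, insulation and TAD-like aggregates, anchor-pair aggregates,
distance-stratified differential interactions, and a rule-based
classifier of H3K27me3 redistribution — together with a synthetic-data
generator that plants all of these structures so that every stage can
be validated against known truth.

# The synthetic genome generator

## Layout and chromatin states

`simulationConfig()` / `buildGenomeLayout()` build a genome of
`n_chrom` chromosomes (default 2) of `chrom_len` 10 Mb at a
`bin_size` of 50 kb — 200 bins per chromosome, the smallest scale at
which compartments, TAD-like domains and saddle analyses are all
resolvable, and the resolution used for real maps of this kind.  The
central `core_frac` (default 0.4) of each chromosome's bins is
constitutive heterochromatin (`const_het`) densely covered by long TEs
(superfamily composition biased toward LTR/Gypsy); arm bins carry one
gene each (60% bp coverage), a shorter TE with probability 0.75
(biased toward LTR/Copia), and are facultative heterochromatin
(`fac_het`) with probability `p_fac` (default 0.3), otherwise active.
The planted compartment label is A for active bins and B otherwise.
`n_tads_per_chrom` (default 10) TAD-like domains tile the repressed
core — in plants TAD-like structures are predominantly repressed
blocks flanked by active chromatin.  Anchor bins (10 shared + 3
mutant-only per chromosome) emulate H3K27me3-marked loci whose
homotypic pairs within 10–100 bins receive an `anchor_boost` (3x)
contact boost.

## Contact model

Counts for bins $i<j$ are Poisson:

$$K_{ij} \sim \mathrm{Poisson}\!\left(L\, (j-i)^{-\alpha}\,
A(s_i, s_j)\, \tau^{[\text{same TAD}]}\, b^{[\text{anchor pair}]}\right)$$

with distance-decay exponent $\alpha = 1$, chromatin-state affinity
$A$ (homotypic 1.6; facultative–constitutive 0.8; active–repressed
0.5), intra-TAD boost $\tau = 1.5$ and anchor boost $b = 3$.  $L$ is
calibrated per chromosome so the expected cis total equals `depth`.
The Poisson form is the minimal count model consistent with the
sparsity of real Hi-C; no polymer dynamics are implied.  Trans
contacts are omitted (all analyses here are cis).

`depth` defaults to 5e6 cis pairs per 10 Mb chromosome.  The principle
is to preserve the *per-cell* coverage of a deeply sequenced 50 kb
map rather than total reads: a 60 Mb chromosome with ~30M cis pairs
has on the order of 70–100 counts per bin pair at mid-range
separations, and 5e6 pairs on a 200-bin chromosome reproduces that.
Shallower settings leave every count-ratio statistic (log-ratio
z-scores in particular) dominated by shot noise.

## The ddm1 mode

`applyDdm1Redistribution()` implements the mutant mechanistically:

* `rho_relocate` (default 0.5) of core bins gain H3K27me3 and lose
  H3K9me2/H3K27me1/DNA methylation, becoming `fac_het`
  (redistribution classes II and III, split by `class3_frac`; class
  III bins additionally carry a constitutively low H3K9me2 base level
  in both genotypes, so their H3K9me2 is "stable but low");
* `rho_loss` (default 0.5) of wild-type facultative bins lose
  H3K27me3 and become active-like (class I);
* the mutant contact map uses the mutant states with raised
  cross-affinities: facultative–constitutive 1.3 (`a_cross_rep_mut`)
  and active–repressed 1.1 (`a_AB_mut`), plus a reduced intra-TAD
  boost (`tau_mut` 1.2).

The near-neutral mutant active–repressed affinity deserves a note: it
is what produces the mutant phenotype of heightened A–B contact and a
flattened PC1.  With a more polar choice the mutant map remains so
well segregated that a K27me3-ordered map looks *more* compartmental
than wild type (once the core carries K27me3, sorting by K27me3 is
sorting by compartment), inverting the biology the mode is meant to
emulate.  The fractions `rho_*` are placeholders — the magnitude of
genome-wide state change in real DDM1-loss material is not quantified
at bin level — so only directions of effect, never magnitudes, should
be read off simulated comparisons.

## Mark tracks and expression

Track values are state base levels times lognormal noise
($\sigma$ = `sigma_track`, default 0.3).  Base levels (arbitrary
units): H3K27me3 2.0 on facultative, 0.3 on active, 0.1 on
constitutive bins — constitutive heterochromatin is K27me3-depleted,
below even active chromatin, which is what makes a K27me3 sort
separate facultative from constitutive material; H3K9me2/H3K27me1 and
CG/CHG/CHH are high (2.0) on constitutive bins; H3K9ac marks active
bins.  The DE table up-shifts genes on class I bins
(log2FC ~ N(2, 0.4), small adjusted p) against a null background —
genes losing Polycomb silencing are the ones expected to activate.

## What the generator does not emulate

Per-bin visibility bias (mappability, restriction density), trans
contacts, replicate structure, peak-level mark geometry below bin
size, and read-level artifacts.  Passing tests therefore demonstrate
correctness of the analysis chain on idealized count data, not
robustness to the technical biases of real libraries.

# Analysis methods

## Matrix stages

`ContactMatrix` objects move forward through
`raw → balanced → oe → pearson`.  Balancing is plain iterative
correction (ICE): rows/columns are repeatedly divided by their
marginals rescaled to unit mean until the marginals deviate by less
than `tol` (1e-5) or `maxIter` (200) sweeps; non-convergence warns
rather than errors, and weights satisfy
`balanced = raw / (w_i w_j)`.  The expected profile is the arithmetic
mean over doubly-unmasked pairs at each separation, so the
observed/expected map has per-separation mean exactly 1 — an identity
the tests assert at 1e-9.  Pearson maps correlate O/E columns over
unmasked rows with pairwise-complete cells (the undefined O/E
diagonal never contributes).

A practical note on balancing synthetic data: the generator plants no
visibility bias, so every marginal difference in a simulated map is
genuine compartment signal; ICE removes part of it (the core's high
marginals) and thereby attenuates compartment strength.  The pipeline
therefore computes compartment-level statistics (PC1, saddle, pentad,
sorted maps, APA, differential z) on the O/E of the raw map — the
O/E contract accepts raw or balanced input — and uses balanced
matrices where per-bin coverage must be equalized, i.e. for insulation
profiles.  On real data with technical bias one would balance first
in both branches.

## Compartments

PC1 is the leading eigenvector of the column-mean-centered Pearson
map, computed per chromosome (compartment signs are
chromosome-local), unit length, oriented so that it correlates
positively with a user-chosen active track (H3K9ac here; gene density
works equally well), with A assigned to positive PC1.  The
eigenvalue-gap ratio is reported; a degenerate map is refused rather
than silently called.

Saddle analysis ranks unmasked bins by ascending PC1 into `Q = 5`
equal-size groups and averages O/E over group pairs at separations
$\ge$ `dMin` = 2 bins (near-diagonal decay is excluded from all
compartment averages).  Strength is
$(\overline{BB} + \overline{AA}) / (2\,\overline{AB})$ over corner
blocks.  The function's default corner (extreme 20% of groups)
follows common practice; the pipeline and the acceptance experiments
use `cornerFrac = 0.4`, i.e. corners spanning the two full
compartments.  With a single contiguous B core, the extreme-quintile
corner sub-samples bins *within* one state and its composition drifts
with sequencing depth and affinity, which destabilizes the strength
ordering; 0.4-corners give a stable, monotone estimator on this
geometry.  Pentad-style category means pool O/E cells over all
interval-pair blocks (AA, BB, AB) of the maximal same-label runs, and
the feature-sorted map reorders the Pearson matrix by a track and
scores segregation as mean same-decile minus mean far-decile (group
distance at least half the number of groups) correlation.

## Insulation and aggregates

Insulation follows the log2 diamond convention: the mean balanced
signal in a `w`-bin diamond crossing each bin, log2-normalized to the
chromosomal (geometric) mean, so valid-bin scores average to zero.
Boundaries are prominence-filtered local minima (ties resolve
leftward), and domains are inter-boundary intervals.  The exported
defaults (`w` 10 bins, `delta` 0.2) suit maps whose domains span tens
of bins; the pipeline and acceptance runs use `w = 6`, `delta = 0.5`,
matched to the planted 8-bin TAD scale and to the arm-noise floor of
the default simulated depth (spurious noise minima reach ~0.3–0.4
log2 prominence there; genuine planted borders exceed 0.8).  Window
and threshold are caller parameters, expected to be tuned to the data
scale, and all recovery bars are evaluated at fixed thresholds
regardless.

Aggregate TAD analysis rescales each domain plus half-length flanks
to a `K x K` grid by area-weighted block averaging — chosen over
interpolation kernels because it is exact on divisible grids, which
the tests exploit — and averages over domains; the differential map
is mutant minus wild type, evaluated on the same (wild-type-called or
planted) domain set so both genotypes aggregate position-matched
structures.  APA averages O/E windows over cross-set anchor pairs
within a separation range and reports center-over-corner enrichment.

## Differential interactions

For every doubly-unmasked cis pair within `dMax` = 100 bins,
`r = log2((OE_mut + eps)/(OE_wt + eps))` (eps = 0.01 guards sparse
zeros) is standardized within 8 log-spaced separation strata;
`z = (r - mu_d)/sigma_d`.  Negative z marks WT-specific contact,
positive z mutant-specific; results are ranked by |z| with no FDR
layer (selection among top pairs is presentation-driven in this kind
of analysis).  Swapping genotypes negates every z exactly, and
within-stratum means/SDs are 0/1 by construction.  If a stratum is
degenerate (identical maps) its ratios are kept at z = 0; a
zero-variance stratum with a non-zero mean is dropped with a warning.

## Mark quantification and classification

Tracks are scaled to genome-wide mean 1 (a deliberate simplification
of multi-factor ChIP normalization schemes; recorded in output
metadata).  Per region, `delta = log2((s_mut + 0.1)/(s_wt + 0.1))` is
thresholded at ±0.5 log2 into up/down/nc, and a region is `low` when
both samples sit below the 25th percentile of pooled genome-wide bin
values.  The three redistribution classes are then pure rules,
evaluated in order:

* **I** — H3K27me3 down, H3K9me2 and H3K27me1 each up-or-unchanged;
* **II** — H3K27me3 up, H3K9me2 and H3K27me1 both down;
* **III** — H3K27me3 up, H3K27me1 down, H3K9me2 unchanged *and* low.

So a H3K27me3 gain is only ever called on regions whose H3K9me2 is
either decreasing or already low.  The thresholds are defaults, not
published values, and are exposed as arguments.  TE location is a
median split on gene-covered bp fraction in a 1 Mb window (ties to
gene_rich); superfamily composition uses the pooled two-proportion
z-test, the statistically appropriate test for category fractions;
and the expression cross-tabulation reports per-DE-status fractions
of mark/methylation status tuples, which sum to one by construction.

# Numerical choices and degenerate inputs

Coordinates are 0-based half-open on disk (cooler convention) and
1-based inside R; bin tables, COO triplets, bedGraph, BED6 and GFF3
writers/readers round-trip all objects (numeric tracks at `%.17g`).
Matrices are dense per chromosome (at most ~2000 bins is the intended
scale; sparse storage only on disk).  Masked bins are `NA` rows and
columns: they reduce averaging counts and never contribute zeros.
Degenerate cases fail loudly: empty pairs files, unknown
chromosomes, zero-total matrices, all-masked chromosomes, degenerate
Pearson maps, orientation tracks with zero PC1 correlation, zero
eligible anchor pairs, and zero usable domains are all errors, while
non-converged balancing and zero-variance strata are warnings.

# Problem sizes in the shipped experiments

The packaged tests and the acceptance script run on the generator's
default scale (2 x 200 bins) with 10-seed panels for paired
directional claims, 3 replicate simulations for boundary-recovery F1,
and single runs for calibration quantities (~30k pairs enter the null
z calibration).  These sizes keep each experiment well-resolved while
the whole suite stays in the minutes range on one CPU.

# Known limitations

Directions, not magnitudes, are the meaningful output of simulated
comparisons; absolute strengths depend on affinities and depth that
are not fitted to any real dataset.  The compartment caller assumes
one A/B axis per chromosome and will not resolve sub-compartments.
The boundary caller detects prominence minima only — nested or
hierarchical domains are out of scope.  The classifier consumes
fixed-bin or user-supplied regions; it does not call peaks, and DMR
intervals are consumed, not computed.
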