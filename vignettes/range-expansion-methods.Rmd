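---
title: "Models and methods: diversity, selection and load along crop expansion routes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: diversity, selection and load along crop expansion routes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(landracepopgen)
```

This vignette documents the statistical models behind `landracepopgen`,
the assumptions they rest on, the tunable parameters and their defaults,
and the design decisions taken where more than one defensible convention
exists. The package targets SNP-array panels of crop landraces — open
pollinated traditional varieties sampled as populations — together with
elite breeding material and doubled-haploid (DH) libraries derived from
single landraces.

## Genotype representation and polarization

The central container is the `genotype_panel`: a samples × sites integer
matrix of allele dosages with site metadata (chromosome, 1-based
position, REF/ALT bases, ancestral allele, array quality class). Dosages
are ALT counts as read from a VCF and become *derived*-allele counts
after `polarize_to_ancestral()`, which flips `d -> 2 - d` at sites whose
annotated ancestral allele equals ALT and swaps the allele labels so
that, post-polarization, `ancestral == ref` holds everywhere and a second
application is the identity. Sites with an unknown ancestral state are
excluded from polarization-dependent analyses (load, iHS) but retained —
under minor-allele coding — for heterozygosity, F_ST and PCA, all of
which are invariant to allele-label swaps. Missing calls are a distinct
`NA` sentinel and are never imputed except where a method requires a
complete matrix (the RDA response and neutral PCs use per-site mean
imputation).

Array data come with per-marker quality classifications rather than
sequencing quality scores; `filter_sites()` therefore whitelists quality
classes (`PolyHighResolution`, `MonoHighResolution`, `NoMinorHom` by
default) and additionally drops indels, multi-allelic records (flagged at
read time, never silently split), sites above a missingness cap, and
optionally monomorphic sites. Attrition is logged per rule because marker
counts after each step are the first thing to reconcile when comparing
runs; the filter is idempotent.

LD pruning follows the sliding-window convention of array toolkits:
within each window, the later site of any pair with squared genotype
correlation above `r2_max` is removed, and the scan repeats up to
`n_iter` times (defaults: window 500, step 200, 5 iterations,
`r2_max = 0.1`). Windows are counted in *variants* by default — the unit
used by the pruning routines common for array data — with a `unit = "bp"`
switch, since the two conventions are easily conflated when only a
"window size of 500" is reported.

## Diversity and inbreeding

Per-population expected heterozygosity is `H = 2pq` per site with `p`
estimated from non-missing calls in that population; the population mean
ignores sites with fewer than two non-missing genotypes and, by default,
averages over all remaining sites (monomorphic sites contribute 0),
matching the NaN-ignoring-mean convention; `segregating_only = TRUE`
exposes the alternative. Inbreeding uses the method-of-moments estimator
`F = (O_hom − E_hom)/(N − E_hom)` with
`E_hom = Σ (1 − 2pq·n/(n−1))`; the small-sample correction follows the
whole-file convention of standard VCF tooling, and the cohort for allele
frequencies is the whole panel by default (`cohort = "population"`
restricts it). With a structured panel the panel-wide cohort inflates F
(a Wahlund effect) — the same behaviour as the reference tooling, and
worth keeping in mind when reading absolute values.

Route gradients are Spearman rank correlations of a per-population
statistic against haversine distance from an entry population
(Earth radius 6371.0088 km), optionally within one cluster. Spearman is
used for all gradient and isolation-by-distance tests in the package:
the expectations being tested are monotone, not linear, and rank
correlation is invariant to monotone transforms (which is also why the
linearized F_ST reproduces exactly the same correlation as raw F_ST).

## Differentiation

Pairwise F_ST uses the Hudson estimator in the unbiased per-site
component form, accumulated as a *ratio of sums* — never a mean of
per-site ratios, which is biased for low-information sites — with a
delete-one-block jackknife over contiguous blocks (default 100,000
variants) for the standard error. Per-site components may be negative;
no clamping is applied to retain unbiasedness, and only the
reported/plotted matrix is floored at zero (`fst_floored`), with raw
values kept alongside. Sites entering each pair are those segregating in
the union of the pair by default (`seg_scope = "global"` is available);
the choice affects absolute values, which is why it is a switch rather
than a constant.

Environmental distance standardizes each of the 19 bioclimatic variables
to zero mean and unit (sample) standard deviation across populations and
takes pairwise Euclidean distances; standardization absorbs any affine
rescaling of a raw variable. Isolation-by-distance tests correlate
upper-triangle F_ST against geographic or environmental distance over
all pairs or within/between-cluster subsets. Pairs sharing a population
are not independent, so the plain-correlation p-values are approximate;
a Mantel permutation option (`mantel = TRUE`, via vegan) is provided and
its use logged. Cluster contrasts compare within- vs between-cluster
F_ST distributions with a two-sample Kolmogorov–Smirnov test.

## EHH, iHS and empirical classification

DH lines are fully homozygous, so a DH library is a naturally phased
haplotype panel: the `haplotype_panel` stores a binary lines × sites
matrix (1 = derived) and rejects heterozygous calls outright. EHH from a
core site counts, at each successive site, the fraction of
carrier pairs identical at every site from the core through it;
the curve starts at 1, is non-increasing, and the walk stops after the
first value below `ehh_cutoff` (kept, so the final trapezoid crosses the
cutoff) or at a chromosome end, which flags the site edge-censored. iHH
is the trapezoidal integral of EHH over physical distance with per-gap
widths capped at `max_gap` so sparse regions cannot dominate;
`iHS_raw = ln(iHH_A/iHH_D)` sums both directions per allele, and raw
scores are z-standardized within equal-width derived-frequency bins.
Defaults (`ehh_cutoff = 0.05`, `maf_min = 0.05`, `max_gap = 200000` bp,
100 bins) follow the conventions of the standard scan tools; physical
distance is used throughout because array panels carry no genetic map.
Edge-censored sites are excluded from standardization by default.

Classification is deliberately simple and rank-based: the empirical
p-value is the site's rank of |iHS| (descending, average rank on ties)
divided by the number of scored sites, and a site is "significant" only
if `p < 0.05` *and* `|iHS| > 2`. Under a standard-normal null the second
condition binds (P(|Z|>2) ≈ 0.0455 < 0.05), which the calibration test
asserts. Nearest-gene annotation reports the closest interval by bp
distance, 0 inside a gene, ties broken toward the lower-coordinate
(upstream) gene, and a signed distance (positive when the gene lies
left of the site).

## Redundancy analysis and variance partitioning

The RDA response is the individual-level centred derived-dosage matrix
(mean-imputed), with population-level climate and coordinates broadcast
to individuals; a population-frequency response is possible by passing
population means instead. Neutral structure enters as the leading PCs of
the panel restricted to a user-supplied fourfold-degenerate site list
(site-degeneracy calling from an annotation is upstream of this
package; simulated runs label truth-neutral sites).

`partial_rda()` removes conditions from response and predictors by OLS
residualization and measures the squared norm of the projection of the
response residuals onto the predictor-residual column space. R² is taken
relative to the total variance of the *condition-residualized* response
(the denominator convention must be fixed somewhere; this one makes the
empty-condition case collapse exactly to OLS R²), the adjustment is
Ezekiel's `1 − (1−R²)(n−1)/(n−p−1)` with `p` the post-residualization
predictor rank, and the p-value comes from free row permutation of the
predictor residuals (999 by default, seeded; a within-population
restricted scheme is a natural extension for structured designs and the
free scheme is therefore logged with the result). The implementation is
deliberately explicit linear algebra so that the seeded permutation
stream is fully controlled; the test suite cross-checks it against
vegan's constrained ordination.

Forward selection adds, at each step, the candidate with the largest
adjusted-R² gain, subject to a double stopping rule: the candidate must
pass a permutation entry test at `alpha` (conditioned on the selected
set), and from the second step on the cumulative adjusted R² may not
exceed that of the all-candidate model. Two guards address known
pathologies of forward selection: a *global* permutation test on the
all-candidate model gates the whole procedure (picking the best of many
candidates inflates the entry test's type-I error badly without it), and
the adjusted-R² ceiling is not applied to the first step because many
irrelevant candidates can drag the full model's adjusted R² *below* that
of the single true driver, which would otherwise return an empty
selection for a clearly significant signal. Near-collinear candidates
(R² ≥ 0.99 on the selected set) are skipped with a warning.

Variance partitioning fits the full model (climate + neutral PCs +
lat/lon as predictors) and the three pure models in which one block is
the predictor and the other two are conditions, reporting adjusted R²
and permutation p per model and flagging the best by adjusted R². The
pure models' conditioned R² values are semi-partial quantities and need
not sum to the full model's.

## Genetic load

Load accounting requires polarized dosages and a per-site GERP track
joined strictly on (chromosome, position). Total load is
`Σ gerp × dosage` — each derived allele counts, so a homozygous-derived
site contributes twice its score. Whether a published "sum of scores"
weighted homozygotes by 1 or 2 is often unstated; the dosage weighting
is declared here, and a presence/absence mode (`mode = "presence"`) is
provided for sensitivity analysis. Missing calls contribute zero with no
rescaling by callable sites; instead, samples above the 95th percentile
of per-sample missingness are excluded up front (strict inequality, so
a panel with no missing data excludes nobody). Highly deleterious
alleles are counted at sites with GERP strictly greater than 5. The
fixed/segregating partition classifies sites within each group on
non-missing calls (derived-fixed, ancestral-fixed, segregating) —
classification is group-relative, so a site may be fixed in one pool and
segregating in another — and with complete data the identity
`total = fixed(group) + segregating(sample)` holds exactly, which the
tests assert.

## The simulator: what it emulates, and what it does not

`simulate_expansion()` is a frequency-level serial-founder model chosen
for desk-scale speed with the structure the estimators need. A pool of
ancestral derived frequencies (Beta(0.5, 0.5) by default — array
ascertainment favours common variants, and post-drift mean
heterozygosity lands near values typical for landrace panels) expands
along two route trees rooted at a south-western and a central-northern
entry (defaults 42.04°N 8.64°W and 49.57°N 3.328°E, with 35 populations
and 24 individuals per population as the default study scale). Each
founding applies a binomial bottleneck (default 20 haploids), each
generation applies Wright–Fisher binomial drift (deme size 200) and
symmetric neighbour mixing along tree edges (rate 0.02, reduced ×0.1 on
the single inter-route contact), and genotypes are drawn under
inbreeding-adjusted Hardy–Weinberg, `P(het) = 2pq(1−F)` (F = 0.05 for
landraces, 0.95 for the optional elite pools, which also undergo strong
extra drift to mimic breeding bottlenecks). Planted sweeps raise a focal
derived frequency in one deme; DH panels drawn from that deme then copy
one shared core haplotype to derived carriers with probability equal to
the sweep's completeness, producing the elevated haplotype homozygosity
a recent hard sweep leaves in a recombination-poor panel. GERP scores
are Gamma-distributed over a quarter of sites with a small point mass
above 5; an optional coupling makes high-GERP derived alleles start
rarer, and an optional per-edge mutation process seeds new deleterious
alleles into founded demes so that load accumulates along routes.
Bioclimatic variables are linear in latitude/longitude plus noise, with
the truth coefficients recorded. All randomness flows from one root seed
through named substreams, and identical configurations produce
byte-identical output bundles.

Deliberate omissions: there is no recombination map (statistics under
test are site-wise; only the sweep-window copying is haplotype-aware),
no selection during the expansion (load accumulation is injected, not
emergent), elite pools are drift caricatures rather than pedigree
breeding, and bioclim surfaces are linear rather than raster-derived.
Passing recovery tests therefore demonstrates that the estimators detect
the targeted signals under drift, bottlenecks, migration and noise — not
that real landrace data are free of the confounders (ascertainment
shifts, uneven sampling, admixture, map errors) that the simulator does
not model.

Two experimental-design notes from the recovery suite. The two routes
are founded independently, so each carries its own baseline load; the
load-accumulation test correlates load with depth *within* routes.
And because the default bioclim gradients make all temperature variables
near-collinear along a route, the forward-selection recovery experiment
plants a single true gradient among otherwise gradient-free variables —
with near-duplicate candidates, "the causal variable before any noise
variable" is not identifiable for any selector.

## Numerical choices and problem sizes

Ties in |iHS| ranking use average ranks (deterministic, order
independent). Degenerate inputs are reported as missing values with
warnings rather than errors where an analysis can proceed (undefined F,
F_ST with zero denominator, constant gradient vectors); they are errors
where it cannot (no usable sites, empty pair sets, rank-zero responses).
Permutation p-values use the `(1 + exceedances)/(1 + n_perm)` estimator,
which can never return 0. The test and acceptance runs use deliberately
small problem sizes — hundreds to a few thousand sites, 8–24
populations, DH panels of 100–400 lines, 99–199 permutations — chosen
so the whole suite exercises every stage end-to-end at desk scale while
leaving the estimators' asymptotic behaviour to the closed-form and
oracle checks.

## Known limitations

Absolute F_ST levels depend on the segregating-site scope (pair vs
global), and published values rarely state it; both are implemented.
The inbreeding cohort convention (panel-wide frequencies) inflates F in
structured panels. Plain-correlation IBD p-values ignore pair
non-independence (use the Mantel option when that matters). iHS marker
counts are sensitive to the standardization bin count, MAF filter and
gap handling; defaults follow the standard tools but exact counts from
other toolchains should not be expected to match marker-for-marker. The
RDA permutation scheme is free row permutation; restricted schemes for
hierarchical designs are not yet implemented.
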