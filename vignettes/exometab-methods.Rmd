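---
title: "Methods: defined-medium stoichiometry and exometabolite profiling"
author: "exometab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: defined-medium stoichiometry and exometabolite profiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exometab)
```

# Scope

`exometab` implements the computational backbone of a defined-medium
exometabolomics study: (1) formulating a tiered defined medium and
accounting its organic carbon and nitrogen; (2) calling growth and
growth kinetics from plate-reader OD600 curves and comparing two media;
(3) turning targeted LC-MS peak tables into normalized utilization
profiles with depletion/production calls and Bray–Curtis clustering;
(4) testing phylogenetic niche conservatism by relating profile
distances to phylogenetic distances; and (5) a fully seeded synthetic
data generator so that every stage can be validated against known
ground truth without any external data. Raw LC-MS processing (peak
integration, spectral matching), molecular networking, and tree
inference are out of scope: trees and peak tables are consumed, not
produced.

# Medium formulation and elemental accounting

A medium definition is a list of components, each with a molecular
formula, a *concentration tier* and a micromolar concentration, plus a
salt profile (mM), pass-through supplements and a pH range. Tiers
(`sugars`, `organic_acids`, `amino_acids`, `other`) are concentration
groups, not strict chemical classes: in the bundled NLDM fixture the
tiers sit at 875, 525, 175 and 17.5 µM (multipliers 50:30:10:1), all
members of a tier equimolar.

For a component at $c$ µM whose formula carries $k$ atoms of element
$E$ with standard atomic weight $A_E$, the contributed mass
concentration is

$$ m_E = k \, A_E \, c \times 10^{-3} \ \mathrm{mg/L}. $$

`stoichiometry_table()` sums these per tier and in total;
`cn_ratio()` forms C:N on a molar or mass basis, optionally adding
inorganic N (ammonium etc.) from the salt profile. Because elemental
mass is linear in concentration, the inverse design problem — what base
tier concentration hits a target organic-carbon budget given the tier
multipliers — has the closed form implemented by `solve_tier_scale()`,
and a recomputation of carbon at the returned base reproduces the
target to 1e-9 relative (property-tested).

Numerical conventions:

* Atomic weights are a fixed bundled table (IUPAC 2021 abridged, at
  most 4 decimals), version-stamped in outputs, so results never depend
  on an external source.
* All internal arithmetic is full precision; only the display variant
  of the stoichiometry table rounds, and it rounds half **away from
  zero** (`round_half_up()`), matching the convention of printed media
  tables, not R's round-half-to-even.
* The formula grammar accepts parenthesised groups and hydrate dots
  (`MgSO4·7H2O`), although the bundled medium needs neither.

## The bundled NLDM fixture

`load_fixture("nldm_medium")` returns a 64-metabolite definition whose
rounded per-tier table is

```{r}
med <- load_fixture("nldm_medium")
stoichiometry_table(med, rounded = TRUE)
```

i.e. totals of 1,042 mg/L organic C and 123 mg/L organic N. (The
published description of this medium also quotes 1,146 mg/L organic C
in a comparative passage; the fixture reproduces the breakdown table,
and we surface both numbers here without adjudicating the
discrepancy.) The design target for the C:N ratio is "9:1" without a
stated basis; the package therefore reports all four variants:

```{r}
c(molar_with_NH4 = cn_ratio(med, "molar", TRUE),
  molar_organic  = cn_ratio(med, "molar", FALSE),
  mass_with_NH4  = cn_ratio(med, "mass", TRUE),
  mass_organic   = cn_ratio(med, "mass", FALSE))
```

The molar ratio including the 1 mM ammonium of the salt base is the one
that lands at ≈ 9:1.

**Provenance flags.** Only about 45 of the 64 members are unambiguously
named in the published main text; the authoritative supplementary
membership list is not bundled. Each fixture row carries a `source`
flag: `main_text` rows are the named members; `inferred` rows are
synthetic stand-ins (plausible R2A/soil metabolites) chosen once so
that each tier's elemental sums reproduce the printed breakdown —
citrulline sits in the 525 µM tier and N-acetylmuramic acid in the
17.5 µM tier because those are the only assignments consistent with
the printed tier nitrogen masses (3 N atoms at 525 µM ⇒ 22 mg/L; 1 N
at 875 µM ⇒ 12 mg/L). Analyses that depend on exact membership beyond
the main-text names should treat `inferred` rows as placeholders.

# Growth curves

The growth call is deliberately simple and sharp: after subtracting the
uninoculated-medium control, `delta_od = max(OD) − OD[1]`, and a well
*grew* iff `delta_od ≥ 0.05` (the threshold itself counts as growth).

The kinetic metrics are not part of the growth call and use a standard
construction documented here because several variants exist in the
field: the maximum specific growth rate $\mu_{max}$ is the steepest
slope of a sliding-window ordinary least-squares fit to $\log(OD)$
(default window 5 points), and the lag is where that tangent crosses
the initial log-OD level, clipped at 0. Two guards matter in practice:

* ODs are clipped at `floor = 1e-4` **only** for the log transform;
  `delta_od` always uses raw values.
* Windows containing any OD below `min_od = 0.01` are excluded from
  the rate fit. Blank-corrected readings near zero are dominated by
  reader noise, and because $\mu_{max}$ is a maximum over windows, the
  noise bias is strictly upward; the quantification limit removes it.
  With 15-minute sampling and noiseless logistic curves, recovery of
  $\mu$ is within 10% across 0.1–1.0 h⁻¹ (tested).

`compare_media()` performs per-isolate Welch t-tests on replicate
maximum ODs (the equal-variance assumption has nothing to recommend it
here), adjusts across isolates with Benjamini–Hochberg, and reports
`log2(mean_A/mean_B)`. Isolates lacking two replicates in either medium
are excluded with a warning, never silently.

# Exometabolite profiles

The pipeline order is: blank-ratio filter → blank subtraction →
normalisation → fold-changes → significance calls. (Whether blank
handling preceded normalisation in the original protocol is not
documented; this order is fixed here and recorded in the run manifest.)

* `blank_ratio_filter()` keeps a feature only if its maximum non-blank
  abundance is ≥ 10× its maximum extraction-blank abundance (boundary
  kept; zero-blank features always kept).
* `blank_subtract()` removes the per-feature blank mean from all
  samples, clipping at zero, and drops the blank samples.
* `normalize_peaks()` rescales each feature so the **maximum over
  uninoculated-control samples is exactly 100**; values are
  percent-of-control-max. Features with zero control signal are masked
  (NA), reported, never silently dropped. The operation is a fixed
  point and is invariant to any positive rescaling of a raw feature
  row — so heights and areas can be mixed across features (the
  per-feature `quant_type` is carried through).
* `fold_change()` is `log2(mean_isolate / mean_control)` of normalized
  values, with both means floored at half the smallest nonzero
  normalized value (configurable) so complete depletions stay finite.

## The rank-sum flavour matters at n = 3

Calls use a two-sided Wilcoxon rank-sum test in its **large-sample
normal approximation without continuity correction** (the flavour of
`scipy.stats.ranksums`, reimplemented here):

$$ z = \frac{R_1 - n_1(N+1)/2}{\sqrt{n_1 n_2 (N+1)/12}}. $$

This choice is reproducibility-critical: at $n = 3$ vs 3, complete
separation gives $z = 4.5/\sqrt{5.25} \approx 1.964$, $p \approx
0.0495 < 0.05$, while the exact permutation distribution over
$\binom{6}{3} = 20$ rank assignments can go no lower than $2/20 =
0.10$. Triplicate depletion calls at $\alpha = 0.05$ are therefore
*only* reachable with the approximation; an exact test would call
nothing. Both flavours are implemented (`ranksum_test(method =
"exact")` enumerates) and the pair of p-values is asserted in the test
suite. Calls use raw p-values (no multiple-testing correction),
matching the convention of targeted panels where each metabolite is a
pre-registered hypothesis; the p-matrix is exposed for anyone wanting
BH-adjusted calls. A significant pair is `depleted` or `produced`
according to the sign of its fold-change.

## Clustering

Bray–Curtis dissimilarity is undefined for negative input, yet
utilization heatmaps display log2 fold-changes. The package therefore
**clusters on per-isolate mean normalized abundances** (non-negative,
0–100) with `vegan::vegdist`, while fold-changes remain the display
quantity; both matrices are emitted. Passing negative values is an
error that says exactly this. Linkage defaults to UPGMA (`average`)
and is configurable; leaf order is deterministic given the input.

# Phylogenetic niche conservatism

`patristic_distances()` (path-length sums via `ape`, with a
brute-force path-enumeration oracle in the tests) supplies the x-axis;
`profile_distances()` — Euclidean distance between isolate log2
fold-change profiles — the y-axis. A scatter-plot regression over the
$n(n-1)/2$ pairs is reported for display parity, but pairwise
distances are not independent observations, so the defensible test
attached to it is a Mantel-style permutation: labels of one matrix are
permuted `n_perm` times and

$$ p = \frac{\#\{\rho_{perm} \ge \rho_{obs}\} + 1}{n_{perm} + 1}, $$

with Spearman's ρ (midranks) as the statistic. An alternative y-axis
using cophenetic distances from the Bray–Curtis dendrogram is provided
(`cophenetic_profile_distances()`) since "distance between the
clusterings" is sometimes constructed that way; Euclidean is the
default. `group_conservatism_test()` compares within-family versus
between-family pairwise Spearman correlations with a one-sided
rank-sum test (within > between). Pairwise profile correlations carry
Bonferroni adjustment over the number of pairs.

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
validated; its defaults are fixed, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| isolates × metabolites | 30 × 64 | dimensions of the motivating screen |
| replicates / controls / blanks | 3 / 18 / 3 | triplicate cultures, pooled control batches |
| σ_phylo / σ_noise | 1 / 0.2 | ratio 5 = "strong phylogenetic signal" regime |
| abundance CV | 0.2 | typical targeted LC-MS replicate variation |
| blank fraction | 0.05 | background well below the 10× filter |
| production probability | 0.02 | occasional secretion events |

Trees come from a forward Yule process (exponential waiting times,
uniform lineage choice, ultrametric by construction). Traits evolve by
Brownian motion along the tree — per-edge increments
$N(0, \sigma_{phylo}^2 \ell)$ — plus independent leaf jitter
$N(0, \sigma_{noise}^2)$, and are mapped through the logistic to
depletion fractions in (0, 1); the induced covariance contract

$$ E[(x_i - x_j)^2] = \sigma_{phylo}^2 d_{ij} + 2\sigma_{noise}^2 $$

is the module's core statistical guarantee and is verified by Monte
Carlo. Peak abundances are control level × (1 − depletion) (or ×
production fold) with mean-one log-normal noise; growth curves are
three-phase logistics with explicit lag and additive Gaussian noise.
Family labels for the group test are clades cut at a fixed fraction of
tree height, so they are ground-truth-consistent by construction.

Every stochastic routine takes an explicit seed and restores global
RNG state; identical configuration and seed give byte-identical
outputs (tested down to file hashes through `run_pipeline()`).

**What the generator does not emulate** — and hence what passing tests
do *not* show about real data: retention-time drift and integration
error, batch effects beyond a flat blank background, censoring at the
detection limit, correlated noise across metabolites sharing a
pathway, non-Brownian trait evolution (selection, saltation), and
chimeric/contaminated cultures. Results on synthetic data bound what
the statistics can do under their own assumptions, nothing more.

## Validation sizes

The packaged validation uses sizes chosen for statistical headroom at
about a minute of runtime each: 200 independent end-to-end replicates
for Mantel power and call recovery at the strong-signal condition;
4,000 zero-signal tests (2,000 metabolites × 2 isolates at n = 5 vs 5)
for type-I calibration, where the discrete null rejection rate of the
uncorrected normal approximation is 14/252 ≈ 0.056; 500 runs for
Mantel-p uniformity (Kolmogorov–Smirnov); and 20,000 trait replicates
for the Brownian contract, at which the Monte-Carlo standard error
(~1%) sits well inside the 5% assertion band — at the 2,000-replicate
minimum the 3.2% standard error would make a 5% band a coin flip.

# Design decisions that were genuinely open

* **Tier membership of two compounds** (citrulline,
  N-acetylmuramic acid): resolved by stoichiometric back-calculation
  from the printed tier nitrogen masses, flagged per row.
* **C:N basis**: all four variants reported rather than guessing one.
* **t-test variant** for medium comparison: Welch, as the variance
  homogeneity across media is implausible; the published variant is
  unstated.
* **µ_max/lag construction**: log-linear sliding window with
  tangent-intercept lag — the simplest estimator that is standard,
  parameter-transparent and testable against generated curves; no
  Gompertz/Baranyi fitting (out of scope, could be added).
* **Rank-sum flavour**: normal approximation without continuity
  correction, for the small-n reproducibility reason above.
* **Clustering input**: mean normalized abundances, because
  Bray–Curtis on log2 values is ill-defined.
* **Mantel p attached to the pairwise regression**, because distance
  pairs are not independent.
* **No shell executable**: the package functions plus the numbered
  driver scripts under `analysis/` are the interface; `run_pipeline()`
  provides the one-call, manifest-writing entry point.

# Known limitations

Masked metabolites (zero control signal) are excluded from distance
computations in complete-case mode; with heavy masking, use
`pairwise_complete = TRUE` and note the caveat above. The exact
rank-sum enumeration is limited to small samples by design. The lag
estimate degrades when the first reading is already inside the
exponential phase, and `compare_media()` treats replicates as
exchangeable (no plate/batch random effects). The medium fixture's
`inferred` rows are stoichiometric placeholders, not a claim about the
true supplementary membership list.
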