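---
title: "Dynamic brain functional redundancy: models, conventions and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain functional redundancy: models, conventions and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The redundancy construct

A functional brain network is *redundant* when region pairs are joined by
multiple independent pathways, so that information can be re-routed if one
route degrades. `redunet` operationalises this on the *dynamic* functional
connectome: each sliding-window correlation matrix is reduced to a family of
binary graphs across connection densities, and a window counts as redundant
when the network holds two independent pathways between every region pair
already at the lowest density at which it holds one. Brain functional
redundancy (BFR) is the fraction of time spent in that state. BFR is then
used as a candidate moderator of the association between structural
brain-change measures and cognitive performance — the statistical signature
of cognitive reserve.

## Pipeline stages and their parameters

### Sliding-window dynamic FC

* `drop_initial` (default 4 volumes): discards pre-steady-state volumes, so
  204-volume acquisitions leave 200 analysed volumes.
* `window_volumes` (default 50) and `step_volumes` (default 1): with TR = 3 s
  the default window spans 150 s, long enough to capture BOLD fluctuations
  near 0.01 Hz, short enough to resolve state dynamics. The count law
  `floor((T − w)/s) + 1` gives 151 windows per 200-volume session, 101 at
  the 100-volume sensitivity setting, and 147 for 196-volume sessions —
  unequal session lengths are handled by the formula, with no padding.
* Windows are raw Pearson correlations: no detrending, filtering or global
  signal regression is applied inside the window. A region that is constant
  within a window raises an error naming the region rather than silently
  yielding NaN, because a NaN would corrupt the threshold rank order
  downstream.

### Density-scanned k-connectedness labeling

* `density_grid()` (default 0.05–0.95 in 0.05 steps, 19 values). At density
  *d* the `round(d · P)` strongest of the `P = n(n−1)/2` off-diagonal edges
  are kept and binarised. Rounding is half-away-from-zero, matching the
  convention of the standard proportional-thresholding implementations.
* Edge ranking uses the *signed* correlation by default (strongest positive
  edges first), the common practice for proportional thresholding of
  functional connectomes; `rank_mode = "absolute"` is available for
  sensitivity analysis. Ties are broken by lexicographic node-pair order.
  Fixing the ranking has an important structural consequence: edge sets are
  *nested* across the grid, so k-connectedness is monotone in density,
  `d₂ ≥ d₁` always holds, and results are deterministic even under massive
  ties.
* "Independent pathways" are internally vertex-disjoint paths, so
  one-connectedness is graph connectedness and two-connectedness is
  biconnectivity (connected with no cut vertex) by Menger's theorem. Both
  are checked in linear time (connected components; articulation points)
  rather than by all-pairs path counting; the equivalence is enforced in the
  test suite against a unit-capacity max-flow oracle on the split-node
  transform (`count_independent_paths()`). An edge-disjoint variant
  (`mode = "edge"`, two-edge-connectivity via bridges) is provided for
  sensitivity analysis.
* The scan runs from sparse to dense and stops at the first k-connected
  density. Because edge sets are nested, the k = 2 scan resumes from `d₁`
  instead of restarting at 0.05 — an efficiency choice that cannot change
  the result. If a window never reaches one-connectedness on the grid
  (impossible at the default grid for realistic sizes, but possible on
  truncated grids), both densities are reported absent, the label is 0, and
  `bfr_score()` emits one aggregated warning per call rather than one per
  window.

### Cognitive component scores

* Complete cases only: rows with any missing test are dropped *before*
  z-scoring, so means and SDs refer to the analysed sample. Z-scoring uses
  the n−1 denominator.
* PCA is computed by `stats::prcomp` on the standardized scores (equivalent
  to the correlation-matrix decomposition). Each loading column is
  sign-flipped so its largest-magnitude coefficient is positive; component
  signs are otherwise arbitrary and do not affect variances or moderation
  results.
* The retained count is the chord-distance elbow: the scree index with
  maximal perpendicular distance to the straight line joining the first and
  last scree points, ties going to the earliest index. Distances are
  computed in raw (index, variance-%) coordinates without axis
  normalization.
* Components are labeled by category coverage: for each category of size k,
  the fraction of the component's k largest-|loading| tests falling in that
  category; the best-covered category wins, and an exact tie raises an
  error from `label_components()` (the pipeline wrapper `cognitive_pca()`
  downgrades this to a warning with placeholder labels, leaving the call to
  the analyst). Lower-is-better tests (Trail Making) enter as-is with no
  reversal — their loadings simply change sign.

### Moderation regressions

* GM volume is normalized to total intracranial volume (a ratio in (0, 1))
  to correct for head size; cortical thickness and brain age enter in their
  native units.
* Subjects with maximum displacement strictly greater than 2.5 mm are
  excluded; a value exactly at the threshold is retained.
* Each model regresses the retained component scores jointly on brain
  change, BFR, their product, and site and sex indicators, with
  chronological age added by default only in the brain-age model (to absorb
  the age bias of brain-age predictions); `include_chron_age` reruns the
  other models with age for sensitivity. Predictors are *not* mean-centered
  before forming the interaction, matching the plain regression formula.
  The multivariate fit is per-outcome OLS on the shared design — point
  estimates are identical to the joint multivariate fit — and the joint
  residual covariance is reported for completeness; no MANOVA statistic is
  computed. p-values are two-sided t tests with residual degrees of
  freedom, reported uncorrected.
* A condition-number guard (κ > 1e10) rejects near-collinear designs, and
  fits require at least 10 more observations than predictors.
* Display splits: `mean_split()` assigns values ≥ mean to "high";
  `threshold_split()` cuts BFR at 0.30 by default (values at the cut go
  high) and reports per-group slopes of outcome on brain change.

## The synthetic cohort: what it emulates, and how

The generator exists so that every downstream stage has computable ground
truth. It emulates: two sessions per subject of ~200 analysed volumes at
TR = 3 s; latent alternation between a redundant and a fragile connectivity
state; a 13-test battery driven by three latent domains; brain-change
measures linear in age; a right-skewed motion summary; and outcomes from a
linear model with a known brain-change × BFR interaction.

### The two connectivity states

The redundant state must threshold to a network that is two-connected at
the same grid density at which it first becomes connected; the fragile
state must connect strictly before it biconnects. Designing covariances
that do this *through 50-volume sampling noise* is the delicate part: the
Pearson estimate of a correlation from 50 volumes has a standard error of
roughly 0.10–0.15, which scrambles edge rank order near the density quota.
Sparse scaffolds (a ring with chords, or clique communities joined by a few
designated bridges) fail in practice — the scaffold's weakest vertex or the
last bridging community attaches with a single edge one grid step before
its second, producing a cut vertex exactly at the connection density.

The implemented redundant state uses a *two-community burst-merge* design:

* Two communities of regions each share one community signal, with
  independent per-region measurement noise of variance `1/snr`. All
  within-community correlations sit at the snr ceiling
  (`snr/(snr+1) ≈ 0.91` at the default snr 10) in a tight band, so both
  community subgraphs complete — and are internally biconnected, being
  near-cliques — well before any between-community edge enters.
* The two community signals are coupled through a global component
  (`ρ = 0.35`), so every cross-community pair sits in a single uniform
  lower band. Because nothing else occupies that value range, once the
  density quota exhausts the intra-community edges the next grid step
  admits several cross edges *at once* (about five at n = 20): the network
  connects and biconnects at the same grid density.
* Three designated cross-community pairs carry a small extra shared signal.
  They are vertex-disjoint by construction, which makes the *population*
  correlation matrix two-connected at its own connection density even under
  the deterministic lexicographic tie-break, and biases the sampled merge
  toward disjoint bridges.

The fragile state is an AR(1) chain (φ = 0.7) over a seeded random region
order: a spanning path whose correlations decay geometrically with chain
distance. Its tight first band is exactly the n−1 path edges, so the
thresholded network connects as a tree (or a near-tree with a dangling
end), which can never be biconnected at its connection density.

At the study conditions (20 regions, 200 volumes, snr 10, window 50) the
full pipeline labels ~96% of all-redundant windows 1 and ~97% of
all-fragile windows 0, a mean BFR separation of ~0.94. State blocks switch
only at block boundaries (`n_volumes` must divide into equal blocks), so
ground-truth labels are unambiguous for windows inside one block; windows
straddling a switch carry no truth and dilute measured BFR toward the
middle, which is why `gen_cohort()` allocates each subject's redundant
blocks deterministically as `round(bfr_true × blocks)` at seeded positions.

### The cognitive battery

A naive three-factor model with i.i.d. noise produces a scree that
collapses after the third component, and the chord-distance elbow then
lands on the first tail point (index 4), not 3. Real batteries decay
gradually. The default battery is therefore calibrated structurally: domain
loadings were fitted numerically so that the *population* eigen-spectrum of
the simulated battery is 41.7 / 16.3 / 9.0 / 6.8 / 5.5 % for the top five
components with a slowly decaying tail. The structure comprises a dominant
episodic axis (on which the executive tests carry a small cross-loading, as
executive tasks do in practice), a semantic factor, a weak executive
factor, two test-family method factors (the seven NIH-toolbox tests; the
three Verbal Paired Associates outcomes), and per-test noise standardizing
each test to unit variance. At n = 260 this yields a 3-component elbow with
correctly labeled domains in ~93% of seeds. `gen_cognitive_scores()`
accepts custom loadings, factor SDs, per-test noise and optional method
factors for degenerate cases (e.g. a rank-1 battery).

### Subject-level measures

Age is uniform over 18–89 years. Cortical thickness declines linearly with
age around 2.9 mm with 0.08 mm residual SD; GM volume is generated as a
declining fraction of a ~1.5 L TIV; brain age is chronological age plus
5-year noise; maximum displacement is log-normal (median 0.8 mm, log-SD
0.6), putting ~3% of subjects past the 2.5 mm exclusion. The ground-truth
BFR is partly age-driven (weight 0.5 by default), so BFR and brain change
covary — required for the supplementary observation that adding
chronological age attenuates BFR effects, which the test suite asserts as
attenuation, not as a significance change.

### What the generator does not emulate

No haemodynamic response, scanner noise spectra, physiological artifacts,
spatial autocorrelation, site-specific acquisition differences (site is a
pure binary covariate), or realistic regional topography. Passing tests
demonstrate that the *algorithms* behave as specified on data with known
structure — not that the biological claims hold on real data, nor that real
cohorts occupy any particular BFR range (the empirical BFR distribution of
real cohorts is unknown to this package; generator defaults were chosen for
state separability).

## Numerical conventions and degenerate inputs

* Edge quota: `floor(d·P + 0.5)` (half away from zero). Grid densities are
  rounded to 10 decimal places at construction to avoid floating-point
  drift in `seq()`.
* All tie-breaks (threshold ranking; elbow ties) are deterministic and
  documented above; identical inputs give bit-identical outputs everywhere,
  and every random routine takes an explicit integer seed (child seeds are
  derived with fixed multipliers modulo 2³¹−1).
* Correlation matrices are symmetrised (`(C + t(C))/2`) before ranking to
  remove BLAS asymmetry at the 1e-16 level.
* Degenerate inputs error early with named offenders: constant regions in a
  window, constant battery columns, non-positive volumes, GM ≥ TIV,
  missing displacement values, unmapped test names, near-collinear designs.

## Problem sizes used by the tests

The suite validates the labeler's graph theory against enumeration and
max-flow oracles on graphs of up to 12 nodes (250 random graphs), the
generator separation on 20-region, 200-volume sessions over 20 seeds per
state, recovery of the moderation coefficients at n = 260 over 200
replicates (with a 500-replicate type-I-error check), and the full pipeline
on a 40-subject cohort of 14-region sessions. These sizes were chosen to
exercise every code path at comfortable interactive runtimes; all scale
linearly if enlarged.

## Known limitations

* The labeler's per-window decision is intrinsically sensitive to sampling
  noise near the density quota; window labels on real (non-synthetic) data
  should be interpreted in aggregate (the BFR score), not individually.
* The elbow rule is a heuristic; on spectra without a clear knee it can
  oscillate between adjacent indices across samples.
* Site and sex enter as single binary indicators; multi-site cohorts with
  more than two sites need dummy recoding upstream.
* The reference category for site/sex is whichever level is coded 0 in the
  input; coefficients change sign accordingly.
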