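---
title: "Methods: nanoscale cluster analysis, colocalisation and single-molecule dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: nanoscale cluster analysis, colocalisation and single-molecule dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucleopol)
```

nucleopol implements the quantitative pipeline used to characterise the
nanoscale organisation of nuclear proteins — prototypically myosin VI and
RNA polymerase II — from single-molecule localisation microscopy (STORM)
coordinate tables, and the dynamics of the same molecules from 3D
single-particle tracks. This vignette describes the models, the parameters
that matter, the synthetic-data generators used for validation, and the
numerical decisions taken where the methodology left the design open.

## Point-pattern analysis

### Ripley's K and L(r) − r

For `n` localisations in an ROI of area `A`, the empirical K function is

    K(r) = A / (n (n − 1)) * Σ_{i ≠ j} w_ij 1[d_ij ≤ r]

and the variance-stabilised linearisation is `L(r) − r = sqrt(K(r)/π) − r`,
which is zero in expectation under complete spatial randomness (CSR) and
rises above zero at radii where molecules cluster. `ripley_k()` computes
both over a radius grid (default 10–500 nm in 10 nm steps, spanning the
50–250 nm scale at which nuclear protein clusters are reported, with
margin; configurable).

Boundary effects bias the uncorrected estimator low: part of the circle of
radius `d_ij` around a point near the ROI edge falls outside the window.
The default isotropic (Ripley) correction weights each ordered pair by the
reciprocal of the fraction of that circle's circumference inside the ROI
polygon, computed exactly from circle–edge intersection angles. The
CSR-zero property only holds cleanly with the correction on;
`correction = "none"` is retained because the uncorrected estimator is the
natural target for brute-force oracle tests. The weight is capped at 1000
(circumference fraction floored at 1e−3) to keep pathological
boundary-touching pairs from dominating.

The largest radius is restricted to half the ROI's shorter extent: beyond
that, circles escape the window on both sides and the correction itself
becomes unreliable.

### The clustering peak and its significance floor

`peak_radius()` reports the radius maximising L(r) − r, with ties broken
toward the smaller radius for determinism. A subtlety: at any finite `n`,
sampling fluctuations push a CSR curve slightly positive somewhere, so
"no peak when the curve never exceeds zero" would almost never trigger.
Under CSR the standard deviation of the L(r) − r estimator is
approximately `sqrt(A / 2π) / n`, independent of `r`; a peak must exceed 3
of these standard deviations to count (`min_peak = 0` restores the strict
non-positivity rule). Genuinely clustered patterns produce peaks tens of
nanometres high, orders of magnitude above the floor.

### DBSCAN cluster detection

`detect_clusters()` applies DBSCAN with the field's parameterisation:

* `epsilon` — the neighbour search radius. Default: the mean localisation
  precision of the analysed table (typically 20 nm for Alexa-Fluor 647,
  30 nm for Alexa-Fluor 488), the convention of setting the search area to
  the dye's localisation precision. The alternative convention of taking
  `epsilon` from the Ripley peak radius is implemented in the pipeline as
  `epsilon_from = "ripley"`; published descriptions of the workflow state
  both, so neither is asserted — every report records which policy was
  used.
* `min_pts = 3` — a molecule is a core point if at least 3 *other*
  molecules fall within `epsilon`. The neighbour count excludes the query
  point itself, reading "a minimum of three molecules within a search
  area" as three molecules found around a seed.
* `min_cluster_size = 10` — density-connected groups below 10
  localisations revert to noise.

Border points join the first cluster that reaches them in ascending-index
scan order, making labels deterministic across runs and platforms;
permuting input rows can renumber clusters but never changes memberships.

### Cluster area

The reported cluster area is the area of the iso-density contour of a
Gaussian kernel-density surface (bandwidth `smoothing_sigma = 7` nm) at
the level that encloses every member, counted on a 5 nm evaluation grid.
With fewer than 5 members a KDE contour is ill-defined and the convex
hull is used; collinear member sets are flagged degenerate with area 0
and a warning. Whether published "cluster area" figures are hull,
contour, or occupied-pixel areas is generally not stated; the contour
choice is documented here, not asserted as the field's single convention,
and contour areas run larger than hull-based figures for the same
clusters because the enclosing level must reach the outermost member.

## Coordinate-based colocalisation (DoC)

For each molecule `i` of channel A (symmetrically for B), density
gradients are formed over concentric shells `r = r_step, 2 r_step, …,
r_max` (defaults 20 nm and 500 nm, the established defaults of the
reference workflow):

    D_A,i(r) = N_A,i(r) / N_A,i(r_max) * r_max² / r²
    D_B,i(r) = N_B,i(r) / N_B,i(r_max) * r_max² / r²

The score is the Spearman rank correlation of the two vectors, damped by
the distance to the nearest other-channel molecule:
`DoC_i = S_i exp(−d_i / r_max)`, giving values in [−1, 1]: 1 is perfect
colocalisation, −1 segregation. A molecule is colocalised when its score
exceeds the threshold (default 0.4).

Numerical decisions:

* **Ties and rounding.** Spearman uses average ranks; ties are common
  because shell counts are small integers. The per-vector factors
  `1/N(r_max)` and `r_max²` cannot change ranks, so ranking is done on
  `N(r)/r²` computed as a single correctly-rounded division — equal
  rationals then compare equal, whereas the chained product splits exact
  ties by rounding order and destabilises the correlation.
* **Coincident points.** Other-channel detections at exactly zero
  distance from the query are treated as the same molecule's correlate:
  they are excluded from the density-gradient counts but still set the
  damping distance (d = 0, damping 1). This makes an exact coordinate
  copy of a channel score exactly 1 — the defining identity of the method
  — and has measure-zero effect on continuous coordinates.
* **Degenerate gradients.** Molecules with no same- or other-channel
  neighbour within `r_max`, or a constant gradient vector, get score 0
  and are flagged rather than NaN, keeping percentage denominators
  well-defined.

A cluster is "colocalised" when it holds at least `min_coloc_in_cluster`
(default 5) flagged members; published analyses do not define this
membership count, so it is an exposed parameter rather than a claimed
fact.

## Single-particle tracking

`compute_msd()` evaluates the time-averaged mean squared displacement
over all overlapping pairs at each lag, excluding pairs that span missing
frames. `fit_anomalous()` fits

    MSD(τ) = 2 d D τ^α

by linear least squares on the log–log form over the first 25% of
available lags (minimum 3, maximum 10) — the usual compromise: short lags
carry the least statistical noise but a fixed small count wastes data on
long tracks. The log-linear fit is deterministic, needs no initial guess,
and inverts noiseless power laws exactly; no localisation-error offset
term is included by default because the source analysis fits the bare
power law. Mobility classes partition on D alone: static
(D < 0.1 µm² s⁻¹), diffusive (0.1 ≤ D ≤ 5), hypermobile (D > 5). The
strict published inequalities leave the boundaries open; both closed on
the diffusive side here, documented rather than guessed. Per-cell
summaries report the static fraction and a mean D that excludes
hypermobile tracks (they are reported but not quantified in the source
workflow; `include_hypermobile = TRUE` overrides).

`link_tracks()` provides greedy nearest-neighbour frame-to-frame linking
under the stated constraints (400 nm maximum displacement, 10-frame
minimum). It reproduces the constraints, not any particular tracking
package's cost function — adequate for well-separated emitters, not for
dense crossing trajectories.

## Enzyme kinetics and CD

`fit_atpase()` fits the actin-activated steady-state ATPase model

    rate = V0 + kcat [actin] / (K_actin + [actin])

by bounded Levenberg–Marquardt least squares (all parameters
non-negative: rates and binding constants are physical, and unbounded
fits on small noisy titrations wander negative). Initial guesses are
V0 = min rate, kcat = max − min, K_actin = the concentration nearest the
half-rise. Units are fixed — µM for concentrations, s⁻¹ for rates — with
conversions kept at the I/O boundary. `mean_residue_ellipticity()`
applies the standard CD normalisation
`θ_MRW = (MW/(n−1) θ) / (10 l c)`.

## Synthetic data: what it emulates, what it does not

The generators exist so every stage is testable by parameter recovery
against known ground truth; truth labels ride along as attributes and are
never read by analysis code.

* `simulate_clustered()` draws a Thomas process: uniform cluster centres,
  Poisson per-cluster counts, isotropic Gaussian offsets, a uniform
  background making up `background_fraction` of molecules, plus Gaussian
  localisation jitter. Defaults target the measured nuclear myosin VI
  regime — 504 clusters of ~64 molecules in a 10 × 10 µm ROI with 81% of
  molecules clustered (background 0.19). The background fraction is a
  free parameter because the measured "% clustered" conflates true
  background with detection-level effects. `cluster_sigma` defaults to
  15 nm, putting the cluster core at the reported few-tens-of-nanometres
  scale.
* `simulate_two_channel()` shares a chosen fraction of channel-B cluster
  centres with channel A, displaced by Gaussian noise; the realised
  shared share is recorded exactly.
* `simulate_tracks()` draws fractional Brownian motion with Hurst
  exponent α/2, scaled so the ensemble MSD is exactly `2 d D τ^α`
  (α = 1 reduces to independent Gaussian steps), with per-frame Gaussian
  localisation error. fBm is the standard stationary-increment process
  with the fitted power-law MSD; it is a modelling choice, not a claim
  about the biological mechanism of anomalous diffusion. Mixtures assign
  deterministic per-component track counts so recorded fractions are
  exact. Defaults mirror the live-cell acquisition: 3D, 32 ms frames,
  20 nm localisation error, 100-frame tracks.
* `simulate_atpase()` evaluates the kinetic model with Gaussian noise.
  kcat defaults to 5.5 s⁻¹ (the wild-type myosin VI value); V0 =
  0.04 s⁻¹ and K_actin = 3 µM are literature-typical placeholders because
  the source titrations report only kcat.

A single integer seed drives named sub-streams (centres, counts, offsets,
background, jitter…), so adding draws to one stream never perturbs
another and results are stable under refactoring.

What the generators deliberately omit: fluorophore photophysics
(blinking, repeated detections of one molecule), camera noise, drift,
chromatic misalignment, 3D structure in the STORM arm, and
density-dependent detection failures. Passing recovery tests therefore
demonstrates that the estimators invert the generative models they
assume, not that those models capture every artefact of real microscopy
data; on real tables, upstream detection grouping and drift correction
are assumed to have been applied by the acquisition software.

## Statistical comparison

`compare_conditions()` implements the plain two-tailed two-sample t test
with pooled variance, each ROI contributing one observation (the
convention of treating per-cell averages as replicates); Welch's form is
available via `welch = TRUE`. Two constant equal groups return p = 1 with
a degeneracy flag. No multiple-testing correction is applied by default,
matching the per-comparison reporting convention of the source analyses;
`stats::p.adjust` composes naturally where correction is wanted.

## Validation scale

The test suite validates each spatial-index implementation against naive
brute-force references (100 random instances of up to 300 points or 50
frames, 1e−9 relative tolerance), calibrates the CSR zero line with 20
replicates of 5,000 points in a 10 × 10 µm ROI (|mean L(r) − r| under
5 nm), and runs parameter-recovery suites at 250 clusters × 60 molecules
(20 seeds) and 200 tracks × 100 frames. These sizes were chosen to give
stable statistics at interactive runtimes; all scale linearly if larger
checks are wanted.

## Known limitations

* The isotropic correction assumes the ROI polygon is simple; very
  concave ROIs with near-touching arms make the circumference-fraction
  weights large and noisy (the 1e−3 floor guards the estimator, not the
  science).
* DoC percentages depend on labelling density in both channels; they are
  comparable across conditions imaged at matched densities, not absolute
  stoichiometries.
* The greedy linker is not a globally optimal assignment; use it for
  sparse fields or import tracks from a dedicated tracker.
* Log–log MSD fitting is biased when localisation error is comparable to
  the per-frame displacement; the fit range rule mitigates but does not
  remove this.
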