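# nucleopol

Quantitative analysis of the nanoscale spatial organisation and dynamics
of nuclear proteins from single-molecule microscopy — the workflow used to
show that nuclear myosin VI anchors RNA polymerase II in high-density
transcription clusters. The package is aimed at microscopists and
quantitative cell biologists who have per-molecule coordinate tables
(STORM/SMLM exports) or 3D single-particle trajectories and need the
standard battery of point-pattern, colocalisation, diffusion and
enzyme-kinetics analyses behind them, plus synthetic-data generators to
validate every stage by parameter recovery.

## What it computes

**Ripley's K and its linearisation.** For localisations in an ROI of area
*A*,

    K̂(r) = A / (n(n−1)) · Σ_{i≠j} w_ij · 1[d_ij ≤ r],     L(r) − r = √(K̂(r)/π) − r

with isotropic polygon edge correction (*w_ij* = reciprocal circle
fraction inside the ROI). L(r) − r is zero under complete spatial
randomness and peaks at the clustering radius.

**DBSCAN cluster detection** with the published SMLM parameterisation:
search radius ε = the dye's mean localisation precision (≈20 nm for
Alexa-647), core points need ≥ 3 other molecules within ε, and a cluster
requires ≥ 10 localisations. Per-cluster areas come from a 7 nm
kernel-density contour (convex hull below 5 members).

**Degree-of-colocalisation (DoC) scoring.** Per molecule, the Spearman
rank correlation of the two channels' density gradients
D(r) = N(r)/N(r_max) · r_max²/r² across 20 nm shells to 500 nm, damped by
exp(−d/r_max) with *d* the nearest other-channel distance; scores ∈
[−1, 1], threshold 0.4, plus the colocalised vs non-colocalised cluster
breakdown.

**MSD / anomalous diffusion.** Time-averaged MSD per 3D track, log–log
fit of MSD(τ) = 2·d·D·τ^α over short lags, mobility classes static
(D < 0.1 µm² s⁻¹) / diffusive (0.1–5) / hypermobile (> 5), per-cell
static-fraction and mean-D summaries; greedy linking under the 400 nm /
10-frame constraints.

**Enzyme kinetics and CD.** Bounded nonlinear least squares for the
actin-activated ATPase model Rate = V₀ + k_cat[actin]/(K_actin+[actin]),
and mean residue ellipticity θ_MRW = (MW/(n−1)·θ)/(10·l·c).

**Synthetic data.** Seeded Thomas-process patterns, two-channel patterns
with a controllable colocalised fraction, fractional-Brownian-motion
track mixtures with exact MSD scaling, and kinetics titrations — each
carrying ground truth for recovery tests.

## Worked example

```r
library(nucleopol)

## --- STORM cluster arm: one nucleus-scale channel --------------------
roi <- roi_rect(10000)                          # 10 x 10 um ROI, nm units
mvi <- simulate_clustered(pattern_spec(seed = 7), channel = "MVI")
mvi <- clip_to_roi(mvi, roi)

ripley_k(mvi, roi)
#> Ripley curve: 39938 points, isotropic correction, r in [10, 500] nm
#>   peak L(r)-r = 132.1 nm at r = 80 nm

cs <- detect_clusters(mvi, cluster_params())    # epsilon = mean precision
summarize_clusters(cs, mvi)
#> Cluster summary: 463 clusters, 76.8% of molecules clustered
#>   mean 66.3 molecules/cluster, mean area 6564 nm^2
```

The pattern was generated in the measured nuclear myosin VI regime
(~500 clusters of ~64 molecules, ~80% clustered); the detector recovers
463 clusters of 66.3 molecules with 76.8% clustered, and the Ripley curve
peaks at 80 nm — clustering at the sub-residual-scatter scale of the
generator. With real exports, replace the simulated table by
`read_localizations("table.csv", dialect = "zeiss")` (or
`"thunderstorm"`) and an ROI drawn around the nucleus.

```r
## --- two-channel colocalisation --------------------------------------
tc <- simulate_two_channel(two_channel_spec(
  pattern_spec(n_clusters = 120, seed = 1),
  pattern_spec(n_clusters = 120, seed = 2),
  coloc_fraction = 0.25, seed = 3))
doc_scores(tc$a, tc$b)
#> DoC result: 32.7% of channel A and 34.9% of channel B colocalised (threshold 0.4)

## --- live-cell tracking arm -------------------------------------------
tracks <- simulate_tracks(track_sim_spec(
  seed = 11,
  mixture = list(list(weight = 0.52, D = 0.03, alpha = 0.7),   # anchored
                 list(weight = 0.48, D = 0.8,  alpha = 1))))   # diffusing
summarize_mobility(fit_tracks(tracks))
#> Mobility summary: 200 tracks, mean D = 0.404 um^2/s, 52% static / 48% mobile

## --- ATPase titration --------------------------------------------------
fit_atpase(simulate_atpase(kinetics_sim_spec(seed = 4)))
#> ATPase fit: V0 = 0.0334 s^-1, kcat = 5.71 s^-1, K_actin = 3.34 uM (rss 0.0149)
```

The mobility summary reads as: of 200 classified tracks, 52% fall below
the 0.1 µm² s⁻¹ static threshold (the generator's anchored share was
0.52), and the mean diffusion coefficient over static + diffusive tracks
is 0.404 µm² s⁻¹. The kinetics fit recovers the generating
k_cat = 5.5 s⁻¹ to within the injected measurement noise.

`run_storm_pipeline()` chains clip → Ripley → DBSCAN → DoC → breakdown
for one or two channels and writes all tables, summaries and the resolved
configuration to an output directory; `compare_conditions()` applies the
per-ROI two-tailed t test used for condition comparisons. A thin CLI over
the same functions ships in `inst/scripts/nucleopol.R`, and small
synthetic example CSVs in `inst/extdata/`.

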