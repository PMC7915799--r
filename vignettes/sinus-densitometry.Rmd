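---
title: "Densitometric and discriminant analysis of maxillary sinus CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Densitometric and discriminant analysis of maxillary sinus CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sinudens)
```

This vignette is the package's own account of the science it
implements: the models, the assumptions behind them, the tunable
parameters, and the design decisions taken where the method left room.

## 1. The diagnostic problem

Odontogenic maxillary sinusitis arises when dental infection, root
fragments, filling material or implants breach the sinus floor. On CT
the relevant signs are quantitative: the density of any effusion
(serous exudate reads near 19 Hu, purulent near 37 Hu), the fraction of
the cavity occupied by fluid or by mucosal/polypous soft tissue, the
patency of the ostium (the drainage opening into the middle meatus),
and — functionally — the aerodynamic resistance of the nasal airway,
which rises when the sinus disease causes reactive mucosal swelling.
The package turns each sign into a number and the numbers into a
diagnosis, with every stage testable on synthetic volumes of known
composition.

## 2. Densitograms and signature rules

A densitogram is the intensity profile along a line between two pixels
of a slice, sampled at the parametric positions `t = 0, 1/d, 2/d, ...`
plus `t = 1`, where `d` is the segment length in pixels — about one
sample per pixel of path. Fans of such profiles are cast radially from
the sinus centre (the centroid of interior-class voxels, rounded to a
voxel) over the *downward* semicircle of a coronal-plane slice, because
gravity-dependent content, the sinus floor and dental lesions all live
in the lower hemisphere. The default fan has 13 rays (15° spacing), a
choice balancing angular coverage against redundancy at typical sinus
radii of 20–30 pixels; the count is a parameter, not a constant of the
method.

Each profile is classified by ordered rules (most specific evidence
first); all thresholds sit on the Hounsfield scale and must be restated
if profiles are taken from windowed 8-bit volumes:

| parameter | default | meaning |
|---|---|---|
| `t_air` | −500 Hu | upper bound of an aerated-cavity sample |
| `t_tissue` | 0 Hu | lower bound of soft-tissue/fluid content |
| `t_bone` | 300 Hu | lower bound of a bone-wall sample |
| `t_foreign` | 1500 Hu | lower bound of foreign-body material |
| `prominence` | 200 Hu | bone peak must exceed the plateau median by this |
| `min_plateau` | 3 samples | shortest run that counts as content |

The rules: a sample at or above `t_foreign` anywhere means
FOREIGN_BODY; a content plateau with *no* qualifying bone peak means
PERFORATION (the wall is missing along that ray); at least two upward
crossings of `t_tissue` before the bone peak mean CYST (the cyst wall
adds a border inside the cavity); one crossing with a bone peak is
TISSUE_CONTENT; an air-level interior with a bone peak is NORMAL.
Samples beyond the first bone-peak sample are ignored, so lengthening
rays past the sinus wall cannot change the call. Per-ray signatures are
aggregated by the same priority order, with a minimum-support parameter
(default 1 ray) to suppress single-ray artifacts if desired.

The intensity cut-offs are engineering defaults chosen from CT tissue
ranges (air ≈ −1000 Hu, effusions and mucosa 0–100 Hu, cortical bone
several hundred, metal/dental material above 1500); the underlying
method describes the shapes of the profiles but publishes no numeric
thresholds, so these are deliberately exposed in `profile_thresholds()`
rather than buried.

## 3. The five indicators

* **x1, fluid density (Hu)** — mean Hu over fluid-labelled voxels.
  Strictly requires a calibrated Hu volume; the function refuses 8-bit
  display data rather than guessing an inverse window. Undefined (and
  flagged) when no fluid exists — an empty sinus has no fluid density,
  not a density of zero.
* **x2, ostium opening (%)** — air fraction of a supplied reference
  region (mask) covering the anatomical ostium cross-section or canal.
  The reference region is an input because normal ostium geometry is
  patient-specific; the phantom generator provides its own mask.
* **x3, mucosa volume (%)** and **x4, fluid volume (%)** — class-voxel
  counts over the cavity (air ∪ fluid ∪ mucosa ∪ cyst ∪ foreign body).
  Cystic content counts toward x3 unless requested otherwise: both are
  soft-tissue occupancy of airspace. Relative measures are used
  precisely so that absolute sinus size — the dominant anatomical
  variable between patients — cancels; the tests verify ±2 percentage
  point stability across grid resolutions 48³–96³ of the same anatomy.
* **x5, aerodynamic drag (kPa/(L/s))** — Δp/Q either measured by
  rhinomanometry or predicted by the hydraulic model below.

## 4. The hydraulic airflow model

Each nasal passage is a series of sections with area S, perimeter P
(hydraulic diameter d_h = 4S/P), length Δl and a local-loss
coefficient ξ. The pressure drop is the loss sum

Δp = Σ [λ(Re)·ρ·Δl/d_h + ξ] · Q² / (2S²),

with ρ = 1.205 kg/m³, μ = 1.81 × 10⁻⁵ Pa·s (standard air; the
viscosity is a package default since the method fixes only ρ), and
λ = 64/Re below Re = 2300 and 0.32/Re^0.25 above. Numerical notes:

* The regime threshold 2300 is the classical pipe-flow transition; the
  two-formula friction law itself carries no switch point. Both the
  threshold and the turbulent numerator (printed 0.32 where Blasius has
  0.3164) are configurable.
* Because λ ∝ 1/Q in the laminar regime, the quadratic loss sum is
  automatically linear in Q there and reproduces Hagen–Poiseuille
  128 μ L Q / (π d⁴) exactly for circular tubes — this is the
  cross-check the test suite runs on randomized laminar geometries. A
  notation that writes laminar Δp = Q·A and turbulent Δp = Q²·A is
  thereby subsumed: the package always evaluates the full sum with
  λ(Re) and reports A = Δp/Q² at the evaluated flow.
* The two-passage split solves Δp₁(Q₁) = Δp₂(Q_Σ − Q₁) by root
  bracketing (`uniroot`, relative tolerance 10⁻⁸ on Q₁). Δp is strictly
  increasing in Q for every valid channel, so the root is unique;
  continuity Q₁ + Q₂ = Q_Σ holds by construction and the residual
  pressure imbalance is reported (bounded by 10⁻⁶ relative in tests).
* Local-loss coefficients default to 0 and are user-supplied per
  section: tabulating ξ for nasal anatomy is beyond both the method
  and this package.
* Section geometry is SI internally; x5 is converted to kPa/(L/s) only
  at the reporting edge.

## 5. The discriminant model

Groups are modelled feature-wise Gaussian and independent. For two
groups the per-indicator separation is δ_i = |m_i⁽⁰⁾ − m_i⁽¹⁾| / σ_i
with σ_i = max(σ_i⁽⁰⁾, σ_i⁽¹⁾) — the conservative choice when the
spreads differ — and the multiparameter distance is δ = √Σ δ_i². The
decision-error probability is

per = 1 − Φ(δ/2),

where Φ is the **probability integral**, Φ(x) = erf(x/√2) =
2Φ_normal(x) − 1, so per = 2(1 − Φ_normal(δ/2)). This reading — the
standard one in the Russian-language metrology literature the model
descends from — reproduces the bundled reference (δ, per) pairs
(3.34 → 0.1, 3.78 → 0.06, 3.36 → 0.09, 1.71 → 0.4, 1.98 → 0.32) at
their printed precision, whereas reading Φ as the normal CDF reproduces
almost none of them; `error_probability()` exposes both conventions.

Degenerate spreads need a convention. The healthy-control group has
σ = 0 for fluid volume (no control patient has any fluid): in two-group
comparisons the max rule absorbs this, and in nearest-cluster
classification a zero-spread indicator is skipped when the patient
matches the centre exactly and otherwise makes that cluster's distance
infinite (ranked last, flagged). That is the strict reading of the
metric — any fluid at all is categorically incompatible with a cluster
whose fluid volume never varies from zero.

Incremental curves add indicators cumulatively (default order x1…x5,
unranked, matching how the reference analysis presents them): δ(j) is
non-decreasing, per(j) non-increasing, and δ(5) is order-invariant
because squared distances add over disjoint feature sets.

`classify_patient()` ranks clusters by distance using each cluster's
*own* σ; reported "compliance weights" are a softmax over negative
squared distances — an explicit extrapolation, labelled as such,
since the ranking itself is the defined output. `mahalanobis_distance()`
generalizes the metric to correlated indicators and reduces exactly to
the classification distance for diagonal covariance; with no
patient-level data available, full covariances cannot be estimated
here, which is why the diagonal model is the operational one.

### Reported versus recomputed separations

The bundled fixture carries both the reference group statistics
(means/SDs per group) and the separations (δ, per) reported with them.
Recomputing δ from the printed statistics does not exactly reproduce
the reported δ — e.g. the norm vs acute-serous comparison evaluates to
δ ≈ 3.47 against a reported 3.34 — and one source table (chronic vs
acute purulent) contains evident transcription errors. The package
therefore reports *both* values side by side (`discriminate` CLI,
`reported_comparisons` attribute) and never silently substitutes one
for the other. Three of the eight reported (δ, per) pairs
(3.16 → 0.12, 4.29 → 0.04, 2.18 → 0.31) are inconsistent with the
error formula under either Φ convention and are treated as reference
metadata only.

## 6. The phantom generator

`make_sinus_phantom()` renders a configurable anatomy — all geometry in
millimetres, so the same phantom exists at any grid resolution:

* a spherical air cavity (default radius 10 mm) inside a bone shell
  (default 1.6 mm) in soft-tissue background, on a default 64³ grid at
  0.4 mm isotropic spacing (the in-plane resolution of typical spiral
  CT protocols for this anatomy);
* gravity-layered content: fluid fills the cavity from the bottom to
  the requested volume fraction, polypous (mucosa-class) content layers
  directly above it. The content plane is placed by rank over
  cavity-voxel depth with a deterministic tie-break, which matches the
  requested fraction exactly at voxel resolution;
* optional uniform mucosal lining, spherical cyst, dense foreign body
  (default 2000 Hu), an angular perforation window in the bone floor,
  and a cylindrical ostium channel through the superomedial bone wall
  whose lumen can be narrowed from the wall inward to any open
  fraction;
* Hounsfield rendering from a per-class map (air −1000, serous fluid
  19, purulent 37, mucosa/polyp 45, bone 700, foreign body 2000,
  background 40). The fluid values are the reference cohort means; the
  mucosa, bone and background values are implementation defaults in
  plausible CT ranges, configurable because no reference values exist
  for them;
* optional seeded impulse noise (the generator restores the global RNG
  state afterwards).

The emitted ground truth is computed by counting the emitted labels,
never from the analytic geometry, so it is exact by construction and
independently re-derivable by brute force — which the tests do.

Presets cover the canonical fill configurations used to define the
volumetric indicators — empty (conditional norm), 60 % polypous
(chronic), 40 % fluid (acute serous/purulent), 30 % polypous + 20 %
fluid (exacerbated chronic; the textual definition of that
configuration is followed where its two statements of the percentages
disagree) — plus one archetype per densitogram signature.

**What the phantom does not emulate:** real sinus shape (ellipsoidal,
septated, with recesses), partial-volume blur at tissue interfaces,
scanner noise texture (only impulse noise is modelled), beam-hardening
and metal artifacts, and anatomically realistic airway channels (the
hydraulic model takes section series as input instead). Passing the
phantom suite therefore demonstrates correctness of the *measurement
and decision pipeline*, not clinical performance on real scans.

## 7. Numerical and I/O choices

* **Median filter:** per-slice 2-D filtering (the acquisition is a
  stack of images), window radius 1 by default, mirror-reflected edges
  without duplicating the edge row. Implemented in vectorised R so the
  edge contract is exact.
* **Windowing:** linear map of [center − width/2, center + width/2]
  to 0–255 with clipping and half-up rounding (platform-independent,
  unlike banker's rounding).
* **Slice stacks:** PNG slices plus a JSON sidecar. 8-bit volumes
  round-trip bit-identically; Hu volumes are stored losslessly as
  16-bit offsets split across two 8-bit PNG channels with the rescale
  recorded DICOM-style (slope/intercept). `rescale_to_hu()` implements
  that affine calibration.
* **Coordinates:** 0-based (k, y, x) with x the column and y the row
  (downward), matching the raster convention of the source data;
  trajectory sampling uses half-up rounding for nearest-voxel lookup.
* **Profile reversal:** the sample set {0, Δt, …, 1} is symmetric
  under t → 1 − t only when the trajectory length is an integer, so
  exact reversal symmetry holds for integer-length trajectories and to
  within one sample otherwise.

## 8. Problem sizes and determinism

The test suite and the acceptance script run phantoms at 48³–96³
(default 64³), fans of 13 rays, 20 randomized duct geometries, and
seeded Monte-Carlo cohorts of 200 synthetic patients per group drawn
feature-wise from the reference (m, σ) — sizes chosen so the entire
suite completes in well under a minute while keeping voxelization error
comfortably inside the ±2 percentage-point bands the relative
indicators are tested to. All stochastic steps take explicit seeds;
phantoms are bit-reproducible given their configuration.

In the Monte-Carlo recovery runs, every pathological group is
re-assigned to its own cluster far above the 20 % chance level, and the
residual confusion concentrates between acute purulent and exacerbated
chronic sinusitis — the pair with the smallest reference separation
(δ = 1.71, per = 0.4) — with chronic vs exacerbated chronic (δ = 1.98)
next. That is the behaviour the separability analysis predicts: the
closer the cluster centres in the normalized metric, the likelier the
mix-up.

## 9. Known limitations

* Segmentation is an input, not a capability: clinical use would
  require a tissue labeller upstream of the indicator stage.
* The discriminant model assumes feature-wise independent Gaussians;
  correlations between indicators (e.g. fluid volume and ostium
  blockage) are not modelled for want of patient-level data.
* DICOM series reading and BMP raster input are not implemented; the
  slice-stack format plus the rescale calibration cover the same
  contract for synthetic and exported data.
* The signature thresholds are Hu-scale defaults validated on
  phantoms; windowed 8-bit data needs re-specified thresholds.
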