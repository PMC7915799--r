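# sinudens

Automated preliminary diagnosis of odontogenic (dental-origin) maxillary
sinusitis from CT-like volumes, for ENT/radiology method developers and
for anyone who needs a fully synthetic, ground-truthed test bench for
sinus densitometry.

Odontogenic sinusitis — inflammation of the maxillary sinus seeded from
diseased upper teeth, endodontic material or implants — shows up on CT
as fluid levels, mucosal/polypous thickening, a blocked ostium, cysts,
bone-floor perforations and dense foreign bodies. `sinudens` implements
an automated reading of those signs in four layers:

1. **Densitograms.** Brightness profiles sampled along the parametric
   line x(t) = x_s + (x_e − x_s)·t, y(t) = y_s + (y_e − y_s)·t,
   t ∈ [0,1], step Δt = 1/d with d the segment length in pixels. Radial
   fans from the sinus centre over the lower hemisphere are classified
   by rule into five signatures: NORMAL (air plateau + pronounced bone
   peak), TISSUE_CONTENT, CYST (an additional border inside the
   cavity), PERFORATION (missing bone peak), FOREIGN_BODY (dense
   inclusion).
2. **Five diagnostic indicators.** x1 mean fluid density (Hu); x2 free
   fraction of the ostium (%); x3 mucosa/polyp volume fraction of the
   cavity (%); x4 fluid volume fraction (%); x5 aerodynamic nasal drag
   A = Δp/Q in kPa/(L/s).
3. **Hydraulic airflow model.** The nasal passages as parallel
   sectioned ducts: Δp = Σ [λ(Re)·ρ·Δl/d_h + ξ]·Q²/(2S²), with
   λ = 64/Re laminar and 0.32/Re^0.25 turbulent, d_h = 4S/P, and the
   two-passage flow split solved from continuity Q_Σ = Q₁ + Q₂ under a
   common pressure drop.
4. **Discriminant model.** Groups are separated by the normalized
   Euclidean distance δ = √Σ_i ((m_i⁽⁰⁾ − m_i⁽¹⁾)/σ_i)² with
   σ_i = max(σ_i⁽⁰⁾, σ_i⁽¹⁾); the decision-error probability is
   per = 1 − Φ(δ/2) with Φ the probability integral
   (Φ(x) = erf(x/√2)). New patients are assigned to the
   nearest cluster centre in the same metric.

Because no public dataset exists for this problem, the package ships a
first-class phantom generator: spherical sinus cavities in a bone shell
with configurable fluid level, polypous filling, mucosal lining, cyst,
foreign body, floor perforation and ostium blockage — every voxel
labelled, every indicator known in advance.

## Worked example

Simulate an acute serous sinusitis (40 % serous fluid, ostium three
quarters blocked), measure the indicators, and classify the case
against the bundled reference cohorts:

```r
library(sinudens)

ph <- make_sinus_phantom(phantom_preset("acute_serous",
                                        anastomosis_open_fraction = 0.25))
iv <- extract_indicators(ph$volume, ph$labels, ph$ostium_mask,
                         dp_kpa = 0.79, q_lps = 0.5)  # rhinomanometry
iv
#> diagnostic indicators:
#>   x1 fluid density, Hu        19
#>   x2 ostium opening, %        24.638
#>   x3 mucosa volume, %         0.158
#>   x4 fluid volume, %          39.917
#>   x5 nasal drag A, kPa/(L/s)  1.58

classify_patient(iv, load_group_stats())
#> sinus_classification: winner = acute_serous
#>                                   group distance weight rank
#> acute_serous               acute_serous    1.176      1    1
#> acute_purulent           acute_purulent    3.467      0    2
#> exacerbated_chronic exacerbated_chronic    3.960      0    3
#> chronic                         chronic    5.094      0    4
#> conditional_norm       conditional_norm      Inf      0    5
```

The fluid reads 19 Hu (serous, not the ~37 Hu of pus), the cavity is
40 % fluid-filled with essentially no mucosal thickening, and the
nearest cluster centre — by a wide margin — is the acute serous group.
The healthy-control cluster is ranked last: its fluid-volume spread is
zero, so any fluid at all puts a case infinitely far from it in the
normalized metric.

The two-group separability analysis works the same way:

```r
gs <- load_group_stats()
summary(incremental_curves(gs$conditional_norm, gs$acute_serous))
#> Two-group discriminant comparison: conditional_norm vs acute_serous
#>   j feature delta_i delta  per
#> 1 1      x1    1.97  1.97 0.33
#> 2 2      x2    1.85  2.70 0.18
#> 3 3      x3    0.43  2.73 0.17
#> 4 4      x4    1.70  3.22 0.11
#> 5 5      x5    1.30  3.47 0.08
```

Each added indicator grows the distance and shrinks the error
probability; fluid density and fluid volume carry most of the
separation from the norm. The recomputed five-indicator distance
(δ ≈ 3.47) is reported alongside the reference value bundled with the
cohort tables (δ = 3.34); the two disagree slightly and the package
deliberately surfaces both (see the vignette).

A thin command-line wrapper covers the same pipeline
(`system.file("cli", "sinudens.R", package = "sinudens")`), with
subcommands `phantom`, `convert`, `densitogram`, `indicators`,
`airflow`, `discriminate` and `classify`, each emitting a JSON report.

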