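---
title: "MagLev fingerprinting of nanoparticle protein coronas: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MagLev fingerprinting: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maglevneb)
```

## The measurement principle

Magneto-Archimedes levitation (MagLev) places a diamagnetic object in a
paramagnetic aqueous solution between two permanent magnets facing each
other through like poles. The magnetic body force on the object is
proportional to `(χs − χm) Bz dBz/dz`, the buoyancy-corrected weight to
`(ρs − ρm) g`; the object comes to rest where the two cancel. Because the
rest height depends on the object's density, MagLev acts as a contact-free
densitometer. In the assay modelled here, graphene oxide (GO) nanosheets
incubated with human plasma acquire a protein corona whose composition —
and therefore effective density — differs between donors and disease
states, so the levitation pattern of the corona-coated particles is used as
a diagnostic fingerprint.

The reference device has square NdFeB magnets (2.5 × 2.5 × 5.0 cm) at
separation `d = 2.8 cm` with about `0.5 T` at each face, a 4 mL cuvette in
the gap, and an 80 mg/mL aqueous dysprosium(III) nitrate medium at 25 °C.
Frames are acquired at 1 frame per 20 s for 20 minutes (61 frames including
t = 0).

## Physics module

**Field model.** The default `linear_axial` model takes the signed axial
component `Bz(z) = B0 (1 − 2 z / d)`; its gradient is constant. We adopt it
as the default because the closed-form height

\[ h = \frac{d}{2} + \frac{(\rho_s-\rho_m)\, g\, \mu_0\, d^2}
            {4 (\chi_s-\chi_m) B_0^2} \]

is *exactly* its consequence, so the closed form serves as an algebraic
oracle for the numerical force-balance solver. A `cuboid_analytic` model
(superposition of two analytic cuboid-magnet on-axis fields, rescaled so
`|Bz(0)| = B0`) is retained as a realism check; the two models agree on the
equilibrium height to within a few millimetres across the workable density
range, and exactly at density match (mid-gap, by symmetry).

**Medium susceptibility.** The assay description fixes only the Dy salt
concentration. We therefore compute a reproducible first-principles
default: the Curie law for the Dy³⁺ free ion (μ_eff ≈ 10.6 μ_B) gives a
molar susceptibility of ≈ 5.9·10⁻⁷ m³/mol at 298 K; at 80 mg/mL
(M ≈ 348.5 g/mol, 0.23 M) plus water's diamagnetic background this yields
χm ≈ 1.27·10⁻⁴ SI. Every quantity is config-overridable; χs for GO–corona
complexes and the medium density are free parameters (the assay paper
reports neither), defaulting to −9·10⁻⁶ SI and 1060 kg/m³.

**Out-of-range equilibria** are reported categorically (`precipitates` /
`floats`) rather than clamped: a real sample with an equilibrium below the
cuvette bottom pellets, and the levitating-fraction analysis depends on
that behaviour. The workable density window at the defaults is roughly
ρm ± 190 kg/m³.

## Simulator

Micron-scale aggregates in water at these field gradients are firmly in the
low-Reynolds regime, so the integrator uses overdamped Stokes dynamics
`dz/dt = F(z)/(6π η r)` with η = 0.9·10⁻³ Pa·s (water, 25 °C), explicit
Euler with automatic sub-stepping (no particle moves more than d/100 per
sub-step), and absorbing boundaries at the cuvette bottom and top. The
relaxation time toward equilibrium is `9 μ0 d² η / (8 |Δχ| B0² r²)` —
about 5 minutes for r = 10 µm at the defaults — so a 20-minute run
approaches equilibrium but, like the real assay, is not fully settled for
the smallest aggregates. Brownian motion is omitted by default
(drift-dominated at these sizes; determinism aids testing), and
particle–particle interactions are ignored (dilute limit): aggregation is
emulated through the input density/size distributions instead.

**Rendering.** Frames are `background + Σ Gaussian kernels + N(0, σ)`
noise, with each particle's kernel summing to `intensity_per_volume × V`
(signal conservation while particles remain in view). The default
`intensity_per_volume = 1e18` puts the band roughly two orders of magnitude
above the read-noise floor, an SNR chosen on physical grounds (a visibly
photographed band) — relevant because background subtraction floors
negatives at zero, which biases a noise-dominated profile toward the ROI
centre. Row 1 of every frame is the *bottom* of the gap; the pixel↔mm
calibration travels in a JSON sidecar next to the ASCII PGM frames (a
text-only, standard grayscale format; 16-bit quantization on write).

## Pattern pipeline

For each frame the vertical profile is the row-mean over the ROI columns.
Background is subtracted (floored at zero) using a pre-injection blank
profile when available, else the per-row minimum across the series; the
profile is then normalized to its maximum inside a reference window
(default: the central 60% of the ROI height), which removes exposure/gain
variation exactly — scaling every pixel by k > 0 leaves both fingerprints
unchanged (bit-identically for power-of-two k; to ~1e-12 otherwise, an
IEEE-representability caveat rather than a property of the method).

The assay defines its two fingerprints operationally but not precisely; we
fixed the open choices as follows and exposed each as a parameter:

* **starting position** — the intensity-weighted *centroid* of the first
  processed frame (robust to noise; a `peak` estimator is available). The
  first frame, not an injection frame, is used: image-level generation
  initializes particles near their equilibrium heights, consistent with the
  sample redistributing through the cuvette before acquisition begins. This
  also makes the density→starting-position monotonicity physically
  coherent: denser samples start (and stay) lower.
* **levitating fraction area** — trapezoidal integral of the normalized
  profile at the last acquisition time (20 min), above a sediment-exclusion
  cut defaulting to the bottom 10% of the ROI, which separates the
  levitating band from the pellet. Comparisons of areas *across* runs
  (e.g. halving the particle count) require a common normalization
  constant, provided via `params$norm_value`.

Replicates are averaged component-wise per donor (triplicate design) before
any classification.

## Statistics

Two-class Fisher LDA with pooled covariance and equal priors
(`w = S⁻¹(μ₁ − μ₀)`, threshold at the projected midpoint) matches the
single straight decision line of the assay's published analysis; a
numerically singular pooled covariance is ridge-regularized
(ε = 10⁻⁸·trace) with a warning. Specificity, sensitivity and accuracy
follow the standard confusion-count definitions with NOP (non-oncological
patients) as the negative class; zero denominators yield flagged `NA`s.
Class comparisons use the *pooled-variance* two-tailed Student's t-test
(not Welch — the named test), with raw p-values and no multiple-testing
correction in the heatmap, as in the source analysis. Confidence ellipses
are mean-centred covariance ellipses at the χ²(2 dof) quantile, default
level 0.95 (the published ellipse construction is unspecified). Blind
validation enforces donor-level disjointness by id and binds model and
holdout hashes into the report. The SAXS mass fractal dimension is the
negated slope of the least-squares line in log I–log q.

## Synthetic cohorts: what they emulate, and what a green test means

No fingerprint coordinates, corona densities or images are published for
the real donors, so the generator's class structure is *synthetic by
construction*. Defaults use the study's cohort sizes (15 NOP, 5 breast, 5
prostate, 5 colorectal, 15 PDAC; 3 replicates) and a two-level variance
hierarchy (donor effect + replicate noise at one quarter of the donor
covariance), with class means arranged to mimic the qualitative published
structure: PDAC shifted most in starting position versus controls, breast
shifted oppositely, prostate/colorectal overlapping. Image-level specs map
classes to bimodal density mixtures (a levitating component near the medium
density plus a dense precipitating component), 60 particles per donor,
10 µm lognormal aggregate radii — values chosen once so that, as observed
in the real assay, a large fraction pellets within 20 minutes.

A green test therefore establishes *internal consistency* — the pipeline
recovers what the simulator injected, the classifier achieves the analytic
two-Gaussian Bayes rate, statistics match independent references — not
clinical performance. The published patient-level accuracies depend on
plasma samples that are not deposited and are deliberately not targets; the
demo's metrics describe the stated synthetic world only.

## Numerical choices

* Root finding on a 513-point bracket grid + `uniroot` (tol 10⁻⁹ m); the
  stable root (negative force gradient) is returned if several exist.
* Euler sub-stepping bound d/100; halving dt moves terminal positions by
  < 0.1% in the test suite.
* Degenerate inputs: zero profile → explicit degenerate-profile error (not
  NaN); zero pooled variance → p ∈ {0, 1} with a `degenerate` flag;
  near-zero covariance eigenvalue → flagged degenerate ellipse.
* Reports are JSON without timestamps; a run is reconstructible from config
  + seed, and reruns are byte-identical.

## Known limitations

Off-axis (3-D) magnetostatics, hydrodynamic wall effects, Brownian motion,
meniscus optics and perspective are not modelled. The cuboid field model's
gradient is computed by central differences. The generator does not emulate
proteome composition — class differences enter only through density/size
distributions — so it cannot say anything about *why* coronas differ, only
whether the downstream pipeline would resolve a given density contrast.
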