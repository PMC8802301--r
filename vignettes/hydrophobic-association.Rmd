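---
title: "Methods: PMFs and excess thermodynamics of hydrophobic association"
author: "hydrotherm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PMFs and excess thermodynamics of hydrophobic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
estimators it implements, the parameters that matter, the numerical
choices behind them, and what the synthetic validation does and does not
demonstrate about real simulation data.

## The physical picture

Two nonpolar solutes in water attract through solvent reorganisation. The
potential of mean force F(ξ) along the intersolute distance ξ shows a
contact minimum (CM) at van-der-Waals contact; for bulky solutes a
desolvation maximum (DM) — the cost of expelling the last water layer —
and a solvent-separated minimum (SSM) appear beyond it. The CM depth is
the excess association free energy ΔF(CM). Repeating the measurement over
a temperature × ionic-strength grid and differentiating ΔF(CM)(T) yields
the excess entropy, energy and heat capacity of association; the
ionic-strength dependence quantifies salting-out.

## Umbrella sampling and WHAM

Direct sampling cannot cover the barrier regions, so each window `i`
applies a harmonic restraint to ξ,

$$ w_i(\xi) = k\,(\xi - d_{0,i})^2 , $$

with no ½ prefactor — the convention of the MD engine family whose
output this package consumes; a `biasConvention = "half_k_sq"` switch is
available because published restraint equations are often ambiguous on
this point. Biased histograms n_ij on a common grid are combined by the
weighted histogram analysis method (WHAM), iterating

$$ p_j \propto \frac{\sum_i n_{ij}}{\sum_i N_i\, e^{-(w_i(\xi_j)-f_i)/k_BT}},
\qquad
 f_i = -k_BT \ln \sum_j p_j\, e^{-w_i(\xi_j)/k_BT} $$

to self-consistency; F_j = −k_BT ln p_j. Numerical contracts:

* Every exponential is evaluated in shifted (log-sum-exp) form; stiff
  far-window biases (hundreds of kcal/mol) underflow harmlessly to zero
  instead of destabilising the iteration.
* The bias is evaluated at bin centres (standard practice at the default
  0.1 Å bin width; the bin-averaging correction is second order in the
  width and negligible here).
* The gauge is fixed by f₁ = 0; the iteration stops when no f_i moves by
  more than `tol` (default 10⁻⁷ kcal/mol, cap 10⁵ iterations — typical
  studies converge in a few thousand). Non-convergence returns a flagged
  profile plus a warning rather than an error, so one bad cell cannot
  abort a grid.
* Empty bins carry `NA` (not +∞); all consumers skip them.
* The default grid spans min(d₀) − 1 Å to max(d₀) + 2 Å — one half-width
  of biased spread below the tightest window and room for the flat tail
  above the loosest.

The PMF offset is anchored by subtracting the unweighted mean of F over a
closed long-distance baseline range where the profile has flattened
(presets: 12–13.5 Å hexane-like, 14–15.4 Å adamantane-like). This absorbs
the constant hydration free energy of the isolated solutes; after
subtraction the baseline mean is exactly zero.

Uncertainties come from a moving-block bootstrap over each window's time
series (default block 100 samples ≈ well above the chain correlation
time, 20 replicates, WHAM warm-started from the full-data shifts). This
respects serial correlation at the block scale; it is an honest
substitute for, not a reproduction of, any particular published error
model.

## Feature location

Extrema are located on a lightly smoothed profile (centred moving
average, default 3 bins) but all reported depths/heights are read from
the unsmoothed profile at the located bins; smoothing only stabilises
*which* bin is chosen. The CM is the global minimum (ties resolve to the
smallest ξ — contact geometry) and must be interior with prominence at
least `minProminence` (default 0.05 kcal/mol, chosen above the
bootstrap-level noise of a 50,000-sample study and recorded in output
metadata). The SSM is the first subsequent minimum whose separating
barrier rises at least `minProminence` above it, and the DM is the
highest maximum in between; profiles that rise monotonically to the
baseline get `hasDM = hasSSM = FALSE` rather than fabricated features.
Whether published CM depths were read from raw bins or smoothed curves is
generally unstated; reading unsmoothed values at smoothed locations is
this package's fixed choice.

## Thermodynamic decomposition

ΔF(CM)(T) at each ionic strength is fitted with the quadratic
ΔF = a + bT + cT², and the excess quantities follow from the standard
relations applied to it:

$$ \Delta S = -(b + 2cT), \qquad \Delta U = a - cT^2, \qquad
   \Delta C_V = -2cT , $$

so ΔF = ΔU − TΔS holds identically (the suite asserts it to 10⁻¹⁰
kcal/mol). ΔC_V is reported in cal mol⁻¹ K⁻¹ — the conventional unit for
excess heat capacities — through a single centralised converter; all
other energies stay in kcal/mol. Constant-volume sampling justifies the
C_V symbol; no pressure–volume correction is applied, and no cubic ΔF(T)
model is offered. ΔC_V is evaluated analytically as −2cT at the reference
temperature (no finite-difference variant).

Fits are weighted 1/σ² when per-point uncertainties are available (then
the covariance is the unscaled (XᵀWX)⁻¹ of known-σ weighted least
squares); otherwise ordinary least squares with residual-scaled
covariance — the appropriate default when the error model is unknown.
The quadratic is solved on a centred/scaled basis and mapped back
exactly, keeping coefficient recovery at machine precision despite T²
spanning 10⁵. ΔF(IS) at each temperature is fitted linearly; with exactly
two points the fit interpolates but its residual covariance is undefined
and flagged `saturated`.

Errors on ΔS, ΔU, ΔC_V are first-order propagations through the
coefficient covariance. With nine temperatures these single-fit intervals
rest on six residual degrees of freedom and are individually wide and
unstable; when a study's generating curvature is shared across ionic
strengths (as in the synthetic presets), pooling the per-IS estimates is
the efficient summary, and the acceptance script reports both the single
IS = 0 value and the pooled one.

## The synthetic-data generator

The generator replaces the MD engine with a known 1-D truth so every
downstream stage is verifiable:

* **Ground truth.** F(ξ) = repulsive wall + up to three Gaussians. The
  wall is (s/(ξ−ξ_w))¹², diverging at ξ_w and vanishing at large ξ; the
  CM Gaussian's amplitude is rescaled per condition so the value at the
  CM position equals the configured depth law
  depth(T, IS) = a* + b*T + c*T² + m*·IS exactly. DM and SSM Gaussians
  are optional: the hexane-like preset has none (CM-only profiles), the
  adamantane-like preset has both.
* **Sampler.** Gaussian random-walk Metropolis on ξ with stationary
  density ∝ exp[−(F + w_i)/k_BT], k_B = 0.0019872041 kcal mol⁻¹ K⁻¹,
  confined to (ξ_w, d₀ + 6 Å] (the upper bound makes the zero-bias
  density proper and is far beyond every feature). Burn-in is 10% of the
  requested length with step adaptation toward 30–50% acceptance; the
  production chain keeps every 5th state. No radial 4πr² Jacobian is
  applied: the profiles are distance PMFs with flat zero tails, matching
  how such data are conventionally presented. Times are synthetic,
  index × 0.2 ps (the emulated save stride).
* **Protocol presets.** Nine temperatures (273–373 K), five ionic
  strengths (0–2 mol/dm³), k = 2 kcal mol⁻¹ Å⁻², 50,000 samples per
  window; an 11-window ladder 4–14 Å (hexane-like, 495 series) and a
  24-window ladder 4–18 Å densified to 0.5 Å through the barrier region
  (adamantane-like, 1080 series). Per-series seeds derive
  deterministically from one master seed, so a study is a pure function
  of (protocol, seed).

The depth-law parameters were fixed once to reproduce the qualitative
thermodynamics of medium-sized hydrophobes: CM depths of roughly −1.5
(hexane-like) and −2 kcal/mol (adamantane-like) at 298 K deepening with
temperature across the whole 273–373 K range (the quadratic's vertex
lies above 373 K) and with salt (slopes −0.15 and −0.10
kcal mol⁻¹ M⁻¹), with ΔU > 0, ΔS > 0 and ΔC_V(298) ≈ −40 and −20
cal mol⁻¹ K⁻¹ respectively — magnitudes in line with reported
simulation-based estimates for such solutes.

What the generator does **not** emulate: explicit solvent and force
fields, the small mismatch between the restrained atom–atom distance and
the histogrammed centre-of-centres distance (both collapse to the single
synthetic coordinate), pressure effects, orientation-dependent
desolvation, or MD-like autocorrelation structure beyond what a thinned
Metropolis chain has. Passing the recovery tests therefore demonstrates
the correctness of the estimators, not the realism of any force field.

## Validation strategy and problem sizes

The test suite cross-checks each stage against an independent oracle:
direct Boltzmann inversion for single-window/zero-bias WHAM, a
brute-force naive fixed-point solver on toy instances (agreement to
10⁻⁸), quadrature of the analytic biased density for the sampler
(Kolmogorov–Smirnov at the 1% level on the effective sample size),
closed-form Gaussian moments for stiff restraints, across-replicate
regeneration for the bootstrap scale, and exact polynomial recovery plus
Monte-Carlo CI-coverage calibration for the fits. End-to-end runs use the
hexane-like preset at full per-window depth (50,000 samples) over 9
temperatures × 3 ionic strengths — grid sizes chosen to keep a complete
verification run in tens of seconds on one CPU while leaving every
estimator in its intended regime; the full 5-IS grid changes nothing
structurally.

## Known limitations

* WHAM assumes uncorrelated histogram counts; no statistical-inefficiency
  weighting is applied (the block bootstrap carries the correlation
  information instead). No MBAR, no 2-D coordinates.
* CM depths read at bin resolution carry O(F″·h²) discretisation noise
  (~0.02 kcal/mol at h = 0.1 Å for these curvatures); it propagates into
  the fit residuals and is the dominant error source of the derived heat
  capacities at the default budget.
* The quadratic ΔF(T) model is exact for the synthetic truth by
  construction; for real data it is a local approximation whose adequacy
  should be judged from the fit residuals.
* A second solvent-separated minimum, discussed for small solutes in the
  literature, is outside the feature model.
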