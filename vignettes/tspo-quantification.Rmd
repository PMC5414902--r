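---
title: "Quantifying TSPO PET in longitudinal rodent cohorts"
author: "tspoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying TSPO PET in longitudinal rodent cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspoquant)
```

## The problem

TSPO (18 kDa translocator protein) PET with [11C]-(R)-PK11195 images
activated microglia, and longitudinal small-animal designs use it to follow
neuroinflammation after an insult — here, the epileptogenesis that follows
pilocarpine-induced status epilepticus in rats. Absolute quantification
needs a metabolite-corrected arterial plasma input function (AIF), but
arterial catheterization is terminal in rats, so blood can be sampled only
at the final imaging session. `tspoquant` implements the complete
quantification chain for this design:

1. build the final-session AIF from sparse arterial samples,
2. derive AIFs for the earlier sessions of the same animal by dose/weight
   rescaling, and a cohort mean AIF for animals without blood sampling,
3. quantify every regional time-activity curve (TAC) with plasma-input and
   reference-tissue models plus SUV,
4. summarize the cohort with the bilateral-significance convention,
   percent changes, coefficients of variation and paired tests.

A seeded synthetic-cohort generator reproduces the whole study design so
that each stage — and the pipeline end to end — is testable without any
image data.

## Kinetic models

All tissue models treat the decay-corrected regional TAC
$C_T(t)$ (kBq/mL) as driven by the plasma parent concentration $C_p(t)$.

**One-tissue compartment (1TC).** $dC_T/dt = K_1 C_p - k_2 C_T$, i.e.
$C_T = K_1\, (C_p \ast e^{-k_2 t})$, with total volume of distribution
$V_T = K_1/k_2$. The model curve is averaged over each acquisition frame
before comparison with the data (the late 900 s frames make mid-time
sampling inaccurate). Fitting profiles $K_1$ out in closed form (the model
is linear in $K_1$ at fixed $k_2$) and searches $\log k_2$ from five
log-spaced starts inside $K_1 \in [0, 10]$, $k_2 \in [10^{-4}, 10]$.

**Two-tissue compartment (2TC).** Adds an exchanging specific compartment
($k_3, k_4$); $V_T = (K_1/k_2)(1 + k_3/k_4)$. The model is retained for
completeness but is not in the default model list: with this tracer it is
poorly identified, so besides optimizer failure the fit is flagged when
identifying parameters pin at a bound or when the delta-method relative
standard error of $V_T$ exceeds 100%. A $k_3$ estimate at zero is the
nested 1TC solution and is not a failure.

**Logan plot (LP).** Late-time linearization: for frame mid-times
$t \ge t^*$, $\int_0^t C_T / C_T(t)$ against $\int_0^t C_p / C_T(t)$ has
slope $V_T$. The plasma integral uses the fine grid, the tissue integral
the frame mid-times (zero at time zero). Default $t^* = 15$ min — with the
20-frame schedule this keeps the three 900 s frames, and on noiseless 1TC
curves the slope agrees with $K_1/k_2$ to within 2%.

**Simplified reference tissue model (SRTM).** For a reference region
devoid of specific binding (brainstem by default),
$C_T = R_1 C_{ref} + (k_2 - R_1 k_{2a}) (C_{ref} \ast e^{-k_{2a} t})$,
solved by basis functions over 100 log-spaced $k_{2a}$ values in
$[0.006, 0.6]\,\mathrm{min}^{-1}$ with a golden-section refinement around
the best grid point (the raw grid alone quantizes $BP_{ND}$ by a few
percent). $BP_{ND} = k_2/k_{2a} - 1$ may legitimately be negative at
baseline, so summaries use $DVR = BP_{ND} + 1$.

**Logan reference (LR).** Slope of $\int_0^t C_T / C_T(t)$ on
$(\int_0^t C_{ref} + C_{ref}/k_2')/C_T(t)$ is the $DVR$. The reference
efflux $k_2'$ defaults to the session median of SRTM-derived $k_2/R_1$
across regions; an explicit value or the late-time approximation (term
omitted, flagged) can be configured.

**SUV.** Frame-duration-weighted mean concentration over a window
(default the full 0–60 min), normalized by injected dose and body weight.
Two conventions are provided: the package's as-printed default
$SUV = C/(\mathrm{dose} \times \mathrm{weight})$, and the conventional
$SUV = C \times \mathrm{weight}/\mathrm{dose}$. Neither is asserted as
"correct"; the switch exists because the convention also fixes the
cross-session AIF rescaling below.

## Input-function construction

Thirteen arterial samples (3 s to 50 min) carry whole-blood activity; four
(5, 25, 40, 50 min) also carry a measured parent fraction.

- **Parent fraction.** Metabolites are negligible early, so the parent
  fraction is exactly 1 up to a *Begin* time and a continuous
  biexponential afterwards: $pf(t) = a_1 e^{-b_1 (t - B)} + a_2 e^{-b_2 (t-B)}$
  with $a_1 + a_2 = 1$ (continuity at the plateau), $b_i \ge 0$. The
  default $B = 0.75$ min lies after the last early sample (50 s) and
  before the first metabolite sample (5 min); it is configurable. Three
  free parameters are fitted by constrained least squares from several
  deterministic starts — with only four metabolite samples a single start
  can stall in a flat region.
- **Plasma-over-blood ratio.** A straight line in time, ordinary least
  squares through the per-sample plasma/blood ratios; a fitted line that
  turns non-positive inside the scan window is flagged.
- **Assembly.** Whole-blood samples are interpolated to the fine grid
  (linear through the origin, flat extrapolation past the last sample —
  the simplest defensible scheme for sparse late samples), multiplied by
  the ratio line to give total plasma, and by the parent-fraction curve to
  give the AIF.

**Cross-session derivation.** The design assumption is that an animal's
AIF is invariant across sessions *when expressed in SUV units*; a
time-varying reading of that statement would be circular (it would divide
the unknown AIF by itself), so the package implements the only
non-circular reading — a scalar: under the as-printed convention
$AIF_{target}(t) = AIF_{source}(t) \times
(\mathrm{dose}_t \mathrm{weight}_t)/(\mathrm{dose}_s \mathrm{weight}_s)$
(weight ratio inverted under the conventional SUV). The factors compose
exactly, so the operation acts as a group action on a subject's sessions.

**Mean AIF.** Each measured AIF is resampled to the common grid, min–max
rescaled to $[0,1]$, and averaged; the average is restored to
concentration units with the mean of the individual $\max - \min$
amplitudes, and the mean dose and weight of the contributing sessions are
attached for subsequent rescaling to individual sessions. The amplitude
restoration recipe is deliberately the simplest dimensionally consistent
one; it is a declared choice, not an estimate.

## Group conventions

- **Bilateral rule.** A change in a paired structure counts only when both
  sides are individually significant (strict inequality at the boundary).
- **Percent change** is always relative to the earlier session, so the two
  directions are reciprocal: $(1 + p_{ab}/100)(1 + p_{ba}/100) = 1$.
- **Tests.** Paired t for within-subject contrasts, with zero-variance
  differences reported as degenerate ($p = 1$) rather than as errors; a
  Mann–Whitney U as the non-parametric companion (exact by full
  enumeration when the smaller group has at most 8 observations — a
  permutation test, valid with ties — and a tie-corrected normal
  approximation otherwise). No multiple-testing correction is applied by
  default; per-region p-values are reported as-is.
- **CoV** (100·sd/mean) summaries flag regions at or above 20%, the
  conventional bound for normal biological variation in such cohorts.
- Failed fits travel as flagged missing values: they are excluded from
  means, counted, and never coerced to zeros.

## The synthetic cohort generator

`cohort_spec()` encodes the emulated design: 9 subjects, 7 of them with
final-session blood sampling; sessions `baseline`, `D0+6`, `D0+35`; 29
atlas labels (13 bilateral tissue regions + 3 ventricle labels; the 26
tissue labels remain after ventricle exclusion); the 20-frame schedule
(9×20 s, 4×60 s, 4×120 s, 3×900 s) and 13-point arterial schedule with the
4-point metabolite subset.

Ground truth per subject and session:

- **Input function.** A template with a linear rise to a peak at 0.5 min
  and a tri-exponential decay, scaled per session by the dose–weight
  factor (so a subject's sessions are exact SUV-scaled copies — the
  assumption the cross-session derivation relies on) and by a 10% lognormal
  between-subject amplitude jitter. Whole blood is derived from the true
  plasma-over-blood line ($1.25 + 0.003 t$) and the true parent-fraction
  model ($B = 0.75$, $a_1 = 0.6$, $b_1 = 0.4$, $b_2 = 0.02$ min⁻¹).
- **Kinetics.** One-tissue truth per label with fixed $K_1 = 0.1$ and
  $k_2 = K_1 / V_T$. Baseline tissue $V_T = 1$ (arbitrary units — only
  ratios and percent changes are compared downstream), ventricles 0.3.
  Acute multipliers: hippocampus ×2.18, amygdala ×1.86, temporal cortex
  ×1.94, thalamus ×1.79, brainstem ×1.17, intermediate values (1.25–1.60)
  for the remaining tissue regions; chronic multipliers apply the partial
  returns (53/44/47/44/31% decreases for the named regions, 45%
  elsewhere) to the acute levels.
- **Biological variability.** A subject-level lognormal baseline factor
  (sdlog 0.10, shared across regions) and a per-subject, per-region,
  **per-side** lognormal response factor (sdlog 0.15) on each post-insult
  multiplier. The response spread was fixed a priori by two constraints
  the emulated design states: the acute intersubject CoV should stay
  below 20% ($\sqrt{0.10^2 + 0.15^2} \approx 18\%$), and a ~17% brainstem
  change in 7 animals should be borderline rather than reliably
  significant. Drawing the factor per side reflects hemispheric asymmetry
  of the inflammatory response and is what gives the bilateral rule its
  protective value in the generator, exactly as intended by the
  convention.
- **Noise.** Independent Gaussian frame noise, sd = 5% of the frame value,
  floor-clamped at zero. Blood samples are read off noiselessly.
- **Dosimetry.** Dose ~ N(37, 3) MBq per session; weights grow across
  sessions (means 244, 260, 320 g) with a subject-level 8% lognormal
  factor.

Every draw is keyed to `(seed, subject, session, label)`, so bundles are
byte-identical across runs and per-label values do not depend on which
regions are requested.

What the generator does **not** emulate: partial-volume and resolution
effects, motion, scanner calibration error, dispersion/delay of the AIF,
plasma protein binding, metabolite-assay noise, decay (inputs are assumed
decay-corrected), and any 2TC-like tissue heterogeneity (a 2TC forward
model exists for robustness tests but the default truth is 1TC). Passing
recovery tests therefore demonstrates correctness of the estimators under
the stated model, not robustness to all the physics of real data.

## Numerical choices

- Fine grid: 1 s spacing on [0, 60] min, resolving the 20 s frames; the
  exponential convolution is evaluated by an exact per-step closed form
  for piecewise-linear inputs (a linear recurrence, computed in C), so
  forward curves are exact rather than quadrature approximations.
- Frame averages come from the cumulative trapezoid of the fine curve, so
  frame boundaries need not be grid points.
- Logan integrals: fine-grid trapezoid for plasma, frame-mid-time
  trapezoid (through the origin) for tissue; frames with non-positive
  tissue activity in the window are dropped with a warning, and fewer than
  3 usable frames is a flagged failure.
- Weighting: frame-duration weights by default (a standard proxy for
  count statistics with decay-corrected data), uniform available.
- No vascular term ($v_B = 0$) in the compartment models by default.
- Fit failures are flags in result tables, never exceptions, so cohort
  runs always complete.

## Validation problem sizes

The test suite validates parameter recovery on noiseless and 5%-noise
curves (200-replicate Monte Carlo for the 1TC), full-cohort recovery on a
noiseless default cohort via rebuilt input functions (every label within
3%), bilateral detection rates over 100 simulated effect cohorts
(α = 0.01; the four target regions fire in ≥95%, brainstem in ≤20%), and
type-I control over 500 simulated null cohorts (α = 0.05, per-region
false-positive rate below α + 3 binomial SEs). The detection-rate
experiments use the Logan estimate of $V_T$ — it is one of the two
plasma-input methods, and its linear algebra makes hundreds of simulated
cohorts cheap; single-cohort percent-change summaries use the 1TC
reference method.

## Known limitations

- The cross-session AIF derivation inherits the SUV-invariance
  assumption; if peripheral clearance changes between sessions (e.g.
  under pharmacological intervention), derived AIFs and SUVs are both
  biased.
- The mean-AIF path deliberately shares one curve shape across animals,
  which shrinks apparent intersubject variability; treat its group
  statistics accordingly.
- The amplitude restoration of the mean AIF and the `begin` default are
  declared conventions; alternatives (e.g. AUC-matched restoration) would
  be equally defensible.
- Correlation is implemented as the Pearson product-moment coefficient
  (covariance over the product of standard deviations).
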