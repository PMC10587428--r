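---
title: "Models, corrections and design choices in petkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, corrections and design choices in petkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`petkin` analyses region-of-interest time-activity curves (TACs) from
dynamic carbon-11 PET of the heart and kidney under a dual
acetoacetate/acetate tracer protocol, and simulates such data with known
kinetic ground truth. This vignette is the package's account of the
science: the models, the corrections, every tunable that matters, the
numerical choices, and the places where the design was genuinely open.

## Acquisition model

The canonical dynamic acquisition is a 30-minute list-mode scan
reconstructed into 26 frames — 12 × 10 s, 6 × 30 s, 6 × 150 s,
2 × 300 s (`default_frame_schedule()`). A TAC is defined as the average
of the underlying continuous concentration over each frame; `petkin`
makes that definition operational by evaluating all continuous curves on
a uniform fine grid (default step 0.5 s, always a divisor of the frame
boundaries) and averaging by trapezoidal integration. The same operation
is used for simulation and for model prediction during fitting, so the
forward and inverse directions are exactly consistent.

All TACs are decay-corrected to injection time, the conventional PET
output; the `tac` container carries a state tag and `decay_correct()`
refuses a second application in the same direction rather than silently
double-scaling. The ¹¹C half-life is fixed at 20.364 min.

## Input function

The paper-protocol input function is image-derived (left-ventricle blood
pool). For simulation, where an analytic form is needed, `petkin` uses
the standard tri-exponential bolus with appearance delay τ
(`feng_params()`):

$$C_p(t) = (A_1(t-\tau) - A_2 - A_3)\,e^{\lambda_1(t-\tau)}
  + A_2 e^{\lambda_2(t-\tau)} + A_3 e^{\lambda_3(t-\tau)}, \quad t>\tau$$

chosen because it is the de-facto standard for input-function
simulation and admits closed-form convolution. Defaults
($A_1 = 2000$ kBq/mL/min, $A_2 = 4$, $A_3 = 12$ kBq/mL,
$\lambda = -4.1, -0.012, -0.6$ min⁻¹, $\tau = 0.3$ min) were set once on
realism grounds: for a typical 320 MBq dose in a 70 kg adult they give a
blood bolus peaking near SUV 40 at ~0.55 min that clears to about SUV 1
by 5 min — the usual proportions of a measured left-ventricle curve. In
the cohort generator the bolus amplitude scales with each subject's
injected dose per body weight. When fitting measured (or simulated)
data, `as_input_function()` turns a blood-pool TAC into a
continuous-time curve by linear interpolation of frame mid-time values,
anchored at zero at injection.

The whole-blood curve is taken equal to total plasma (no red-cell
partitioning); tissue is driven by the metabolite-corrected *parent*
plasma curve.

## Metabolite corrections

Parent fraction is modelled per tracer (`tracer_metabolite_model()`):

* **Acetoacetate** — labelled CO₂ accumulates linearly in plasma. The
  measured accumulation rate, 1.323 per minute, is interpreted as
  *percent of total plasma activity per minute*, i.e. parent fraction
  $1 - \min(1.323\,t/100,\ 1)$. The alternative reading
  (fraction·min⁻¹) would exceed total plasma activity before the scan
  ends, so the percent interpretation is the only self-consistent one;
  the slope is a configurable parameter.
* **Acetate** — corrections conventionally come from published curves
  built into vendor software. `petkin` exposes this as an interpolated
  `(time, parent fraction)` table; the shipped default is a smooth
  mono-exponential-plateau curve typical of published human arterial
  data, and any laboratory-specific table can be substituted
  (`read_metabolite_table()`).

Parent fractions are clamped to [0, 1] and must equal 1 at t = 0.

## Compartment models

The one-tissue model (K₁, k₂) and the irreversible two-tissue model
(K₁, k₂, k₃) are computed from their closed-form impulse responses,

$$C_t^{1TC}(t) = K_1 \int_0^t C_p(s)\,e^{-k_2(t-s)}\,ds,\qquad
  C_t^{2TC}(t) = \frac{K_1}{k_2+k_3}\left[k_3 + k_2
  e^{-(k_2+k_3)t}\right] \otimes C_p ,$$

with measured signal $(1-V_b)C_t + V_b C_b$. The convolution against the
sampled plasma curve is evaluated *exactly* for a piecewise-linear input
— each grid segment contributes a closed-form increment and the running
integral decays by $e^{-\beta h}$ per step (a first-order recursive
filter) — rather than by FFT, which loses accuracy on the uneven late
frames, or by an ODE solver, which would make fitting far slower. When
$\beta h < 10^{-8}$ the increment switches to its trapezoidal limit to
avoid cancellation. Degenerate cases are exact: $k_3 = 0$ routes through
the identical 1TC code path (model nesting holds bit-for-bit), and
$k_2 + k_3 = 0$ falls back to pure integration $K_1\int C_p$. Validation
against a stiff ODE oracle (`deSolve::lsoda`, tolerances 1e-10) over 100
random parameter draws bounds the frame-level relative error near 1e-7,
three orders of magnitude inside the 1e-3 requirement.

## Noise model

Frame noise is zero-mean Gaussian with

$$SD_i = \sigma\sqrt{\max(y_i,0)\, e^{\lambda t_i}/\Delta t_i},$$

the standard heteroscedasticity of decay-corrected PET TACs: variance
proportional to activity, inflated by the decay factor, inversely
proportional to frame duration. The dimensionless scale σ defaults to
0.05, which for the default activity levels corresponds to roughly 1%
relative noise on mid-scan tissue frames and several percent on the
short early frames — appropriate for large-ROI TACs from a modern
high-sensitivity scanner. σ = 0 is exactly noiseless, and a fixed seed
reproduces noise bit-for-bit without disturbing the caller's RNG stream.

## The synthetic cohort

`generate_cohort()` draws, per subject: vitals (HR ~ N(62, 8) bpm,
SBP ~ N(121, 11) mmHg, dose ~ N(319, 53) MBq, weight ~ N(70, 10) kg,
truncated to physiological ranges), a subject-specific input function,
and per-tracer TACs for left-ventricle blood pool, myocardium, renal
cortex and renal pelvis. Kinetic truth is drawn from the default truth
table (`default_kinetic_truth()`), whose means and SDs are
representative resting healthy-adult values for the two tracers —
myocardial K₁ 0.61 (0.07) vs 0.69 (0.10) mL/min/g, k₂ 0.063 (0.021) vs
0.081 (0.022) min⁻¹; cortical 1TC K₁ 0.83 (0.10) vs 1.77 (0.43), k₂
0.31 (0.04) vs 0.21 (0.02); cortical 2TC for the ketone tracer K₁ 0.87
(0.10), k₂ 0.37 (0.06), k₃ 0.021 (0.015) — truncated at zero. The
myocardial blood fraction defaults to 0.40 (0.05), reflecting the large
spillover/partial-volume blood contribution of a myocardial ROI (this
is also what makes the simulated myocardial peak occur at the early
blood transit, ~0.6 min); the cortical blood fraction is fixed at 0.10.

The renal pelvis is modelled as an early vascular transit (a scaled
blood curve, default fraction 0.25) plus — ketone tracer only — a
delayed gamma-variate excretion component
$A\,u^{\alpha}e^{\alpha(1-u)}$, $u = (t-t_0)/(t_m-t_0)$, peaking at
value $A$ at its mode $t_m$. Defaults: mode 7 min (the package default;
reported values for this phenomenon span roughly 6.6–7.1 min, and the
mode is configurable rather than asserted), onset at 25% of the mode,
shape α = 3, amplitude drawn as SUV 38.6 (31.5) truncated to [5, 150]
and converted to kBq/mL with the subject's dose and weight. With the
second component disabled the pelvis is single-peaked, emulating the
acetate pattern.

**What the generator does and does not emulate.** It reproduces frame
averaging, realistic bolus/tail proportions, tracer-specific metabolite
loss, count-statistics noise, between-subject parameter spread, and the
tracer-specific pelvis signature. It deliberately does *not* include
model error: the generating model is exactly the fitted model, the input
function is exactly known, and partial-volume and spillover enter only
through the single $V_b$ mixing term. Passing recovery tests therefore
demonstrates the correctness of the estimation machinery, not robustness
to the model misspecification present in real scans (see *Model
comparison* below for where this matters).

## Fitting

`fit_model()` minimizes the weighted residual sum of squares over
bounded parameters with Levenberg-Marquardt (`minpack.lm::nls.lm`).
Defaults, all configurable via `fit_config()`:

* **Window** 0–15 min (22 frames): the rapid ¹¹C decay makes later
  frames uninformative, and this is the conventional analysis window
  for this protocol.
* **Weights** $w_i = \Delta t_i e^{-\lambda t_i}$ — inverse variance
  under the noise model up to the activity term, which is omitted so
  that weights do not depend on the measured values.
* **Bounds** K₁ ∈ [0, 5] mL/min/g, k₂ ∈ [0, 2], k₃ ∈ [0, 1] min⁻¹,
  V_b ∈ [0, 1]; initial values 0.5, 0.1, 0.01, 0.3.
* **Multi-start**: 5 restarts, the first at the initial values, the
  rest log-normally jittered by a seeded private RNG; the best weighted
  RSS wins, so fits are deterministic given the configuration.
* **V_b** is estimated for the myocardium, where blood spillover is
  large, but fixed (default 0.10) for the renal cortex, where careful
  segmentation away from large vessels makes the vascular
  contamination small and poorly identifiable; both choices are
  configuration, not hard-coded behaviour.

An all-zero (or K₁-at-bound) fit is flagged `degenerate`; optimizer
failure across all starts is flagged via `converged`. Noiseless
simulated TACs are recovered to well below 0.1% relative error, and at
noise scale 0.05 the median relative bias of K₁ and k₂ stays below 1%
in both organs (the test suite checks 200 replicates per organ; the
acceptance script recomputes this).

## Model comparison

`compute_aic()` uses the least-squares convention
$AIC = n\ln(RSS/n) + 2p$ (AICc optional); only differences between
models fitted to the same data are meaningful, and `compare_models()`
declares equivalence when $|\Delta AIC| < 2$. A known limitation
follows from the generator's lack of model error: when cortical ketone
TACs are generated from the irreversible two-tissue truth
(k₃ ≈ 0.02 min⁻¹) with an exactly known input function, the trapped
component is statistically identifiable at any realistic noise level,
so AIC systematically prefers the two-tissue model in simulation. The
near-equivalence of the two models reported on real data of this
protocol arises from residual model error shared by both models
(input-function, partial-volume and metabolite imperfections), which an
exact-model simulation cannot reproduce. The acceptance script reports
the equivalence fraction it actually measures rather than asserting the
real-data phenomenon.

## Derived metrics

* **SUV**: $C \cdot \text{weight}/\text{dose}$ (kBq/mL, kg, MBq;
  density 1 g/mL). Invariant to joint rescaling of activity and dose.
* **RPP scaling**: RPP = HR·SBP/10⁴ and K₁ˢ = K₁/RPP. The 10⁴ scaling
  is the dimensionally consistent choice: resting HR·SBP ≈ 7500 gives
  RPP ≈ 0.75, so that K₁ ≈ 0.61 maps to K₁ˢ ≈ 0.81, the conventional
  magnitude; a 10³ scaling (sometimes printed) would place K₁ˢ an
  order of magnitude low.
* **MVO₂** = (1.35 k₂ − 9.6×10⁻³)·100 mL/100g/min, floored at 0; the
  established linear calibration of acetate washout, reported per
  100 g.
* **MBF**: inversion of K₁ = MBF(1 − a e^{−b/MBF}) by monotone
  bracketed root finding (tolerance 1e-8, round-trip error < 1e-6 over
  MBF ∈ [0.2, 5]). The extraction constants default to a = 0.64,
  b = 1.20 mL/min/g, the standard acetate parameterization; they are
  configuration values, not asserted ground truth.
* **Percent differences** are reported relative to the *reference*
  (acetate) value with the direction stored in the record — the
  convention under which both canonical contrasts of this protocol
  (22% in heart k₂, 53% in cortical K₁) are reproduced from the truth
  table means. **Fold summaries** report both the mean (SD) of
  per-subject ratios and the ratio of cohort means, because the two
  conventions differ for skewed ratios and published values mix them.
* **Peak detection** finds local maxima by topographic prominence
  (plateau-tolerant; ties broken toward the earlier frame), default
  threshold 5% of the TAC's dynamic range — high enough to suppress
  frame-noise wiggles at the default noise scale, low enough to keep
  the pelvis vascular peak. At most the first two peaks are reported.
  On the 150-s late frames the detected second-peak time is quantized
  to frame mid-times, so a 7-min excretion mode is located within one
  frame (±2.5 min).
* **Pelvis early sum** (summed SUV over 0–2 min by default) is a
  package convention for the initial transit; published analogues of
  this summary are not precisely defined, so it is configurable and
  carries no asserted reference value.

## Cohort statistics

Paired comparisons use Student's paired t-test or the Wilcoxon
signed-rank test — the method is chosen by configuration per metric,
not inferred from normality tests. Zero-variance difference vectors are
flagged degenerate (identical samples: statistic 0, p = 1). Pearson
correlation comes from `cor.test`. The repeated-measures one-way ANOVA
is fitted as the randomized-block model `value ~ condition + subject`
with Tukey HSD on condition means; a condition sum of squares at
machine zero is reported as F = 0, p = 1 rather than a 0/0 artifact.
Significance markers use the conventional tiers (≤ 0.05, ≤ 0.01,
≤ 0.001), each backed by the stored test record. The paired t-test's
type-I error at n = 10 is verified by simulation to sit within
[0.035, 0.065] at nominal α = 0.05.

## Problem sizes used in validation

The shipped tests and acceptance script use: 100 random parameter draws
for forward-model/ODE-oracle agreement (50 in the unit tests); 200
noisy replicates per organ for recovery bias; cohorts of 10 subjects
(the protocol's natural size) for cohort-level checks; 2000 null
simulations for t-test calibration; 1000 replicates for the noise-SD
Monte-Carlo check. These sizes keep Monte-Carlo error comfortably below
the tolerances being checked.

## Known limitations

* ROI-level only: no image-space simulation, no scanner resolution or
  reconstruction effects, no segmentation.
* Single V_b mixing term; no separate geometric spillover from tissue
  to blood.
* No reversible two-tissue (k₄) model, and no graphical (Patlak/Logan)
  analyses.
* The whole-blood/plasma ratio is fixed at 1; a configurable
  partitioning hook is future work.
* Simulated data contain no model error, with the consequences for AIC
  model comparison described above.
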