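# petkin

Compartmental kinetic analysis of dynamic carbon-11 PET time-activity
curves (TACs) for the heart and kidney, built around a dual-tracer
acetoacetate/acetate protocol.

## What problem this addresses

Ketones are alternative energy substrates for the myocardium and the
kidney. A dual-tracer dynamic PET protocol — ¹¹C-acetoacetate (the ketone
tracer, `acac`) and ¹¹C-acetate (the established oxidative-metabolism
tracer, `ac`) scanned back-to-back in the same subject — lets both organs'
uptake and clearance kinetics be compared head to head. Analyzing such
scans requires a chain of well-defined steps: an arterial input function,
metabolite and decay corrections, compartment-model fitting over a short
early window (the ¹¹C signal decays with a 20.4-min half-life), and a set
of derived physiological quantities. `petkin` implements that chain for
R users working at the region-of-interest TAC level, together with a
fully synthetic data generator so that every stage can be validated
against known ground truth without any scan data.

Intended users: imaging scientists and methodologists who need a
transparent, scriptable reference implementation of ROI-level tracer
kinetics — for simulation studies, teaching, or cross-checking vendor
software — not a clinical image-processing pipeline (no DICOM, no
segmentation, no reconstruction).

## The models

**One-tissue compartment model (1TC)** — parameters K₁ (mL/min/g, uptake)
and k₂ (min⁻¹, clearance):

    dC_t/dt = K₁ C_p(t) − k₂ C_t(t)
    C_model(t) = (1 − V_b) C_t(t) + V_b C_b(t)

**Irreversible two-tissue model (2TC)** — adds k₃ (min⁻¹, irreversible
local accumulation):

    dC₁/dt = K₁ C_p − (k₂ + k₃) C₁ ,   dC₂/dt = k₃ C₁ ,   C_t = C₁ + C₂

Both are computed by exact closed-form convolution of the impulse
response with a piecewise-linear plasma curve (no FFT, no ODE solver),
then averaged over the acquisition frames — the same operation the
simulator uses, so noiseless simulations are recovered to numerical
precision. C_p is the metabolite-corrected parent plasma curve; C_b is
whole blood; V_b is the fractional blood signal in the region.

Derived quantities: SUV normalization, rate-pressure-product-scaled
uptake K₁ˢ = K₁/RPP, myocardial blood flow by inverting the
Renkin-Crone relation K₁ = MBF·(1 − a·e^(−b/MBF)), oxygen consumption
MVO₂ = (1.35·k₂ − 9.6×10⁻³)·100 mL/100g/min, kinetic ratios K₁/k₂, and
renal-pelvis double-peak statistics. Cohort-level tools provide paired
t/Wilcoxon tests, Pearson correlation, repeated-measures one-way ANOVA
with Tukey comparisons, fold summaries under both conventions, and a
publication-style summary table.

## Worked example

Simulate a ten-subject dual-tracer cohort with known kinetic truth, fit
both organs, and summarize:

```r
library(petkin)

co   <- generate_cohort(10, seed = 42)   # vitals, AIF, noisy TACs, truth
fits <- fit_cohort(co)                   # weighted NLS, 0-15 min window
met  <- derive_metrics(co, fits)         # SUV peaks, K1s, MBF, MVO2, ...
st   <- build_summary_table(met)         # mean (SD) + paired-test markers

st[st$region == "myocardium" & st$metric %in% c("K1_1tc", "k2_1tc"), ]
#>      region metric tracer   mean     sd  n p_vs_ref marker
#>  myocardium K1_1tc     ac 0.6900 0.1083 10       NA
#>  myocardium K1_1tc   acac 0.6028 0.0528 10   0.0286      *
#>  myocardium k2_1tc     ac 0.0782 0.0337 10       NA
#>  myocardium k2_1tc   acac 0.0606 0.0179 10   0.2466
```

The fitted cohort means recover the generator's truth distributions
(myocardial K₁ of 0.61 and 0.69 mL/min/g for the ketone and acetate
tracers): the ketone tracer's uptake is moderately but significantly
lower under the paired test, its clearance k₂ lower on average. Derived
physiology from single values:

```r
percent_diff_vs_ref(0.063, 0.081)$percent   # heart k2 contrast
#> 22.2  (% lower than the acetate reference)
mbf_from_k1_acetate(0.69)                   # Renkin-Crone inversion
#> 0.81  mL/min/g
mvo2_from_k2(0.081)
#> 9.98  mL/100g/min
```

The renal pelvis shows the tracer-specific excretion signature: two
detected peaks (the second, larger one near 7 min) for acetoacetate,
a single early vascular peak for acetate:

```r
s <- co$subjects[[1]]
detect_peaks(suv_curve(s$tacs$acac$renal_pelvis, s$vitals))
#>     peak  SUV_max     T_max
#> 1  first 10.25066 0.5833333
#> 2 second 55.59969 6.2500000
```

`run_pipeline(n = 10, seed = 1, out_dir = "out")` chains
simulate → fit → derive → summarize and writes CSV artifacts plus a
manifest with output hashes; identical configurations reproduce
identical hashes.

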