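---
title: "Quantifying serum hormone levels from dried capillary microsamples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying serum hormone levels from dried capillary microsamples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vamsquant)
```

## The measurement problem

Volumetric absorptive microsampling (VAMS) devices wick a fixed 30 µL of
capillary whole blood from a fingertip onto a polymeric tip, which is dried
and shipped at ambient conditions. For endocrine monitoring — steroids
(androstenedione, cortisol, DHEA-S, progesterone, testosterone, estradiol)
and thyroid hormones (T3, T4) — this replaces venipuncture, but it changes
the measurand: the tip holds *whole blood*, while clinical reference
intervals are defined on *serum*. Whole blood is a two-compartment matrix:
a serum fraction $(1-h)$ and a red-blood-cell (RBC) fraction $h$, where $h$
is the hematocrit. `vamsquant` implements the conversion between the two
measurands, the internal-standard calibration that turns peak areas into
concentrations, the bioanalytical validation battery that certifies the
assay, Bland–Altman agreement analysis against venous serum, and a seeded
simulator that generates every input the pipeline consumes.

## The whole-blood compartment model

The total concentration on a tip is the volume-weighted mixture

$$c_\mathrm{VAMS} = (1-h)\,c_\mathrm{serum} + h\,c_\mathrm{RBC},$$

with the RBC term tied to the serum term by the analyte's partition
behaviour. Two modes are supported (`partition_spec()`):

* **ratio mode** — the analyte equilibrates at a fixed plasma-to-RBC
  concentration ratio $r$, so $c_\mathrm{RBC} = c_\mathrm{serum}/r$. The
  panel ships $r = 4$ for A4, DHEA-S and T, $r = 5$ for cortisol and
  $r = 3.2$ for T3.
* **fixed mode** — thyroxine's RBC level is essentially constant; the panel
  uses 0.54 ng/mL, the midpoint of the reported 0.30–0.78 ng/mL range.

At the calibration standardization hematocrit $h = 0.40$ the serum
compartment is 60% of the absorbed volume (18 µL of 30 µL), which is the
0.6/0.4 arithmetic of `vams_from_serum()`.

The back-conversion is written in the literature as
$c_\mathrm{serum} = (c_\mathrm{VAMS} - h\,c_\mathrm{RBC})/(1-h)$, which for
ratio-mode analytes is circular ($c_\mathrm{RBC}$ depends on
$c_\mathrm{serum}$). `serum_from_vams()` instead solves the two linear
relations simultaneously:

$$c_\mathrm{serum} = \frac{c_\mathrm{VAMS}}{(1-h) + h/r},$$

which is exact, order-free, and reproduces the sequential arithmetic at
$h = 0.40$. For fixed-mode analytes the printed formula is used directly;
values driven below zero by measurement noise near the blank are clamped to
zero and flagged (`attr(x, "truncated")`) rather than raising an error,
because a noisy batch should not crash on one blank-level sample.

Progesterone and estradiol have no established partition ratio. Refusing to
convert them would hide the gap; converting silently would hide the
uncertainty. The panel therefore applies the steroid default $r = 4$ but
marks it (`defaulted = TRUE`), and every conversion through a defaulted
ratio carries a `defaulted_partition` attribute. The ratio is a loud config
override away (`load_panel()`).

### Hematocrit bias

A method calibrated at $h_0 = 0.40$ mis-measures samples at other
hematocrits. For ratio mode the predicted relative deviation,

$$\Delta(h) = \frac{(1-h) + h/r}{(1-h_0) + h_0/r} - 1,$$

is independent of concentration (asserted internally at 0.01, 1 and
1000 ng/mL) and, for $r = 4$, reaches ±10.7% at $h \in \{0.30, 0.50\}$ —
inside the ±20% robustness band across the full healthy-adult hematocrit
range. `hct_bias_profile()` returns the profile and the contiguous passing
sub-range around the reference.

## Calibration

Quantification uses analyte/internal-standard peak-area ratios
(`area_ratio()`): the co-extracted stable-isotope standard cancels
preparation and detection losses, which is why every ratio-based statistic
in the package is invariant to a common rescaling of all areas (a tested
property).

The surrogate blank matrix (washed RBCs in albumin) is not perfectly
hormone-free: residual endogenous levels of 45 ng/mL (DHEA-S), 0.001 ng/mL
(T) and 0.15 ng/mL (T4) remain. Each run therefore measures blank samples,
and `fit_calibration()` subtracts the run's mean blank ratio from every
calibrator response before the least-squares fit; `quantify()` subtracts the
same blank ratio from unknowns (symmetric treatment — the alternative,
correcting calibrators only, is a one-line change and the choice is flagged
in reports). Blank-shift invariance is a tested property.

Linearity is accepted when the determination coefficient of the ordinary
least-squares fit of the corrected points reaches $R^2 \ge 0.99$ and the
residual signs show no systematic pattern. "No systematic pattern" is
operationalized as a one-sided Wald–Wolfowitz runs test on residual signs at
$\alpha = 0.05$ (too few runs = bowing); residuals at machine-epsilon scale
are treated as unsigned so a perfect fit never flags.

**Weighting.** `fit_calibration()` defaults to unweighted OLS with a `"1/x"`
switch. The batch pipeline (`calibrate_runs()`), however, fits with `"1/x"`
by default: the panel's calibration ranges span up to 800-fold (LOQ to the
physiological maximum), and with multiplicative noise the *unweighted*
intercept's sampling error in concentration units ($\approx 0.5\,\mathrm{CV}
\cdot c_\mathrm{max}$) exceeds the testosterone LOQ itself, corrupting every
low-end result. Inverse-concentration weighting anchors the intercept at the
bottom of the range; linearity diagnostics are still computed from the OLS
fit, the conventional linearity assessment, so the acceptance criterion is
unchanged by the weighting choice.

## The validation battery

`analyze_validation_batch()` computes, per analyte, against
`threshold_config()` (defaults in parentheses):

| component | estimator | gate |
|---|---|---|
| imprecision | intraday CV per run, interday CV pooled over all runs' values | ≤ 15% |
| accuracy | $100\cdot\overline{c}_\mathrm{measured}/c_\mathrm{nominal}$ | within ±15% of 100% |
| linearity | OLS $R^2$ + runs test, all runs | $R^2 \ge 0.99$, no pattern |
| LOQ | lowest level with replicate CV ≤ 20% *and* mean SNR ≥ 10 *and* all higher levels passing | an LOQ exists |
| recovery | mean pre-extraction-spike area / mean post-extraction-spike area | reported |
| matrix effect | mean matrix-spike area / mean solvent-spike area | reported |
| carryover | blank-after-high area / high area | ≤ 0.01% |
| Hct robustness | deviation of serum-corrected concentration vs. the 0.40 reference | passing range reported |
| stability | scheduled-day means vs. day 0 | day-28 pass at −18 °C |

Design choices worth stating explicitly:

* **Interday CV** is the pooled CV over all runs' values (closest to a
  bandwidth-style reading of a three-run design); an ANOVA
  variance-component decomposition is available via `method = "anova"`.
* **Carryover** is numeric (area ratio against the 0.01% bound) even though
  carryover is often judged by visual inspection — a package must compute.
* **LOQ monotone closure**: a level only qualifies if every higher level
  also passes, so a noisy mid-level cannot certify a nonsensically low LOQ.
  The replicate CV at each level is computed on the area ratios (the same
  quantity the imprecision experiment uses), not on back-calculated
  concentrations, which would fold calibration-intercept noise into every
  low level. SNR is an input column — the package never derives an SNR from
  areas, because the noise-band estimator lives upstream in the peak
  integration software.
* **Recovery and matrix effect carry no gate**: the assay accepts
  recoveries down to 27% (thyroid hormones) because the isotope-labelled
  internal standard compensates; they are reported, not judged.
* **Hct robustness does not gate** `overall_pass`: the assay is considered
  valid *within* the reported passing hematocrit range, which is the
  clinically actionable output.
* **Stability gates on the frozen (−18 °C) series**: frozen storage is the
  recommended archival route; the room-temperature series is reported so
  that shipping windows (e.g. cortisol's 14 days) can be read off.
* Missing components are reported as "not assessed", excluded from the
  conjunction, and warned about.

## Agreement analysis

`bland_altman()` computes, per analyte over paired serum/corrected-capillary
measurements: the mean difference (bias), its SD, the 95% limits of
agreement $\mathrm{bias} \pm 1.96\,\mathrm{SD}$, the bias CI
($\pm t_{0.975,n-1}\,\mathrm{SD}/\sqrt{n}$), and the standard large-sample
LoA CIs ($\pm t_{0.975,n-1}\,\mathrm{SD}\sqrt{3/n}$). Percent differences
(difference over pairwise mean) feed the percentage-scale difference plot
(`plot_bland_altman()`); zero-mean pairs are excluded from the percentage
series and counted.

The difference direction is fixed to serum − corrected-VAMS. Published
agreement tables of this design are not always internally sign-consistent
(one analyte's printed bias can sit opposite its LoA midpoint); rather than
chase a sign, the package documents the direction and tests the
flip-invariance property: reversing the direction negates bias and limits
and leaves every p-value unchanged. The symmetric-LoA identity — the
midpoint of the limits equals the bias to $10^{-12}$ — is asserted for every
result.

`paired_comparison()` screens the differences with Shapiro–Wilk; when
normality is not rejected the paired two-sided t-test decides, otherwise the
Wilcoxon signed-rank test is used under an explicit flag (the t-test p-value
is always reported alongside, so the default report matches the
t-test-only convention). All-zero differences return p = 1 with a
degenerate flag. Beyond 5000 pairs the Shapiro screen is moot (and
undefined); it is reported as NA and the t-test used.

## The simulator

`simulate_measurement()` is the forward model:

$$\mathrm{ratio} = s \cdot c_\mathrm{VAMS} \cdot e^{-k d} \cdot
  \mathrm{rec} \cdot \mathrm{ME} \cdot e^{\delta_\mathrm{run}} (1+\varepsilon)
  + \varepsilon_\mathrm{floor},$$

with $c_\mathrm{VAMS}$ from the compartment model at the sample's hematocrit
plus the blank residual, first-order storage degradation $e^{-kd}$, the
recovery and matrix-effect attenuations, a run-level log-scale effect
$\delta_\mathrm{run}$ shared by every measurement of a run, multiplicative
intraday noise $\varepsilon$, and an additive response floor
$\varepsilon_\mathrm{floor}$ calibrated to induce a 15% CV at the LOQ — the
mechanism that makes relative error blow up below the LOQ, as in real
chromatograms. Noise is multiplicative because the published CVs are
scale-free and the hormone levels span four orders of magnitude.

Parameter conventions:

* `default_noise_model()` carries the validated assay's per-analyte
  magnitudes (intraday CV 2–8%, interday 3–12%, recovery 27–87%, matrix
  effect 85–95%). The interday column is read as the **total** pooled
  interday CV; the generator derives the between-run component as
  $\sqrt{\mathrm{inter}^2 - \mathrm{intra}^2}$, so the pooled estimator the
  validation module computes targets the stated value.
* `default_degradation_model()` is first-order — endpoint retentions
  under-determine kinetics, and one rate per (analyte, temperature) is the
  minimal model reproducing them. Frozen (−18 °C) rates are zero; at 20 °C
  every analyte retains ≥ 85% through day 28 except cortisol, parameterized
  to ~86% at day 14 (and hence < 85% at day 28).
* `default_cohort_model()` draws lognormal between-subject serum levels per
  (analyte, sex) at healthy-active-adult magnitudes (e.g. testosterone
  5.2 ± 1.4 ng/mL male, 0.2 ± 0.1 female) and truncated-normal hematocrits
  (0.47/0.40 ± 0.02, bounded to [0.30, 0.55]). Estradiol and progesterone
  are female-only; the luteal-phase statistics are used as given — no
  menstrual-cycle time model is attempted.
* `response_model()` sets an arbitrary instrument slope (area ratio 2 at the
  top calibrator) and a fixed nominal ISTD area; all results are invariant
  to both by construction.
* Calibrator levels are config-driven: 6 geometric levels from the LOQ to a
  physiologically covering maximum per analyte, plus a blank; the QC sits at
  the geometric midpoint. Serum measurement error in paired studies reuses
  the capillary intraday CV (no separate serum-assay CV is available).

Every generator takes a `seed` and is byte-reproducible.

### What passing tests do and do not show

The simulator emulates the *statistical* structure the analysis assumes:
compartment mixing, multiplicative run/replicate noise, attenuations,
first-order decay, lognormal cohorts. It does not emulate chromatographic
reality — co-elution, integration errors, device volume bias, hemolysis,
derivatization chemistry, menstrual-cycle dynamics — so green tests certify
the arithmetic and the statistical behaviour of the pipeline, not the
field performance of any particular assay.

One finding from the simulation study deserves emphasis: at the default
noise magnitudes the *complete* battery passes in roughly half of simulated
batches. The marginal gates are progesterone's linearity (single-point 8%-CV
calibrators against $R^2 \ge 0.99$) and precision (pooled interday truth 12%
against the 15% limit) — population values within one estimator-SD of their
acceptance limits. A single published all-pass table is consistent with
being one (favorable) realization of exactly this regime; the package's
end-to-end test therefore asserts the pass/fail *pattern* over 20 seeds
rather than demanding one lucky batch.

### Study sizes used by the test suite

The suite runs the designs at their native sizes: 3 runs × 6 replicates for
precision, 5 × 6 LOQ levels, 6+6/4+4 recovery and matrix-effect sets,
quadruplicate stability points over the 0–28-day grid, paired studies at
n = 11, cohorts at 32 + 18. Monte-Carlo recovery uses 500 seeds (noise
parameters), 1000 seeds (t-test size, against the 95% binomial band around
0.05), 300 seeds (interday CV, against oracle bounds computed by brute-force
simulation before the implementation existed), and n = 10⁴ for LoA coverage
(accepted range [0.94, 0.96]). The type-I-error study uses cortisol: its
between-subject distribution is nearly identical across sexes, so the
differences are close to normal and the t-test's nominal size is the right
reference; a testosterone-style 10-female/1-male mixture puts ~96% of the
difference variance on one subject and makes the t-test grossly
conservative — a property of the design, not of the implementation.

## Known limitations

* Authentic (non-surrogate) samples do not contain the surrogate blank
  residual, so the symmetric blank subtraction slightly under-reports
  analytes with a large residual (≈ 3% for DHEA-S at cohort levels). The
  correction convention is flagged in every report.
* The LOQ of estradiol (0.04 ng/mL) sits above male/early-follicular serum
  levels; cohort simulations censor accordingly, as the assay would.
* No regression-based method comparison (Passing–Bablok, Deming) and no
  serum↔VAMS conversion factor: deriving one needs a larger paired cohort
  than the n = 11 design the agreement module targets.
* Selectivity is a pass-through boolean: chromatogram inspection cannot be
  computed from peak areas.
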