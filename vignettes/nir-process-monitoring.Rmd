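---
title: "Quantitative on-line NIR process monitoring with nirflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative on-line NIR process monitoring with nirflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirflow)
```

## The monitoring problem

Water precipitation is a purification step in the manufacture of
botanical injections: adding water to an ethanol extract precipitates
fat-soluble impurities, while the phenolic-acid actives — danshensu
(DSS), protocatechuic aldehyde (PA), rosmarinic acid (RA) and
salvianolic acid B (SAB) — are supposed to stay in solution. Some of
each active is nevertheless lost by co-precipitation, so their
concentrations must be tracked through the batch. Off-line HPLC gives
accurate values but only every couple of minutes and with a lag;
an FT-NIR spectrometer reading a bypass flow cell produces an
absorbance spectrum every 30 s in real time. `nirflow` implements the
chemometric bridge between the two: multivariate calibration models
that turn each NIR spectrum into the four concentrations instantly.

The pipeline is the standard one in process analytical technology
(PAT):

1. exclude unusable spectral regions (saturated or noise-dominated),
2. pretreat the remaining channels (derivatives, scatter correction),
3. regress pretreated spectra on reference concentrations with partial
   least squares regression (PLSR), choosing the number of latent
   variables (LVs) by leave-one-out cross-validation,
4. judge each model by the usual figures of merit, and
5. stream new spectra through the accepted models.

## The PLSR core

`plsr_nipals()` implements single-response NIPALS. With
column-centred spectra $X$ and centred concentrations $y$, each
component $a$ computes

$$w_a = X^\top y / \lVert X^\top y \rVert,\qquad
  t_a = X w_a,\qquad
  p_a = X^\top t_a / t_a^\top t_a,\qquad
  q_a = y^\top t_a / t_a^\top t_a,$$

then deflates $X \leftarrow X - t_a p_a^\top$,
$y \leftarrow y - t_a q_a$. The regression vector is
$b = W (P^\top W)^{-1} q$ with the intercept recovered from the
centring means. Channels are centred but *not* variance-scaled — all
channels share absorbance units, and autoscaling would blow up the
noise-only channels. NIPALS (rather than SIMPLS or kernel PLS) was
chosen because the single-response case makes it the simplest
factorization to verify independently; the test suite checks it
against a separately coded per-component oracle, against ordinary
least squares at full rank, and against an external PLS
implementation.

Cross-validation (`loo_rmsecv()`) refits the model on every
leave-one-out fold, including re-centring and refitting any
data-dependent pretreatment state (the MSC reference spectrum), so no
information from the held-out sample leaks into the fold's model. One
NIPALS run per fold supplies the predictions for *all* component
counts because NIPALS components are nested; a brute-force test
refitting separately per (fold, count) confirms the equivalence to
$10^{-10}$. `select_lv()` takes the RMSECV argmin with ties broken
toward fewer components, capped at 10 by default — about one tenth of
a typical ~100-sample calibration set, a conventional guard against
overfitting. Whether a parsimony rule such as a one-standard-error or
F-test criterion should replace the plain argmin was an open choice;
the argmin is used because it is the only criterion that can be read
off the screening table directly, and the cap bounds its optimism.

## Spectral pretreatment

`pp_spec()` builds ordered pipelines from seven operators. Their exact
definitions vary between vendor packages; the ones implemented here
are documented stand-ins chosen once:

* **SG derivative** (`sg_derivative()`): moving-window least-squares
  polynomial fit (default 17 points, quadratic — the conventional
  choice when only the window width is reported), derivative of the
  fitted polynomial at the window centre, divided by the grid step so
  a first derivative has units AU/cm$^{-1}$ and results are
  grid-independent. Edge channels shrink the window to the channels
  that exist and refit (asymmetric least squares) rather than padding,
  so the channel count — and with it all region bookkeeping — is
  preserved.
* **SLS** (straight line subtraction): per-spectrum OLS line in
  wavenumber removed (degree-1 detrend).
* **VN** (vector normalization): subtract the mean intensity, scale to
  unit Euclidean norm.
* **SNV**: per-spectrum centring to mean 0 and sample SD 1.
* **MSC**: OLS regression of each spectrum on the mean calibration
  spectrum, then removal of the fitted offset and slope. The reference
  is part of the fitted state: estimated from calibration data by
  `pp_fit()`, stored, and reused verbatim by `pp_apply()` at
  prediction time.
* **Constant offset elimination**: subtract the spectrum minimum.

Pretreatment is applied *after* region extraction, and window-based
operators (SG, SLS) act independently inside each contiguous region so
a filter window never straddles the excluded gap between 6100 and
7700 cm$^{-1}$. In the pipeline `1st Der + SLS` the listed order is
taken literally: derivative first, then detrend.

## Region selection

Raw process spectra saturate below ~5450 cm$^{-1}$ (water absorption
drives absorbance past 1.5 AU, i.e. zero transmissivity) and are
noise-dominated inside the strong water bands and above
~9400 cm$^{-1}$. `saturation_mask()` excludes any channel on which
*any* calibration spectrum reaches 1.5 AU (the threshold is inclusive).
The default modeling windows are the closed intervals
[5450, 6100] and [7700, 8700] cm$^{-1}$ (206 channels on the default
grid); the wider screening variant [5450, 6100] + [7400, 9500] is
available as `alt_regions()`. `correlation_profile()` reports the
per-channel Pearson correlation with concentration; the conventional
0.6 level is a diagnostic to confirm a window choice, not an automatic
filter — automatic interval searches (iPLS and relatives) are out of
scope.

## What the synthetic study emulates

No spectra from a real campaign ship with the package, so
`simulate_study()` generates a full five-batch campaign with the
statistical structure the calibration assumes:

* **Grid**: 4000–12000 cm$^{-1}$ at 8 cm$^{-1}$ (1001 channels),
  stored ascending. Instruments are sometimes configured to start at
  4500 cm$^{-1}$; the wider range is the default and the narrower one
  is a `wn_grid()` call away.
* **Chemistry**: Beer–Lambert mixing, $A = \sum_a c_a
  \varepsilon_a(\nu) + A_{water}(\nu)$. Pure-component signatures
  $\varepsilon_a$ are Gaussian band sums placed inside the two
  modeling windows, with deliberate overlap between analytes. Plateau
  concentrations default to the end-of-process batch averages of the
  study system (1.28, 0.260, 0.564, 2.07 mg/mL).
* **Trajectories**: two phases joined continuously at $t = 0$.
  During water addition ($t<0$, 30 min) concentration follows exact
  dilution $c(t) = c_{start}V_0/(V_0 + q(t + D_w))$ (100 L, 1 L/min
  by default); during the thermostatic stage ($0 \le t \le 100$ min)
  it relaxes first-order to the plateau. Loss fractions (18–35 %) and
  rates (0.035–0.08 min$^{-1}$) differ per analyte so the four
  trajectories are linearly independent — without that, one latent
  variable would explain every analyte and the calibration exercise
  would be degenerate. A lognormal per-batch scale (sdlog 0.03,
  matching the few-percent batch-to-batch RSDs seen in end-of-process
  assays) makes batches genuinely different.
* **Measurement model**: $A(\nu) = m\,[\mathrm{chem}] + \alpha +
  \beta\nu + e(\nu)$ with lognormal multiplicative scatter
  ($\sigma_{\log} = 0.01$), per-spectrum baseline offset
  ($\sigma = 0.01$ AU) and tilt ($\sigma = 2\times10^{-6}$
  AU/cm$^{-1}$), and white noise (floor $10^{-3}$ AU) inflated 5-fold
  at the water-band maxima — reproducing the noise pattern a flowing
  sample produces from 4600–5450 and 6100–7500 cm$^{-1}$. Water bands
  (amplitudes 2.5–3 AU) saturate the low-wavenumber region so the
  saturation mask has real work to do.
* **Schedule and roles**: spectra every 0.5 min, reference samples
  every 2 min (the reference cadence must be a multiple of the
  spectral one so every reference row has a paired spectrum); batch 1
  is the pre-experiment, batches 2–4 calibrate (3 × 66 = 198 paired
  samples), batch 5 validates (66). Reference concentrations are the
  exact trajectory values by default — the reference assay is treated
  as ground truth, with `reference_noise_sigma` available when assay
  error should be studied.
* **Seeding**: batch $i$ is drawn under `base_seed + i`, so any batch
  is reproducible in isolation and the whole study is bit-deterministic
  in `(config, base_seed)`.

What the generator does *not* emulate: real analyte NIR signatures
(Gaussian bands stand in for overtone/combination structure),
unmodelled co-varying matrix constituents, drift of the instrument
between batches, bubbles/particulates, or nonlinear detector response.
Because every systematic effect in the simulator is one the pipeline
is designed to remove, synthetic figures of merit are *more favourable*
than a real campaign's (validation RSEP well under 1 % here, versus
the few-percent values typical of real water-precipitation
monitoring). Passing tests therefore demonstrate correctness of the
algorithms and honest information flow, not field performance.

## Figures of merit and acceptance

`rmse()` uses the uniform-$n$ convention for RMSEC, RMSECV and RMSEP
alike so the three are directly comparable. RSEC/RSEP
(`rse()`) normalize the RMS residual by the RMS of the reference
values, the standard definition in NIR process work. RPD (`rpd()`) is
the sample SD (n−1) of the set's reference values over the relevant
RMSE; the calibration RPD uses RMSEC (consistent, via
$RPD \approx 1/\sqrt{1-R^2}$, with how screening tables are usually
tabulated), the prediction RPD uses RMSEP. A model is accepted for
on-line use when RSEP < 20 % *and* RPD > 3.0, both strict
(`acceptance_check()`).

One caveat `batch_summary()` deliberately does not paper over: RSDs
recomputed from *rounded* per-batch concentrations need not reproduce
RSDs computed from the unrounded assay values (for the reference
end-of-process table, only RA's 3.13 % survives the rounding; the
recomputed DSS/PA/SAB values are 2.06/4.45/7.42 %). The function
computes from the values it is given and leaves reconciliation to the
caller.

## Workflow

```{r workflow, eval = FALSE}
study <- simulate_study(study_config())

# screening: which pretreatment wins by RMSECV?
comparison <- compare_pretreatments(study)
attr(comparison, "shared_winner")

# final models with the default first-derivative pipeline
cal <- nir_calibrate(study)
summary(cal)
plot(cal)

# stream the validation batch as an on-line monitor would
mon <- monitor_stream(cal, study$batches[[5]]$spectra,
                      reference = study$batches[[5]]$reference,
                      control_limits = default_control_limits(study$config))
mon
```

`compare_pretreatments()` screens the six standard pipelines per
analyte and flags the RMSECV winner (ties to the simpler pipeline,
i.e. the one listed first); because no single criterion for "best
pretreatment" is universal, the table reports both per-analyte winners
and a shared winner by lowest mean RMSECV rank. SNV and MSC are not in
the default screening list but are first-class pipeline steps.
`monitor_stream()` consumes spectra one at a time, emits one record
per spectrum, flags predictions outside control limits (default:
plateau ± 20 %), continues past record-level errors, and — when a
reference table is supplied — closes the loop with RSEP/RPD against
the reference assay. Streamed predictions are identical to batch
`predict()` output on the same spectra.

## Numerical and design notes

* Degenerate inputs fail loudly and early: zero-variance spectra in
  SNV/VN, constant `y` in correlation or $R^2$, MSC slopes below
  $10^{-12}$, an exhausted covariance in NIPALS ("no covariance
  remaining" — typically a request for more components than the data's
  chemical rank, common on noise-free synthetic data), RMSE of 0 in
  RPD (a perfect fit makes RPD undefined).
* Saturation masking is monotone in the threshold; channel extraction
  is idempotent and independent of interval listing order.
* Model files are JSON with full-precision doubles; a load→save cycle
  is bit-identical and a round-tripped model predicts identically.
  YAML study configurations round-trip at 17 significant digits, which
  is exact for IEEE doubles.
* Calibration artifacts are provably independent of the validation
  batch (tested by corrupting it and comparing coefficients).
* Problem sizes: the default campaign (5 × 261 spectra × 1001
  channels; LOO over 198 samples × 10 LVs × 4 analytes) calibrates in
  a few seconds on one core; the test suite uses a compact variant
  (10 + 20 min phases, 1/2 min cadences) wherever full scale adds
  nothing.

## Limitations

PLS2 (joint multi-response fitting) is intentionally absent — one
model per analyte mirrors how process models are validated and
released individually. No uncertainty intervals accompany predictions.
The proprietary binary formats of instrument vendors are not parsed;
spectra enter and leave as CSV. Automated wavelength-interval
selection is out of scope, as are physical instrument models (the
noise model is a statistical proxy for pump- and flow-induced
effects).
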