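---
title: "Methods: quantifying the benzodiazepine-site GABA shift with [11C]flumazenil PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the benzodiazepine-site GABA shift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gabashift)
```

## The measurement problem

Raised extracellular GABA increases the affinity of GABA-A receptors for
benzodiazepine-site ligands (the "GABA shift"). With PET this appears as an
increase in [11C]flumazenil binding between a baseline scan and a scan after
a GABA-elevating challenge. Because flumazenil has substantial specific
binding even in reference regions, the analysis works with the total
distribution volume $V_T$ from full kinetic modeling with an arterial input
function, and extracts the affinity change with a graphical (Lassen)
analysis that needs no reference region at all.

## Input function

Arterial samples (about 35 per scan, dense in the first two minutes) give
total plasma activity. The unmetabolized parent fraction, measured at 2, 5,
15, 30, 45, 75 and 90 min, is fitted as

$$f(t) = a e^{-bt} + c,$$

an exponential decay to a plateau, and used to interpolate between
measurements; predictions are clamped to $[0, 1]$. The parent input curve
(total activity times fitted fraction) is fitted to a sum of three
exponentials *from the time of peak plasma activity*; before the peak the
measured values themselves are used, by linear interpolation anchored at
zero activity at injection. That pre-peak convention is a design choice: the
bolus shape before the peak is never well modeled by smooth functions, and
keeping the measured points preserves it. On ties at the maximum, the
earliest sample is the peak.

The area under the curve is the pre-peak trapezoid plus the closed-form tail
integral $\sum_i A_i/\lambda_i$; clearance is dose/AUC, converted to L/h at
the reporting layer. The plasma free fraction $f_P$ is the mean
ultrafiltrate-to-total ratio over plasma triplicates divided by the same
ratio for saline, which corrects for filter retention of free tracer. The
correction formula is our choice (the retention measurement itself does not
dictate one), so both corrected and raw values are returned.

Both plasma fits use *unweighted* least squares; frame-duration weighting is
specific to the emission data. Each fit is multi-started over log-spaced
rate seeds (three per configuration) to avoid local minima; the best
residual wins, with ties broken toward the smaller rate vector.

## Two-tissue-compartment model

With rate constants $K_1$ (mL g$^{-1}$ min$^{-1}$, delivery), $k_2$
(min$^{-1}$, efflux), $k_3$ (binding) and $k_4$ (dissociation), the tissue
impulse response is

$$h(t) = \frac{K_1}{\alpha_2 - \alpha_1}\left[(k_3 + k_4 - \alpha_1)e^{-\alpha_1 t} + (\alpha_2 - k_3 - k_4)e^{-\alpha_2 t}\right],
\qquad
\alpha_{1,2} = \frac{(k_2+k_3+k_4) \mp \sqrt{(k_2+k_3+k_4)^2 - 4k_2k_4}}{2},$$

and the tissue curve is $h \ast C_p$ with $C_p$ the parent input. The
convolution is evaluated in closed form: exponential-times-linear integrals
on the pre-peak piecewise-linear segment and exponential-times-exponential
integrals on the fitted tail, written in forms that only ever exponentiate
non-positive arguments (no overflow at late times) and switch to series
expansions where the exact expressions cancel catastrophically
(thresholds around $10^{-3}$ in the relevant dimensionless products, giving
roughly $10^{-10}$ relative accuracy throughout).

A frame's predicted value is the *time-average of the tissue curve over the
frame interval* — matching how emission frames integrate counts — not a
midpoint evaluation. Averages use 5-point Gauss–Legendre quadrature on
subintervals split at the input knots, where the integrand is smooth. The
tests verify agreement with a brute-force fine-grid numerical convolution to
better than $10^{-4}$ relative error across random parameter sweeps.

With $k_3 \ge 0$ the eigenvalues can only coincide when $k_3 = 0$ and
$k_2 = k_4$; that $t e^{-\alpha t}$ limit is evaluated by symmetric
eigenvalue splitting ($\alpha(1 \pm 10^{-6})$), which reproduces the
analytic limit to $O(10^{-12})$ and is covered by the oracle tests.

### Fitting

The fit minimizes $\sum_i d_i (y_i - \hat y_i)^2$ with $d_i$ the frame
acquisition time — longer frames carry proportionally more information under
counting statistics. Levenberg–Marquardt runs from four spread starting
points within numerical-safety bounds ($K_1 \in (0, 2]$,
$k_2, k_3, k_4 \in (0, 1]$ min$^{-1}$); the model itself is meant to be
unconstrained, so a free refit from the best bounded solution is the final
answer whenever it improves the weighted residual and stays physically
admissible. Convergence diagnostics are returned rather than silently
repaired. Outcome measures:

$$V_T = \frac{K_1}{k_2}\left(1 + \frac{k_3}{k_4}\right), \qquad
BP_P = V_T - V_{ND}, \qquad BP_{ND} = V_T/V_{ND} - 1,$$

with $V_{ND}$ the pons $V_T$. $B_{max}$ and $K_D$ are not separately
identifiable from these data and are never estimated; only the composite
$BP_P \propto f_P B_{max}/K_D$ is interpreted. Decay correction is assumed
already applied to both plasma and PET data; the module performs none.

## Regions

Ten component ROIs (DLPFC, OFC, MPFC, ACC, PC, OC, AMY, HIP, ENT, PHG) are
aggregated into three functional composites — Association Cortex, Sensory
Cortex, Medial Temporal Lobe — as volume-weighted averages; bilateral
regions average left and right. Composites are computed on $V_T$/BP values
(mirroring the output-table structure), with the group-mean sampled volumes
shipped as defaults and per-subject volumes overriding when available
(subject-specific weighting is the better estimator when the data exist).

## Lassen analysis

For each subject, ordinary least squares of
$V_{T,\mathrm{base}} - V_{T,\mathrm{post}}$ on $V_{T,\mathrm{base}}$ across
the ten ROIs gives slope $= \Delta BP$ and x-intercept $= V_{ND}$, assuming
the affinity change is uniform across regions. The affinity shift is
$1 - \mathrm{slope}$. Unweighted OLS is used deliberately; orthogonal
regression could be argued (both axes share measurement error) but plain
regression is the field's convention for this plot and is what the group
summary statistics assume. Fits are per subject, then summarized by
unweighted mean and SD across subjects — not pooled. A slope of exactly zero
leaves the x-intercept undefined; it is flagged, not an error, and negative
or extreme shifts are reported raw rather than truncated.

## Group statistics

Paired two-tailed t-tests with paired-difference Cohen's
$d = \overline{(x_{base} - x_{post})}/SD(x_{base} - x_{post})$ (negative
when binding increases, matching the table sign convention); per-subject
percent change (whose mean is deliberately *not* the ratio of group means);
and a split-plot repeated-measures ANOVA with brain region as the
within-scan factor and condition as the between-scan factor — scans, not
subjects, are the units, which is the stated hybrid design even though
condition is within-subject; a fully-repeated alternative would change the
error strata and is out of scope. No multiple-testing correction is applied
anywhere (uncorrected $\alpha = 0.05$ convention). PET–EEG correlations use
Pearson's $r$ after a Kolmogorov–Smirnov check of each variable against a
normal with estimated mean and SD (the estimated-parameter reference is a
choice; the classical Lilliefors correction would shift the KS p-values but
not $r$).

## EEG induced gamma power

Epochs (250 Hz, −400 to +1900 ms around the cue) are screened per trial:
any channel with a within-epoch amplitude range above 200 µV or a
consecutive-sample step above 60 µV rejects the trial (strict inequalities;
boundary cases at exactly 200/60 µV are kept). The time-frequency transform
is a complex Morlet wavelet, $\psi(x) \propto e^{-x^2/2} e^{i\omega_0 x}$
with $\omega_0 = 7$, at 20 linearly spaced center frequencies spanning
14–80 Hz (the spacing is a choice and configurable; the 42 Hz sub-band of
interest falls within one step of 41.8 Hz). The printed form of the wavelet
admits two readings of the constant; we read it as the cycles-like parameter
$\omega_0$ and normalize amplitudes so a unit sinusoid at a sub-band's
center frequency yields unit peak power, independent of frequency.

Induced power is the mean over trials of per-trial squared magnitude, so
activity with random per-trial phase survives; evoked power (transform of
the trial average) is provided for contrast. Baseline correction subtracts
the mean power in −300 to −100 ms per channel and frequency (subtraction
rather than ratio/dB; the raw-power objects are kept so other conventions
can be applied). The frontal summary averages two frontal electrodes over
the 42 Hz sub-band and the 500–1500 ms delay window, returning per-condition
values and the high-minus-low contrast. The electrode pair is configurable
because published electrode listings for such montages are often internally
inconsistent; the default is E23/E24. ICA artifact removal, re-referencing,
filtering and bad-channel interpolation are upstream concerns: the module
consumes cleaned epochs.

## The synthetic-data generator

The generator reproduces the study conditions so that every stage has
ground truth:

- **Plasma**: linear rise from zero to a peak at 1 min (the pre-peak shape
  is unspecified in practice and linear is our choice), tri-exponential tail
  (default rates 2, 0.25, 0.02 min$^{-1}$), parent fraction
  $0.55e^{-0.15t} + 0.40$, ~35 samples dense early, metabolite samples at
  the seven study times.
- **Scan pairs**: ten regional baseline $V_T$ values at the observed
  magnitudes (5.1–7.2 mL g$^{-1}$), cortical/limbic $K_1$ near 0.26–0.42
  mL g$^{-1}$ min$^{-1}$, a shared nondisplaceable volume (default
  1.0 mL g$^{-1}$), and a uniform shift $s$ applied by scaling $k_4 \to
  k_4/s$ with $K_1, k_2, k_3$ fixed — an affinity increase slows
  dissociation and leaves delivery untouched, consistent with unchanged
  $K_1$ under challenge. Before noise,
  $V_{T,post} = V_{ND} + s\,(V_{T,base} - V_{ND})$ holds exactly.
- **Frame noise**: zero-mean Gaussian with
  $SD = \sigma\sqrt{\hat y_i/d_i}$, the variance structure that makes
  frame-duration weighting the right weighting; $\sigma$ is calibrated via
  `calibrate_noise_scale()` to a target early-frame CV (10% for
  study-condition runs). This is a documented stand-in for counting
  statistics, not a scanner noise model.
- **EEG**: pink (1/f) background noise plus a condition-scaled 42 Hz burst
  with Hann envelope confined to 500–1500 ms and independent uniform phase
  per trial — induced, not evoked, by construction — with a 70%/30%
  low/high-control trial split.

What the generator does *not* emulate: image reconstruction and scanner
effects, head motion, dispersion/delay between sampling site and brain,
between-region noise correlation, real EEG artifact topographies (blinks,
ECG), or volume-conduction structure across channels. Passing tests
therefore demonstrate correctness of the estimators under the stated model,
not robustness to every real-data pathology.

## Reproducibility and problem sizes

All randomness flows through explicit seeds; simulation functions restore
the caller's RNG state. The test suite runs the forward-model oracle on
100-draw parameter sweeps, noiseless generate-and-refit on 20 draws,
100 Monte-Carlo noisy refits at the 10% early-frame CV calibration
(median $|V_T|$ bias under 2%), 200-replicate noise-scaling checks, 1000
null simulations for the correlation type-I rate, and 2-subject end-to-end
pipeline runs — sizes chosen to give stable statistics at desk scale.
Cohort-scale runs (9 subjects per dose group) use the same code paths.

## Known limitations

- The pre-peak input convention (linear interpolation of measured values)
  differs from fitting the whole curve; with sparse early sampling the AUC
  inherits sampling error directly.
- The unconstrained final polish can, on very noisy data, return boundary-
  adjacent or poorly conditioned solutions; convergence flags and residuals
  are reported and should be screened, as any kinetic-modeling workflow
  does.
- The split-plot ANOVA treats scans as independent units per the stated
  design; a mixed-effects model would use the pairing and is deliberately
  not provided.
- The Lassen estimate assumes a regionally uniform shift and a shared
  $V_{ND}$; regional heterogeneity biases both slope and intercept, and no
  diagnostic beyond $R^2$ is attempted.
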