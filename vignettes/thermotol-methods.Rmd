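---
title: "Deriving critical heat-injury temperatures from leaf thermal and fluorescence curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving critical heat-injury temperatures from leaf thermal and fluorescence curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotol)
```

## The problem

Heat injury in plant leaves develops through a sequence of molecular events:
reversible impairment of photosystem II (PSII), membrane leakage,
denaturation of proteins, and finally aggregation of cellular compounds.
Three complementary measurement techniques capture different points in that
sequence, and `thermotol` implements the analysis side of all three:

1. **DSC thermograms.** Intact leaf pieces are heated at 1 K min⁻¹ from 25
   to 65 °C in a differential scanning calorimeter while heat flow (mW) is
   recorded; after cooling, the now heat-killed piece is reheated under
   identical conditions (the two runs total 160 min; `dsc_protocol()`).
   Vital leaves show an initial shallow endothermic decline, a steeper
   decline, a sharp endothermic dip (the "jag") and a large exothermic
   peak; reheated heat-killed leaves show only a near-linear decline. Three
   parameters summarise the vital curve: the peak temperatures of the
   endotherm (T_endo, protein denaturation) and exotherm (T_exo,
   aggregation), and T_init, the intersection of two fitted line segments,
   interpreted as the onset of denaturation.
2. **T-F0 curves.** Basic chlorophyll fluorescence F₀ recorded during the
   same heating ramp rises steeply when PSII is impaired. The critical
   temperature T_c (start of the rise, reversible impairment), the first
   peak T_p (irreversible impairment) and a second peak T_pII are extracted.
3. **Classical heat-tolerance assays.** Leaves heated to a ladder of target
   temperatures are scored days later by Fv/Fm; a four-parameter sigmoid
   fitted to Fv/Fm versus target temperature yields LT_10 and LT_50, the
   temperatures causing 10% and 50% tissue damage.

No instrument data ship with the package; a synthetic-data module generates
all three curve types with known ground truth so that every analysis stage
is testable by parameter recovery.

## The DSC analysis

All analysis happens on fresh-weight-normalized heat flow (mW g⁻¹;
`normalize_heat_flow()`), which makes the extracted temperatures
independent of sample mass, and on a uniform 0.1 K temperature grid
(`resample_uniform()`). The package-wide sign convention is
exothermic-positive; instruments that write endothermic-positive traces are
handled by the `endo_up` flag on reading.

**Peak detection.** The exotherm is the most prominent local maximum at or
above 50 °C (`search_min_exo`), with topographic prominence measured
against the whole curve and a threshold of 5% of the curve's heat-flow
range (`prominence_frac`; the original determination was by eye, so this is
a tunable formalisation). The endotherm is the deepest local minimum below
the exotherm's onset. A plain prominence rule is not sufficient there: any
curve that declines into a large peak has a topographically prominent
minimum at the foot of the peak, whether or not a real endothermic dip
exists. A candidate minimum therefore additionally has to drop at least the
same threshold below the continuation of the decline that precedes it,
estimated by a short line fitted 2–4 K to its left (`endo_ref_offset`).
This rejects the decline-to-peak corner on dip-free (heat-killed-like)
curves while leaving true jags untouched.

**Line fitting and T_init.** Following the published procedure, a 10 K band
slides from 29 °C up to T_endo in 0.1 K steps; within each band an ordinary
least-squares line of heat flow on temperature is fitted and the band with
the highest R² wins (ties go to the lowest band start, for
reproducibility). A 3 K band then searches between the first line's upper
edge and T_endo the same way, and T_init is the intersection of the two
lines. Two numerical details deserve mention:

* On noiseless piecewise-linear curves every band inside a linear segment
  ties at R² = 1, and the lowest-start tie-break would leave the second
  search room to re-fit the baseline, making the two lines parallel. The
  search therefore records the upper edge of the highest-starting band that
  is *colinear* with the winning line (`t_high_tied`) and starts the second
  search there. On noisy data R² maxima are unique and this reduces to the
  plain band-edge rule (`dsc_config(second_lower = "selected")` restores
  the literal rule).
* Band fits and extremum detection run on a lightly smoothed signal
  (centered moving mean, 5 points = 0.5 K; `smooth_k`). Without it,
  realistic noise both creates spurious single-point "peaks" above the
  prominence threshold and inflates the R² of steep mixed-slope bands
  relative to the true shallow baseline band, biasing T_init by ~2 K.
  A centered moving mean leaves linear segments exactly linear, so all
  noiseless results are unchanged.

**Vitality.** A curve is `vital` when both dip and peak pass their
thresholds, `heat_killed` when neither does and one line fits the whole
span with R² ≥ 0.98 (`linearity_r2`; the reheated-curve description in the
source is qualitative, so this constant is a design choice), and
`indeterminate` otherwise — e.g. a clear exotherm with a sub-threshold dip.

## The T-F0 analysis

The classical determination of T_c is graphical. It is formalised here as
the intersection of two lines: a *baseline* line through the flat
low-temperature region and a *rise* line through the steep initial F₀
increase. Two departures from the obvious construction were necessary:

* The baseline is the **flattest** 5 K band below the F₀ maximum
  (`baseline_method = "min_slope"`), not the best-fitting one: R² is
  undefined on an exactly flat band and, under noise, any steep segment
  out-scores a genuinely flat baseline, which would put the "baseline" on
  the rise itself.
* The rise line is the 3 K band of maximal slope between the baseline and
  the first peak, with the search capped at the temperature where F₀ has
  climbed halfway from the baseline level to that peak
  (`rise_cap_frac = 0.5`). Without the cap the steeper left flank of the
  T_p peak itself wins, biasing T_c upward by ~2.5 K on default synthetic
  curves.

T_p is the first prominent local maximum above T_c, T_pII the next one
above T_p (absent is a valid outcome; the prominence threshold is
boundary-inclusive). Thresholds are invariant under any positive rescaling
of F₀ because every constant scales with the signal range.

## The heat-tolerance fit

The damage model is `y = A2 + (A1 − A2) / (1 + (x/x0)^p)`, evaluated in
log space (`plogis(−p·log(x/x0))`) so large `p` cannot overflow. For
`p > 0`, `x0` is the inflection and equals LT_50; inverting at damage
fraction `d` gives the closed form `LT_d = x0 · (d/(1−d))^(1/p)`, which the
tests verify against numeric root finding to 10⁻⁶ K. Fitting uses bounded
nonlinear least squares (`nls`, port algorithm) with data-driven starts
(`A1`/`A2` from the extreme per-temperature means, `x0` at the
mid-response temperature, `p = 30`, a typical steepness for damage curves
dropping over ~5 K). Damage is defined on the fitted curve's own span
(A1 → A2) rather than against the unheated control, because both
asymptotes are free parameters in the model.

The published resampling scheme is reproduced by `bootstrap_lt()`: 250
repetitions, each drawing 3 replicates per target temperature — without
replacement by default, since "three samples were used" reads as
subsampling the 6–10 available replicates; with-replacement sampling is a
flag. Failed repetitions are dropped with their count reported rather than
redrawn, keeping the 250-repetition accounting transparent; more than 50%
failures is an error. Both bootstrap medians and means are reported, since
the original summary statistic is unstated.

## The synthetic world

Generators are pure functions of a truth object and its seed.

* **Vital thermogram** (`dsc_truth()`): two-segment piecewise-linear
  decline (slopes −0.5 and −3 mW g⁻¹ K⁻¹, breakpoint 52 °C) minus a
  Gaussian dip (center 57.5 °C, depth 12 mW g⁻¹, width 1 K) plus a
  Gaussian peak (center 60.5 °C, height 25 mW g⁻¹, width 0.8 K), plus
  homoscedastic Gaussian noise (sd = 2% of the exotherm height). The
  centers sit inside the pooled ranges reported for summer-active
  mountain-plant leaves; widths are visual matches to the published curve
  shape, and the noise model is a choice (none is stated). Because the
  Gaussians ride on a slope, the true extremum of the analytic curve is
  displaced from the Gaussian center by roughly |slope|·width²/amplitude
  (≈ +0.23 K for the default dip, −0.07 K for the peak); the truth object
  records these analytic extrema (`t_endo_true`, `t_exo_true`) and they —
  not the centers — are the recovery targets. Likewise T_init's truth is
  the construction breakpoint, while the estimator intersects *fitted*
  lines, so the two coincide only up to band-placement error; tolerances
  (2 grid steps noiseless) are set accordingly.
* **Reheat thermogram** (`reheat_truth()`): a single declining line plus
  noise.
* **T-F0 curve** (`f0_truth()`): flat baseline (100 r.u.) to T_c = 43 °C,
  linear rise (40 r.u. K⁻¹) saturating at 50 °C, Gaussian peaks at 52 and
  58.5 °C.
* **Viability assay** (`assay_truth()`): sigmoid truth (A1 = 0.8,
  A2 = 0.05, x0 = 50 °C, p = 40) sampled at ten targets 38–56 °C in 2 K
  steps with 8 replicates (within the stated 6–10) and replicate noise
  sd = 0.03 in Fv/Fm units, clipped to [0, 1]; optionally an unheated
  control and a single 65 °C full-damage sample, mirroring the published
  design. Note the single 65 °C sample cannot enter a without-replacement
  3-per-temperature bootstrap, so bootstrap experiments generate with
  `full_damage_temp = NA`.

What a green recovery test establishes is that the estimators recover the
parameters of *this* stated world — additive homoscedastic noise on
analytically clean shapes. Real thermograms have drifting baselines,
asymmetric transitions, overlapping events and autocorrelated instrument
noise; none of these are emulated, and the published species-level
threshold values cannot be reproduced because the underlying instrument
data were never released.

## Worked example

```{r example}
set.seed(1)
g <- generate_thermogram(dsc_truth(seed = 1))
analyze_thermogram(g$thermogram)

tf0 <- analyze_f0(generate_f0_curve(f0_truth(seed = 3))$curve)
tf0

assay <- generate_viability_assay(assay_truth(seed = 4, full_damage_temp = NA))
bootstrap_lt(assay$assay, per_temp = 3, reps = 250, seed = 5)
```

## Numerical choices and degenerate inputs

* Grid step 0.1 K everywhere (matches the one-decimal rounding used for
  mean curves); band search step likewise.
* R² of an exactly flat, exactly fitted band is defined as 1 (0/0
  otherwise); residual-vs-total comparisons use a relative epsilon.
* Ties in any band criterion break toward the lowest band start.
* Line intersections require |Δslope| ≥ 10⁻⁶ mW g⁻¹ K⁻¹, otherwise a
  degeneracy error; an intersection falling outside the curve's span is
  discarded with a diagnostic.
* Prominence thresholds are boundary-inclusive with a 10⁻⁹-relative slack
  so an exactly-at-threshold feature counts.
* Fresh masses outside the 9.40–33.46 mg working range warn but do not
  fail (an observed range, not a requirement); non-positive mass, Fv/Fm
  outside [0, 1] and non-monotone heating ramps are hard errors.
* `analyze_thermogram()` and `analyze_f0()` never silently default: stages
  that fail on a feature-less curve yield `NA` plus a diagnostic message.

## Known limitations

* Enthalpy (peak-area) integration, overlapping-transition deconvolution
  and scan-rate kinetics are out of scope, as are ANOVA-style group
  comparisons (the summary tables are designed to be consumed by standard
  statistics tools).
* The criterion by which an exotherm is "undeterminable" in real data is
  unstated in the source; the absent-exotherm pathway models it via the
  prominence threshold only.
* LT_10/LT_50 are assay-level (not per-leaf) quantities; correlating them
  with per-leaf parameters should use species means
  (`correlate_parameters` operates on whatever pairing the parameter table
  encodes).
* "Pearson rank correlation" is ambiguous; both Pearson (default) and
  Spearman are available and the method is recorded in the result.
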