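---
title: "Methods: phosphorescence-lifetime oximetry, RBC flux and densitometry in plimox"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phosphorescence-lifetime oximetry, RBC flux and densitometry in plimox}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plimox)
```

## The measurement

Two-photon phosphorescence-lifetime imaging (2P-PLIM) encodes the oxygen
partial pressure (pO2) of blood plasma in the decay rate of an injected
phosphorescent probe: molecular oxygen collisionally quenches the excited
triplet state, so higher pO2 means a shorter phosphorescence lifetime. A
pointwise acquisition at one intravascular location consists of repeated
cycles of a 10 µs excitation gate followed by a 290 µs collection window in
which time-correlated single-photon counting (TCSPC) hardware accumulates a
time-binned histogram of photon arrivals. The 300 µs cycle is repeated 2000
times (0.6 s) to build one decay histogram, and 20 such repetitions are
acquired per location. The same per-cycle photon totals, viewed as a 0.6 s
time course, also carry the capillary's red-blood-cell traffic: RBCs are not
labeled by the plasma probe, so each passage through the focal volume
produces a transient intensity valley.

## The lifetime model and fit

The core estimator is `plim_fit()`. Its stages, in order:

1. **Repetition rejection.** Animal motion corrupts individual repetitions,
   visible as outlying total photon counts. The per-repetition totals are
   screened with an iterated two-sided Grubbs test: at each iteration the
   single most extreme total is tested against the closed-form critical
   value $G_{\mathrm{crit}}(n,\alpha)=\frac{n-1}{\sqrt n}
   \sqrt{t^2_{1-\alpha/2n,\,n-2}\,/\,(n-2+t^2_{1-\alpha/2n,\,n-2})}$ and
   removed if it exceeds it; iteration stops at the first non-rejection or
   when fewer than 3 repetitions remain. Rejection happens **before**
   averaging. The default $\alpha = 0.05$; the test is undefined below
   $n = 3$, in which case everything is kept with a warning.
2. **Averaging.** The surviving repetitions are averaged per bin.
3. **Windowed mono-exponential fit.** The first 5 µs of the collection
   window are discarded (early bins mix in residual excitation and
   short-lived background), and $y(t) = A\,e^{-t/\tau} + C$ is fitted to
   the remaining 285 µs by Levenberg–Marquardt nonlinear least squares
   with $\tau$ constrained positive. The lifetime is fitted on the averaged
   decay, not averaged over per-repetition fits.
4. **Calibration.** pO2 follows from the Stern–Volmer relation
   $1/\tau = 1/\tau_0 + k_q\,\mathrm{pO_2}$, inverted exactly; hemoglobin
   saturation follows from the Hill equation
   $\mathrm{SO_2} = 100\,\mathrm{pO_2}^h/(\mathrm{pO_2}^h + P_{50}^h)$
   with C57BL/6 coefficients $h = 2.59$, $P_{50} = 40.2$ mmHg.

```{r fit-example}
cal <- plim_calibration()
decays <- replicate(20, simulate_decay(40, cal, photon_budget = 5e4),
                    simplify = FALSE)
fit <- plim_fit(decays, cal)
summary(fit)
```

### Numerical choices

* **Start values** are data-driven and derivative-free: $C_0$ is the mean of
  the last 10% of window bins, $\tau_0^{\mathrm{init}}$ comes from the slope
  of $\log(y - C_0)$ over the first half of the window (guarded against
  non-positive values, falling back to a third of the window span), and
  $A_0$ is the first window bin above $C_0$.
* **Weighting** is unweighted by default, matching generic nonlinear curve
  fitting of a high-SNR averaged decay; Poisson weighting
  ($w_i = 1/\max(y_i, 1)$) is available via `weighting = "poisson"`.
* **Convergence failures** return a flagged result (`converged = FALSE` with
  the optimizer's message), never a silent number. A decay with zero dynamic
  range in the window is a degenerate-input error.
* **Calibration violations** ($\tau > \tau_0$ beyond a $10^{-6}$ relative
  tolerance, i.e. "negative oxygen") are an error unless `clamp_po2 = TRUE`
  maps them to 0 mmHg.
* The probe constants $\tau_0$ and $k_q$ are batch- and
  temperature-specific, so they are configuration with documented defaults
  ($\tau_0 = 40$ µs, $k_q = 2.8\times10^{-4}\,(\mu s\cdot mmHg)^{-1}$),
  chosen so lifetimes span roughly 15–40 µs over 0–150 mmHg. Every accuracy
  contract in the test suite is a round-trip or self-consistency statement,
  so it holds for any valid constants. The implemented calibration is the
  linear Stern–Volmer form; probe-specific calibrations can depart mildly
  from linearity, which is why both constants are exposed.

## Vessel classes, layers and summaries

Diving arterioles and ascending venules are separated by their baseline
(day 0) pO2 at 50 µm subpial depth: strictly above 66 mmHg is an arteriole,
otherwise (ties included) a venule. The classification is frozen at baseline
and propagated to later days of the same vessel. Capillaries are identified
morphologically; primary branches of penetrating vessels carry a metadata
flag and are excluded from capillary pools.

Cortical layers are half-open depth bands — I: [0, 100), II/III: [100, 320),
IV: [320, 450] µm — so each standard measurement depth
{50, 100, 200, 300, 400} µm maps to exactly one layer and a measurement at
exactly 100 µm falls in II/III, giving every layer representation.

Per-layer statistics are mean, SE ($s/\sqrt n$) and the coefficient of
variation CV $= s/\bar x$ with the sample (n−1) standard deviation — the
package's heterogeneity metric. Depth-dependent oxygen extraction is the
non-normalized arteriovenous gap $\mathrm{DOE} =
\overline{\mathrm{SaO_2}} - \overline{\mathrm{SvO_2}}$ per layer (the
SaO2-normalized extraction fraction is deliberately not used). Cohort
aggregation treats the **animal as the unit of averaging**: per-animal layer
statistics are computed first and then averaged unweighted across animals,
with the cohort SE taken over animals; the same convention is applied to
pO2, SO2, flux and their CVs. Longitudinal changes
($\Delta\mathrm{SO_2} = \mathrm{SO_2}(d) - \mathrm{SO_2}(0)$) align the same
vessel point across days before aggregating.

## RBC flux from intensity valleys

`count_rbc()` thresholds a 2000-sample trace and counts valleys:

* **Baseline**: a sliding-window upper quartile (window 101 samples,
  evaluated on a reversal-symmetric decimated grid and interpolated),
  recentred by the normal-theory offset $0.6745\,\hat\sigma$. A rolling
  *median* was rejected during development: it collapses into the valleys
  whenever RBCs occupy more than half of a local window, which happens
  routinely above ~100 RBC/s; the upper quartile tolerates ~75% local
  occupancy while still tracking slow drift.
* **Noise scale** $\hat\sigma$ comes from the *positive*-side residuals only
  (median positive residual ÷ 0.4758, its expectation under Gaussian
  noise), because samples above the upper-quartile envelope are never inside
  valleys — so the estimate stays clean at any realistic occupancy, where a
  MAD over all residuals inflates badly.
* **Detection**: samples strictly below baseline $- k\hat\sigma$ (default
  $k = 3$); runs separated by a single above-threshold sample are merged
  (debounce); runs at least 2 samples (600 µs) long count as valleys; and a
  valley must additionally dip below baseline $- 5\hat\sigma$ (depth
  confirmation). An erythrocyte suppresses ~90% of the plasma signal — about
  9 robust SDs at typical count rates — while paired shot-noise dips sit
  near the 3-SD threshold, so the depth criterion removes essentially all
  false positives without touching true valleys.

The raw estimate is `flux = n_valleys / duration`. Overlapping transits
merge into one valley, so with Poisson arrivals the raw count undercounts by
the factor $e^{-\lambda L}$ ($L$ = transit time) — 16% at 60 RBC/s with the
default 3 ms transit, and worse at higher flux. Because valley onsets occur
at rate $\lambda \cdot P(\mathrm{idle})$ for any i.i.d. transit duration,
and the idle fraction is directly measurable from the thresholded trace, the
package also reports

$$\widehat\lambda \;=\; \frac{n_{\mathrm{valleys}}}
{T\,(1 - \text{occupied fraction})}$$

as `flux_corrected`, and the pipeline uses this merging-corrected estimate
by default (`flux_cohort(..., estimate = "counted")` restores raw
counting; both columns are always present). In simulation the corrected
estimate recovers ground-truth flux across 10–150 RBC/s, while the raw
count's undercount is itself a tested, quantified property.

```{r flux-example}
tr <- simulate_flux_trace(60, seed = 1)
count_rbc(tr)
```

## Immunofluorescence densitometry

`densitometry()` computes, per channel: a maximum-intensity projection over
the full stack thickness (default 40 µm at a 3.96 µm z-step), binarization
at **one** threshold shared by the entire batch, and the percent area
PA $= 100\cdot$ positive/total pixels, globally and within cortical-layer
bands (pial surface at the top image row; rows map to depth via the pixel
size). The histogram-based threshold rule is Otsu's method computed on the
brightest image of the batch and then frozen batch-wide — mirroring
acquisition practice where gain is fixed on one of the brightest slices.
The exact histogram rule used in any given lab is rarely recoverable, so the
threshold can also be supplied explicitly; requesting per-image thresholds
in batch mode is a contract violation, since percent areas are only
comparable under an identical threshold.

## The synthetic forward model

No in vivo recordings ship with the package, so every pipeline stage is
exercised against a generator with retained ground truth:

* `simulate_decay()` draws Poisson counts around
  $A e^{-t/\tau(\mathrm{pO_2})} + C$, with the amplitude scaled so the
  expected total equals the photon budget exactly. The offset defaults to
  $C = 0.5\%$ of the amplitude and the TCSPC bin width to 1 µs (290 bins) —
  fine enough that binning bias on a 20–40 µs lifetime is negligible.
* `simulate_flux_trace()` draws RBC arrivals from a Poisson process
  (memoryless single-file transit), each suppressing the expected per-cycle
  count by 90% for a 3 ms transit; overlaps merge; the arrival list and
  occupancy mask are returned. Defaults (3 ms, 90% depth, 100
  photons/cycle baseline) are chosen so typical capillary fluxes produce
  clearly resolvable valleys at realistic shot noise.
* `simulate_cohort()` builds a longitudinal two-cohort study: diving
  vessels traced along all measurement depths with surface pO2 on the
  correct side of 66 mmHg by construction, capillaries and flagged primary
  branches per depth, per-day pO2 offsets emulating a systemic inflammatory
  challenge, and full raw measurements per vessel point. Default layer
  means are seeded from published cohort-level values for 8-month-old
  APP/PS1 mice and wild-type littermates (e.g. layer-IV arteriolar pO2
  69.33 vs 80.79 mmHg, WT capillary pO2 near 48.6 mmHg), with day-7
  offsets (−9 mmHg WT, −15 mmHg AD) sized so the layer-IV capillary
  saturation drop lands near −13% (WT) and −23% (AD); these are
  configuration inputs that define the simulated conditions, not asserted
  facts. The photon budget per decay defaults to $10^5$ (no published count
  rate constrains it; at that budget the fitted-pO2 noise is ~1 mmHg,
  comparable to reported standard errors).
* `simulate_if_stack()` paints random bright blobs into a z-stack until the
  projection's positive-area fraction reaches its target, recording the
  exact painted mask.

Identical (configuration, seed) pairs reproduce every generator output
bit-for-bit. What the generator does **not** emulate: optical scattering
and depth-dependent SNR loss, motion beyond outlier-decay injection,
partial-volume effects at vessel walls, non-exponential probe kinetics,
spatially correlated vascular topology, and stained-structure morphology
beyond isotropic blobs. Passing tests therefore demonstrate correctness of
the estimators under the stated noise model, not robustness to every
artifact of real microscopy.

## Problem sizes and test budget

The suite runs in about a minute on one CPU: noiseless recovery and
round-trip identities are instant; Poisson lifetime recovery uses 500
decays at $10^5$ photons; Grubbs size calibration uses $10^4$ null sets of
20; valley counting is checked against a brute-force run enumerator on
1,000 constructed traces and against generator ground truth at 200 traces
per rate over 10–150 RBC/s; end-to-end cohort checks use 2–3 animals per
cohort with reduced vessel counts and photon budgets of
$2\text{–}3\times10^4$, which keeps the full pipeline exact in zero-noise
mode and representative in noisy mode.

## Known limitations

* The linear Stern–Volmer form is an approximation to probe-specific
  calibration curves; constants must come from the probe batch in use.
* The Hill conversion uses fixed physiological coefficients and does not
  model inflammatory shifts of the oxygen dissociation curve (pH,
  temperature, CO2, 2,3-DPG).
* Valley counting assumes single-file capillary transit; it does not
  estimate velocity or hematocrit, and at extreme flux (occupancy near 1)
  flux is flagged unresolvable rather than estimated.
* CV aggregation averages per-animal CVs (each animal counts once); pooled
  CVs across vessels of a cohort would differ and are not reported.
* The container uses native R serialization for raw measurement arrays with
  CSV/JSON sidecars for tables and metadata; it is not a cross-language
  archive format.
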