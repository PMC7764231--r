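---
title: "Methods: quantifying Lunar New Year firework effects on PM2.5"
author: "FireworkPM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying Lunar New Year firework effects on PM2.5}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Firework discharge around the Chinese Lunar New Year injects a large,
short-lived pulse of fine particulate matter (PM2.5) into the atmosphere,
concentrated in the first hours of New Year's Day. Three distinct
questions arise: how strong is the *instantaneous* effect (the hours-scale
burst), how strong is the *sustained* effect (the mean level over the
whole 17-day celebration), and what do firework *prohibition policies*
change? Answering them requires an hourly station record for the burst,
satellite-retrieved PM2.5 for long-term spatial coverage, and a calendar
framework anchored on the lunar date of the festival rather than the
Gregorian year.

FireworkPM implements that full chain as reusable, tested components, and
ships a synthetic-data generator with known ground truth so that each
stage — and the pipeline end to end — can be validated by parameter
recovery rather than by eyeballing real data.

# The synthetic study

`generateStationSeries()` simulates each station's hourly concentration
as

\[
\mathrm{PM}_{2.5}(t) = \max\!\big(0,\; [\,b + S(d) + D(h)\,]\cdot
H(d) + \varepsilon(t) + F(t)\big)
\]

* **Baseline** \(b\): 50 µg/m³ by default, a typical annual-mean urban
  level in central China.
* **Seasonal term** \(S(d)\): a cosine with amplitude 30 µg/m³ peaking on
  15 January. Winter maxima are a robust feature of Chinese PM2.5; the
  exact phase is a free choice and mid-January places the festival near
  the seasonal peak, as observed.
* **Diurnal term** \(D(h)\): two circular Gaussian bumps centred at 09:00
  (sd 2 h) and 22:30 (sd 1.5 h, 80% weight), amplitude 15 µg/m³, so that
  ordinary daily maxima fall in the morning or late-evening windows.
* **Holiday factor** \(H(d)\): multiplies the structural signal by
  \(1 - r\) (default \(r = 0.1\)) across each 17-day celebration window,
  emulating the emission reduction from factory shutdowns and travel.
* **Noise** \(\varepsilon(t)\): stationary AR(1) with marginal SD
  10 µg/m³ and lag-1 correlation 0.6 — hourly PM2.5 is strongly
  autocorrelated, and uncorrelated noise would make detection unrealistically
  easy.
* **Firework spike** \(F(t)\): a Gaussian profile over the configured
  discharge hours (default 00:00–04:00 of New Year's Day) with unit peak
  at the central hour (02:00) scaled by `spikePeak` (default 250 µg/m³,
  chosen so that national peaks land in the 180–280 µg/m³ range of severe
  festival nights). `spikePeak` may be a vector over years, which is how
  a prohibition policy is expressed (e.g. `c(250, 50)`); `spikeFraction`
  controls which share of stations discharge at all.

Concentrations are truncated at zero rather than modelled as log-normal;
for pipeline validation the truncation is simpler and changes nothing
away from the zero boundary.

`generateGrids()` produces the satellite side. Meteorology (RH, TEMP, WS,
SP, HPBL) is smooth in space (low-order harmonics of the bounding box),
seasonal in time, and carries AR(1) daily anomalies. The daily *true*
PM2.5 field is the structural station model (with the diurnal term
replaced by its daily mean) plus a smooth spatial modulation. The true
AOD field is then obtained by **inverting the ground-truth mapping**

\[
\mathrm{PM}_{2.5} = \beta_0 + 40\,\mathrm{AOD}\cdot
\frac{1500}{\mathrm{HPBL}+500}\cdot\Big(1+\frac{\mathrm{RH}}{100}\Big)
+ f(\mathrm{TEMP},\mathrm{WS},\mathrm{SP}) + g(\mathrm{lon},\mathrm{lat})
+ s(d)
\]

at that PM2.5 level, so that with zero noise the nine predictors
reproduce true PM2.5 *exactly* — the property the noiseless recovery
tests rely on. The mapping is smooth and nonlinear in the way
AOD–PM relationships are understood to be: the AOD term is amplified by
hygroscopic growth (RH) and diluted by a deep boundary layer (HPBL).
Label grids add independent daily observation noise with SD
\(\sigma/\sqrt{24}\) (the daily-mean noise implied by the hourly level
\(\sigma\)), which is what makes cross-validated skill degrade as
\(\sigma\) grows. Terra-like and Aqua-like overpasses both observe the
daily AOD — overpass-to-overpass differences are treated as absorbed into
label noise — and are independently cloud-masked per pixel (default 50%
missingness, typical of winter MODIS coverage).

What the generator does **not** emulate: transport and chemistry (no
plumes, no advection), station-level spatial heterogeneity beyond noise,
diurnally varying meteorology, and realistic spatially correlated cloud
fields (masking is i.i.d. per pixel). Passing tests therefore demonstrate
the pipeline's correctness and statistical behaviour under its stated
assumptions, not retrieval skill on real MODIS/NCEP archives.

# Merging the two overpasses

`mergeDailyAOD()` applies the per-pixel rule: both missing → missing;
both present → arithmetic mean; one present → that value. No quality-flag
screening is applied (none is defined at this stage of the chain). The
rule is symmetric, its missing mask is the conjunction of the input
masks, and the output is bounded by the present inputs — all verified as
properties.

# The retrieval network

`trainRetrieval()` fits a three-layer feed-forward network: nine inputs
(lon, lat, day of year, AOD, RH, TEMP, WS, SP, HPBL) → 18 hidden tanh
units → one linear output. Eighteen hidden units is the default; a
common heuristic bounds the useful width by \(2n+1 = 19\) for \(n = 9\)
inputs, and widths outside \([2, 19]\) warn but proceed. Day of year
enters as a raw integer (the simplest reading; a cyclic encoding would be
a straightforward extension but is not the default).

Inputs and label are z-scored; predictions are transformed back and
clamped at zero. Pixels with any missing predictor propagate to missing
retrievals.

**Optimiser.** Training is full-batch back-propagation. The default
update rule is iRPROP− (per-weight adaptive step sizes with sign-change
backtracking), with plain gradient descent plus momentum available as
`method = "gd"`. The choice is deliberate: the recovery regime this
package must support — fitting a smooth nonlinear mapping to ~0.1% RMSE
of label SD on noiseless data — demands an optimiser that converges
reliably without per-problem learning-rate tuning, and RPROP achieves
that while remaining a classic back-propagation variant and fully
deterministic given the initialisation seed. Early stopping triggers on a
relative loss change below `tol` (default 1e−10, i.e. effectively running
the full `maxEpochs = 2000`); both are exposed.

**Validation.** `pearsonR()` and `rmse()` implement the two fit metrics
in their standard forms (the covariance/SD form for R), and
`crossValidate()` performs sample-based 10-fold cross-validation: a
random partition with fold sizes differing by at most one, each sample
predicted exactly once out-of-fold, metrics pooled over all out-of-fold
predictions. On the default synthetic study with `noiseSd = 0` and 2,000
samples, 10-fold CV achieves R ≈ 0.9999 and RMSE ≈ 1% of label SD; skill
degrades monotonically as label noise grows, and CV R stays at or below
the in-sample fit — the signature of a well-specified, non-overfitting
model.

# The 17-day period schema

`celebrationWindow()` spans New Year's Eve through the day after the
Lantern Festival. Counting from New Year's Day to the day after the
Lantern Festival gives only 16 days, while the celebration span is fixed
at 17; including the Eve reconciles the two, and is also physically
right — the displays that produce the 02:00 peak begin on the Eve's
night. This inclusion is a considered design choice, not an arbitrary
offset.

`divideCycle()` tiles one lunar cycle (celebration start to the day
before the next celebration starts) with exactly 21 periods: the
celebration, ten 17-day post-celebration blocks counted forward, nine
17-day pre-celebration blocks counted backward from the next celebration,
and a residual `pre-10` that absorbs whatever days remain (15 for the
2013→2014 cycle; zero-length residuals are permitted, and cycles shorter
than 340 days are rejected with the deficit reported). The residual is
deliberately parked in the 10th *pre*-celebration block: those days fall
in summer, far from the festival, where they cannot contaminate the
winter comparisons.

# Fusion and period means

`fusePeriods()` averages, per pixel, all non-missing daily retrieved
values carrying the same period label across all years; a fused pixel is
missing only if no contributor exists. `periodMeans()` averages station
observations over all stations and hours of each labeled period,
unweighted (plain national averages; no area weighting).
`celebrationComparison()` compares each celebration mean against the
equal-weight mean of its adjacent flanking periods (the pre-1 period of
the preceding cycle's division and the post-1 period of its own); a
`flanking = "all"` option widens the baseline to all ten blocks on each
side for sensitivity analysis.

# Response classification

`classifyResponse()` labels one city for one celebration, using the
00:00–04:00 window of New Year's Day and excluding the Lantern Festival
period (implemented as the final three days of the window — the
festival's eve, day, and morrow — since a finer definition is not
available):

1. **significant** — the city's celebration-period maximum falls inside
   the discharge window. Implemented strictly: the window maximum must
   *exceed* every value outside the window, so a flat series (which ties
   everywhere) is not significant. This also makes the category invariant
   under strictly increasing transforms of the series, which the test
   suite checks directly.
2. **obvious** — failing rule 1, New Year's Day must have *both* the
   largest increase (value at 04:00 minus value at 00:00) and the largest
   increase rate (increase divided by the 00:00 value) among all
   considered days, strictly; ties fail. The increase operands are the
   window endpoints because the window is defined by them; a
   max-minus-min variant would be a one-line change but is not the
   default.
3. **weak** — everything else. The three categories are exhaustive and
   mutually exclusive by construction.

The rule-1 maximum is taken over the celebration period only (the
classification is per celebration), and rule-2 comparisons likewise span
the celebration period's remaining days. Missing window endpoints
produce a completeness warning and the affected day drops out of rule-2
comparisons.

`peakRatio()` expresses a New Year's daily maximum as a percentage of the
mean daily maximum of its flanking days; the default window is one day on
each side, configurable.

# Policy analysis

`baseline34day()` represents the "normal" level around one celebration as
the mean of all hourly values in the adjacent 17-day pre- and
post-celebration periods — a single scalar, not an hour-of-day
climatology (an hour-matched baseline would also remove the diurnal cycle
from the anomalies, which is not what the descriptive comparison calls
for). Completeness below 50% warns; no data errors.
`celebrationAnomaly()` subtracts that baseline from every celebration
hour, and `comparePolicyYears()` summarises, per year, the mean anomaly
over the discharge window (00:00–04:00 of New Year's Day) and over the
full celebration, flagging whether the discharge-window anomaly declined
once the policy took effect. On the default two-year policy scenario
(spike 250 → 50 µg/m³) the discharge-window anomaly drops by roughly
75 µg/m³ while the full-period mean moves by about 1 µg/m³ — the burst
responds to the policy, the sustained level does not.

# Numerical choices and degenerate inputs

* Daily-maximum ties break toward the earliest hour.
* Retrieved concentrations clamp at zero; generated series truncate at
  zero.
* Zero-variance features are given unit scale (not an error) during
  z-scoring; constant labels are an error.
* Pearson correlation on a zero-variance vector is an error, not NaN.
* Duplicate (station, timestamp) keys, negative concentrations, and
  malformed rows are rejected at read time with line numbers.
* All randomness flows from a single integer seed through independent
  derived streams, so every stage is bit-reproducible; the global RNG
  state of the caller is restored after each call.

# Problem sizes

The shipped validation suite exercises: 2,000-sample training sets with
10-fold cross-validation on a 40×40-pixel, weekly-sampled year of grids;
a 12-station, two-New-Year network for the end-to-end regime checks; the
1,389-day 2013–2016 station span for the calendar statistics; 10,000
random grid pairs for merge properties; and 200 random anchor pairs for
the tiling invariant. These sizes give stable statistics while keeping
the full suite in the low minutes on a single CPU.

# Known limitations

* The generator's spatial field is a fixed low-order harmonic; it cannot
  probe retrieval skill for fine spatial structure.
* Cloud masking is independent per pixel; real cloud fields are spatially
  correlated, which changes fusion coverage statistics.
* The anchor-date table covers 2002–2016; other years must be supplied by
  the user (no astronomical lunar computation is performed).
* The policy comparison is descriptive, as specified — no meteorological
  adjustment or causal-inference design is attempted.
* Real-archive headline numbers (national peak levels, response-category
  proportions, retrieval R/RMSE on MODIS collocations) require the real
  station and satellite archives and are out of scope by design.
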