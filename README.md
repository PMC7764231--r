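# FireworkPM

Quantifying the effect of Chinese Lunar New Year firework discharge on
fine particulate matter (PM2.5): the instantaneous burst in the first
hours of New Year's Day, the sustained level over the 17-day celebration,
and the change brought by firework prohibition policies.

The package is aimed at air-quality researchers who need the full
analysis chain as tested, reusable components:

* **Satellite AOD merging** — same-day Terra/Aqua aerosol optical depth
  grids combined per pixel (both missing → missing; both present → mean;
  one present → that value).
* **Neural AOD→PM2.5 retrieval** — a three-layer back-propagation network
  mapping nine predictors (lon, lat, day of year, AOD, RH, TEMP, WS, SP,
  HPBL) through 18 hidden tanh units to daily PM2.5, validated by Pearson
  R, RMSE

  R = Σ(yᵢ − ȳ)(yᵢ′ − ȳ′) / √[Σ(yᵢ − ȳ)² Σ(yᵢ′ − ȳ′)²],
  RMSE = √[ (1/n) Σ (yᵢ − yᵢ′)² ]

  and sample-based 10-fold cross-validation (fold sizes differ by at most
  one; every sample predicted exactly once out-of-fold).
* **Lunar-anchored calendar** — each 17-day celebration window runs from
  New Year's Eve through the day after the Lantern Festival; every lunar
  cycle is tiled by exactly 21 labeled periods (celebration, post-1 …
  post-10, pre-10 … pre-1), all 17 days long except the residual pre-10.
* **Multi-year fusion** — retrieved daily grids carrying the same period
  label are averaged across years into one distribution map per label.
* **Response classification** — each city × celebration is labeled
  *significant* (period maximum inside 00:00–04:00 of New Year's Day),
  *obvious* (that window has the strictly largest increase *and* increase
  rate), or *weak*, with Lantern Festival days excluded.
* **Policy analysis** — hourly celebration anomalies against a 34-day
  flanking baseline (adjacent 17-day pre- and post-celebration periods),
  compared across pre- and post-policy years.
* **Synthetic study generator** — hourly station series (seasonal +
  diurnal + AR(1) noise + firework spike − holiday reduction) and
  consistent AOD/meteorology grids with a known smooth nonlinear
  ground-truth mapping, so every stage is testable by parameter recovery.

## Worked example

Twelve stations over two New Years (2013 and 2014), with fireworks in 9
of the 12 cities and a prohibition policy cutting the 2014 spike from 250
to 50 µg/m³:

```r
library(FireworkPM)

cfg <- simulationConfig(nStations = 12, spikeFraction = 0.75,
                        startDate = "2012-12-15", endDate = "2014-03-31",
                        newYearDates = c("2013-02-10", "2014-01-31"),
                        spikePeak = c(250, 50), seed = 7)
sim <- generateStationSeries(cfg)
sim$series
#> StationSeries: 12 stations x 11328 hours
#>   span: 2012-12-15 to 2014-03-31 23:00:00
#>   pm25: mean 60.0 ug/m3, 0.0% missing

divs <- divideAllCycles(as.Date(c("2012-01-23", "2013-02-10",
                                  "2014-01-31", "2015-02-19")))
divs[[2]]
#> PeriodDivision [cycle 2013]: 21 periods, 2013-02-09 to 2014-01-29
#>   (pre-10 residual: 15 days)

nat  <- nationalHourlyMean(sim$series)
dmax <- dailyMaxSeries(nat)
dmax[dmax$date == as.Date("2013-02-10"), ]
#>          date max_value max_hour
#> 58 2013-02-10  255.8821        2

peakRatio(dmax, "2013-02-10")
#> [1] 289.9932

table(classifyAllStations(sim$series, divs[[2]])$category)
#> significant        weak
#>           9           3

celebrationComparison(sim$series, divs)[2, ]
#>   cycle celebration_mean pre_mean post_mean flanking_mean  deficit
#> 2  2013         73.90892 83.48532  74.49074      78.98803 5.079107
```

Reading the output: the national hourly mean peaks at 255.9 µg/m³ at
**02:00 on New Year's Day** — 290% of the flanking days' maxima — and
exactly the nine firework cities are classified *significant*. Yet the
celebration-period mean (73.9 µg/m³) sits 5.1 µg/m³ *below* the flanking
level, because the holiday emission reduction outweighs the short burst:
a strong instantaneous effect with no sustained aggravation.

`runDemo("artifacts", seed = 1)` runs the whole chain — simulation,
overpass merging, network training and 10-fold cross-validation, grid
retrieval, period fusion, classification, and the policy comparison —
writing every artifact plus a checksum manifest, deterministically for a
fixed seed. A thin command-line wrapper lives in
`inst/scripts/fireworkpm.R`.

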