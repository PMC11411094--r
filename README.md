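# calvetrend

Early calving alerts for dairy cows from heart-rate trend turning points.

In the last week of gestation a cow's mean R-R interval (ECG beat-to-beat
interval; HR(bpm) = 60/RR(s)) drifts upward and then drops sharply,
starting roughly two days before calving. `calvetrend` implements the full
analysis around that observation for researchers in precision livestock
monitoring:

* **Preprocessing** of beat-level Holter R-R series: a causal outlier rule
  (exclude beats deviating from the running average of the last 60
  accepted beats by more than 30 %), 30-min averaging, and linear gap
  imputation.
* **STL decomposition** (seasonal-trend decomposition using LOESS) of the
  binned series into trend + 24-h cycle + remainder, with the exact
  reconstruction identity trend + seasonal + remainder = input.
* **Financial technical indicators on the trend** `P_t`:
  - `SMA_{n,t} = (P_t + ... + P_{t-n+1})/n`, n = 12 (6 h);
  - `MAD_{n,t} = 100 (P_t - SMA_{n,t}) / SMA_{n,t}` (moving average
    deviation rate);
  - `MACD = EMA_12 - EMA_26` with `EMA_{n,t} = a P_t + (1-a) EMA_{n,t-1}`,
    `a = 2/(n+1)` (reported as a percentage of the long EMA);
  - `RSI_14 = 100 U/(U+D)`, the ratio of summed upward changes to total
    absolute changes over the last 14 bins.
* **Turning-point detection**: the indicator peak, either retrospectively
  (global maximum, earliest bin on ties, with signalling floors MAD/MACD
  > 0 and RSI > 50) or online (first local maximum above its floor
  confirmed by k = 3 non-increasing bins, so the alert is available 1.5 h
  after the peak), plus the combined rule MAD > 0 & RSI > 50. The
  remaining time to calving is calving time minus signal time.
* **Indicator comparison**: randomized-block / mixed-model analysis of
  remaining times with cow as block, paired F tests (squared paired t) at
  the Bonferroni level 0.05/3.
* **A seeded synthetic R-R generator** with known trend, daily cycle,
  AR(1) remainder, beat jitter, artifacts and dropout, providing ground
  truth for end-to-end recovery studies (no raw recordings from the
  original study are public).

## Worked example

The package ships the published remaining-hours table of the six-cow
feasibility study (`calving_study_hours()`): hours from each indicator's
turning-point signal to observed calving.

```r
library(calvetrend)
m <- calving_study_hours()
m
#>      h021 h045 h057 h055 h058 h886
#> SMA  53.0 69.5   61   NA 42.5 44.5
#> MAD  56.0 76.0   66 43.0 47.5 63.5
#> MACD 53.5 72.0   62 42.5 43.5 59.5
#> RSI  56.0 72.0   62   NA 43.5 45.0

s <- summarize_remaining(m)
within(s$rows, { mean <- round(mean, 1); sd <- round(sd, 1) })
#>   indicator mean   sd n
#> 1       SMA 54.1 11.3 5
#> 2       MAD 58.7 12.3 6
#> 3      MACD 55.5 11.4 6
#> 4       RSI 55.7 11.9 5
```

MAD alerts on average 3.17 h earlier than MACD across all six cows, and
the paired test on the five cows with complete MAD/MACD/RSI triples is
decisive:

```r
d6 <- pairwise_compare(m, c("MAD", "MACD"))
sprintf("MAD leads MACD by %.2f +/- %.2f h (n = %d cows)", d6$mean_diff, d6$sd_diff, d6$n)
#> "MAD leads MACD by 3.17 +/- 1.44 h (n = 6 cows)"
f5 <- pairwise_compare(m, c("MAD", "MACD"), complete_triples = TRUE)
sprintf("paired F = %.2f, p = %.3g", f5$F, f5$p)
#> "paired F = 152.11, p = 0.000248"
```

An end-to-end synthetic run — generate a recording whose trend peaks 55 h
before calving at hour 113, decompose it, and read the MAD peak:

```r
sp  <- synthetic_spec(seed = 42)                     # 168-h recording
b   <- composite_series(generate_components(sp), calving_time = 168)
sig <- detect_peak_retrospective(ind_mad(stl_decompose(b)))
sig
#> <turning_point> MAD (retrospective): t = 104 h, peak = 0.3065
remaining_hours(sig, 168)$hours
#> [1] 64
```

The alert fires 64 h before calving — 9 h before the true turning point
in this replicate. That early offset is systematic: a symmetric trend
smoother lets the steep post-peak decline pull the smoothed slope down
before the corner, so MAD/MACD peaks are conservative (early) alerts
rather than unbiased estimates of the turning time. The methods vignette
(`vignettes/calving-alert-methods.Rmd`) quantifies this with 100-replicate
recovery studies.

## The analysis workflow

Numbered drivers under `analysis/` rebuild the whole study on a synthetic
six-cow cohort (beat-level intermediates go to `scratch/`, small summary
tables to `results/`):

```sh
Rscript analysis/01_simulate.R     # six cows, ~1e6 beats each, known truth
Rscript analysis/02_preprocess.R   # 30% rule, 30-min bins, imputation
Rscript analysis/03_decompose.R    # STL; trend RMS error vs truth ~2-4 ms
Rscript analysis/04_indicators.R   # SMA/MAD/MACD/RSI panels
Rscript analysis/05_signals.R      # retrospective + online signals
Rscript analysis/06_evaluate.R     # summaries, comparisons, recovery study
```

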