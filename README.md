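# nsfecg

Blind source separation of non-invasive abdominal ECG recordings into
maternal and fetal components, for researchers working on fetal heart-rate
monitoring and cardiac signal processing.

A pregnant abdomen yields a mixture `X = A S + E`: `M` recorded channels,
`L = 2` unknown sources (the maternal ECG and a fetal ECG some 10–30 dB
weaker), an unknown full-rank gain matrix `A`, and noise. `nsfecg` recovers
the sources through the null space of an **idempotent transformation
matrix**:

```
W  = (1/N) Xpᵀ Cx⁻¹ Xp ,   Cx = (1/N) Xp Xpᵀ ,   Q = W − I
```

`W` is the orthogonal projector onto the row space of the preprocessed
mixture `Xp` (so `W² = W`), every source waveform satisfies `Q Yᵀ = 0`, and
an orthonormal basis of `null(Q)` — ordered by the variance of `Xp` along
each direction — yields the maternal (dominant) and fetal waveforms. The
raw fetal trace is then cleaned by an adaptive comb filter: valley-shaped
windows `a_r = 0.46 − 0.46 cos(2πr/(2U+1))` centred on detected maternal R
peaks zero out residual maternal beats, gated by control logic on the fetal
heart-rate mean and variance. PCA-whitening, fixed-point ICA and
parallel-linear-predictor baselines share the same interface, and the full
metric suite (SPI, SIR/SAR/SDR, qSNR, SE/ACC/PPV) plus a seeded abdominal
mixture simulator make every stage testable without external recordings.

## Worked example

```r
library(nsfecg)

rec <- simulate_fecg_record(duration_s = 10, fs = 250,
                            fmsnr_db = -10, channel_snr_db = 12, seed = 7)
rec
#> <multichannel_record> 7 channels x 2500 samples @ 250 Hz
#> roles: abdominal, abdominal, abdominal, abdominal, abdominal, thoracic, thoracic
#> ground truth: present

run <- run_pipeline(rec)
run
#> <fecg_run> method nsitm, 2500 samples @ 250 Hz
#> MHR 79.3 bpm, FHR 140.1 bpm, maternal-beat removal: not needed

glance(run)
#> # A tibble: 1 × 6
#>   method mhr_bpm fhr_bpm maternal_beats fetal_beats control_applied
#>   <chr>    <dbl>   <dbl>          <int>       <int> <lgl>
#> 1 nsitm     79.3    140.             13          23 FALSE
```

The simulated mother beats at 80 bpm and the fetus at 140 bpm; the pipeline
recovers both rates to within a fraction of a beat per minute, and the
control logic correctly leaves the clean fetal trace untouched (no maternal
beats leaked into it). Against the simulator's ground truth:

```r
separation_report(run$sources, rec)
#>   spi_db sir_db sar_db sdr_db qsnr_db fetal_corr se_pct acc_pct ppv_pct
#> 1 -14.31  24.18   16.8   8.92    8.92       0.94    100     100     100
```

`spi_db` is a similarity index (more negative = more similar), `sir/sar/sdr`
are the BSS-eval interference/artifact/distortion ratios of the fetal
estimate, `qsnr_db` its quality SNR against the true fetal waveform, and
`se/acc/ppv` the fetal R-peak detection statistics within ±50 ms — here
every fetal beat was found with no false alarms. `tidy()` and `autoplot()`
methods on records, peak sets and runs support ggplot2-based inspection,
and `fmsnr_sweep()` / `extraction_benchmark()` run multi-method comparison
grids as tibbles.

A thin command-line front end ships in `inst/scripts/fecg`
(`fecg simulate | extract | detect-peaks | evaluate | bench`).

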