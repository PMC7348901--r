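---
title: "Null-space fetal ECG extraction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null-space fetal ECG extraction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(nsfecg)
```

## The separation problem

A non-invasive abdominal ECG recording is modelled as a linear, instantaneous
mixture

$$X = A\,S + E,$$

where $X$ is the $M \times N$ zero-mean matrix of recorded channels, $S$ the
$L \times N$ matrix of unknown source waveforms (here $L = 2$: the maternal
ECG and the much weaker fetal ECG), $A$ an unknown full-column-rank
$M \times L$ gain matrix determined by electrode placement, and $E$ additive
noise. Blind source separation recovers $S$ up to the unavoidable scale, sign
and permutation ambiguities; `nsfecg` therefore returns unit-norm rows and
resolves fetal/maternal identity by beat rate, and all evaluation metrics are
computed after optimal sign/permutation alignment.

## The idempotent transformation matrix

The core estimator builds

$$W = \tfrac{1}{N}\,X_p^\top C_x^{-1} X_p,
\qquad C_x = \tfrac{1}{N}\,X_p X_p^\top,$$

from the preprocessed mixture $X_p$. Algebraically $W$ is the symmetric
orthogonal projector onto the row space of $X_p$: $W^2 = W$ exactly, its
eigenvalues are 0 and 1, and its trace equals the numerical rank of $X_p$.
Because every noiseless source waveform lies in that row space, the sources
satisfy $Q\,Y^\top = 0$ with $Q = W - I$, so they can be read out of the null
space of $Q$ — equivalently, the eigenvalue-1 eigenspace of $W$.
`compute_itm()` evaluates $W$ by the formula above (with a ridge
$\lambda = 10^{-10}\,\mathrm{tr}(C_x)/M$ so that rank-deficient noiseless
mixtures still produce an exact projector), and obtains the null-space basis
from the thin SVD of $X_p$ rather than an $N \times N$ SVD of $Q$ — the right
singular vectors of $X_p$ span its row space, which makes the method
practical at $N$ in the thousands. A memory guard refuses $N > 20{,}000$,
where the explicit $N \times N$ projector would be unreasonable; longer
records should be processed in windows.

### Choosing vectors inside the null space

For a full-rank $M$-channel record the null space of $Q$ has dimension $M$,
and any orthonormal basis of it solves $QY^\top = 0$; the degeneracy means an
SVD routine's column order there is arbitrary. `null_space_extract()` makes
the choice explicit: the basis is ordered by the energy of $X_p$ along each
direction (descending), and the **dominant** $L$ directions are returned by
default. The rationale: the maternal component always carries the largest
variance; the fetal component is next as long as its per-direction power
exceeds the per-direction noise power; the trailing (minor) directions of the
row space carry noise. Selecting the minor directions instead — available as
`select = "minor"` — only coincides with source recovery in the noiseless
case, where the numerical null space collapses to dimension $L$ and the two
rules pick the same vectors. Whether any further rotation inside the null
space should be applied is left open by the method itself; `nsfecg` applies
none, which is why separation degrades when the two sources approach equal
power (see *Limitations*).

## Preprocessing

Three cascaded channel-wise filters precede separation: a Butterworth
low-pass at `f1` (default 100 Hz, limits the ECG band), a Butterworth
high-pass at `f2` (default 0.5 Hz, removes baseline wander) and a
second-order IIR notch at `f3` (50 or 60 Hz by regional power-line standard,
quality factor 30). Orders default to 4. Filters are applied
forward–backward (zero phase) by default so that R-peak positions are not
shifted against ground truth; a causal single-pass mode is available
(`zero_phase = FALSE`) since either reading of a hardware-oriented cascade
is plausible. The cascade is linear and stateless; its passband (10–40 Hz)
gain is within 1 dB of unity and its stopband attenuations are at least
20 dB, which the test suite measures directly.

## R-peak detection and heart rates

R peaks are found with the Pan–Tompkins chain: band-pass, five-point
derivative, squaring, moving-window integration and an adaptive
dual-threshold search with search-back, followed by refinement of each
detection to the extremum of the band-passed trace (the squaring stage makes
detection polarity-blind, which matters because separation recovers
waveforms up to sign). The classic parameterisation targets adult rates;
`nsfecg` keeps it for the maternal mode (5–15 Hz band, 150 ms integration
window, 200 ms refractory period) and shifts the fetal mode to 10–25 Hz,
80 ms and 150 ms to suit rates up to 180+ bpm. All three knobs are
overridable per call. Heart rates are exact arithmetic on peak indices:
`dp(l) = p(l+1) - p(l)` samples, per-interval rate $60 f_s / dp$, mean rate
over intervals. Indices are 1-based sample positions, the R convention.

## Control logic and maternal-beat removal

A maternal beat that leaks into the raw fetal trace shortens some fetal
inter-peak intervals, which simultaneously inflates the per-interval fetal
heart rates and their variance; a clean fetal trace shows neither. The
control logic therefore activates removal only when `var(FHR) > maxvar`
**and** the fetal rate exceeds `maxFHR` (mean rate by default; an `any` mode
triggers on a single wild interval, since the printed rule does not say
which was intended). Defaults: `maxFHR = 180` bpm (appropriate from about
20 weeks of gestation) and `maxvar = 3` (the useful range is about 1–5).

Removal multiplies the raw fetal trace by a gain vector $h(n)$: inside a
window of length $2U+1$ centred on each maternal R peak,
$h(p + r) = 0.46 - 0.46\cos\!\big(2\pi r/(2U+1)\big)$ — a valley that is
exactly zero at the peak itself (this window equals one minus a centred
Hamming window); outside all windows $h = 1$. Taken literally, a gain that
is zero outside the windows would annihilate the fetal signal everywhere
except near maternal beats — the opposite of the stage's purpose — so the
unit passband outside the supports is the only reading consistent with
"removing the unwanted maternal component". Overlapping windows combine by
pointwise minimum; edge windows are truncated. The default window length is
21 ms of samples (21 samples at 1 kHz, the scale on which window lengths of
20–45 samples are appropriate), scaled by the record's sampling rate. A
Hann-shaped valley (`shape = "hann_valley"`), which recovers unit gain at
the window edge, is available as an alternative.

After removal, the reported fetal peak set is re-detected on the cleaned
trace: the maternal residual that triggered removal also corrupts raw-trace
detections.

## Baseline extractors

* **PCA whitening** — components of $C_x^{-1/2} X_p$, mutually uncorrelated
  by construction. Component selection mirrors the null-space rule: the $L$
  largest-variance components by default, `select = "minor"` for the
  smallest.
* **Fixed-point ICA** — symmetric FastICA with the log-cosh contrast on the
  $L$-dimensionally whitened data; seeded random orthonormal start,
  symmetric (eigenvalue) orthogonalisation, tolerance $10^{-6}$ on the
  rotation update, 200-iteration cap with a convergence warning. Near-zero
  excess kurtosis on every component is flagged as the non-identifiable
  all-Gaussian case.
* **Parallel linear predictors (PLP)** — a bank of $L$ extractors on the
  whitened data descending the energy of their own one-step
  linear-prediction error with learning rate $\mu_y$, kept mutually
  orthogonal by symmetric decorrelation. The published update is stated in
  signal space as $y \leftarrow y + \mu_y (R - I_N) E_r$ with $R$ the Gram
  operator of the whitened data and $E_r$ an unspecified error vector; since
  that operator only moves $y$ through the whitened row space, `nsfecg`
  performs the equivalent projected update in whitening coordinates and
  defines $E_r$ as the one-step linear prediction error — quasi-periodic
  sources are precisely the highly predictable ones. Defaults:
  $\mu_y = 0.02$, at most 2000 iterations, stop when the bank rotation per
  step falls below $10^{-5}$ or stalls; sustained growth of the step (10
  consecutive increases by more than 20 %) raises a divergence error naming
  $\mu_y$. Initialisation is the whitened component basis (deterministic) by
  default, seeded random as an option.

## Evaluation metrics

* **SPI** $= \frac{1}{L}\sum_i 10\log_{10}\!\big(
  \langle y,y\rangle\langle s,s\rangle / \langle y,s\rangle^2 - 1\big)$, i.e.
  $10\log_{10}(1/\rho^2 - 1)$ per pair: 0 dB at $\rho^2 = 0.5$, more
  negative is more similar. This algebraic form is the one consistent with
  similarity indices that are negative for good separations. Exact
  proportionality floors at −300 dB, orthogonality caps at +300 dB.
* **SIR/SAR/SDR** from the standard BSS-eval orthogonal decomposition
  $y = s_\text{target} + e_\text{interf} + e_\text{noise} + e_\text{artif}$
  by nested projections onto the matched source, the span of all sources,
  and the span of sources plus noise. The parts are mutually orthogonal and
  sum to $y$ exactly, so energies add; these metrics require ground truth
  and are simulation-only.
* **qSNR** $= 10\log_{10}\big(\sum \hat s^2 / \sum (s - \hat s)^2\big)$,
  implemented with the estimate in the numerator exactly as printed (a
  `conventional` switch substitutes the true-signal energy); the estimate is
  least-squares amplitude-aligned to the truth first.
* **SE/ACC/PPV** from TP/FP/FN counts produced by greedy one-to-one
  nearest-peak matching within ±50 ms (the usual fetal-QRS scoring window;
  configurable). ACC never exceeds min(SE, PPV).

One printed formula required a decision: the fetal scaling factor for a
target fetal-to-maternal SNR of $q$ dB appears as
$p = \sqrt{p_m/p_f}\cdot 10^{-q/20}$, which for negative $q$ *amplifies* the
fetal signal. `scale_fetal()` uses $p = \sqrt{p_m/p_f}\cdot 10^{q/20}$, the
unique form for which the post-scaling fetal-to-maternal power ratio equals
$q$ dB, matching the sweep's evident intent.

## The synthetic-data generator

`simulate_fecg_record()` provides ground truth for every test. Each source
is a train of Gaussian deflections (P, Q, R, S, T) on a per-beat time axis —
the simplest morphology with the right qualitative structure — with
per-beat multiplicative RR jitter (Gaussian, truncated at ±3σ, default 3 %
of the mean RR) supplying the quasi-periodicity of real cardiac rhythms.
Defaults: maternal 80 bpm, fetal 140 bpm, 250 Hz sampling, fetal power set
−10 dB relative to maternal, white Gaussian channel noise at 12 dB mixture
SNR. The geometry is 5 abdominal + 2 thoracic electrodes: abdominal channels
mix both sources with uniform random gains, and the fetal gains carry random
polarity because electrodes at different abdominal sites see the fetal
cardiac dipole under different projections; thoracic (reference) channels
see essentially only the maternal signal. All draws are seeded and
bit-reproducible.

What the generator does **not** emulate: volume-conductor propagation,
electrode motion or contraction events, coloured physiological noise (real
muscle/electrode noise is heavily low-frequency, while the generator's noise
is white — a *harder* condition for subspace methods after band-limiting),
P/T morphology variability, and fetal–maternal beat overlap statistics of
real labour records. Tests passing on these simulations therefore
demonstrate algorithmic correctness and ordering between methods, not
clinical performance.

## Problem sizes and numerical choices

The test and acceptance workloads use 10 s records at 250 Hz ($N = 2500$,
the scale at which the explicit $N \times N$ projector is comfortable),
100-case randomized projector sweeps at $N \le 500$, 20-seed end-to-end
recovery runs, and 4-point fmSNR sweeps with 5 seeds per point — sizes
chosen so the whole suite completes in minutes on one core. Numerical
thresholds: singular values of $X_p$ below $10^{-8}$ of the largest count as
zero (rank and null-space dimension); null-space residuals must satisfy
$\|QY^\top\| \le 10^{-6}$; dB metrics are capped at ±300; degenerate inputs
(zero-power signals, rank-deficient mixing, too-few peaks) raise classed
errors rather than propagating NaN.

## Limitations

Two behaviours observed in the package's own acceptance runs are worth
stating plainly. First, with white channel noise at 12 dB and random signed
gains, the matched fetal correlation concentrates around 0.93 but the worst
~10–15 % of geometries — those whose fetal polarity draws happen to align
across electrodes, making the fetal mixing column nearly collinear with the
maternal one — fall just below 0.9; no orthogonal-projection method can do
better there, since the informative direction is then buried under the
noise floor. Second, as the fetal-to-maternal SNR approaches 0 dB the
sources have comparable power and the dominant covariance directions rotate
away from the sources whenever the mixing columns are correlated; the
projector estimate (like PCA, and unlike higher-order ICA) then recovers
rotated mixtures and its qSNR drops rather than continuing to rise. Both are
properties of second-order subspace separation, not of the implementation.
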