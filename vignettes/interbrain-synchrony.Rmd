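---
title: "Measuring inter-brain synchrony in sliding windows: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring inter-brain synchrony in sliding windows: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibsync)
```

## The problem

Hyperscanning experiments record EEG from two or more interacting people at
once and ask how statistically dependent their neural time-series are.
When that dependence -- *inter-brain synchrony* -- is computed continuously
and fed back to the participants (as light, sound, or visuals), the analysis
has to run on short sliding windows, tolerate imperfect signals, and keep
emitting values at a steady cadence. `ibsync` implements that engine: a
windowed analytic-signal pipeline producing one connectivity value per
subject pair per frequency band, normalized into a bounded feedback range.

The processing chain per analysis step is:

1. **Ingest**: each stream's samples accumulate in a per-stream ring buffer
   (default capacity 30 s).
2. **Window**: the most recent `window_size + pad` seconds are extracted
   (window 3 s by default; pad explained below).
3. **Band-pass**: a causal 4th-order Butterworth filter per configured band
   (defaults: delta 1–4, theta 4–8, alpha 8–12, beta 12–20 Hz).
4. **Analytic signal**: the Hilbert-transform analytic signal
   $X(t) = A(t)e^{i\theta(t)}$ gives instantaneous envelope $A = |X|$,
   power $|X|^2$, and phase $\theta = \arg X$.
5. **Connectivity**: one of six metrics per electrode pair, averaged over
   the configured pair set to one value per (subject pair, band), then
   multiplied by the band weight.
6. **Normalize, pack, emit**: min-max normalization into $[0,1]$, packing
   into a flat pair-major/band-minor vector, delivery to sinks.

## The six metrics

With $X(i,t)$, $Y(j,t)$ the analytic samples of channel $i$ of subject $x$
and channel $j$ of subject $y$, $N$ samples per window, and $^*$ complex
conjugation:

* **Coherence** $\;|\sum_t X Y^*| \big/ \sqrt{\sum_t |X|^2 \sum_t |Y|^2}$.
  The numerator is the magnitude of the *summed* cross-spectrum: on
  instantaneous analytic signals the cross-spectrum is the expectation of
  the sample-wise dot product, so the sum over the window is the windowed
  estimate of it. A sample-wise form without the sum would be dimensionally
  inconsistent with the summed denominator (it would collapse to 1 for any
  pair of nonzero samples).
* **Imaginary coherence**: same denominator, numerator
  $|\mathrm{Im}\sum_t X Y^*|$. Zero-lag (purely real) coupling -- the
  signature of volume conduction and shared reference artifacts within one
  head, and of shared stimulus drive across heads -- is discarded.
* **Envelope correlation**: Pearson correlation of $|X|$ and $|Y|$.
* **Power correlation**: Pearson correlation of $|X|^2$ and $|Y|^2$.
* **PLV** $\;\frac1N |\sum_t \varphi_x \varphi_y^*|$ with
  $\varphi = X/|X|$: the resultant length of the relative phase,
  amplitude-blind by construction.
* **CCorr**, the circular correlation coefficient
  $\frac{\sum_t \sin(\theta_x - \bar\theta_x)\sin(\theta_y - \bar\theta_y)}
        {\sqrt{\sum_t \sin^2(\theta_x - \bar\theta_x)
               \sum_t \sin^2(\theta_y - \bar\theta_y)}}$,
  where $\bar\theta$ is the **circular** mean
  ($\arg \sum_t e^{i\theta_t}$ -- the arithmetic mean of angles is not
  well-defined on the circle). CCorr requires the two phases to *covary*,
  which makes it more robust to coincidental phase alignment than PLV.

Electrode pairing is either *one-to-one* (matched channel positions only;
with unequal channel counts, pairs are formed up to the smaller count with a
warning) or *all-to-all* (every cross-subject combination); the per-pair
values are averaged with equal weights. Band weights multiply the averaged
value per band; bands are never summed together, so the output stays one
value per band.

### Degenerate inputs

A flat channel, a zero envelope, or zero circular variance would make the
formulas 0/0. Because a feedback loop must keep emitting frames, every
metric returns 0 with a `degenerate` flag in that case, and the flag is
propagated into the frame. NaNs never enter the output stream.

## Windowing choices

* **Window size 3 s** (default): short enough for feedback immediacy, long
  enough for stable estimates in the alpha band (~30 cycles). It is a
  trade-off the user owns; the engine accepts any window that fits the
  buffer.
* **Pad 1 s** (default): filtering is causal and stateless per window, so
  the first ~filter-settling period of each window is contaminated, and the
  Hilbert transform's circular-boundary assumption corrupts both edges. The
  engine therefore pulls `window + pad` seconds and discards the leading
  pad after the transform. Stateless per-window filtering is what makes the
  simulated-live and offline paths *exactly* equal -- a continuous stateful
  filter would make frames depend on the chunking history.
* **Hop 0.25 s** (default): the original engine ran "as fast as the CPU
  allows", which is irreproducible by design; a fixed hop makes every run
  of the same data identical. No frame is emitted before `window + pad`
  seconds exist ("warming up").
* **Filter**: 4th-order Butterworth band-pass, applied causally. Flat
  passband, modest transient, standard in real-time EEG. Zero-phase
  (forward-backward) filtering is deliberately excluded: it is acausal and
  unavailable in a live loop.
* **Band power** is reported as the time-averaged power of the band-limited
  real signal, $\tfrac1{2N}\sum_t |X(t)|^2$ (the analytic envelope squared
  is twice the real signal's instantaneous power), so a unit in-band
  sinusoid reports 0.5.

## Normalization

Feedback consumers need values in a known range. Min-max normalization maps
a raw value $r$ through $\mathrm{clip}((r - m)/(M - m),\, 0,\, 1)$ where the
limits $(m, M)$ blend a manual setting with limits derived from a recorded
baseline session: $m = w\,m_\text{manual} + (1-w)\,m_\text{baseline}$ (and
likewise for $M$), $w \in [0,1]$. Baseline limits are per-(pair, band) --
pairs differ systematically in raw synchrony -- with a global fallback for
unseen keys, and an optional percentile mode (e.g. 5th/95th) to resist
outliers. Constant baselines are guarded (`max` inflated by $10^{-6}$)
rather than allowed to produce division by zero. Clipping, not rescaling,
handles out-of-range values, keeping the feedback channel bounded.

## The output contract

A frame for $S$ subjects and $B$ bands is a flat vector of length
$\binom{S}{2} \times B$ -- e.g. 24 values for 4 subjects and 4 bands --
ordered pair-major (pairs lexicographic by stream position: (1,2), (1,3),
..., (2,3), ...) and band-minor (configuration order). The ordering is
carried in the frame metadata so consumers need not guess. Sinks receive
every frame independently; a failing sink is logged and skipped, never
allowed to stall the loop. The CSV recorder writes
`(timestamp, pair, band, value)` rows that round-trip losslessly.

## The synthetic generator

Validation needs data with *known* coupling. For each dyad the generator
builds:

* a common carrier $\phi(t) = 2\pi f_0 t + d(t) + w(t)$, with $d$ a small
  slow Gaussian drift and $w$ a slow wander with uniform circular marginal.
  The wander cancels inside the dyad but decorrelates the dyad from any
  other stream at the same base frequency -- independently generated
  oscillators at one shared frequency would otherwise be trivially
  phase-locked within any window;
* subject A: $a(t)\cos\phi(t)$, subject B:
  $b(t)\cos(\phi(t) + \delta(t))$;
* the phase offset $\delta(t)$: a standard Gaussian process ideally
  low-passed at `jitter_cutoff` (default 1 Hz, so B stays narrowband), then
  pushed through the probability integral transform to a von Mises$(0,
  \kappa)$ marginal. Because the marginal is *exact*, the population PLV is
  exactly the Bessel ratio $I_1(\kappa)/I_0(\kappa)$ (`expected_plv()`);
* envelopes $a, b$: a Gaussian copula over log-normal marginals
  ($\sigma = 0.4$, modulation bandwidth 2 Hz -- the timescale of alpha-burst
  amplitude dynamics). The latent Gaussian correlation is chosen so the
  log-normal Pearson correlation equals the requested `env_corr` exactly in
  population;
* additive $1/f$ background noise, scaled to the requested
  oscillation-to-noise power ratio, independent across subjects.

Multi-subject sessions compose dyads plus independent background streams and
return a ground-truth table per pair.

### Calibration protocol and its finite-sample bias

A window's PLV is $|\bar Z|$, the modulus of a mean of unit phasors; it is
biased upward relative to the population resultant $R$:
$E|\bar Z| \approx R + (1 - R^2)/(2 R N_\mathrm{eff})$, with
$N_\mathrm{eff} \approx 2 f_c T$ the effective number of independent phasors
in a $T$-second window when the offset process has bandwidth $f_c$. With
the default 1 Hz offset bandwidth, the calibration studies therefore use
20 s windows ($N_\mathrm{eff} \approx 40$, predicted bias $\le 0.023$ at
$\kappa = 1$ and smaller for larger $\kappa$), 200 windows at a 5 s hop, and
a wide 2–30 Hz analysis band so the filter does not clip the jitter
sidebands. Under that protocol the window-averaged PLV is required to sit
within 0.03 of $I_1(\kappa)/I_0(\kappa)$ for $\kappa \in \{1, 2, 4\}$.

The $\kappa = 0$ null has no closed form at finite $N_\mathrm{eff}$, so the
chance level is obtained from an independently coded simulation of the
offset process (1000 replicate windows), and the pipeline's mean PLV and
CCorr must agree with the simulated chance mean within three combined
standard errors plus a 0.005 allowance for the residual systematic
difference between the oracle's pure carrier and the pipeline's filtered,
Hilbert-transformed signals.

Envelope-correlation recovery is intrinsically noisier: 60 s of a 2 Hz
envelope process carries only ~100–200 effective samples, so a
single-session window-averaged Pearson estimate has a standard error of
roughly 0.07–0.09. The recovery checks therefore average the window-mean
estimate over four replicate 60 s sessions (10 s windows, 2 s hop,
oscillation-to-noise ratio 50), bringing the standard error to ~0.03
against the required 0.1 band.

### What the generator does not emulate

The synthetic signals are narrowband oscillations with controlled coupling;
real EEG is broadband, nonstationary, and contaminated by ocular, muscular
and motion artifacts -- motion artifacts in particular are themselves
correlated across interacting people and can masquerade as synchrony.
Passing the calibration suite demonstrates that the *estimators and the
pipeline plumbing* are correct, not that any particular observed synchrony
in real recordings is neural. Online artifact handling is out of scope.

## Other design decisions

* **Stream alignment**: windows are aligned per-stream by
  most-recent-sample; there is no cross-stream clock-drift correction. This
  is a documented limitation, adequate for transports that already
  timestamp on a common clock.
* **Unequal sampling rates** across streams are rejected rather than
  silently resampled.
* **Missing samples** in a chunk are repaired by carrying the previous
  value forward, with a warning -- a live loop cannot stall on a dropped
  sample.
* **File adapter**: recordings are plain CSV with a
  `# sampling_rate=` header line and a channel-label row, written and read
  by `write_eeg_csv()`/`read_eeg_csv()`. The chunk contract is
  transport-agnostic, so in-memory streams (live-transport mocks) and files
  exercise identical code paths.
* **Interfaces**: `run_offline()` is the batch driver; `run_session()`
  replays the same data through ring buffers chunk-by-chunk, emitting to
  sinks -- the two are sample-for-sample identical by construction, and the
  test suite asserts it. A thin command-line wrapper
  (`inst/scripts/ibsync.R`) exposes `analyze`, `baseline`, `simulate` and
  `validate-config` over these functions.
* **Problem sizes in the test suite** follow the calibration protocols
  above (200 × 20 s windows for phase calibration; 4 × 60 s sessions for
  envelope recovery); the full suite and the reproduction script each run
  in well under a quarter hour on a single CPU.

## Worked example

```{r example}
spec <- coupling_spec(kappa = 2, env_corr = 0.6, snr = 10,
                      duration = 12, fs = 250, seed = 7)
dyad <- generate_dyad(spec)
cfg <- session_config(bands = list(alpha = band_spec("alpha", 8, 12)),
                      metric = "plv", window_size = 3, hop_seconds = 1,
                      pad_seconds = 1)
tab <- run_offline(dyad, cfg)
head(tab)
c(measured = mean(tab$value), expected = expected_plv(2))
```

The window-averaged alpha PLV lands close to the Bessel-ratio prediction
for $\kappa = 2$; the residual gap is the finite-window bias discussed
above (3 s windows were chosen here for brevity, not calibration).
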