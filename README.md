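# ibsync — real-time inter-brain EEG synchrony

`ibsync` computes inter-brain connectivity between two or more
simultaneously recorded EEG streams ("hyperscanning") over sliding windows,
the way a live neurofeedback engine does: ring-buffered ingestion, causal
band-pass filtering, Hilbert analytic signals, six pairwise connectivity
metrics with electrode-pair averaging, min-max normalization against manual
and baseline-derived limits, and packed output frames for downstream
visualization or sonification clients. A synthetic multi-subject generator
with known ground-truth coupling makes the whole chain testable without any
recorded data.

It is aimed at researchers building interpersonal-biofeedback or
hyperscanning analysis setups who need a reproducible, scriptable engine
rather than a GUI.

## The statistics at the core

Each analysis window yields the analytic signal
$X(i,t) = A(t)e^{i\theta(t)}$ per channel and band. For subjects $x, y$ and
channels $i, j$, the available metrics are (sums over the $N$ window
samples, $^*$ = complex conjugate):

| metric | definition | range |
|---|---|---|
| coherence | $\lvert\sum_t X Y^*\rvert \,/\, \sqrt{\sum \lvert X\rvert^2 \sum \lvert Y\rvert^2}$ | [0, 1] |
| imaginary coherence | $\lvert\mathrm{Im}\sum_t X Y^*\rvert \,/\, \sqrt{\sum \lvert X\rvert^2 \sum \lvert Y\rvert^2}$ | [0, 1] |
| envelope correlation | Pearson $r$ of $\lvert X\rvert, \lvert Y\rvert$ | [−1, 1] |
| power correlation | Pearson $r$ of $\lvert X\rvert^2, \lvert Y\rvert^2$ | [−1, 1] |
| PLV | $\frac1N \lvert\sum_t (X/\lvert X\rvert)(Y/\lvert Y\rvert)^*\rvert$ | [0, 1] |
| CCorr | circular correlation of $\theta_x, \theta_y$ about their circular means | [−1, 1] |

Values are computed for every electrode pair (one-to-one or all-to-all),
averaged to one value per subject pair per band, multiplied by the band
weight, and optionally min-max normalized into [0, 1]. A 4-subject,
4-band session emits frames of 6 × 4 = 24 values.

The synthetic generator couples dyads through a von Mises$(0,\kappa)$ phase
offset with an exact marginal (so the population PLV is exactly
$I_1(\kappa)/I_0(\kappa)$, exposed as `expected_plv()`) and through
log-normal envelopes with a controlled Pearson correlation; see the methods
vignette (`vignettes/interbrain-synchrony.Rmd`) for the construction and
its calibration.

## Worked example

Generate a coupled dyad with phase concentration $\kappa = 2$, then measure
alpha-band PLV in 3 s windows:

```r
library(ibsync)

spec <- coupling_spec(kappa = 2, env_corr = 0.6, snr = 10,
                      duration = 12, fs = 250, seed = 7)
dyad <- generate_dyad(spec)

cfg <- session_config(bands = list(alpha = band_spec("alpha", 8, 12)),
                      metric = "plv", window_size = 3, hop_seconds = 1,
                      pad_seconds = 1)
tab <- run_offline(dyad, cfg)
head(tab)
#>   timestamp pair  band     value
#> 1         4  A|B alpha 0.6730212
#> 2         5  A|B alpha 0.6147538
#> 3         6  A|B alpha 0.5329043
#> 4         7  A|B alpha 0.6468086
#> 5         8  A|B alpha 0.7396599
#> 6         9  A|B alpha 0.7435577

c(measured = mean(tab$value), expected = expected_plv(2))
#>  measured  expected 
#> 0.7094259 0.6977747
```

The first frame appears at `timestamp = 4` (3 s window + 1 s
transient-absorbing pad), then one per hop. The window-averaged PLV
(`0.709`) sits near the theoretical mean resultant length for
$\kappa = 2$ (`0.698`); short windows carry a small, predictable upward
bias, quantified in the vignette.

The same analysis runs from the shell over recorded CSVs:

```sh
Rscript inst/scripts/ibsync.R simulate --out-dir demo --subjects 3 --kappa 6 --duration 20 --seed 3
Rscript inst/scripts/ibsync.R analyze --files demo/S1.csv,demo/S2.csv,demo/S3.csv \
    --metric plv --bands wide:2:30 --window 3 --hop 1 --out demo/frames.csv
```

`run_session()` replays recordings chunk-by-chunk through ring buffers and
emits every frame to configured sinks (in-memory, CSV recorder); it is
sample-for-sample identical to `run_offline()` on the same data.

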