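# crossfreq

Cross-frequency phase synchrony (CFS) analysis of oscillatory brain
networks: estimation, group statistics, network summaries and confound
audits, with a synthetic-data generator that makes every stage testable
against planted ground truth.

## Who this is for

Electrophysiologists and methods researchers analyzing
source-reconstructed M/EEG (or LFP) parcel time series for
*cross-frequency* interactions — n:m phase locking between oscillations
at $f_{low}$ and $f_{high} = m \cdot f_{low}$ — alongside
within-frequency (1:1) synchrony, phase-amplitude coupling (PAC) and
amplitude correlations, in task designs with baseline and retention
windows and a graded condition such as working-memory load.

## The core quantities

Narrow-band analytic signals come from Morlet wavelets
($\sigma_f = f/m$, $m = 5$; 25 log-spaced frequencies, 3–90 Hz).
The central estimator is the phase-locking value over trials $r$ and
samples $t$,

$$\mathrm{PLV}_{n:m} \;=\; \frac{1}{N}\Bigl|\sum_{r,t}
  e^{\,i\,(m\,\theta_p(r,t,f_{low}) \,-\, n\,\theta_q(r,t,f_{high}))}\Bigr|,$$

with PAC as the 1:1 PLV against the fast band's envelope phase and
amplitude coupling as the Pearson correlation of envelopes.  On top of
the estimators sit: time-shift surrogate nulls; retention-vs-baseline
(paired t, "Mean condition") and load-correlation (Spearman, "Load
condition") edge statistics with FDR control; connection density $K$
and the harmonic-consistency index
$C = \bar K \exp(-\sum_m |K_m - \bar K| / N\bar K)$; ratio-pooled
summary graphs with cross-talk-aware hyperedge bundling; 7-system
interaction matrices with randomized-graph nulls; hub-degree
correlations; network-strength-versus-capacity behavioral correlations;
and an SNR audit that predicts how much PLV change an amplitude change
alone would produce, via a simulated coupled-oscillator surface
$\mathrm{PLV}_{sim}(c, \mathrm{SNR}_x, \mathrm{SNR}_y)$.

The methods vignette (`vignettes/cross-frequency-synchrony.Rmd`)
documents every model, default and numerical choice.

## Worked example

Plant one retention-only 1:3 CFS edge (parcel 1 at 10 Hz driving
parcel 4 at 30 Hz, coupling factor 0.8) in a small six-subject study,
then recover it:

```r
library(crossfreq)

cfg <- study_config(n_subjects = 6, n_loads = 2, n_trials_per_load = 20,
                    n_parcels = 6, n_coarse = 6, sampling_rate = 300,
                    snr = 2, mixing_width = 0, pad = 0.55, seed = 11)
truth <- list(coupling_spec(1, 4, 10, 3, 0.8, "cfs"))
study <- generate_study(cfg, truth)

tensor <- compute_coupling(study, f_low = 10, ratio_m = 3)
cs     <- condition_summaries(tensor)
graph  <- mean_condition_test(cs$retention, cs$baseline,
                              edges = tensor$edges)
graph
#> stat_graph (mean condition, directed): 2/30 edges significant (alpha = 0.05, bh FDR)

e <- which(tensor$edges$p_low == 1 & tensor$edges$q_high == 4)
round(c(effect = graph$effect[e], p = graph$p[e],
        plv_retention = mean(cs$retention[, e]),
        plv_baseline  = mean(cs$baseline[, e])), 4)
#>        effect             p plv_retention  plv_baseline
#>        2.8992        0.0009        0.3676        0.0985

connection_density(graph)
#> [1] 0.06666667
```

The planted edge is recovered with a paired effect size of 2.9: its
retention-period 1:3 PLV (0.37) far exceeds its pre-stimulus baseline
(0.10, the chance floor for these trial counts).  Of the 29 unplanted
directed edges one is significant — consistent with the 5% level.  The
power analysis behind the full design's effect-size mask:

```r
minimal_detectable_effect(n = 12, alpha = 0.05, power = 0.8,
                          design = "one_sample_t")
#> [1] 0.8886543
```

i.e. a 12-subject paired design resolves effects of $d \approx 0.9$.
`run_pipeline()` chains all stages (simulate → filter/couple → stats →
consistency → networks → behavior) and writes TSV edge lists plus a
JSON manifest with seeds and checksums.

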