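---
title: "Cross-frequency phase synchrony: models, estimators and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-frequency phase synchrony: models, estimators and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Cortical oscillations at different frequencies are thought to coordinate
through *cross-frequency phase synchrony* (CFS): n:m phase locking
between a slow oscillation at $f_{low}$ and a fast one at
$f_{high} = m \cdot f_{low}$.  In visual working-memory (VWM)
experiments, inter-areal CFS between frontoparietal and visual regions
strengthens during the memory-retention period and scales with memory
load, alongside the better-known within-frequency (1:1) synchronization
and phase-amplitude coupling (PAC).  Establishing such effects from
source-reconstructed M/EEG parcel time series requires a long chain of
statistical machinery — narrow-band filtering, phase-locking estimators,
surrogate nulls, group statistics over subjects and loads with
false-discovery control, graph summaries, and careful confound auditing
— and every link of that chain can manufacture spurious effects if
miscalibrated.

`crossfreq` implements this chain as a reusable, testable pipeline.
Because raw M/EEG data of this kind are rarely shareable, the package
treats the *synthetic-data generator* as a first-class module: studies
with known planted coupling structure are the ground truth against
which every stage is validated end to end.

## Signal model and filtering

All estimators operate on complex narrow-band analytic series
$X(t, f) = A(t, f) e^{i \theta(t, f)}$ obtained by convolution with
complex Morlet wavelets

$$w(t, f) = A_0 \, e^{-t^2 / 2 \sigma_t^2} \, e^{2 i \pi f t}, \qquad
  \sigma_f = \frac{f}{m}, \quad \sigma_t = \frac{1}{2 \pi \sigma_f},$$

with Morlet parameter $m = 5$ and, by default, 25 log-spaced
frequencies from 3 to 90 Hz ($f_i = 3 \cdot 30^{(i-1)/24}$; the
"approximately logarithmic" spacing is realized as an exact geometric
rule).  Numerical choices:

* kernels are truncated at $\pm 5 \sigma_t$ (Gaussian tail loss
  $< 10^{-5}$) and normalized to unit energy so band amplitudes are
  comparable across frequencies;
* convolution runs in the frequency domain, and samples within one
  kernel half-width of a series edge are flagged **invalid** rather
  than padded — estimators must exclude them, so no phase is ever
  fabricated at trial edges.  Trials must therefore be generated (or
  recorded) with enough padding around the analysis windows for the
  lowest frequency used; at 8 Hz the half-width is about 0.5 s.

## Coupling estimators

For parcels $p, q$ and ratio $1{:}m$ the phase-locking value pools unit
phasors over trials $r$ and valid samples $t$:

$$\mathrm{PLV}_{n:m} = \frac{1}{N}\Bigl|\sum_{r,t}
  e^{\,i (m\,\theta_p(r,t,f_{low}) - n\,\theta_q(r,t,f_{high}))}\Bigr|,
  \qquad N = N_r N_t.$$

Amplitudes are discarded (unit phasors only).  PAC is the 1:1 PLV
between the slow phase and the phase of the fast band's amplitude
envelope re-filtered at $f_{low}$; a constant envelope has essentially
no power at $f_{low}$ after filtering, in which case PAC is undefined
rather than zero.  Cross-frequency amplitude correlation is the Pearson
correlation of the two amplitude series over the same observations.
Each estimator is held to a literal loop-based evaluation of its
defining sum at $10^{-10}$ tolerance in the test suite.

Single-trial dynamics use 300 ms sliding windows at 50 ms spacing, with
significance from **time-shift surrogates**: one series is circularly
shifted by a random lag in (0, 0.3] s and the estimator recomputed
(1000 realizations; threshold at the 99th percentile).  Circular
shifting preserves every single-series property — spectrum,
autocorrelation, amplitude dynamics — and destroys only alignment.
For the PLV the surrogate values at all lags come from one FFT
cross-correlation of the unit-phasor series, which is exactly
equivalent to shifting and re-estimating.

**A calibration caveat worth knowing.** The nominal level of a
percentile threshold presumes an effectively independent surrogate
ensemble.  The PLV-versus-lag function of narrow-band signals
decorrelates only over roughly $1/\text{bandwidth}$; with a 0.3 s shift
range and a 10/30 Hz pair that leaves a handful of effectively
independent surrogate values, and the 99th-percentile threshold becomes
anti-conservative (we measure ~8% exceedance where 1% is nominal).
With temporally unstructured inputs the ensemble is effectively
independent and the level is held (the acceptance suite verifies 1%
within binomial error over 1000 uncoupled simulations).  When applying
the threshold to narrow-band data, widen `max_shift` well beyond the
phase-decorrelation time — the package exposes it as an argument.

## Group statistics

Coupling tensors are estimated per (edge, window, load, subject), with
four windows: two pre-stimulus baselines and retention windows at
0.4–0.7 s and 0.7–1.0 s after stimulus onset.  Trial counts are
equalized across loads within subject (PLV is biased by $N$), and fine
(400-parcel scale) adjacency matrices may be collapsed to a coarse
(148-scale) parcellation by cell means before statistics, preserving
the low→high orientation of cross-frequency edges.

* **Mean condition** — per edge, a paired two-sided t-test of
  retention (averaged over the two retention windows and all loads)
  against the first baseline; effect size is the mean difference over
  the SD of the difference.  Retention windows are averaged before the
  test; per-window testing is available via
  `condition_summaries()`.
* **Load condition** — per edge, the Spearman rank correlation of
  retention coupling with memory load over the pooled subject × load
  observations (72 points at full scale); the correlation coefficient
  is the effect size.  Pooling (rather than per-subject correlation
  followed by aggregation) was chosen because the power analysis that
  motivates the 0.35 effect-size threshold matches the pooled sample
  size.
* **FDR** — the default is Benjamini–Hochberg.  An alternative
  `"expected_fp"` rule (delete the $\lceil \alpha N \rceil$ least
  significant discoveries — the expected false-positive count) is
  provided, but note it removes that many discoveries *unconditionally*:
  with tens of edges it deletes every true discovery, and under a
  global null it does not control the false-discovery proportion.  It
  is only sensible when the number of tests is large relative to
  $1/\alpha$.
* **Robustness masks** — leave-one-out cohorts (significant edges must
  keep $p < \alpha$ in every $n-1$ subject re-analysis) and effect-size
  thresholds.  `minimal_detectable_effect()` inverts the noncentral-t
  (or Fisher-z) power function: a 12-subject paired design at
  $\alpha = 0.05$ and power 0.8 resolves effects of $d \approx 0.9$;
  a 72-point correlation resolves $r \approx 0.33$.

Connection density $K$ is the fraction of significant edges among
possible edges — directed $n(n-1)$ for cross-frequency graphs,
unordered pairs for 1:1 graphs.  **Harmonic consistency** summarizes
how uniformly CFS at one low frequency spans the ratio set:

$$C = \bar K \exp\Bigl(-\frac{\sum_m |K_m - \bar K|}{N \bar K}\Bigr),$$

with $C = 0$ when $\bar K = 0$.  Its null distribution shuffles the
$K$ values across low frequencies independently within each ratio
column (the shuffle unit is the frequency, which preserves each
ratio's marginal density distribution; shuffling rows jointly would
instead preserve per-frequency profiles and cannot detect
concentration at one frequency, which is the question being asked).

## Networks, bundling, systems

Edges significant at multiple ratios are pooled with per-ratio
provenance; hyperedges are formed by average-linkage agglomerative
clustering of the edge–edge affinity matrix (affinity = product of the
maximum pairwise parcel cross-talk among low ends and among high ends),
cut at distance 0.5 — linkage and cut are configurable since nothing
deeper pins them down.  Bundles smaller than 4 edges are dropped, as
are members below the bundle's median end-vertex degree (the "<50%
centrality" rule is read as below-median within the bundle).
Hyperedges whose ratio composition is attributable to a single ratio
(permutation test against labels drawn from the pooled edge set,
$p < 0.05$ uncorrected) are excluded from cross-ratio summaries.
System-level interaction matrices collapse a parcel graph to a 7×7
density matrix and compare each cell against randomized graphs with
the identical edge count (5000 at full scale).  Hub structure is
compared across networks by Pearson correlation of parcel degree
vectors (CFS low-frequency-end degree versus the 1:1 network at
$f_{low}$, and analogously for the high end), BH-corrected.

## Behavior

VWM capacity is $C(l) = \mathrm{HR}(l) \cdot l$.  Per-subject network
strength $S$ sums coupling over the positive-tail Mean-condition mask
and the two retention windows.  Both $S$ and $C$ are detrended —
subtract the subject mean across loads, then the load-wise population
mean of the centered values — and normalized by
$\bar S_{abs} = \frac{1}{N_s}\sum_s \sum_l |S - \bar S_L(s)|$ (the
literal formula: summed over loads, averaged over subjects).  The
output has exactly zero mean over subjects at every load and zero
grand sum; a per-load offset in the input changes only the overall
scale, never a downstream correlation.  Strengths averaged within
ratio groups (low 1:2–1:5, high 1:6–1:9; a 1:2 versus 1:3–1:5 split is
available for post-hoc dissection) are correlated with capacity over
all subject × load points, BH-corrected across the tested
frequencies.

## The SNR confound audit

Rising oscillation amplitude improves phase estimation and inflates
PLV without any change in underlying coupling.  The audit asks whether
an observed PLV change exceeds what the amplitude (SNR) change alone
predicts:

1. simulate the canonical coupled pair — Morlet-filtered white noise
   $X, Y$ at $f_1, f_2 = n f_1$, fast series receives
   $c \, A_x e^{i n \varphi_x}$, both normalized to unit instantaneous
   amplitude, plus independent unit-amplitude noise scaled by
   $1/\mathrm{SNR}$ — over a geometric SNR grid (factor 1.3) and a
   coupling-factor grid, measuring PLV after Morlet re-filtering
   exactly as experimental PLV is measured;
2. map apparent SNR, $\mathrm{aSNR} = (A_{exp} - A_{noise}) /
   A_{noise}$, to simulator SNR through a numerically estimated
   monotone link;
3. invert the surface at the initial SNRs to get the coupling factor
   $c_{in}$ behind the observed initial PLV;
4. predict $\Delta\mathrm{PLV}$ from the surface at the modulated SNRs
   with $c_{in}$ fixed, and compare with the observed change (focusing
   on the largest observed changes, 200 edges at full scale).

A design note: the coupled-pair construction injects into the *fast*
series only.  A reciprocal slow-side term $c\,A_y e^{i n \varphi_y}$
(available via `reciprocal = TRUE`) oscillates at $n f_2$, outside
both analysis bands; it contributes no n:m locking, but through the
amplitude normalization it corrupts the slow phase enough to make
PLV *non-monotone* in $c$ — which would break the monotone inversion
in step 3.  Symmetric injection with the frequency-divided phase
$\varphi_y / n$ fares no better: at measurement the half-angle branch
ambiguity makes the mean phasor cancel.  One-sided injection is
monotone in $c$ throughout and is therefore the package's default
and the basis of the audit.

Simulations default to $10^5$ samples here (the Monte-Carlo floor of a
PLV on such a series is ~0.03; production analyses should use $10^6$,
which the functions accept unchanged).

## What the synthetic generator does and does not emulate

`generate_study()` assembles, per subject × load × trial × parcel,
broadband real series as sums of narrow-band stochastic oscillators
plus pink noise, with planted interactions:

* **cfs** — one-sided phase injection, active only inside the
  retention windows (50 ms raised-cosine ramps avoid spectral
  splatter); effective factor $c + \text{slope} \cdot (l - 1)$,
  clipped to [0, 1] with a warning;
* **pac** — fast amplitude modulated by the slow phase,
  $1 + c\cos\varphi_x$ (renormalized to keep mean power stable), fast
  phase untouched, so PAC exists with no phase–phase locking;
* **amp_corr** — shared amplitude envelopes with independent phases;
* **one_to_one** — same-frequency phase injection.

Noise is pink (1/f) with RMS set to $1/\mathrm{SNR}$ of a unit
oscillator's real-signal RMS; linear mixing between parcels decays
exponentially with parcel-index distance (row-normalized, diagonally
dominant), from which the fidelity / cross-talk / spread metrics are
derived analytically as cosine similarities of mixing rows.  Hit rates
decline logistically with load from ~0.98 toward ~0.59 — above chance
at the highest load — realized as binomial proportions; an optional
`behavior_link` ties a subject's hit-rate logit to the same latent
ability that multiplies their planted coupling factors, planting a
strength–capacity association.  All randomness derives from one master
seed through deterministic per-(subject, load, trial, parcel) streams:
equal configs give bit-identical studies.

Deliberately *not* emulated: anatomically realistic lead-field
cross-talk (mixing is index-distance-based), inter-subject anatomical
variability, non-stationary noise, eye/muscle artifacts, and volume
conduction asymmetries.  Passing tests on these studies therefore
validate the statistical machinery — estimator correctness, null
calibration, FDR behavior, recovery power, PAC/CFS dissociation, SNR
auditing — not the neurophysiological interpretation of any real
dataset.

## Validation sizes and what the suite shows

The test and acceptance runs use desk-scale studies chosen to keep the
whole suite under a minute while leaving comfortable statistical
margins: 300 Hz sampling (250 Hz for the null-calibration batch),
4–8 parcels, 5–8 subjects, 12–60 trials per load, frequencies 8–10 Hz
with ratio 1:3, and $10^5$-sample coupled-pair simulations.  Under
those conditions the suite demonstrates: estimator–oracle agreement to
$10^{-10}$; surrogate false-positive rates at the nominal 1% within
binomial error; group-level BH false-discovery proportions below
$\alpha$ on global-null studies; recovery of planted CFS edges
(coupling factor 0.8, SNR 2, 60 trials, 8 subjects) with sensitivity
1.0 and edge-level false positives below $2\alpha$; recovery of
load-slope edges by the Load condition; PAC-only edges detected by PAC
but at chance in CFS; and SNR-audit behavior in which amplitude-only
modulation leaves observed minus predicted $\Delta$PLV centered at
zero while genuine coupling changes exceed the prediction for every
planted edge.

## Known limitations

* The time-shift threshold's level depends on the shift range relative
  to the signal bandwidth (see the calibration caveat above).
* The `"expected_fp"` FDR rule is faithful to its verbal description
  but statistically degenerate at small edge counts; BH is the
  default.
* Coupling-factor inversion saturates where the PLV surface is flat
  (very low SNR, or observed PLV above the simulated maximum); such
  edges are clipped with a warning and their predictions are
  conservative.
* The parcel-exclusion rule (low fidelity with high cross-talk and
  spread) uses a configurable threshold on $f/(c \cdot s)$; the
  appropriate cutoff depends on the mixing model and is left at "no
  exclusion" for synthetic studies by default.
* Arrays persist as RDS, tables as TSV, configurations as YAML and
  manifests as JSON; no HDF5 container is used.
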