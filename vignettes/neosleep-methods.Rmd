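---
title: "Multi-scale permutation entropy and automatic staging of neonatal sleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale permutation entropy and automatic staging of neonatal sleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosleep)
```

## The problem

Neonatal sleep does not yet show the adult EEG landmarks (spindles,
K-complexes, mature slow waves), so only three vigilance states can be
distinguished in the first weeks of life: quiet sleep (NREM), active sleep
(REM) and wakefulness. Visual staging of 30-second polysomnography (PSG)
epochs is slow, expensive and only moderately reproducible in this
population. `neosleep` implements an automatic alternative: it quantifies
the irregularity of each PSG channel with multi-scale permutation entropy
(MSPE), and feeds those per-epoch features to a random-forest classifier
evaluated with leakage-free, subject-level cross-validation, within and
across two recording sessions ("week-2" and "week-5") that bracket a period
of rapid cortical development.

## Permutation entropy and its multi-scale extension

For a signal $x_1, \dots, x_N$, embedding order $m$ and lag $\tau$, each
window $(x_t, x_{t+\tau}, \dots, x_{t+(m-1)\tau})$ is mapped to the
permutation that sorts it — its *ordinal pattern*. With $m = 3$ there are
$3! = 6$ possible patterns. Permutation entropy (PE) is the Shannon entropy
of the pattern relative frequencies $p_i$,

$$ H = -\sum_i p_i \ln p_i \in [0, \ln m!], $$

zero for a monotone ramp (a single pattern) and $\ln 6 \approx 1.79$ when
all six patterns are equally frequent. Because only order relations enter,
PE is invariant under any strictly increasing amplitude transformation —
a valuable property for noisy, non-stationary neonatal EEG where absolute
amplitudes are unreliable.

The multi-scale extension computes PE after *coarse-graining*: the signal
is replaced by means of non-overlapping windows of $s$ samples. Like
low-pass filtering, this removes fluctuations faster than the window, so
entropy at scale $s$ reflects slower dynamics. With 11 channels and scales
$1\dots5$, each 30-s epoch yields a 55-dimensional feature vector
(channel-major order). "Fast scale" refers to scale 1, "slow scale" to
scale 5.

Defaults and the reasons for them:

* **Order $m = 3$, lag $\tau = 1$.** Six ordinal patterns keep estimates
  well-conditioned on 3750-sample epochs (30 s at 125 Hz); at scale 5 only
  750 coarse samples remain, and $m = 3$ still leaves >100 windows per
  pattern. Entropies are reported in nats and not normalized by $\ln m!$
  (a `normalized` flag exists).
* **Ties** between equal sample values (common after 16-bit quantization)
  are broken by temporal order: the earlier sample ranks lower. Fixed so
  results are reproducible across implementations.
* **Coarse-graining remainders** are dropped (`floor(N/s)` windows), the
  common convention in the multiscale-entropy literature.

## Spectral features

As a linear comparison feature set, Welch power spectral densities are
computed per channel with 4-s Hamming windows at 50% overlap (≥13 averages
per epoch, 0.25 Hz native resolution) and aggregated to 1-Hz bins centered
on 1–30 Hz: 330 features per epoch (11 × 30). Density normalization is
checked against Parseval's identity, and the 1-Hz aggregation preserves
band power exactly because the native bin width divides the 1-Hz bins.
Window length and overlap are configurable; the defaults trade variance
against resolution on 30-s epochs. A log transform is left to plotting and
statistics; stored features are raw densities.

## Preprocessing

The conditioning chain is fixed and logged in each epoch set's provenance:
down-sample (500 → 125 Hz), reduce to the 11-channel sleep montage,
band-pass 0.5–35 Hz, cut 30-s epochs, exclude artifact epochs.

* **Filtering** uses Hamming-window FIR designs applied with zero phase via
  a frequency-domain $|B(f)|^2$ transfer (the magnitude response of
  forward–backward filtering). This avoids the $O(N \cdot \text{taps})$
  cost of time-domain convolution with the ~800-tap filter the 0.5 Hz edge
  requires; edge transients are confined to a filter length at each end.
  Phase handling is a package choice: zero-phase keeps epoch boundaries
  aligned across channels.
* **Artifact exclusion** operates in two stages. Epochs labeled MOVEMENT or
  TRANSITIONAL are removed unconditionally. Remaining epochs are scored by
  mean Welch power in 19–21 Hz over the EEG channels — a fully automatic
  surrogate for the semi-manual screening of electrode-impedance artifacts,
  which carry a 20 Hz signature — and the top `floor(n * 0.05)` scores
  (the 95th-percentile rule) are removed, ties keeping the earlier epoch.
  The exact score a human screener thresholds is not recoverable, so the
  band and percentile are configurable and the score definition is
  documented rather than guessed at.
* **Idempotence.** The percentile is defined on the raw recording's score
  distribution. Re-applying the same exclusion to an already-cleaned set
  would discard clean epochs, so the operation consults the provenance log
  and does not re-threshold a set that already records the same
  band/percentile exclusion.

## The synthetic cohort

No public neonatal recordings accompany this pipeline, so a generator
produces labeled two-session cohorts with the statistical structure the
analysis assumes — *orderings and separability, not EEG realism*:

* **Hypnograms** are semi-Markov: geometric bouts (mean dwell NREM 3,
  REM 6, WAKE 4 epochs) with bout states drawn proportionally to
  prevalence/dwell, so long-run time fractions equal the prevalences
  (week-2: 11.5/60.6/27.9% for NREM/REM/WAKE; week-5: 19/57.2/23.8%).
  Dwell means are short enough that a 30-min recording usually contains
  all three states — a prerequisite for balanced cross-validation folds.
  Note that at 60 epochs per recording the realized fractions still carry
  substantial sampling noise (REM-fraction SD ≈ 0.1); only long-run
  fractions are tight.
* **Signals** per state are mixtures of band-limited Gaussian noise
  (delta/theta/alpha/beta, exact band edges via FFT masking), a white
  broadband component, and event processes: tracé-alternant-like NREM
  bursts, slow-eye-movement EOG excursions, a quasi-periodic ECG,
  tone-scaled EMG. The broadband fractions (NREM 0.08 < REM 0.28 <
  WAKE 0.50) order fast-scale entropy WAKE > REM > NREM by construction.
  WAKE additionally carries a high-amplitude coherent ~2.5 Hz oscillation;
  after coarse-graining it dominates the ordinal structure and makes WAKE
  the most regular state at the slow scale, yielding the slow-scale
  reversal (REM > WAKE). The week-2 session adds +0.12 to every state's
  broadband fraction, so week-2 entropy exceeds week-5 entropy at the fast
  scale by construction.
* **Artifacts**: 8% of epochs (near the commonly reported exclusion rate)
  are relabeled MOVEMENT/TRANSITIONAL and overwritten with high-amplitude
  broadband noise so exclusion logic is exercised.
* **Burst parameters are placeholders**: no quantitative tracé-alternant
  model is available for this population; only the presence of bursting in
  NREM is meaningful, and the rate/duration/gain defaults should not be
  interpreted physiologically.

What passing tests on this cohort do and do not show: they validate the
pipeline's mechanics and its ability to recover *constructed* orderings and
separable states; they say nothing about accuracy on real neonatal EEG,
whose morphology, artifacts and inter-subject variability the generator
does not model.

## Staging and evaluation

* **Cross-validation** is subject-level repeated two-fold: subjects are
  halved, both halves serve once as test set, and a subject's two sessions
  never straddle the split (asserted per fold). Within-session schemes
  train and test on the same session; cross-session schemes train on one
  half's week-X epochs and test on the other half's week-Y epochs. Default
  20 repetitions (the variant tied to reported medians where sources also
  mention 10), medians reported.
* **Balancing**: both training and test sets are randomly under-sampled to
  the minority class, so chance accuracy is 1/3 for three classes. A flag
  restores unbalanced-test evaluation for real-world use. Folds in which a
  random subject half lacks a class entirely (possible for sparse week-2
  NREM) are skipped and recorded rather than imputed.
* **Hyper-parameters**: trees {100, 300} × depth {∞, 8} × mtry
  {√p, 0.3p}, selected by 3-fold inner CV on the training half; first
  candidate wins ties. A one-row grid skips the search.
* **Chance level** is estimated by globally permuting epoch labels (a
  stricter null than within-subject permutation, since it also destroys
  subject structure) and re-running the full CV per shuffle; default 100
  shuffles, one repetition each — replication comes from the shuffles. The
  null forest configuration is fixed (300 trees): chance is insensitive to
  tuning and the saved search time goes into more shuffles.
* **Bootstrap summaries**: per (subject, session, stage, location, scale)
  cell, 1000 bootstrap draws of 10 epoch-level values are averaged and
  averaged again, equalizing observations across subjects and stages
  before the cell means are exported as the long-format table a linear
  mixed model consumes. The resampling is within subject-stage cells, per
  the equal-observations rationale. Model fitting itself (lme4-style
  LMMs, Wald tests, post-hocs) is deliberately out of scope: those are
  off-the-shelf statistics, and the exported table is their exact input.
* **Metrics**: accuracy, per-class precision/recall/F1 from the 3×3
  confusion matrix; zero denominators yield 0 with an explicit flag rather
  than NaN, keeping JSON outputs machine-readable. The identity
  "recall weighted by row sums = accuracy" is asserted in tests.

## Numerical and design choices

* EDF I/O is a minimal implementation of the fixed-layout 16-bit format
  (1-s records); round trips are exact up to per-channel quantization of
  the physical range. Hypnograms travel as `epoch_index,stage` CSVs.
* Epochs are 0-based with half-open sample intervals
  `[i·30·fs, (i+1)·30·fs)`; trailing partial epochs are dropped; epoching
  is partition-exact (concatenating epochs reproduces the trimmed signal
  bit-for-bit).
* Down-sampling requires an integer decimation factor and applies an
  anti-alias FIR (cutoff 0.8 × new Nyquist) before keeping every q-th
  sample.
* All stochastic stages (generation, splits, under-sampling, forests,
  bootstrap, shuffles) derive their seeds from user-supplied integers;
  identical configurations reproduce feature tables bit-for-bit.
* The pipeline runner tags every output file with an FNV-1a hash of its
  configuration and leaves a manifest, so partial failures are resumable
  and outputs are traceable.

## Problem sizes used in the shipped checks

The package's own validation uses cohorts scaled to desk hardware: unit
tests run on 2–4 subjects with 6–10-minute recordings; the
structure-recovery and chance-level checks use the 6-subject demo cohort
with full 30-minute sessions, 5 CV repetitions with a fixed 300-tree
forest, and 100 label shuffles. These sizes are the package's choice of a
demonstration scale; all of them are configuration parameters, and the
defaults in `run_config()` match the demo scale.

## Known limitations

* The generator's band-mixture model cannot probe morphology-dependent
  staging cues (spindle-like events, delta-brush topography) and encodes
  the developmental effect as a single broadband offset.
* Cross-session transfer on synthetic data is easier than on real data;
  the observed within/cross accuracy gap depends on the constructed
  session effect size.
* The artifact score is a surrogate; on real recordings the 19–21 Hz band
  and the 95th percentile should be revisited against visual screening.
* MOVEMENT/TRANSITIONAL injection replaces whole epochs; partial-epoch
  artifacts are not modeled.
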