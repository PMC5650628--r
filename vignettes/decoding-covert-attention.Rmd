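---
title: "Decoding covert visual attention with CCA spatial filters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding covert visual attention with CCA spatial filters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccabci)
```

## The decoding problem

A subject fixates a central cross while `m = 12` objects arranged around it
are flashed one at a time.  Each object is flashed 5 times per trial in a
constrained pseudo-random order (one flash per stimulus onset asynchrony of
1/6 s, 60 flashes in ~10 s), with two flashes of the same object always at
least 0.5 s apart — i.e. separated by at least two other-object flashes.
The subject covertly attends one object; its flashes are rare, relevant
events among distractors and therefore evoke an oddball (P300-like)
response.  Because every object owns a temporally unique flash sequence,
identifying *which* sequence of post-flash responses is present in the
multichannel EEG/MEG recording identifies the attended object.

`ccabci` implements the full pipeline: schedule generation, preprocessing,
joint estimation of spatial and temporal filters by canonical correlation
analysis (CCA), sequence scoring, and the evaluation harness around it.

## Model

For a trial let $X \in \mathbb{R}^{n \times c}$ be the preprocessed signal
($n$ samples, $c$ channels).  For each object $e$ with onset samples
$t_e$, the *reference functions* form a binary matrix
$Y_e \in \{0,1\}^{n \times d}$ whose column $j$ has a 1 at row $j + t$ for
every $t \in t_e$: one impulse train per post-stimulus latency, spanning a
window of $d$ samples (0.8 s, $d = 41$ at the 50.863 Hz analysis rate).
Multiplying by a temporal template $s \in \mathbb{R}^d$ overlap-adds a copy
of $s$ at every onset: $v_e = Y_e s$ is the time course the trial *should*
contain if object $e$ was attended and each of its flashes evoked $s$.

Training trials (with known attended object) are concatenated along time
into a common $X$ and a common $Y$ (each trial contributing its target's
$Y_e$).  CCA then finds pairs $(w_k, s_k)$ maximizing
$\rho_k = \mathrm{cor}(X w_k,\; Y s_k)$: $w_k$ is a *spatial filter*
(channel weighting producing a surrogate channel), $s_k$ a *matched
filter* (data-driven response template).  No assumption is made about the
location or shape of the response — both are estimated simultaneously.

Components are retained while $\rho_k \ge 0.1$ **and** the sequential
Bartlett $\chi^2$ test rejects, at $\alpha = 0.05$, the hypothesis that all
correlations from $k$ onward are zero
($\chi^2_i = -(N - 1 - (c+d+1)/2)\sum_{j \ge i}\ln(1-\rho_j^2)$ with
$(c-i+1)(d-i+1)$ degrees of freedom).  The retention sentence could also be
read as removing only components failing *both* criteria; we retain only
components passing both, since keeping non-significant surrogate channels
contradicts the purpose of the reduction.  `K = 0` is a valid outcome; the
decoder then falls back to the initial model.

To decode a new trial, $u_k = X w_k$ is correlated with $v_{k,e} = Y_e s_k$
for every candidate object; correlations are variance-stabilized with
$\mathrm{atanh}$ (clamped at $1 - 10^{-12}$), averaged over the $K$
components, and the highest-scoring object is predicted (ties, which occur
only on degenerate inputs, break to the lowest index).  Before any training
data exist, the *initial model* — $w_i = 1$ for all channels and a
triangular "hat" template — already permits a prediction in the first
trial of an online session.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `soa` | 1/6 s | flash-to-flash interval (any object) |
| `min_gap` | 0.5 s | minimum same-object onset separation (3 slots) |
| `post_window` | 0.8 s | analysis window after each onset |
| `d` | 41 | template length in samples (`round(0.8 * 50.863)`) |
| `factor` | 10 | decimation factor (508.63 Hz to 50.863 Hz) |
| `rho_min`, `alpha` | 0.1, 0.05 | component retention |
| `ridge` | 1e-8 | covariance regularization (see below) |

`ridge` adds `ridge * mean(diag(C))` to each covariance block diagonal.
With 245-channel arrays and few training trials the sample covariance is
rank deficient and the unregularized whitening is unstable; the default is
small enough to be inert once a handful of trials is available (the exact
oracle comparisons in the tests run with `ridge = 0`).

## Numerical choices

* **Zero-phase filtering.** The anti-alias low-pass (Hamming windowed
  sinc, cutoff at the output Nyquist, transition band at most 20% of it) is
  applied as a centred convolution over edge-reflected padding.  A causal
  application would delay every channel by half the filter order and shift
  all matched-filter latencies; edge reflection keeps the first flash
  (which sits at the very start of the segment) usable together with the
  100 ms buffers cut during segmentation.
* **Indexing.** Onset times convert to 0-based sample indices by rounding
  half away from zero; the same-object gap is enforced in integer slot
  units so no floating-point comparison is involved.
* **Sign convention.** CCA components are sign-indeterminate; each pair is
  flipped so the matched filter's largest-magnitude coefficient is
  positive, making templates comparable across fits and subjects.
* **Degenerate inputs.** Zero-variance surrogate time courses (possible
  after truncation) contribute a correlation of 0 rather than `NA`;
  perfect correlations are clamped before `atanh`.
* **Schedule sampling.** Rejection sampling over uniform shuffles (100
  attempts) falls back to a randomized backtracking search ordered by a
  most-remaining-first heuristic, restarted with a bounded node budget
  because randomized DFS runtimes are heavy-tailed.  Infeasible constraint
  sets raise an error; nothing is silently relaxed.

## The synthetic cohort generator

Real recordings for this paradigm are not redistributable, so the package
ships a generator that emulates exactly the structure the decoder exploits:

* a Gaussian-windowed positive deflection (peak 0.40 s in the EEG-like
  preset, 0.34 s in the MEG-like preset; width 60 ms) after every
  *attended* flash, spread over a smooth focal channel pattern;
* a short common response after *every* flash on a broad pattern, whose
  superposition at the stimulation rate reproduces the stimulus-locked
  ~6 Hz oscillation that cancels in attended-minus-ignored difference
  waves but survives in single-condition averages;
* white sensor noise plus spatially correlated AR(1) background sources
  (the latter create the cross-channel covariance structure that makes
  regularization necessary on large arrays);
* per-subject topography/latency perturbations (`subject_variability`), or
  fully independent per-subject patterns (`topography_mode =
  "independent"`) to emulate the poor cross-subject geometry of
  individually positioned sensor arrays.

The default evoked-to-noise scaling (`snr = 1.5`) was calibrated once so
that a single default EEG-like subject reaches a leave-one-run-out
accuracy in the high 80s/low 90s percent — the regime reported for real
EEG — and is pinned together with the cohort seeds.  What passing tests on
this generator shows is that the *algorithm* recovers planted structure
and behaves correctly under chance, truncation, channel-subset and
transfer manipulations; it does not certify performance on real recordings,
which contain artifacts, latency jitter across trials, and non-Gaussian
noise the generator deliberately omits (no eye blinks, no cardiac
components, no biophysical forward model).

## Evaluation harness and problem sizes

`leave_one_run_out_cv()`, `online_simulation()` (per-trial refits in the
first two runs, per-run afterwards), `leave_one_subject_out()`,
`pooled_transfer_curve()` with `select_transfer_pool()` (foreign trials
ranked by the atanh-correlation of their own target sequence under the
donor model — our reading of selecting the trials "providing the highest
canonical correlation"), `permutation_chance()` (full CV per permutation), and `truncate_stimuli()`
for shorter stimulation intervals.

A note on the permutation scheme: labels are reassigned uniformly over
*all* `m` sequences, not only the 11 non-attended ones.  Under a uniform
assignment the probability that the winning sequence carries the
reassigned label is exactly `1/m` whatever the classifier does — the
calibration a guessing level must have.  Excluding the truly attended
object would bias the estimate below `1/m` whenever predictions still
track the true target; on this generator's highly stereotyped evoked
responses that residual tracking is substantial (wrong-label training
partially recovers the template through the heavily overlapping 0.8 s
windows), so the exclusive variant is measurably miscalibrated.

The test suite exercises these at deliberately modest sizes — single
subjects with 4–5 runs of 12 trials, 4-subject cohorts, 60–120
permutations, and a scaled-down 4-object design for structural checks —
chosen so the whole suite completes in a few minutes while keeping every
statistical assertion comfortably powered.  The full-scale design (500
permutations, 100-trial transfer pools, 19-subject cohorts) runs through
the same code paths unchanged.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config("eeg", n_subjects = 1, n_runs = 4, seed = 11)
ds  <- simulate_dataset(cfg)
cv  <- leave_one_run_out_cv(ds$trials)
cv$da
#> [1] 0.875
wolpaw_itr(cv$da, N = 12, trial_seconds = 10, overhead_seconds = 2.5)
#> [1] 12.52305
```

## Known limitations

* No EDF/BDF reader: trials enter either from the generator or from the
  package's plain-text container (`write_trials()`/`read_trials()`).
* Reference-sensor noise cancellation is a per-trial least-squares
  projection, not the adaptive variant used on real MEG systems.
* Group-level inference (signed-rank tests, ANOVA) is out of scope; the
  package reports per-subject and pooled accuracies only.
* The generator's subjects differ only in topography and template latency;
  real inter-subject variability also involves waveform shape and
  component rank.
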