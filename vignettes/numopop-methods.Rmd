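---
title: "Models and methods behind numopop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numopop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`numopop` analyses single-neuron spike data from number production tasks:
a numerical instruction cue (1–5, dot array or numeral sign) is held
through a motor planning delay and then converted into the matching count
of self-generated actions. This vignette documents the generative model
behind the synthetic data, the statistical procedures of each analysis
stage, the tunable parameters and their defaults, and the design choices
made where the methodology left genuine freedom.

## Task structure

A trial is `fixation (300 ms) → instruction (500 ms) → planning (1000 ms)
→ execution`. All times are in milliseconds relative to instruction onset;
fixation times are negative. Five numerosities × two formats (dot, sign) ×
two stimulus conditions (standard, control) give 20 trial conditions. The
timing of the execution-period responses follows one of three arrangements
(`temporal_arrangement()`): uniform draws from {200, 500, 800, 1100} ms,
constant 200 ms intervals, or a fixed-total-duration schedule (2100 ms ×1,
800 ms ×2, 400 ms ×3, 200 ms ×4 for values 2–5). Each session pairs the
standard arrangement with one control, alternating between sessions.

## The behavioral model

No generative behavioral model is prescribed by the task itself; the
package's choice — documented as its own — is a log-Gaussian internal
estimate. On a trial with instructed value $n$ the subject produces

$$k = \max\{1,\ \mathrm{round}(e^x)\}, \qquad x \sim
\mathcal N(\log n,\ w^2),$$

with Weber fraction $w$ (default 0.2). This single parameter reproduces
both approximate-number-system signatures: errors concentrate on
numerically adjacent values and decay with distance (distance effect), and
the spread of produced counts grows proportionally with $n$ (size effect).
It deliberately omits non-numerical error sources (lapses, motor slips,
sequential effects), so real behavior will generally be noisier than the
simulation at matched $w$.

An `abort_rate` fraction of extra trials (default 5%) is aborted
(fixation breaks, premature releases); aborted trials carry no produced
count and no spikes and are excluded from every analysis, which is why the
generator must produce some.

## The spiking model

Each neuron is an inhomogeneous Poisson process with piecewise-constant
rate

$$\lambda(t) = \max\Big(0,\ b + g\,
\exp\!\big(-\tfrac{(\log n_d - \log p)^2}{2\sigma^2}\big)\,
\mathbf 1[t \in W] + f\,\mathbf 1[\text{sign format},\ 0 \le t <
1500]\Big)$$

with baseline $b \sim U(3, 12)$ Hz, gain $g$ (default 20 Hz; negative and
bounded by $0.9\,b$ for inhibited neurons, which are one third of tuned
cells), preferred value $p \in \{1..5\}$, tuning width $\sigma = 0.3$ on a
log-numerosity axis (a linear axis is a configuration switch; the
logarithmic default matches Weber-law behavior), response window $W$, and
a format offset $f$ for the small fraction of format-coupled nuisance
neurons. Static-code neurons have windows from ~100–300 ms after
instruction onset to the end of planning; dynamic-code neurons have
transient windows of 250–400 ms placed anywhere in the instruction or
planning period. Execution-phase activity is baseline only, since no
in-scope analysis uses it.

The driving numerosity $n_d$ is, by default, the count the subject goes on
to produce (clipped to 1–5), not the instructed value. This encodes the
central hypothesis — planning activity predicts the intended action count
— and is what makes the error-trial analyses behave as they should:
activity at the instructed preferred value drops on error trials, and a
decoder trained on correct trials degrades on errors. Setting
`drive = "instructed"` yields the null world in which errors are purely
motoric.

Reproducibility: every draw derives from one root seed through
multiplicative-congruential substreams per session, per neuron and per
(neuron, trial), so datasets are bit-identical under a fixed seed and
growing the population never perturbs existing neurons or trials.

## Binning conventions

Firing rates use left-aligned half-open sliding windows
$[s + b\,\Delta,\ s + b\,\Delta + w)$ — a spike exactly on the right edge
belongs to the next bin — with canonical width 200 ms and step 20 ms
(100 ms steps for coarse confusion-matrix time courses). Bin indices are
0-based; the bin count is $\lfloor (e - s - w)/\Delta \rfloor + 1$. These
edge conventions are the package's own; nothing in the methodology fixes
them, and all tests and oracles use the same convention.

## Selectivity analysis

Neurons enter if their mean rate over baseline-to-planning-end is at least
0.5 Hz and at least five correct trials exist per condition (both
boundaries inclusive; "below 40%" for session exclusion is likewise read
strictly, so exactly 40% is included).

Per sliding bin, a two-factor fixed-effects ANOVA (numerosity × format)
yields p-values for both main effects and the interaction. Cells are
mildly unbalanced once error trials are excluded, so type-II sums of
squares are the default (`type = 1` is available); with balanced cells
they coincide with the sequential decomposition. The implementation
computes residual sums of squares for the five nested design matrices by
QR decomposition once per neuron and applies them to all bins
simultaneously; `car::Anova` serves as an independent oracle in the test
suite, never as the implementation.

A neuron is *exclusively number selective* if its numerosity p-series
sustains a run of ≥ 11 consecutive bins below α = 0.01 anywhere in the
analysis interval (100 ms after instruction onset to 100 ms into
execution) while neither format nor interaction sustains such a run. At a
20 ms step, 11 bins span 400 ms of data from first-bin start to last-bin
end; the run count, not the stated total duration, is the operative rule.
If several runs qualify, the one with the largest range of per-numerosity
mean rates wins (exhaustive enumeration is the test oracle). Phase-wise
classification (instruction vs planning) restricts the run search to bins
100 ms after the respective phase onset, mirroring response latencies; the
offsets are configurable. A 500 ms window variant for coarse sample-period
classification is available by passing a different bin scheme — the two
window sizes are one parameter, not two code paths.

Preferred numerosity is the argmax of window rates (ties broken toward the
smaller value, deterministically). For inhibited neurons the argmax
definition cannot recover the generative dip location, so parameter
recovery statements apply to excited populations. The excited/inhibited
split compares the window rate, collapsed over numerosities, with the
fixation baseline. Split-half reliability stratifies the halves by
numerosity × format, correlates the two five-point curves, and ranks the
observed $r$ within a label-permutation null (canonically 10,000
permutations; permutations that empty a (label, half) cell score zero).
Min-max normalization maps flat curves to a constant 0.5 instead of
dividing by zero and is idempotent.

## Decoding protocols

All decoders are linear one-vs-one multiclass SVMs (libsvm via `e1071`)
with regularization cost fixed at 1.0 — the conventional default; the
methodology does not specify it, and it is exposed in
`decoding_protocol()`. Features are trial-mean rates in a window
(canonically the 900 ms planning period), assembled into
pseudopopulations: per neuron, `trials_per_class` trials are sampled
without replacement per class and conjoined across neurons by (class, draw
index) — the trial-conjunction rule across sessions is the package's
choice. Folding is stratified; z-scoring uses training-fold statistics
applied to held-out trials (leak-free) by default, with a `pooled`
mode that z-scores the sampled matrix before cross-validation for
comparison with the classical recipe. Zero-variance features are dropped
from scaling. Confusion matrices are empirical prediction frequencies,
row-normalized; overall accuracy is the mean of the diagonal; shuffle
nulls rerun the identical protocol on permuted labels.

The canonical protocols: within-condition (20 trials/class, tenfold,
1000 resamples), cross-format (10 trials/class per format, train on one
format and test on the other), cross-phase (20 trials/class, 18/2 folds,
non-overlapping windows: instruction 250–550 ms, planning 700–1600 ms —
the planning window runs 100 ms into execution by construction),
error-trial (train on 9 correct per class, test each fold on one held-out
correct trial plus one freshly drawn error trial per class, the two test
subsets scored separately and compared by paired Wilcoxon across
resamples), and three-class outcome decoding (correct / −1 / +1, 30
trials/class, 27/3 folds, chance 33.3%). In `decode()` a "resample" is a
fresh stratified fold partition; the dataset-level wrappers additionally
redraw the pseudopopulation every resample.

## Time-resolved population statistics

The ω² percent explained variance of factor $T$ is

$$\omega^2 = \frac{SS_T - df_T\, MS_{error}}{SS_{total} + MS_{error}}
\times 100,$$

computed per neuron per bin from the same two-factor decomposition and
averaged over neurons. Small negative values are the honest small-sample
behavior of the estimator under the null and are reported as-is (clipping
is an explicit flag). The trace is repeated over 50 random balanced trial
subsets (mean ± SEM), and the chance baseline pools 20 label shuffles per
subset — 1000 null values per time step — whose 95th percentile is the
threshold. Inclusion requires 10 correct trials per factor level.

Cross-temporal matrices train one SVM per time bin per fold and test it on
every bin's held-out-fold features (train and test trials are disjoint
also off the diagonal), averaged over 50 redraws. The `generalization
index` — mean off-diagonal minus mean diagonal accuracy — is near zero for
static codes and strongly negative for dynamic ones, and is the statistic
behind the static/dynamic comparison.

Cluster-based permutation testing thresholds each cell at the 95th
percentile of its empirical shuffle null (not a parametric test), forms
4-connected clusters (8-connectivity by flag) of supra-threshold cells,
takes cluster *size* (cell count) as the statistic, and compares observed
sizes with the permutation distribution of maximum cluster sizes. The
observed matrix joins the permutation pool when thresholds are computed:
with only tens of permutations, excluding it makes the rank test markedly
anti-conservative (each permutation competes against a pool containing
itself, the observed matrix against one that does not); pooling restores
exchangeability, and the simulated family-wise error at α = 0.05 is ~3%
with 20 permutations. Confusion-diagonal distance curves average the
entries at |instructed − predicted| = d, pooling +d and −d.

## Problem sizes in the tests

The test and acceptance suites run the full chain at reduced but
informative scales, chosen once as realistic desk-scale study conditions:
a 30-neuron mixed population with 20 trials per condition for the shared
dataset; 1000 resamples for the shuffle-null calibration; 100 random
layouts for the ω² oracle; 20 paired datasets on a 30-bin grid for the
static/dynamic dichotomy; 500 simulations on a 12×12 grid for family-wise
error. Parameter-recovery runs use noise-free behavior ($w = 0$) so that
"20 trials per ANOVA cell" holds exactly rather than in expectation. The
acceptance thresholds (≥ 90% preferred-value recovery at gain 15 Hz,
nulls within one point of 1/K, FWER ≤ 7.5%) were fixed from the stated
study conditions, not tuned to runs.

## What the simulations do and do not show

Passing tests establish that every stage does what it claims on data whose
ground truth is known and whose assumptions match the analysis (Poisson
spiking, Gaussian log-axis tuning, rate-additive format effects,
independent trials). Real recordings violate several of these —
non-Poisson dispersion, correlated noise across neurons and time, drift,
eye-movement confounds — so recovered percentages on real data will differ
even when the code is correct. The generator is a validation instrument,
not a model of cortex.

## Known limitations

- Pseudotrial conjunction assumes independence across neurons; noise
  correlations within a session are discarded by design.
- The error-trial analyses condition on the produced count being within
  ±1 of the instruction for the outcome decoder; larger errors are
  excluded there (they are rare under the behavioral model).
- `chance_level()` implements the reciprocal-of-modal-maximum construction
  exactly as used in practice; it is a heuristic, and per-stratum
  adjustment is supported only through the `chance` argument of
  `test_above_chance()`, defaulting to the global value.
- No LFP/time-frequency analyses, no state-space models, no biophysical
  neurons, and no readers for proprietary acquisition formats.
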