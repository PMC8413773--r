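---
title: "Decoding newly learned word meanings from EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding newly learned word meanings from EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semdecode)
```

`semdecode` implements a decoding analysis for a vocabulary-learning
experiment: participants learn, through trial and error, a mapping from
unfamiliar symbols to familiar English words while EEG is recorded. The
question the analysis answers is whether — and when, and where — the brain's
response to a symbol carries the *meaning* of its mapped word, operationalized
as the ability of a linear model to predict the word's distributional
embedding (a word vector) from the evoked EEG.

This vignette explains the model, the paradigm simulator, the numerical
choices, and what passing the package's tests does and does not establish.

## The decoding model

For a chosen set of trials, electrodes and time samples, epochs are averaged
per symbol and the resulting symbol-by-electrode-by-time tensor is flattened
into a design matrix $X \in \mathbb{R}^{n_s \times (n_e \cdot l_s)}$
(electrode-major, time-minor feature order). The targets are word vectors
$Y \in \mathbb{R}^{n_s \times v}$, one row per symbol. For each embedding
dimension $i$ an independent ridge regression is solved in closed form:

$$\min_{W_{:,i}} \lVert X W_{:,i} - Y_{:,i} \rVert_2^2
  + \alpha \lVert W_{:,i} \rVert_2^2 .$$

Design choices:

* **Regularization.** $\alpha = 0.1$ by default, fixed rather than tuned;
  the 2 vs. 2 outcome is insensitive to moderate changes of $\alpha$ because
  cosine distance discards the overall scale of the predictions.
* **Centering instead of an intercept.** The loss has no offset term, so
  both $X$ and $Y$ columns are centered on the training data and the centers
  are restored at prediction time. This is the standard way to keep ridge
  well-posed without penalizing an offset. Feature standardization is off by
  default (all features are in the same unit, microvolts) but available.
* **Dual solver.** With far more features than symbols the solution is
  computed through the $n \times n$ Gram formulation
  $W = X^\top (X X^\top + \alpha I)^{-1} Y$, which equals the primal
  normal-equations solution exactly; the test suite asserts agreement to
  $10^{-8}$.

## The 2 vs. 2 test

Accuracy is measured leave-two-out: for every unordered pair of symbols the
model is trained on the other $n_s - 2$, predicts the two held-out vectors,
and the pair *passes* when the summed cosine distances of the correctly
matched true/predicted pairs are smaller than under the swapped matching.
Chance is 50%. An exact tie scores 0.5 — with heavy regularization both
predictions can collapse onto the training mean, and a 0.5 tie keeps the
null centered instead of biasing it toward 0 or 1. Zero-norm vectors get
cosine distance 1 with a warning.

Because the shuffle of a permutation test changes only $Y$, the per-pair
fit-and-predict map is a *linear operator* on $Y$ that depends on $X$ alone.
`loto_operator()` precomputes it from the Gram matrix once, after which each
of the `choose(ns, 2)` folds — and each permutation — costs a single matrix
product. The suite verifies the operator against naive per-fold refitting to
$10^{-10}$.

## Inference

* **Permutation test.** The symbol-to-vector assignment is shuffled
  `n_perm` times (default 1000) and the full leave-two-out accuracy is
  recomputed per shuffle. The add-one estimator
  $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + n_\text{perm})$ keeps
  $p$ valid and never exactly zero. Within one analysis (all windows of a
  time course; all electrode groups of a searchlight) the permutation draws
  are shared, which makes the nulls comparable across units and reuses the
  expensive operator precomputation.
* **Multiple testing.** Benjamini–Hochberg–Yekutieli step-up control with
  the harmonic factor $c(m) = \sum_{i=1}^m 1/i$, applied across the units of
  one analysis (windows, or electrode groups within a time window). Note the
  practical floor: a unit can only survive correction if
  $1/(n_\text{perm}+1)$ is below its step-up threshold, so many-unit
  analyses need permutation counts in the high hundreds or more.
* **Bootstrap comparison.** To compare two conditions (e.g., early versus
  late exposure triples) symbols are resampled with replacement — symbols,
  not pairs, are the exchangeable unit of the 2 vs. 2 design — and both
  accuracies are recomputed per replicate over the resampled symbols' pairs
  (identical-symbol pairs skipped, replicates with fewer than three distinct
  symbols redrawn). A normal-theory CI and two-sided p come from the
  bootstrap standard deviation.

## The paradigm simulator

The study's recordings are not redistributable, so the package ships a
generator that emulates the paradigm end to end; every analysis is exercised
on data whose ground truth is known.

**Schedule and behavior.** The default paradigm starts with 6 symbols and
adds 3 per block over 19 blocks (60 symbols). Blocks cycle through 6 active
symbols — the new ones plus randomly carried, previously introduced ones —
and end when rolling response accuracy over the last 10 trials reaches 90%.
Choice sets contain the correct word plus 3 distractors drawn from the other
5 active words. Learner models:

* `perfect` — knows a mapping after `acquire_after` exposures (default 1),
  whether or not that trial's guess was right (the feedback reveals the
  answer). On unknown symbols it eliminates displayed words whose mappings
  it already knows and guesses uniformly among the rest. These two rules are
  exactly the idealization under which the closed-form first-exposure
  accuracy below holds.
* `exposure_rate` — acquires a mapping with a fixed probability per
  exposure (0.3 in the dataset defaults). With elimination guessing this
  produces a learning curve rising from the low 60s in percent on first
  exposures to near 90% by the sixth, matching the qualitative behavioral
  profile of the task, and block lengths around 250–350 word trials.
* `random` — never learns; blocks then terminate at a configurable trial
  cap and are flagged.

**The 71% baseline.** For a perfect learner the expected first-exposure
accuracy has a closed form: at a first encounter with $u$ still-unknown
words among the other five, the number $k$ of unknown distractors among the
three drawn is hypergeometric and the success probability is
$E[1/(1+k)]$. First-block encounter positions have $u = 5,4,3,2,1,0$;
later-block new symbols have $u = 2,1,0$. Averaging equally over all 60
symbols gives $\approx 0.7121$, i.e. 71%. The package computes this by
enumeration (`perfect_learner_first_trial_accuracy()`) and the tests check
it against an independent Monte-Carlo oracle.

A caveat the simulator makes visible: in the *full* simulation the mastery
rule ends blocks after roughly ten trials for fast learners, so some first
encounters are censored — disproportionately those late encounter positions
where most distractors would be eliminable — and the realized first-exposure
accuracy sits a few points below the closed form. The closed form is the
idealized per-symbol expectation, not a property of truncated sessions.

**EEG generation.** Epochs are per-electrode AR(1) noise (coefficient 0.95,
stationary SD 10 microvolts — values typical of baselined, band-passed EEG)
plus, on trials where the simulated learner has already acquired the
mapping, a planted linear signal $\text{gain} \cdot g(t) \cdot (M y_s)$:
a fixed electrodes-by-dimensions mixing matrix $M$ (jittered
multiplicatively per participant to emulate inter-participant variability)
applied to the symbol's word vector, under a raised-cosine envelope
supported on 150–650 ms. The envelope places decodable signal where
sliding-window analyses can resolve it both before and after the 500 ms
choice onset. The default gain of 2 puts whole-window trial-averaged
decoding in the moderately-above-chance regime; gains of 8 and above
saturate it. Artifacts are injected with a configurable rate as one-sample
150 microvolt spikes, which violate both rejection rules by a wide margin so
the rejection report can be validated against ground-truth flags exactly.

What the generator does *not* emulate: 1/f spectral structure, ocular and
muscle artifact morphology, volume-conduction correlations between
electrodes, non-stationarity across a session, and any nonlinearity between
meaning and signal. Passing tests therefore demonstrate that the pipeline
is correct and well calibrated — recovering planted effects and staying at
chance in their absence — not that real recordings would yield any
particular accuracy.

## Preprocessing conventions

* Epochs are trimmed to [0, 1000) ms after symbol onset; baseline
  correction subtracts the per-electrode mean of the 200 ms before onset
  (so it must run before trimming when the generator includes a baseline
  span).
* Rejection: an epoch is dropped when any electrode's range exceeds
  100 microvolts, or any adjacent-sample step exceeds
  10 microvolts/ms × the sampling interval (40 microvolts at 250 Hz) —
  the only defensible discretization of a per-ms slope rule at a fixed
  sampling rate. Both comparisons are strict.
* Exposure indices count *presentations* in original order, so rejection
  cannot change which exposures are a symbol's "first two".
* Trial selection keeps participant-symbol series with at least 6
  presentations and drops the first 2 exposures (or keeps an explicit
  exposure window, as in the onset analysis).
* Averaging pools all selected trials across participants with equal
  weight per trial, not participant means of means; with unequal trial
  counts the two differ, and pooling is the reading consistent with a
  single averaging step over "all selected trials and participants".
* Millisecond windows are half-open, mapped to samples by
  $t_k = k \cdot 1000 / f_s$; at 250 Hz a 50 ms window holds 12 or 13
  samples depending on alignment, and adjacent 25 ms-stepped windows tile
  the axis consistently.

## Analysis defaults and problem sizes

The four orchestrated analyses follow the structure above: whole-window
(0–500 ms), sliding 50 ms windows stepped by 25 ms (39 windows over one
second), exposure triples (1–3 … 4–6) × two windows (0–500, 0–700 ms) with
a bootstrap first-versus-last comparison, and a searchlight of each
electrode with its montage neighbors across 0–500/500–1000/0–1000 ms.
The packaged 32-channel extended 10-20 montage stores explicit neighbor
lists (median 5 neighbors); adjacency is shipped as data rather than
derived from geometry at run time.

The test suite and the acceptance script run the full 60-symbol paradigm
with 4–6 simulated participants, 32 electrodes and 250 Hz epochs, with
permutation counts between 99 and 999 and 500–1000 bootstrap replicates,
sizes at which every stage's behavior is already resolvable; all of these
scale up by configuration.

## Known limitations

* The behavioral simulator treats acquisition as binary per symbol; there
  is no forgetting, confusion between similar symbols, or response-time
  model.
* The planted signal is strictly linear in the word vector, the best case
  for a linear decoder; real representations need not be.
* Bootstrap CIs are normal-theory; with few symbols the accuracy
  distribution can be skewed.
* The electrode-group searchlight localizes only as finely as the montage
  neighborhoods; it does not attempt source localization.
* Group-level 2 vs. 2 accuracy saturates well below 1 even in noiseless
  constructions: a group of $k$ electrodes spans at most a $k$-dimensional
  slice of the $v$-dimensional embedding, and with only tens of training
  symbols the leave-two-out ridge partly overfits the orthogonal component
  of the targets. Searchlight power therefore depends jointly on the
  embedding dimension, the group size and the symbol count — the package's
  own localization checks use a lower-dimensional embedding for exactly
  this reason.
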