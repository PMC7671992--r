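---
title: "Language-based prediction of FESS navigation steps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Language-based prediction of FESS navigation steps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fessnav)
```

## The problem

Functional endoscopic sinus surgery (FESS) restores ventilation and drainage
of the paranasal sinuses. The endoscope repeatedly passes a small set of
salient anatomical landmarks — the middle nasal concha and meatus, the
uncinate process, the ethmoidal bulla, the maxillary sinus orifice, the
spheno-ethmoidal recess — and a wayfinding assistant would like to predict
which landmark configuration the surgeon will see next. `fessnav` treats
this as a language problem: each timed endoscope state is verbalized as a
fixed-slot *navigation sentence*,

```
step <count> <cavity> <group> <landmark_1> ... <landmark_k> <direction>
```

with `k` between 1 and 3, giving 6–8 tokens per sentence. Consecutive
sentences are paired, and next-step prediction becomes next-sentence
translation.

## The state model and the direction rule

A navigation state carries a step count, main cavity, landmark group, a
landmark combination (the set of landmarks simultaneously visible) and a
movement direction. Directions are not annotated; they are derived from a
*spatial ontology* that ranks landmarks by anatomical depth along the
anterior-to-posterior approach. Moving to a combination whose deepest member
ranks deeper than the previous one is `inwards`, shallower is `outwards`,
equal is `dwell`; the first state of a workflow is a `dwell`.

The depth ordering itself is configuration, not hard-coded anatomy: the
built-in table ranks `out_of_patient` 0, concha 1, meatus 2, uncinate process
and ethmoidal bulla 3 (they face each other across the infundibulum, so
passing between them is neither in nor out), maxillary orifice 4 and
spheno-ethmoidal recess 5. Published descriptions of this representation
state only the "spatially follows / precedes" relation, not the full table,
so these ranks are an informed default and any table can be supplied through
`spatial_ontology()`. The representative rank of a combination is the
*maximum* over its members — the deepest visible landmark is what marks
progress.

```{r}
ont <- default_ontology()
infer_direction("middle_nasal_concha", "ethmoidal_bulla", ont)
infer_direction("ethmoidal_bulla", "middle_nasal_concha", ont)
```

## The synthetic workflow generator

The clinical recordings behind the published FESS study (22 procedures, 3850
annotated activities) were never released. The package therefore ships a
simulator whose defaults reproduce the *published summary statistics* of
that data, so that every downstream stage is testable:

* a first-order Markov chain over 12 landmark-combination states (six
  singletons, six pairs), with a zero-diagonal transition matrix calibrated
  by iterative reweighting (`calibrate_transitions()`) so that the chain's
  stationary distribution gives each landmark exactly its published
  accumulated observation fraction — concha 0.51, meatus 0.27, maxillary
  orifice 0.18, out-of-patient 0.13, uncinate 0.06, bulla 0.04, recess 0.01;
* workflow lengths from a truncated normal with mean 167 states (the
  published mean step count) and sd 60, truncated at 20;
* log-normal dwell times with median ~9 s (published mean landmark
  visibility ≈ 9.4 s); durations decorate states but do not enter sentences;
* one master seed; per-workflow seeds derived by fixed offset, so corpora
  are reproducible and single workflows can be regenerated in isolation.

What the simulator deliberately does *not* emulate: the published tables
describe only marginal statistics, so the simulated transition *structure*
(which landmark follows which) is an artifact of the calibration, not of
surgical practice; the split between "individual" and "in combination"
observations is not matched (the published individual/in-combination counts
are not jointly consistent with 3850 total states, so only the accumulated
fractions are targeted); and there is no patient anatomy, instrument events
or annotation noise. Passing calibration tests therefore shows the pipeline
handles data with realistic marginals and imbalance — not that models trained
on it would transfer to clinical recordings.

```{r, eval = FALSE}
corp <- simulate_corpus(default_sim_config(n_workflows = 22, seed = 1))
corpus_statistics(corp$workflows)$per_landmark
```

## Models

Four predictors sit behind a common next-step contract.

**GRU encoder-decoder (S2S).** Two GRU layers (reference width 512,
embedding 256 — the embedding width is not part of the published description
and 256 is this package's default) encode the source sentence; their final
hidden states initialize an equally deep decoder trained with cross-entropy.

**Transformer (TRF).** Shared embeddings scaled by sqrt(d_model) plus
sinusoidal positional encoding; post-norm residual blocks of multi-head
scaled dot-product attention, `Attn(Q,K,V) = softmax(QK^T / sqrt(d_K)) V`,
and position-wise feed-forward layers. Two presets: `reference`
(512/8/6/2048/0.1, the standard machine-translation configuration the
original study cites) and `desk` (64/4/2/256/0.1), which trains in seconds per epoch on one
CPU and is what the tests use. Trained with the label-smoothed KL loss
(smoothing 0.1): the target distribution puts 0.9 on the true token and
spreads 0.1 over the remaining non-padding vocabulary, and
`D_KL = H(P_truth, P_pred) − H(P_truth)`.

**LSTM class baseline.** Landmark combinations are enumerated as integer
classes; a 2-layer LSTM (reference width 200) reads a window of the last 6
class ids (left-padded with a reserved padding class that is excluded from
the output layer, so it can never be predicted) and classifies the next one.

**Gaussian HMM baseline.** 12 hidden states with 1-D Gaussian emissions over
the class encoding, fitted by Baum-Welch (at most 500 iterations,
log-likelihood tolerance 0.01). Encoding a categorical class id as its
integer position on the real line is the simplest faithful reading of
"Gaussian emissions over classes"; it is isolated in one place and imposes a
spurious metric on classes — a known limitation of that baseline, not of this
implementation. Prediction filters the hidden posterior, advances it one
step and emits the class maximizing the predictive density (ties to the
lowest id).

The package carries its own small reverse-mode autodiff engine over dense
matrices (a tape of vector-Jacobian products) on which all three neural
models are built, so they run anywhere base R runs, with no deep-learning
framework dependency. Every model's gradients are verified against finite differences in
the test suite; batches are processed as per-example forward passes whose
scalar losses are averaged, which is mathematically identical to padded
batching.

## Training

Adam with betas (0.9, 0.98) and eps 1e-9, batch size 20 reshuffled each
epoch, 10 epochs for S2S/LSTM (cross-entropy) and 40 for the transformer
(smoothed KL). The learning rate follows the warm-up schedule

```
lr = d_model^(-0.5) * min(step^(-0.5), step * n_warmup^(-1.5)),  n_warmup = 200.
```

Published descriptions sometimes print the leading factor as sqrt(d_model);
that form yields learning rates above 1 for realistic widths and diverges,
so the inverse-root form is the default and the literal form is kept behind
`lr_mode = "literal"` for comparison. Source sentences can be
augmented with 1 random swap and 0.1 deletion probability (the cited
easy-data-augmentation defaults); the step keyword and numerals are exempt
from deletion so sources stay alignable. Evaluation uses leave-one-out
cross-validation over workflows, with the left-in pairs shuffled and split
9:1 into train/validation (`floor(n/10)` validation pairs).

## Decoding with recurrence decay

Sentences are generated by beam search (beam 4 — the vocabulary is small)
over `next_word_distribution()`. FESS sentences repeat tokens across
consecutive steps, and an unpenalized decoder tends to lock onto the
over-represented landmarks. Each candidate token `y` is therefore rescored
with `d(y) = 1 − exp(−r_y / r_mean(y))`, where `r_y` counts how many
consecutive preceding sentences contained `y` (0 at first appearance, reset
on absence — maintained across a `rollout()`), and `r_mean(y)` is the mean
number of subsequent recurrences over maximal runs in the training corpus,
floored at 1. The template's slots draw from disjoint token sets, so
tracking sentence containment is equivalent to the slot-wise tracking the
statistic is defined over.

The published score form `s = log p · (1 − d)` *raises* the score of a
recurring token whenever `log p < 0`, contradicting the stated intent of
penalizing recurrence; the package's default therefore applies the decay to
the probability itself, `s = log p + log(1 − d)`, and retains the literal
form behind `score_mode = "literal"`. Neither is presented as the
original authors' certified intent. Hypothesis ties are broken by shorter
hypothesis, then lexicographic token order; decoding stops on the
end-of-sentence token or after 10 tokens (the best partial hypothesis is
returned flagged if nothing completed).

## Metrics

`bleu1()` (clipped unigram precision times brevity penalty), `rougeL_recall()`
(LCS over reference length), their harmonic mean `f1_br()` — the study's
"approximated translation accuracy" — and the word-level `jaccard_distance()`.
Slot-level precision/recall macro-averages per-value scores within each of
the five template slots (the landmark combination compared as a set); the
landmark-level table scores each landmark's occurrence (alone or in
combination) at aligned steps. Overall rows are unweighted macro means —
this choice is verified by arithmetic: the macro mean of the published HMM
per-landmark cells reproduces the printed 0.30/0.27 overall. A landmark
never predicted *and* never present is excluded from the macro mean; a side
that is undefined while the other is defined counts as 0. Reports round
half-up to 2 decimals; full precision is kept internally, since several
published overall cells recompute to ±0.01 of their printed values,
indicating rounding from unrounded internals.

## Numerical choices and degenerate inputs

* Vocabulary indices reserve PAD=0, SOS=1, EOS=2, UNK=3; step numerals are
  covered up to a cap of 999 (published workflow maxima are below that) and
  map to UNK beyond it.
* Landmark tokens are emitted in depth-rank order (ties alphabetical), so
  every state has one canonical surface form; any order is accepted on
  decode.
* Emission variances in the HMM are floored at 1e-3; quantile-spread means
  break the uniform-initialization symmetry deterministically.
* `augment()` never deletes below 2 tokens; length-1 sentences pass through.
* An empty record list, an empty training set, a zero-length observed
  sequence and a non-positive `d_K` are errors; validation problems in
  workflows are *returned* by `validate_workflow()` rather than raised.

## Problem sizes used in the tests

The test suite trains the desk transformer (64/4/2/256) for 40 epochs on a
deterministic 8-sentence cyclic corpus (~10 s), fits HMMs on 5000-6000-step
sequences, and simulates 22 workflows of ~167 states for the calibration
checks; these sizes were chosen as the smallest that make the respective
properties (overfitting to ≥0.95 word accuracy, transition recovery within
0.1, marginals within ±0.05) clearly observable.

## Known limitations

The reference-scale transformer preset (512/8/6/2048) is configuration-complete
but not something you want to train in pure R; the autodiff engine is
desk-scale by design. The sentence surface form is this package's own
deterministic template — the original study does not print its exact
wording, only the 6-10 token band. Clinical accuracy figures from the
published study (translation accuracy 0.83, landmark accuracy 0.53 for the
transformer) depend on the unreleased recordings and are not reproducible
here; the package reproduces their arithmetic relations and the study's
methodology, not the headline numbers.
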