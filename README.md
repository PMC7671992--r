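# fessnav

Language-based representation and prediction of endoscopic navigation steps
in functional endoscopic sinus surgery (FESS).

During a FESS the endoscope repeatedly passes a small set of salient
anatomical landmarks (middle nasal concha, middle nasal meatus, uncinate
process, ethmoidal bulla, maxillary sinus orifice, spheno-ethmoidal recess).
`fessnav` is for surgical-data-science researchers who want to study
*wayfinding assistance*: it turns timed landmark annotations into structured
navigation workflows, verbalizes each endoscope state as a fixed-slot
navigation sentence

```
step <count> <cavity> <group> <landmark_1> ... <landmark_k> <direction>
```

and treats next-step prediction as next-sentence translation. Movement
directions are derived from a depth-ranked spatial ontology (`inwards` when
the current combination "spatially follows" the previous one, `outwards` for
the converse, `dwell` for equal depth).

The package provides:

* **Parsing and corpora** — annotation readers (CSV/JSON), workflow
  derivation with merge-on-identical-combination, sentence/pair corpus
  writers, vocabularies with PAD/SOS/EOS/UNK, class-id sequences.
* **Models** — a GRU encoder-decoder and a transformer (multi-head scaled
  dot-product attention, `Attn(Q,K,V) = softmax(QK^T/sqrt(d_K))V`, sinusoidal
  positional encoding, label-smoothed KL loss), plus LSTM and
  Gaussian-emission HMM class baselines (Baum-Welch, greedy filtering
  prediction). The neural models run on a small built-in reverse-mode
  autodiff engine and train on one CPU at the `desk` preset (64/4/2/256).
* **Training** — Adam (0.9, 0.98, 1e-9) with the 200-step warm-up schedule
  `lr = d_model^(-0.5) min(step^(-0.5), step n_warmup^(-1.5))`, random
  swap/deletion source augmentation, leave-one-out cross-validation over
  workflows with a 9:1 train/validation split of the left-in pairs.
* **Decoding** — beam search (beam 4) with exponential-decay recurrence
  rescoring `d(y) = 1 − exp(−r_y / r_mean(y))`, greedy decoding, and
  multi-step rollout where each generated sentence seeds the next.
* **Evaluation** — BLEU-1, ROUGE-L recall, their harmonic mean `F1_BR`
  (an approximated translation accuracy), Jaccard distance, slot-level and
  landmark-level precision/recall tables, and corpus summary statistics.
* **Simulation** — a Markov workflow generator calibrated so its long-run
  landmark marginals match the published 22-procedure FESS annotation study
  (concha 0.51, meatus 0.27, maxillary orifice 0.18, out-of-patient 0.13,
  uncinate 0.06, bulla 0.04, recess 0.01; ~167 steps per workflow), since the
  clinical recordings themselves were never released.

## Worked example

```r
library(fessnav)

# simulate a small corpus of FESS-like workflows
corp <- simulate_corpus(default_sim_config(n_workflows = 4, seed = 11))
wfs <- corp$workflows
sentence_text(workflow_sentences(wfs[[1]])[[1]])
#> "step 1 nasal_cavity concha_group middle_nasal_concha dwell"

# train the desk-scale transformer on consecutive-sentence pairs
pairs <- corpus_pairs(wfs)
vocab <- build_vocabulary(unlist(lapply(wfs, workflow_sentences), recursive = FALSE))
model <- transformer_model(vocab, transformer_config("desk"), seed = 11)
fit <- train_model(model, pairs,
                   training_config(epochs = 10, loss = "kl_smoothed", seed = 11))

# predict the next navigation step with decay-rescored beam search
stats <- recurrence_stats(wfs)
res <- beam_search(fit$model, pairs[[1]]$source, beam_config(), stats)
sentence_text(res$sentence)

# evaluate against the true next sentences
report <- evaluate_sentence_predictions(
  predict_pairs(fit$model, pairs, beam_config(), stats),
  lapply(pairs, `[[`, "target"))
report
```

On this 4-workflow toy run (611 pairs, 10 short epochs) the report prints

```
BLEU-1 0.54  JD 0.57  ROUGE-L 0.54  F1_BR 0.54  (n=611)
slot overall P 0.35 R 0.24 F1 0.28 | landmark overall P 0.21 R 0.22 F1 0.22
```

BLEU-1 is the clipped unigram precision of the predicted sentences, ROUGE-L
recall the longest-common-subsequence coverage of the references, and F1_BR
their harmonic mean — the "approximated translation accuracy" used to score
sentence generation. The slot table in `report$slots` shows which sentence
parts (step count, sinus, landmark group, landmark combination, direction)
are predicted reliably, and `report$landmarks` scores each anatomical
landmark's occurrences.

A command-line interface wraps the same functions:

```sh
fessnav simulate --n-workflows 4 --seed 11 --out data/
fessnav train --data data/ --model transformer --epochs 10 --out model.rds
fessnav predict --model model.rds --sentence "step 1 nasal_cavity meatus_group middle_nasal_meatus dwell" --horizon 3
fessnav evaluate --model model.rds --data data/ --out report.json
```

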