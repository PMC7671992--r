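Package: fessnav
Title: Language-Based Prediction of Endoscopic Navigation Steps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for representing functional endoscopic sinus surgery (FESS)
    navigation workflows as fixed-slot natural-language sentences and for
    predicting the next navigation step. Timed landmark annotations are parsed
    into navigation states with ontology-derived movement directions,
    verbalized into sentence corpora, and fed to sequence-to-sequence
    predictors (a GRU encoder-decoder and a transformer, trained with a small
    built-in reverse-mode autodiff engine) alongside LSTM and Gaussian-emission
    hidden Markov model baselines. Decoding uses a beam search with
    exponential-decay recurrence rescoring; evaluation covers BLEU-1, ROUGE-L
    recall, their harmonic mean, Jaccard distance, and slot- and landmark-level
    precision/recall. A calibrated Markov simulator generates FESS-like
    workflows so the whole pipeline is testable without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
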