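# End-to-end orchestration shared by the command-line interface and the
# cross-validation driver.

# Landmark combination of a template sentence, or character(0) if malformed.
sentence_combination <- function(sentence) {
  slots <- sentence_slots(sentence)
  if (is.null(slots)) return(character(0))
  strsplit(slots$landmark_combination, "+", fixed = TRUE)[[1]]
}

#' Predict the target sentence for every pair
#'
#' Runs the decay-rescored beam search once per source sentence.
#'
#' @param model A sentence model.
#' @param pairs List of `fess_pair`.
#' @param config A `fess_beam_config`.
#' @param stats Recurrence statistics from the training corpus.
#' @return List of predicted `fess_sentence`.
#' @export
predict_pairs <- function(model, pairs, config = beam_config(), stats = NULL) {
  lapply(pairs, function(p) {
    beam_search(model, p$source, config, stats)$sentence
  })
}

#' Full evaluation report for sentence-level predictions
#'
#' Combines the translation metrics (BLEU-1, ROUGE-L recall, F1, Jaccard
#' distance), the slot-level precision/recall table and the landmark-level
#' precision/recall table into one report.
#'
#' @param predicted,target Parallel lists of sentences.
#' @return List of class `fess_report` with components `translation`,
#'   `slots`, `landmarks`.
#' @export
evaluate_sentence_predictions <- function(predicted, target) {
  pred_combos <- lapply(predicted, sentence_combination)
  targ_combos <- lapply(target, sentence_combination)
  structure(list(
    translation = translation_metrics(predicted, target),
    slots = slot_precision_recall(list(predicted = predicted, target = target)),
    landmarks = landmark_precision_recall(pred_combos, targ_combos)
  ), class = "fess_report")
}

#' @export
print.fess_report <- function(x, ...) {
  print(x$translation)
  cat(sprintf("slot overall P %.2f R %.2f F1 %.2f | landmark overall P %.2f R %.2f F1 %.2f\n",
              x$slots$overall["precision"], x$slots$overall["recall"], x$slots$f1,
              x$landmarks$overall["precision"], x$landmarks$overall["recall"],
              x$landmarks$f1))
  invisible(x)
}

report_to_list <- function(report) {
  list(
    translation = report$translation[c("bleu1", "jaccard_distance",
                                       "rougeL_recall", "f1_br", "n")],
    slots = list(per_slot = report$slots$per_slot,
                 overall = as.list(report$slots$overall),
                 f1 = report$slots$f1,
                 n_malformed = report$slots$n_malformed),
    landmarks = list(per_landmark = report$landmarks$per_landmark,
                     overall = as.list(report$landmarks$overall),
                     f1 = report$landmarks$f1)
  )
}

#' Write an evaluation report as JSON (and the tables as CSV)
#'
#' @param report A `fess_report`.
#' @param path JSON output path; sibling `<path>.slots.csv` and
#'   `<path>.landmarks.csv` files hold the tables.
#' @param seed Seed recorded in the report header.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, seed = NULL) {
  obj <- c(list(seed = seed), report_to_list(report))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  utils::write.csv(report$slots$per_slot,
                   paste0(tools::file_path_sans_ext(path), ".slots.csv"),
                   row.names = FALSE)
  utils::write.csv(report$landmarks$per_landmark,
                   paste0(tools::file_path_sans_ext(path), ".landmarks.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Leave-one-out cross-validation of a sentence model
#'
#' For each fold: train on the left-in pairs, roll the beam search over the
#' held-out workflow's pairs, and evaluate. This is the full study protocol;
#' run it with small simulator and model settings unless you have hours.
#'
#' @param workflows Corpus of `fess_workflow`.
#' @param model_factory Function `(vocab, seed)` returning a fresh model.
#' @param train_config A `fess_train_config`.
#' @param beam_cfg A `fess_beam_config`.
#' @param seed Master seed.
#' @param max_folds Optionally evaluate only the first folds.
#' @return List with `per_fold` reports and `pooled` report.
#' @export
crossval_sentences <- function(workflows, model_factory,
                               train_config = training_config(),
                               beam_cfg = beam_config(), seed = 1L,
                               max_folds = NULL) {
  folds <- loocv_folds(workflows, seed)
  if (!is.null(max_folds)) folds <- utils::head(folds, max_folds)
  vocab <- build_vocabulary(unlist(lapply(workflows, workflow_sentences),
                                   recursive = FALSE))
  per_fold <- list()
  all_pred <- list()
  all_targ <- list()
  for (i in seq_along(folds)) {
    fold <- folds[[i]]
    model <- model_factory(vocab, seed + i)
    fit <- train_model(model, fold$train, train_config)
    stats <- recurrence_stats(list(lapply(fold$train, `[[`, "source")))
    preds <- predict_pairs(fit$model, fold$test, beam_cfg, stats)
    targs <- lapply(fold$test, `[[`, "target")
    per_fold[[fold$test_workflow_id]] <- evaluate_sentence_predictions(preds, targs)
    all_pred <- c(all_pred, preds)
    all_targ <- c(all_targ, targs)
  }
  list(per_fold = per_fold,
       pooled = evaluate_sentence_predictions(all_pred, all_targ))
}
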