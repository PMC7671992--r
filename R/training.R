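#' Training configuration
#'
#' Batch size 20, cross-entropy over 10 epochs for the GRU encoder-decoder
#' and the LSTM baseline, label-smoothed (0.1) KL loss over 40 epochs for the
#' transformer, Adam with betas (0.9, 0.98), eps 1e-9 and a 200-step warm-up
#' schedule; batches are reassembled and reshuffled every epoch.
#'
#' @param epochs Training epochs.
#' @param batch_size Examples per batch (default 20).
#' @param label_smoothing Smoothing factor for the KL loss (default 0.1).
#' @param loss `"cross_entropy"` or `"kl_smoothed"`.
#' @param augment Logical: apply random swap / random deletion augmentation
#'   to source sentences.
#' @param n_swaps,p_delete Augmentation strengths (defaults 1 swap, 0.1
#'   deletion probability).
#' @param n_warmup Warm-up steps of the learning-rate schedule.
#' @param lr_mode `"standard"` or `"literal"` (see [lr_at()]).
#' @param beta1,beta2,eps Adam parameters.
#' @param seed Seed for shuffling, augmentation and dropout.
#' @return A `fess_train_config`.
#' @export
training_config <- function(epochs = 10L, batch_size = 20L,
                            label_smoothing = 0.1,
                            loss = c("cross_entropy", "kl_smoothed"),
                            augment = FALSE, n_swaps = 1L, p_delete = 0.1,
                            n_warmup = 200L,
                            lr_mode = c("standard", "literal"),
                            beta1 = 0.9, beta2 = 0.98, eps = 1e-9, seed = 1L) {
  stopifnot(batch_size >= 1, label_smoothing >= 0, label_smoothing < 1,
            beta1 > 0, beta1 < 1, beta2 > 0, beta2 < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 label_smoothing = label_smoothing, loss = match.arg(loss),
                 augment = augment, n_swaps = as.integer(n_swaps),
                 p_delete = p_delete, n_warmup = as.integer(n_warmup),
                 lr_mode = match.arg(lr_mode), beta1 = beta1, beta2 = beta2,
                 eps = eps, seed = as.integer(seed)),
            class = "fess_train_config")
}

#' Read a training configuration from a YAML file
#'
#' The file holds the fields of [training_config()] (any subset; the rest
#' keep their defaults).
#'
#' @param path YAML file path.
#' @return A `fess_train_config`.
#' @export
read_training_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(training_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown training config field(s): ",
                            paste(unknown, collapse = ", "))
  do.call(training_config, vals)
}

#' Random swap / random deletion sentence augmentation
#'
#' `n_swaps` random position swaps followed by independent per-token deletion
#' with probability `p_delete`. A sentence is never reduced below 2 tokens,
#' length-1 sentences pass through unchanged, and the step-count slot (the
#' literal `step` keyword and numeral tokens) is exempt from deletion so that
#' augmented sources stay alignable with their targets. Applied to source
#' sentences only.
#'
#' @param sentence A `fess_sentence` or character token vector.
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @param p_delete Per-token deletion probability.
#' @param n_swaps Number of random swaps.
#' @return The augmented `fess_sentence`.
#' @export
augment <- function(sentence, seed = NULL, p_delete = 0.1, n_swaps = 1L) {
  tok <- as.character(sentence)
  if (length(tok) <= 1) return(as_sentence(tok))
  rng <- NULL
  if (!is.null(seed)) rng <- local_rng(seed)
  for (k in seq_len(n_swaps)) {
    ij <- sample.int(length(tok), 2)
    tok[ij] <- tok[rev(ij)]
  }
  if (p_delete > 0) {
    protected <- tok == "step" | grepl("^[0-9]+$", tok)
    drop <- !protected & stats::runif(length(tok)) < p_delete
    if (sum(!drop) < 2) drop <- rep(FALSE, length(tok))
    tok <- tok[!drop]
  }
  if (!is.null(seed)) restore_rng(rng)
  as_sentence(tok)
}

#' Leave-one-out cross-validation folds over workflows
#'
#' One fold per workflow: the fold's test set is that workflow's sentence
#' pairs, and the pairs of all remaining workflows are pooled, shuffled and
#' split 9:1 into training and validation sets (validation size =
#' `floor(n/10)`).
#'
#' @param workflows List of >= 2 `fess_workflow` objects.
#' @param seed Seed for the within-fold shuffles.
#' @return List of folds, each `list(test_workflow_id, train, val, test)`
#'   where the last three are lists of `fess_pair`.
#' @export
loocv_folds <- function(workflows, seed = 1L) {
  W <- length(workflows)
  if (W < 2) stop("leave-one-out cross-validation needs at least 2 workflows")
  # tag every pair with its source workflow: textually identical pairs can
  # occur in several workflows, so provenance is what defines the partition
  per_wf_pairs <- lapply(workflows, function(wf) {
    lapply(make_pairs(workflow_sentences(wf)), function(p) {
      p$workflow_id <- wf$workflow_id
      p
    })
  })
  rng <- local_rng(seed)
  folds <- vector("list", W)
  for (i in seq_len(W)) {
    left_in <- unlist(per_wf_pairs[-i], recursive = FALSE)
    perm <- sample.int(length(left_in))
    left_in <- left_in[perm]
    n_val <- floor(length(left_in) / 10)
    folds[[i]] <- list(
      test_workflow_id = workflows[[i]]$workflow_id,
      train = if (n_val > 0) left_in[-(seq_len(n_val))] else left_in,
      val = if (n_val > 0) left_in[seq_len(n_val)] else list(),
      test = per_wf_pairs[[i]]
    )
  }
  restore_rng(rng)
  folds
}

# Scalar loss node for one training example, dispatched on model type.
example_loss_node <- function(tape, L, model, ex, training, config) {
  if (inherits(model, "fess_lstm")) {
    lstm_example_loss(tape, L, model, ex$window, ex$target)
  } else {
    src <- ex$source
    if (training && config$augment) {
      src <- augment(src, p_delete = config$p_delete, n_swaps = config$n_swaps)
    }
    src_ids <- encode_sentence(src, model$vocab)
    tgt_ids <- encode_sentence(ex$target, model$vocab)
    smoothing <- if (config$loss == "kl_smoothed") config$label_smoothing else 0
    if (inherits(model, "fess_transformer")) {
      trf_pair_loss(tape, L, model, src_ids, tgt_ids, training, smoothing)
    } else {
      s2s_pair_loss(tape, L, model, src_ids, tgt_ids, training, smoothing)
    }
  }
}

#' Train a model
#'
#' Mini-batch Adam training with the warm-up learning-rate schedule. Batches
#' are reassembled and reshuffled at every epoch; all randomness (shuffling,
#' augmentation, dropout) flows from `config$seed`, so two runs with the same
#' seed produce identical models. With `epochs = 0` the model is returned
#' unchanged with an empty history.
#'
#' @param model A `fess_transformer`, `fess_s2s` or `fess_lstm`.
#' @param data For sentence models a list of `fess_pair`; for the LSTM a list
#'   of `list(window =, target =)` examples (see [class_windows()]).
#' @param config A `fess_train_config`.
#' @return List with the trained `model` and `history` (mean training loss
#'   per epoch).
#' @export
train_model <- function(model, data, config = training_config()) {
  if (!length(data)) stop("training data is empty")
  if (config$epochs == 0L) return(list(model = model, history = numeric(0)))
  d_for_lr <- if (inherits(model, "fess_lstm")) {
    model$config$hidden_units
  } else if (inherits(model, "fess_transformer")) {
    model$config$d_model
  } else {
    model$config$hidden_units
  }
  sched <- lr_schedule(d_for_lr, config$n_warmup, config$lr_mode)
  opt <- adam_init(model$params)
  step <- 0L
  history <- numeric(config$epochs)
  rng <- local_rng(config$seed)
  for (epoch in seq_len(config$epochs)) {
    perm <- sample.int(length(data))
    batches <- split(perm, ceiling(seq_along(perm) / config$batch_size))
    epoch_losses <- numeric(0)
    for (b in batches) {
      step <- step + 1L
      tape <- ad_tape()
      L <- make_leaves(tape, model$params)
      ids <- vapply(b, function(k) {
        example_loss_node(tape, L, model, data[[k]], TRUE, config)
      }, 0L)
      loss <- if (length(ids) > 1) ad_mean_scalars(tape, ids) else ids[[1]]
      grads <- ad_backward(tape, loss)
      upd <- adam_step(model$params, grads, opt, lr_at(step, sched),
                       config$beta1, config$beta2, config$eps)
      model$params <- upd$params
      opt <- upd$opt
      epoch_losses <- c(epoch_losses, ad_value(tape, loss)[1, 1])
    }
    history[epoch] <- mean(epoch_losses)
  }
  restore_rng(rng)
  list(model = model, history = history)
}

#' Mean evaluation loss of a model on held-out data
#'
#' Same loss as training (no dropout, no augmentation).
#'
#' @inheritParams train_model
#' @return Scalar mean loss.
#' @export
evaluate_loss <- function(model, data, config = training_config()) {
  if (!length(data)) stop("evaluation data is empty")
  tape <- ad_tape()
  L <- make_leaves(tape, model$params)
  ids <- vapply(data, function(ex) {
    example_loss_node(tape, L, model, ex, FALSE, config)
  }, 0L)
  mean(vapply(ids, function(i) ad_value(tape, i)[1, 1], 0))
}
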