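#' Per-token recurrence statistics from a training corpus
#'
#' Navigation sentences repeat tokens across consecutive steps (the same
#' landmark often stays visible for several states). For each token the mean
#' number of subsequent recurrences is estimated: within each workflow, a
#' maximal run of `L` consecutive sentences containing the token contributes
#' `L - 1` recurrences, and the per-token mean over runs is floored at 1.
#' Because the sentence template draws each slot from a disjoint token set,
#' tracking containment is equivalent to tracking slot-wise repetition.
#'
#' @param sentence_lists List of workflows' sentence lists (each a list of
#'   `fess_sentence`), or a list of `fess_workflow` objects.
#' @return A `fess_recurrence_stats`: named numeric vector of per-token mean
#'   run recurrences (>= 1), with a default of 1 for unseen tokens.
#' @export
recurrence_stats <- function(sentence_lists) {
  if (length(sentence_lists) && inherits(sentence_lists[[1]], "fess_workflow")) {
    sentence_lists <- lapply(sentence_lists, workflow_sentences)
  }
  runs <- list()  # token -> vector of (run length - 1)
  for (sents in sentence_lists) {
    open <- integer(0)  # token -> current run length
    open <- stats::setNames(integer(0), character(0))
    for (s in sents) {
      toks <- unique(as.character(s))
      ended <- setdiff(names(open), toks)
      for (tk in ended) {
        runs[[tk]] <- c(runs[[tk]], open[[tk]] - 1L)
      }
      open <- open[toks[toks %in% names(open)]]
      for (tk in toks) {
        open[tk] <- if (tk %in% names(open)) open[[tk]] + 1L else 1L
      }
    }
    for (tk in names(open)) runs[[tk]] <- c(runs[[tk]], open[[tk]] - 1L)
  }
  means <- vapply(runs, function(v) max(1, mean(v)), 0)
  structure(means, class = "fess_recurrence_stats")
}

# Mean recurrence for a token, defaulting to the floor of 1.
r_mean_of <- function(stats, token) {
  if (is.null(stats) || !token %in% names(stats)) 1 else unname(stats[[token]])
}

#' Exponential-decay recurrence penalty
#'
#' `d(y) = 1 - exp(-r_y / r_mean)`: grows from 0 (token not currently
#' recurring) towards 1 as the token's current recurrence count `r_y` exceeds
#' its mean training recurrence `r_mean`.
#'
#' @param r_y Current number of subsequent recurrences of the token (>= 0).
#' @param r_mean Mean training recurrences of the token (>= 1).
#' @return Penalty in \code{[0, 1)}, monotone increasing in `r_y`.
#' @export
decay_penalty <- function(r_y, r_mean) {
  if (any(r_y < 0)) stop("recurrence count r_y must be >= 0")
  stopifnot(all(r_mean >= 1))
  1 - exp(-(r_y / r_mean))
}

#' Rescore a candidate token's log-probability by the decay penalty
#'
#' Default `log_additive` mode: `s = log p + log(1 - d)`, i.e. the candidate
#' probability is multiplied by `1 - d`, so a larger penalty always lowers
#' the score (a fully decayed candidate, `d = 1`, is eliminated with score
#' `-Inf`). The `literal` mode computes `s = log p * (1 - d)` as
#' sometimes printed; note that for `log p < 0` that form raises the score of
#' recurring tokens and is kept only for comparison.
#'
#' @param log_prob Log-probability of the candidate (<= 0).
#' @param d Decay penalty from [decay_penalty()].
#' @param mode `"log_additive"` (default) or `"literal"`.
#' @return Rescored value.
#' @export
rescore <- function(log_prob, d, mode = c("log_additive", "literal")) {
  mode <- match.arg(mode)
  if (mode == "literal") return(log_prob * (1 - d))
  if (d >= 1) return(-Inf)
  log_prob + log(1 - d)
}

#' Decoding configuration for the decay-rescored beam search
#'
#' @param beam_size Number of hypotheses kept per step (default 4; the small
#'   navigation vocabulary does not need the 16-32 beams of general text
#'   translation).
#' @param decay Logical: apply recurrence-decay rescoring.
#' @param score_mode Passed to [rescore()].
#' @param max_len Maximum generated tokens per sentence (default 10).
#' @return A `fess_beam_config`.
#' @export
beam_config <- function(beam_size = 4L, decay = TRUE,
                        score_mode = c("log_additive", "literal"),
                        max_len = 10L) {
  stopifnot(beam_size >= 1)
  structure(list(beam_size = as.integer(beam_size), decay = isTRUE(decay),
                 score_mode = match.arg(score_mode),
                 max_len = as.integer(max_len)),
            class = "fess_beam_config")
}

# Order hypotheses: best score first; ties broken by shorter length, then
# lexicographically by token ids.
order_hypotheses <- function(hyps) {
  scores <- vapply(hyps, `[[`, 0, "score")
  lens <- vapply(hyps, function(h) length(h$ids), 0L)
  keys <- vapply(hyps, function(h) paste(sprintf("%06d", h$ids), collapse = ","), "")
  order(-scores, lens, keys)
}

#' Beam search with recurrence-decay rescoring
#'
#' Expands `beam_size` hypotheses one token at a time from the model's
#' [next_word_distribution()]. Each candidate token's log-probability is
#' rescored by the decay penalty computed from its current recurrence count
#' (how many consecutive preceding sentences contained it, tracked across a
#' [rollout()]) and its mean training recurrence. A hypothesis completes on
#' the end-of-sentence token or at `max_len` tokens; the best complete
#' hypothesis is returned (ties: shorter first, then lexicographic token
#' order). If no hypothesis completes, the best partial one is returned with
#' `complete = FALSE`.
#'
#' @param model Any model implementing [next_word_distribution()].
#' @param src_ids Encoded source sentence (see [encode_sentence()]), or a
#'   `fess_sentence` when the model carries a vocabulary.
#' @param config A `fess_beam_config`.
#' @param stats Optional `fess_recurrence_stats` (required when
#'   `config$decay`).
#' @param counts Named numeric vector of current per-token recurrence counts
#'   (empty for a standalone call; maintained by [rollout()]).
#' @param eos_id End-of-sentence token index (0-based; default the
#'   vocabulary's EOS).
#' @return List with `ids` (generated 0-based token indices, without EOS),
#'   `sentence` (a `fess_sentence` if the model has a vocabulary, else NULL),
#'   `score`, `log_prob`, `complete`, and `beam` (the final hypothesis set).
#' @export
beam_search <- function(model, src_ids, config = beam_config(), stats = NULL,
                        counts = numeric(0), eos_id = EOS_IDX) {
  vocab <- model$vocab
  if (inherits(src_ids, "fess_sentence") || is.character(src_ids)) {
    if (is.null(vocab)) stop("source must be pre-encoded for models without a vocabulary")
    src_ids <- encode_sentence(src_ids, vocab)
  }
  if (config$decay && is.null(stats)) {
    stop("decay rescoring needs recurrence statistics")
  }
  hyps <- list(list(ids = integer(0), log_prob = 0, score = 0, complete = FALSE))
  completed <- list()
  for (step in seq_len(config$max_len)) {
    cand <- list()
    for (h in hyps) {
      p <- next_word_distribution(model, src_ids, h$ids)
      lp <- log(p)
      inc <- lp
      if (config$decay) {
        # vectorized decay rescoring over the whole vocabulary
        nms <- if (!is.null(vocab)) vocab$tokens else as.character(seq_along(p) - 1L)
        r_y <- rep(0, length(p))
        hit <- match(nms, names(counts))
        r_y[!is.na(hit)] <- counts[hit[!is.na(hit)]]
        r_mean <- rep(1, length(p))
        sm <- match(nms, names(stats))
        r_mean[!is.na(sm)] <- unclass(stats)[sm[!is.na(sm)]]
        d <- 1 - exp(-(r_y / r_mean))
        inc <- if (config$score_mode == "literal") lp * (1 - d) else {
          lp + log(1 - d)
        }
      }
      # only the top beam_size expansions of a hypothesis can survive the
      # global pruning; ties prefer the lower token id (lexicographic rule)
      ok <- which(is.finite(inc))
      if (!length(ok)) next
      top <- ok[order(-inc[ok], ok)]
      top <- utils::head(top, config$beam_size)
      for (j in top) {
        tok <- j - 1L  # 0-based token index
        cand[[length(cand) + 1]] <- list(
          ids = c(h$ids, tok),
          log_prob = h$log_prob + lp[j],
          score = h$score + inc[j],
          complete = tok == eos_id
        )
      }
    }
    if (!length(cand)) break
    cand <- cand[order_hypotheses(cand)]
    keep <- utils::head(cand, config$beam_size)
    newly_done <- Filter(function(h) h$complete, keep)
    completed <- c(completed, newly_done)
    hyps <- Filter(function(h) !h$complete, keep)
    if (!length(hyps)) break
  }
  pool_complete <- length(completed) > 0
  pool <- if (pool_complete) completed else hyps
  best <- pool[[order_hypotheses(pool)[1]]]
  out_ids <- best$ids
  if (best$complete) out_ids <- out_ids[-length(out_ids)]  # strip EOS
  sentence <- if (!is.null(vocab)) decode_indices(out_ids, vocab) else NULL
  list(ids = out_ids, sentence = sentence, score = best$score,
       log_prob = best$log_prob, complete = pool_complete,
       beam = c(completed, hyps))
}

#' Greedy decoding
#'
#' Equivalent to [beam_search()] with beam size 1 and decay off.
#'
#' @inheritParams beam_search
#' @param max_len Maximum generated tokens.
#' @return Same structure as [beam_search()].
#' @export
greedy_decode <- function(model, src_ids, max_len = 10L, eos_id = EOS_IDX) {
  beam_search(model, src_ids, beam_config(beam_size = 1L, decay = FALSE,
                                          max_len = max_len), eos_id = eos_id)
}

#' Multi-step sentence rollout
#'
#' Autoregressive prediction across sentences: the sentence generated at step
#' t becomes the source at step t + 1. Per-token recurrence counts are
#' maintained across the series: a token's count increases by 1 for every
#' consecutive generated (or seed) sentence containing it and resets to 0
#' when it is absent, so the decay penalty builds up for tokens that persist
#' past their mean training run length.
#'
#' @param model A sentence model.
#' @param seed_sentence The current (observed) navigation sentence.
#' @param horizon Number of future sentences to predict (>= 1).
#' @param config A `fess_beam_config`.
#' @param stats `fess_recurrence_stats` from the training corpus.
#' @return List with `sentences` (list of predicted `fess_sentence`) and
#'   `results` (the per-step [beam_search()] returns).
#' @export
rollout <- function(model, seed_sentence, horizon, config = beam_config(),
                    stats = NULL) {
  stopifnot(horizon >= 1)
  counts <- numeric(0)
  # a token's first appearance is not yet a recurrence (r_y = 0); every
  # consecutive sentence it persists in adds one; absence resets it
  update_counts <- function(counts, sentence) {
    toks <- unique(as.character(sentence))
    prev <- names(counts)
    kept <- counts[prev %in% toks]
    for (tk in toks) {
      kept[tk] <- if (tk %in% prev) counts[[tk]] + 1 else 0
    }
    kept
  }
  counts <- update_counts(counts, seed_sentence)
  current <- seed_sentence
  sentences <- vector("list", horizon)
  results <- vector("list", horizon)
  for (t in seq_len(horizon)) {
    res <- beam_search(model, current, config, stats, counts)
    results[[t]] <- res
    sentences[[t]] <- res$sentence
    counts <- update_counts(counts, res$sentence)
    current <- res$sentence
  }
  list(sentences = sentences, results = results)
}
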