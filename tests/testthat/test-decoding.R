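test_that("decay penalty follows its closed form", {
  expect_equal(decay_penalty(0, 1), 0)          # no recurrence, no penalty
  expect_equal(decay_penalty(1, 1), 1 - exp(-1))
  expect_equal(decay_penalty(3, 3), 1 - exp(-1))
  expect_equal(decay_penalty(1e6, 1), 1)        # limit
  r <- 0:20
  expect_true(all(diff(decay_penalty(r, 2.5)) > 0))  # monotone in r_y
  expect_true(all(decay_penalty(r, 2.5) >= 0 & decay_penalty(r, 2.5) < 1))
  expect_error(decay_penalty(-1, 1), "r_y")
  # pure function: same inputs, same outputs
  expect_identical(decay_penalty(2, 1.5), decay_penalty(2, 1.5))
})

test_that("rescoring degrades scores with the penalty", {
  expect_equal(rescore(-1.5, 0, "log_additive"), -1.5)
  expect_equal(rescore(-1.5, 0, "literal"), -1.5)
  # d = 1 - e^(-1): log-additive score drops by exactly 1
  expect_equal(rescore(-1, 1 - exp(-1), "log_additive"), -2)
  expect_equal(rescore(-1, 1, "log_additive"), -Inf)
  d <- seq(0, 0.99, by = 0.01)
  s <- vapply(d, function(dd) rescore(-0.7, dd, "log_additive"), 0)
  expect_true(all(diff(s) < 0))  # larger penalty never raises the score
  # the literal product form instead raises it for negative log-probabilities
  expect_gt(rescore(-1, 0.5, "literal"), -1)
})

test_that("recurrence statistics count same-slot repetitions across sentences", {
  # concha persists 3 sentences (2 recurrences), then is absent, then 1 more
  combos <- list("middle_nasal_concha", "middle_nasal_concha",
                 "middle_nasal_concha", "out_of_patient", "middle_nasal_concha")
  # avoid record merging: build states directly
  ont <- default_ontology()
  sents <- list()
  prev <- NULL
  for (i in seq_along(combos)) {
    sents[[i]] <- state_to_sentence(navigation_state(
      i, combos[[i]], infer_direction(prev, combos[[i]], ont), i - 1, i, ont))
    prev <- combos[[i]]
  }
  stats <- recurrence_stats(list(sents))
  # runs of lengths 3 and 1 -> mean recurrences (2 + 0) / 2 = 1
  expect_equal(unname(stats[["middle_nasal_concha"]]), 1)
  # out_of_patient: single run of length 1 -> 0 recurrences, floored at 1
  expect_equal(unname(stats[["out_of_patient"]]), 1)
  # numerals never repeat across steps
  expect_equal(unname(stats[["1"]]), 1)
  expect_true(all(stats >= 1))
})

test_that("beam size 1 without decay is greedy argmax decoding", {
  # toy model: next-token distribution depends on the last generated token
  V <- 4
  set.seed(51)
  M <- matrix(runif((V + 1) * V), V + 1, V)
  M <- M / rowSums(M)
  fn <- function(prefix) {
    last <- if (length(prefix)) prefix[length(prefix)] + 2L else 1L
    M[last, ]
  }
  model <- toy_lm(fn)
  res <- beam_search(model, integer(0),
                     beam_config(beam_size = 1, decay = FALSE, max_len = 4),
                     eos_id = -1L)
  manual <- integer(0)
  for (t in 1:4) manual <- c(manual, which.max(fn(manual)) - 1L)
  expect_equal(res$ids, manual)
  expect_identical(res$ids,
                   greedy_decode(model, integer(0), max_len = 4, eos_id = -1L)$ids)
})

test_that("decay-off beam search equals exhaustive argmax on toy models", {
  set.seed(52)
  for (V in c(3, 4)) {
    for (L in c(3, 4)) {
      M <- matrix(runif((V + 1) * V) + 0.05, V + 1, V)
      M <- M / rowSums(M)
      fn <- function(prefix) {
        last <- if (length(prefix)) prefix[length(prefix)] + 2L else 1L
        M[last, ]
      }
      model <- toy_lm(fn)
      res <- beam_search(model, integer(0),
                         beam_config(beam_size = V^L, decay = FALSE, max_len = L),
                         eos_id = -1L)
      oracle <- exhaustive_argmax(fn, V, L)
      expect_equal(res$ids, oracle$ids)
      expect_equal(res$log_prob, oracle$log_prob, tolerance = 1e-12)
    }
  }
})

test_that("decay rescoring switches away from an over-recurring token", {
  # two candidates: 'a' slightly likelier than 'b', then forced EOS
  fn <- function(prefix) {
    if (!length(prefix)) c(0, 0, 0, 0.6, 0.4) else c(0, 0, 1, 0, 0)
  }
  model <- toy_lm(fn)
  stats <- c("3" = 1, "4" = 1)        # both tokens rarely recur in training
  counts <- c("3" = 5, "4" = 0)       # but 'a' (id 3) has persisted 5 sentences
  with_decay <- beam_search(model, integer(0),
                            beam_config(beam_size = 4, decay = TRUE, max_len = 2),
                            stats = stats, counts = counts)
  without <- beam_search(model, integer(0),
                         beam_config(beam_size = 4, decay = FALSE, max_len = 2))
  expect_equal(without$ids, 3L)    # repeated token wins with decay off
  expect_equal(with_decay$ids, 4L) # alternative wins under decay
})

test_that("rollout feeds predictions forward and tracks recurrence counts", {
  # overfit a cyclic corpus, then roll 3 steps from the first sentence
  pairs <- cyclic_pairs()
  sents <- cyclic_sentences()
  vocab <- build_vocabulary(sents, max_step = 20)
  model <- transformer_model(vocab, transformer_config("desk"), seed = 7)
  fit <- train_model(model, pairs,
                     training_config(epochs = 40, batch_size = 8,
                                     loss = "kl_smoothed", seed = 7))
  stats <- recurrence_stats(list(sents))
  cfg <- beam_config(beam_size = 4, decay = TRUE)
  ro <- rollout(fit$model, sents[[1]], horizon = 3, config = cfg, stats = stats)
  expect_length(ro$sentences, 3)
  expect_identical(as.character(ro$sentences[[1]]), as.character(sents[[2]]))
  expect_identical(as.character(ro$sentences[[2]]), as.character(sents[[3]]))
  expect_identical(as.character(ro$sentences[[3]]), as.character(sents[[4]]))
  # horizon 1 is a single beam-search call
  one <- rollout(fit$model, sents[[1]], horizon = 1, config = cfg, stats = stats)
  # after only the seed sentence every token's recurrence count is still 0,
  # so a fresh beam-search call with empty counts must match
  direct <- beam_search(fit$model, sents[[1]], cfg, stats)
  expect_identical(as.character(one$sentences[[1]]), as.character(direct$sentence))
})
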