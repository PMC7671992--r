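test_that("scaled dot-product attention matches its closed forms", {
  # a single key/value pair gets weight 1: output is exactly V
  Q <- matrix(rnorm(6), 3, 2)
  K <- matrix(c(1, 0), 1, 2)
  V <- matrix(c(4, -2, 7), 1, 3)
  res <- scaled_dot_product_attention(Q, K, V)
  expect_equal(res$output, matrix(rep(V, each = 3), 3, 3))
  expect_true(all(res$weights == 1))

  # orthogonal queries (QK^T = 0) give uniform weights: column means of V
  Q0 <- matrix(c(0, 0), 1, 2)
  K2 <- matrix(rnorm(8), 4, 2)
  V2 <- matrix(rnorm(12), 4, 3)
  res0 <- scaled_dot_product_attention(Q0, K2, V2)
  expect_equal(res0$output[1, ], colMeans(V2))

  # 2x2 numeric case against hand-computed softmax weighting
  Q2 <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE)
  K3 <- matrix(c(2, 0, 0, 2), 2, 2, byrow = TRUE)
  V3 <- matrix(c(1, 2, 3, 4), 2, 2, byrow = TRUE)
  res2 <- scaled_dot_product_attention(Q2, K3, V3, d_K = 2)
  z <- 2 / sqrt(2)
  w11 <- exp(z) / (exp(z) + exp(0))
  expect_equal(res2$weights[1, 1], w11, tolerance = 1e-12)
  expect_equal(res2$output[1, 1], w11 * 1 + (1 - w11) * 3, tolerance = 1e-12)

  # weight rows always normalize
  for (i in 1:5) {
    res <- scaled_dot_product_attention(matrix(rnorm(8), 2, 4),
                                        matrix(rnorm(12), 3, 4),
                                        matrix(rnorm(6), 3, 2))
    expect_equal(rowSums(res$weights), c(1, 1))
  }
  expect_error(scaled_dot_product_attention(Q2, K3, V3, d_K = 0), "positive")
})

test_that("next-word distributions are normalized and deterministic", {
  sents <- cyclic_sentences()
  vocab <- build_vocabulary(sents, max_step = 20)
  src <- encode_sentence(sents[[1]], vocab)
  trf <- transformer_model(vocab, transformer_config("custom", d_model = 16,
                                                     n_heads = 2, n_layers = 1,
                                                     d_ff = 32), seed = 2)
  s2s <- s2s_model(vocab, s2s_config(hidden_units = 12, embedding_dim = 8), seed = 2)
  for (model in list(trf, s2s)) {
    p1 <- next_word_distribution(model, src)
    p2 <- next_word_distribution(model, src)
    expect_equal(sum(p1), 1, tolerance = 1e-6)
    expect_true(all(p1 >= 0))
    expect_identical(p1, p2)
    p3 <- next_word_distribution(model, src, prefix = c(4L, 5L))
    expect_equal(sum(p3), 1, tolerance = 1e-6)
    expect_error(next_word_distribution(model, src, prefix = rep(4L, 40)),
                 "maximum length")
  }
})

test_that("model gradients agree with finite differences", {
  ns <- asNamespace("fessnav")
  vocab <- build_vocabulary(list(as_sentence(c("alpha", "beta"))), max_step = 5)
  src <- encode_sentence(as_sentence(c("alpha", "beta")), vocab)
  tgt <- encode_sentence(as_sentence(c("beta", "alpha")), vocab)
  check <- function(model, loss_builder, param_names) {
    tape <- ns$ad_tape()
    L <- ns$make_leaves(tape, model$params)
    g <- ns$ad_backward(tape, loss_builder(tape, L, model))
    value_at <- function(params) {
      t2 <- ns$ad_tape()
      L2 <- ns$make_leaves(t2, params)
      ns$ad_value(t2, loss_builder(t2, L2, modifyList(model, list(params = params))))[1, 1]
    }
    base <- value_at(model$params)
    eps <- 1e-6
    set.seed(13)
    for (nm in param_names) {
      for (k in sample(length(model$params[[nm]]), 3)) {
        p2 <- model$params
        p2[[nm]][k] <- p2[[nm]][k] + eps
        num <- (value_at(p2) - base) / eps
        expect_equal(g[[nm]][k], num, tolerance = 5e-3)
      }
    }
  }
  trf <- transformer_model(vocab, transformer_config("custom", d_model = 8,
                                                     n_heads = 2, n_layers = 1,
                                                     d_ff = 16, dropout = 0), seed = 3)
  check(trf, function(tape, L, m) ns$trf_pair_loss(tape, L, m, src, tgt, FALSE, 0.1),
        c("emb", "enc1_Wq", "dec1_Wk2", "enc1_ln1_g", "Wout"))
  gru <- s2s_model(vocab, s2s_config(hidden_units = 6, embedding_dim = 5), seed = 4)
  check(gru, function(tape, L, m) ns$s2s_pair_loss(tape, L, m, src, tgt, FALSE, 0),
        c("emb", "enc1_Wz", "dec2_Uh", "Wout"))
  lstm <- lstm_model(4, lstm_config(hidden_units = 6, embedding_dim = 4,
                                    window_length = 4), seed = 5)
  check(lstm, function(tape, L, m) ns$lstm_example_loss(tape, L, m, c(0L, 1L, 2L), 3L),
        c("emb", "l1_Wi", "l2_Uf", "Wout"))
})

test_that("the LSTM class predictor is normalized and overfits a pattern", {
  # alternating ABAB...: the continuation is fully determined by the window
  seqs <- list(rep(c(0L, 1L), 30))
  model <- lstm_model(2, lstm_config(hidden_units = 16, embedding_dim = 8), seed = 6)
  p <- lstm_predict_next(model, c(0L, 1L))
  expect_length(p, 2)  # padding class is not in the output space
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # short warm-up: with 6 batches per epoch the default 200-step warm-up
  # would keep the learning rate negligible for this tiny corpus
  fit <- train_model(model, class_windows(seqs),
                     training_config(epochs = 25, batch_size = 10,
                                     n_warmup = 10L, seed = 6))
  expect_gt(lstm_predict_next(fit$model, c(1L, 0L))[2], 0.9)
  expect_gt(lstm_predict_next(fit$model, c(0L, 1L))[1], 0.9)
})

test_that("Baum-Welch log-likelihood is monotone and recovers a known chain", {
  # monotone EM trace on assorted inputs
  set.seed(21)
  inputs <- list(
    list(round(runif(40, 0, 3))),
    list(round(runif(25, 0, 5)), round(runif(35, 0, 5))),
    list(rep(c(0, 1, 2), 20))
  )
  for (x in inputs) {
    fit <- hmm_fit(x, hmm_config(n_hidden_states = 3, max_iter = 50))
    expect_true(all(diff(fit$loglik_trace) > -1e-6))
  }

  # one hidden state: transitions degenerate to [[1]]
  fit1 <- hmm_fit(list(c(0, 1, 0, 1)), hmm_config(n_hidden_states = 1))
  expect_equal(fit1$transition, matrix(1, 1, 1))

  # 2-state chain with separated Gaussian emissions, 5000 steps
  set.seed(22)
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  z <- integer(5000); z[1] <- 1L
  for (t in 2:5000) z[t] <- sample(1:2, 1, prob = A[z[t - 1], ])
  x <- rnorm(5000, c(0, 5)[z], 0.3)
  fit <- hmm_fit(list(x), hmm_config(n_hidden_states = 2))
  perm <- order(fit$mu)  # relabel by emission mean
  expect_lt(max(abs(fit$transition[perm, perm] - A)), 0.1)

  expect_error(hmm_fit(list(c(1))), "length >= 2")
})

test_that("greedy HMM prediction follows the filtered chain", {
  # near-deterministic alternating chain: after A predict B and vice versa
  set.seed(23)
  A <- matrix(c(0.01, 0.99, 0.99, 0.01), 2, 2, byrow = TRUE)
  z <- integer(2000); z[1] <- 1L
  for (t in 2:2000) z[t] <- sample(1:2, 1, prob = A[z[t - 1], ])
  obs <- as.numeric(z - 1L)
  fit <- hmm_fit(list(obs), hmm_config(n_hidden_states = 2))
  expect_equal(hmm_predict_next(fit, c(1, 0)), 1)
  expect_equal(hmm_predict_next(fit, c(0, 1)), 0)
  expect_error(hmm_predict_next(fit, numeric(0)), "non-empty")

  # absorbing state predicts itself
  fit_abs <- fit
  fit_abs$transition <- matrix(c(1, 0, 0, 1), 2, 2)
  fit_abs$mu <- c(0, 1); fit_abs$var <- c(0.01, 0.01)
  fit_abs$initial <- c(0.5, 0.5)
  fit_abs$classes <- c(0, 1)
  expect_equal(hmm_predict_next(fit_abs, c(1, 1)), 1)
  expect_equal(hmm_predict_next(fit_abs, c(0, 0)), 0)

  # exact ties resolve to the lowest class id
  fit_tie <- fit_abs
  fit_tie$transition <- matrix(0.5, 2, 2)
  expect_equal(hmm_predict_next(fit_tie, c(0)), 0)
})

test_that("HMM parameter recovery holds on simulator-generated classes", {
  # 3 well-separated states on the class line, known transition matrix
  set.seed(24)
  A <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.8, 0.1,
                0.05, 0.15, 0.8), 3, 3, byrow = TRUE)
  z <- integer(6000); z[1] <- 1L
  for (t in 2:6000) z[t] <- sample(1:3, 1, prob = A[z[t - 1], ])
  x <- rnorm(6000, c(0, 4, 8)[z], 0.4)
  fit <- hmm_fit(list(x), hmm_config(n_hidden_states = 3))
  perm <- order(fit$mu)
  expect_lt(max(abs(fit$transition[perm, perm] - A)), 0.1)
})
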