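#' GRU encoder-decoder configuration
#'
#' The reference configuration is two GRU layers with 512 units in both
#' encoder and decoder; the embedding width (not part of the published
#' description) defaults to 256. Tests and examples use far smaller widths.
#'
#' @param layers Number of GRU layers in encoder and decoder.
#' @param hidden_units GRU state width.
#' @param embedding_dim Token embedding width.
#' @param max_len Longest supported token sequence.
#' @return A `fess_s2s_config`.
#' @export
s2s_config <- function(layers = 2L, hidden_units = 512L, embedding_dim = 256L,
                       max_len = 12L) {
  stopifnot(layers >= 1, hidden_units >= 1, embedding_dim >= 1)
  structure(list(layers = as.integer(layers),
                 hidden_units = as.integer(hidden_units),
                 embedding_dim = as.integer(embedding_dim),
                 max_len = as.integer(max_len)),
            class = "fess_s2s_config")
}

gru_layer_params <- function(p, pre, d_in, d_h) {
  for (gate in c("z", "r", "h")) {
    p[[paste0(pre, "W", gate)]] <- glorot(d_in, d_h)
    p[[paste0(pre, "U", gate)]] <- glorot(d_h, d_h)
    p[[paste0(pre, "b", gate)]] <- zeros(1, d_h)
  }
  p
}

#' Construct an (untrained) GRU encoder-decoder model
#'
#' The standard sequence-to-sequence architecture: a stack of GRU layers
#' encodes the source sentence into its final hidden states, which initialize
#' an equally deep GRU decoder that emits one token at a time through a
#' linear projection and softmax. Trained with cross-entropy via
#' [train_model()].
#'
#' @param vocab A `fess_vocab`.
#' @param config A `fess_s2s_config`.
#' @param seed Seed for weight initialization.
#' @return A `fess_s2s` model object.
#' @export
s2s_model <- function(vocab, config = s2s_config(), seed = 1L) {
  V <- vocab_size(vocab)
  rng <- local_rng(seed)
  p <- list(emb = glorot(V, config$embedding_dim))
  for (side in c("enc", "dec")) {
    for (l in seq_len(config$layers)) {
      d_in <- if (l == 1) config$embedding_dim else config$hidden_units
      p <- gru_layer_params(p, sprintf("%s%d_", side, l), d_in,
                            config$hidden_units)
    }
  }
  p$Wout <- glorot(config$hidden_units, V)
  p$bout <- zeros(1, V)
  restore_rng(rng)
  structure(list(params = p, config = config, vocab = vocab),
            class = c("fess_s2s", "fess_model"))
}

# One GRU step: x (1 x d_in), h (1 x d_h) -> new h.
gru_step <- function(tape, L, pre, x, h) {
  z <- ad_sigmoid(tape, ad_add(tape, ad_add(tape,
         ad_matmul(tape, x, L[[paste0(pre, "Wz")]]),
         ad_matmul(tape, h, L[[paste0(pre, "Uz")]])), L[[paste0(pre, "bz")]]))
  r <- ad_sigmoid(tape, ad_add(tape, ad_add(tape,
         ad_matmul(tape, x, L[[paste0(pre, "Wr")]]),
         ad_matmul(tape, h, L[[paste0(pre, "Ur")]])), L[[paste0(pre, "br")]]))
  hh <- ad_tanh(tape, ad_add(tape, ad_add(tape,
          ad_matmul(tape, x, L[[paste0(pre, "Wh")]]),
          ad_matmul(tape, ad_mul(tape, r, h), L[[paste0(pre, "Uh")]])),
          L[[paste0(pre, "bh")]]))
  # h' = (1 - z) * h + z * hh  ==  h + z * (hh - h)
  ad_add(tape, h, ad_mul(tape, z, ad_sub(tape, hh, h)))
}

# Run a GRU stack over a sequence of ids; returns list(outputs=list of 1xH
# nodes per step from the top layer, hidden=list of final 1xH per layer).
gru_run <- function(tape, L, model, side, ids, h0 = NULL) {
  cfg <- model$config
  n <- length(ids)
  emb <- ad_rows(tape, L$emb, ids + 1L)
  hs <- h0
  if (is.null(hs)) {
    hs <- lapply(seq_len(cfg$layers), function(l) {
      ad_const(tape, zeros(1, cfg$hidden_units))
    })
  }
  outputs <- vector("list", n)
  for (t in seq_len(n)) {
    x <- ad_row(tape, emb, t)
    for (l in seq_len(cfg$layers)) {
      hs[[l]] <- gru_step(tape, L, sprintf("%s%d_", side, l), x, hs[[l]])
      x <- hs[[l]]
    }
    outputs[[t]] <- x
  }
  list(outputs = outputs, hidden = hs)
}

# Loss node for one pair; tgt_ids includes SOS ... EOS.
s2s_pair_loss <- function(tape, L, model, src_ids, tgt_ids, training,
                          smoothing) {
  enc <- gru_run(tape, L, model, "enc", src_ids)
  n <- length(tgt_ids)
  dec <- gru_run(tape, L, model, "dec", tgt_ids[-n], h0 = enc$hidden)
  out <- ad_rbind(tape, dec$outputs)
  logp <- ad_log_softmax_rows(tape, ad_add(tape, ad_matmul(tape, out, L$Wout),
                                           L$bout))
  ad_pick_nll(tape, logp, tgt_ids[-1] + 1L)
}

#' @export
next_word_distribution.fess_s2s <- function(model, src_ids,
                                            prefix = integer(0)) {
  if (length(prefix) + 1L > model$config$max_len) {
    stop("prefix longer than the model's maximum length")
  }
  tape <- ad_tape()
  L <- make_leaves(tape, model$params)
  enc <- gru_run(tape, L, model, "enc", src_ids)
  dec <- gru_run(tape, L, model, "dec", c(SOS_IDX, prefix), h0 = enc$hidden)
  out <- dec$outputs[[length(dec$outputs)]]
  logits <- ad_value(tape, ad_add(tape, ad_matmul(tape, out, L$Wout), L$bout))
  p <- exp(logits[1, ] - max(logits[1, ]))
  p / sum(p)
}

#' LSTM class-predictor configuration
#'
#' The reference baseline is a 2-layer LSTM with 200 units over windows of
#' the last `window_length = 6` landmark-combination class ids.
#'
#' @param layers LSTM layers.
#' @param hidden_units LSTM state width.
#' @param window_length Input window in steps (default 6).
#' @param embedding_dim Class embedding width.
#' @return A `fess_lstm_config`.
#' @export
lstm_config <- function(layers = 2L, hidden_units = 200L, window_length = 6L,
                        embedding_dim = 32L) {
  stopifnot(window_length >= 1)
  structure(list(layers = as.integer(layers),
                 hidden_units = as.integer(hidden_units),
                 window_length = as.integer(window_length),
                 embedding_dim = as.integer(embedding_dim)),
            class = "fess_lstm_config")
}

lstm_layer_params <- function(p, pre, d_in, d_h) {
  for (gate in c("i", "f", "o", "g")) {
    p[[paste0(pre, "W", gate)]] <- glorot(d_in, d_h)
    p[[paste0(pre, "U", gate)]] <- glorot(d_h, d_h)
    p[[paste0(pre, "b", gate)]] <- zeros(1, d_h)
  }
  p
}

#' Construct an (untrained) LSTM next-class predictor
#'
#' Predicts the landmark-combination class of the next navigation step from a
#' window of the previous 6 class ids. Windows shorter than the window length
#' are left-padded with a dedicated padding class whose embedding row is
#' reserved and which is never part of the output layer, so padding can never
#' be predicted.
#'
#' @param n_classes Number of landmark-combination classes.
#' @param config A `fess_lstm_config`.
#' @param seed Seed for weight initialization.
#' @return A `fess_lstm` model object.
#' @export
lstm_model <- function(n_classes, config = lstm_config(), seed = 1L) {
  rng <- local_rng(seed)
  # embedding row 1 is the padding class, rows 2..n_classes+1 the classes
  p <- list(emb = glorot(n_classes + 1L, config$embedding_dim))
  for (l in seq_len(config$layers)) {
    d_in <- if (l == 1) config$embedding_dim else config$hidden_units
    p <- lstm_layer_params(p, sprintf("l%d_", l), d_in, config$hidden_units)
  }
  p$Wout <- glorot(config$hidden_units, n_classes)
  p$bout <- zeros(1, n_classes)
  restore_rng(rng)
  structure(list(params = p, config = config, n_classes = as.integer(n_classes)),
            class = c("fess_lstm", "fess_model"))
}

lstm_step <- function(tape, L, pre, x, h, c) {
  gate <- function(g, act) {
    pre_act <- ad_add(tape, ad_add(tape,
      ad_matmul(tape, x, L[[paste0(pre, "W", g)]]),
      ad_matmul(tape, h, L[[paste0(pre, "U", g)]])), L[[paste0(pre, "b", g)]])
    act(tape, pre_act)
  }
  i <- gate("i", ad_sigmoid)
  f <- gate("f", ad_sigmoid)
  o <- gate("o", ad_sigmoid)
  g <- gate("g", ad_tanh)
  c_new <- ad_add(tape, ad_mul(tape, f, c), ad_mul(tape, i, g))
  h_new <- ad_mul(tape, o, ad_tanh(tape, c_new))
  list(h = h_new, c = c_new)
}

# Pad a class window on the left to the configured length. `window` 0-based.
lstm_pad_window <- function(window, config) {
  n <- config$window_length
  if (length(window) > n) window <- window[(length(window) - n + 1):length(window)]
  # padding class encoded as -1 (embedding row 1)
  c(rep(-1L, n - length(window)), window)
}

# Forward to logits for one padded window.
lstm_forward <- function(tape, L, model, window) {
  cfg <- model$config
  emb <- ad_rows(tape, L$emb, window + 2L)  # -1 -> row 1 (pad), 0 -> row 2
  hs <- cs <- lapply(seq_len(cfg$layers), function(l) {
    ad_const(tape, zeros(1, cfg$hidden_units))
  })
  for (t in seq_len(cfg$window_length)) {
    x <- ad_row(tape, emb, t)
    for (l in seq_len(cfg$layers)) {
      st <- lstm_step(tape, L, sprintf("l%d_", l), x, hs[[l]], cs[[l]])
      hs[[l]] <- st$h; cs[[l]] <- st$c
      x <- hs[[l]]
    }
  }
  ad_add(tape, ad_matmul(tape, hs[[cfg$layers]], L$Wout), L$bout)
}

#' Distribution over next landmark-combination classes from an LSTM
#'
#' @param model A `fess_lstm`.
#' @param window Integer vector of the most recent 0-based class ids; shorter
#'   windows are left-padded, longer ones truncated to the last 6 (or the
#'   configured window length).
#' @return Probability vector over the `n_classes` classes (sums to 1); the
#'   padding class is not part of the output space.
#' @export
lstm_predict_next <- function(model, window) {
  tape <- ad_tape()
  L <- make_leaves(tape, model$params)
  logits <- ad_value(tape, lstm_forward(tape, L, model,
                                        lstm_pad_window(as.integer(window),
                                                        model$config)))
  p <- exp(logits[1, ] - max(logits[1, ]))
  p / sum(p)
}

# Loss node for one (window, next-class) example.
lstm_example_loss <- function(tape, L, model, window, target) {
  logits <- lstm_forward(tape, L, model, lstm_pad_window(window, model$config))
  logp <- ad_log_softmax_rows(tape, logits)
  ad_pick_nll(tape, logp, target + 1L)
}

#' Sliding-window training examples from class sequences
#'
#' @param sequences List of integer vectors of 0-based class ids.
#' @param window_length Window size (default 6).
#' @return List of `list(window =, target =)` examples; windows shorter than
#'   `window_length` occur at sequence starts and are padded downstream.
#' @export
class_windows <- function(sequences, window_length = 6L) {
  out <- list()
  for (s in sequences) {
    s <- as.integer(s)
    if (length(s) < 2) next
    for (t in 2:length(s)) {
      lo <- max(1, t - window_length)
      out[[length(out) + 1]] <- list(window = s[lo:(t - 1)], target = s[t])
    }
  }
  out
}
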