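#' Transformer configuration
#'
#' Two presets are provided: `reference` (512 model width, 8 heads, 6 layers,
#' 2048 feed-forward width, dropout 0.1) matching the standard machine
#' translation architecture the published study trained on GPU, and `desk`
#' (64/4/2/256/0.1), a small preset that trains in minutes on one CPU core
#' and is used throughout the package's tests and examples.
#'
#' @param preset `"desk"` (default) or `"reference"`, or `NULL` to use the
#'   explicit arguments.
#' @param d_model Embedding/model width.
#' @param n_heads Attention heads; must divide `d_model`.
#' @param n_layers Encoder and decoder layers.
#' @param d_ff Feed-forward inner width.
#' @param dropout Dropout probability.
#' @param max_len Longest token sequence (with specials) supported.
#' @return A `fess_trf_config`.
#' @export
transformer_config <- function(preset = c("desk", "reference", "custom"),
                               d_model = 64L, n_heads = 4L, n_layers = 2L,
                               d_ff = 256L, dropout = 0.1, max_len = 12L) {
  preset <- match.arg(preset)
  if (preset == "reference") {
    d_model <- 512L; n_heads <- 8L; n_layers <- 6L; d_ff <- 2048L; dropout <- 0.1
  } else if (preset == "desk") {
    d_model <- 64L; n_heads <- 4L; n_layers <- 2L; d_ff <- 256L; dropout <- 0.1
  }
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_layers = as.integer(n_layers), d_ff = as.integer(d_ff),
                 dropout = dropout, d_k = as.integer(d_model / n_heads),
                 max_len = as.integer(max_len)),
            class = "fess_trf_config")
}

#' Construct an (untrained) transformer sentence-translation model
#'
#' An encoder-decoder transformer over navigation-sentence tokens: shared
#' source/target embeddings with sinusoidal positional encoding, post-norm
#' residual blocks of multi-head attention and position-wise feed-forward
#' layers, and a linear projection to vocabulary logits. Train with
#' [train_model()]; decode with [beam_search()] or [greedy_decode()].
#'
#' @param vocab A `fess_vocab`.
#' @param config A `fess_trf_config`.
#' @param seed Seed for weight initialization.
#' @return A `fess_transformer` model object.
#' @export
transformer_model <- function(vocab, config = transformer_config(), seed = 1L) {
  V <- vocab_size(vocab)
  d <- config$d_model
  rng <- local_rng(seed)
  p <- list(emb = glorot(V, d))
  for (side in c("enc", "dec")) {
    for (l in seq_len(config$n_layers)) {
      pre <- sprintf("%s%d_", side, l)
      p[[paste0(pre, "Wq")]] <- glorot(d, d)
      p[[paste0(pre, "Wk")]] <- glorot(d, d)
      p[[paste0(pre, "Wv")]] <- glorot(d, d)
      p[[paste0(pre, "Wo")]] <- glorot(d, d)
      p[[paste0(pre, "ln1_g")]] <- matrix(1, 1, d)
      p[[paste0(pre, "ln1_b")]] <- zeros(1, d)
      if (side == "dec") {
        p[[paste0(pre, "Wq2")]] <- glorot(d, d)
        p[[paste0(pre, "Wk2")]] <- glorot(d, d)
        p[[paste0(pre, "Wv2")]] <- glorot(d, d)
        p[[paste0(pre, "Wo2")]] <- glorot(d, d)
        p[[paste0(pre, "ln3_g")]] <- matrix(1, 1, d)
        p[[paste0(pre, "ln3_b")]] <- zeros(1, d)
      }
      p[[paste0(pre, "W1")]] <- glorot(d, config$d_ff)
      p[[paste0(pre, "b1")]] <- zeros(1, config$d_ff)
      p[[paste0(pre, "W2")]] <- glorot(config$d_ff, d)
      p[[paste0(pre, "b2")]] <- zeros(1, d)
      p[[paste0(pre, "ln2_g")]] <- matrix(1, 1, d)
      p[[paste0(pre, "ln2_b")]] <- zeros(1, d)
    }
  }
  p$Wout <- glorot(d, V)
  p$bout <- zeros(1, V)
  restore_rng(rng)
  structure(list(params = p, config = config, vocab = vocab,
                 pe = positional_encoding(config$max_len, d)),
            class = c("fess_transformer", "fess_model"))
}

# Create tape leaves for every parameter; returns a lookup closure.
make_leaves <- function(tape, params) {
  ids <- lapply(names(params), function(nm) ad_leaf(tape, params[[nm]], nm))
  names(ids) <- names(params)
  ids
}

# Multi-head attention sublayer on the tape. q_in attends over kv_in.
trf_mha <- function(tape, L, pre, q_in, kv_in, config, mask = NULL,
                    cross = FALSE, collect = NULL) {
  sfx <- if (cross) "2" else ""
  Q <- ad_matmul(tape, q_in, L[[paste0(pre, "Wq", sfx)]])
  K <- ad_matmul(tape, kv_in, L[[paste0(pre, "Wk", sfx)]])
  V <- ad_matmul(tape, kv_in, L[[paste0(pre, "Wv", sfx)]])
  heads <- vector("list", config$n_heads)
  for (h in seq_len(config$n_heads)) {
    idx <- (h - 1) * config$d_k + seq_len(config$d_k)
    Qh <- ad_cols(tape, Q, idx)
    Kh <- ad_cols(tape, K, idx)
    Vh <- ad_cols(tape, V, idx)
    scores <- ad_scale(tape, ad_matmul(tape, Qh, Kh, transpose_b = TRUE),
                       1 / sqrt(config$d_k))
    if (!is.null(mask)) scores <- ad_add_const(tape, scores, mask)
    A <- ad_softmax_rows(tape, scores)
    if (!is.null(collect)) {
      collect$weights[[paste0(pre, if (cross) "cross_" else "self_", "h", h)]] <-
        ad_value(tape, A)
    }
    heads[[h]] <- ad_matmul(tape, A, Vh)
  }
  ad_matmul(tape, ad_cbind(tape, heads), L[[paste0(pre, "Wo", sfx)]])
}

trf_ffn <- function(tape, L, pre, x, config) {
  h <- ad_relu(tape, ad_add(tape, ad_matmul(tape, x, L[[paste0(pre, "W1")]]),
                            L[[paste0(pre, "b1")]]))
  ad_add(tape, ad_matmul(tape, h, L[[paste0(pre, "W2")]]), L[[paste0(pre, "b2")]])
}

trf_sublayer <- function(tape, L, x, sub, ln_g, ln_b, config, training) {
  if (training && config$dropout > 0) {
    mask <- draw_mask(nrow(ad_value(tape, sub)), ncol(ad_value(tape, sub)),
                      config$dropout)
    sub <- ad_dropout(tape, sub, mask, config$dropout)
  }
  ad_layer_norm(tape, ad_add(tape, x, sub), L[[ln_g]], L[[ln_b]])
}

trf_embed <- function(tape, L, model, ids, training) {
  n <- length(ids)
  x <- ad_scale(tape, ad_rows(tape, L$emb, ids + 1L),
                sqrt(model$config$d_model))
  x <- ad_add_const(tape, x, model$pe[seq_len(n), , drop = FALSE])
  if (training && model$config$dropout > 0) {
    mask <- draw_mask(n, model$config$d_model, model$config$dropout)
    x <- ad_dropout(tape, x, mask, model$config$dropout)
  }
  x
}

trf_encode <- function(tape, L, model, src_ids, training, collect = NULL) {
  cfg <- model$config
  x <- trf_embed(tape, L, model, src_ids, training)
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("enc%d_", l)
    att <- trf_mha(tape, L, pre, x, x, cfg, collect = collect)
    x <- trf_sublayer(tape, L, x, att, paste0(pre, "ln1_g"),
                      paste0(pre, "ln1_b"), cfg, training)
    ff <- trf_ffn(tape, L, pre, x, cfg)
    x <- trf_sublayer(tape, L, x, ff, paste0(pre, "ln2_g"),
                      paste0(pre, "ln2_b"), cfg, training)
  }
  x
}

causal_mask <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- -1e9
  m
}

trf_decode <- function(tape, L, model, enc_out, tgt_in_ids, training,
                       collect = NULL) {
  cfg <- model$config
  x <- trf_embed(tape, L, model, tgt_in_ids, training)
  mask <- causal_mask(length(tgt_in_ids))
  for (l in seq_len(cfg$n_layers)) {
    pre <- sprintf("dec%d_", l)
    att <- trf_mha(tape, L, pre, x, x, cfg, mask = mask, collect = collect)
    x <- trf_sublayer(tape, L, x, att, paste0(pre, "ln1_g"),
                      paste0(pre, "ln1_b"), cfg, training)
    xatt <- trf_mha(tape, L, pre, x, enc_out, cfg, cross = TRUE,
                    collect = collect)
    x <- trf_sublayer(tape, L, x, xatt, paste0(pre, "ln3_g"),
                      paste0(pre, "ln3_b"), cfg, training)
    ff <- trf_ffn(tape, L, pre, x, cfg)
    x <- trf_sublayer(tape, L, x, ff, paste0(pre, "ln2_g"),
                      paste0(pre, "ln2_b"), cfg, training)
  }
  ad_log_softmax_rows(tape, ad_add(tape, ad_matmul(tape, x, L$Wout), L$bout))
}

# Loss node for one source/target index pair. tgt_ids includes SOS ... EOS.
trf_pair_loss <- function(tape, L, model, src_ids, tgt_ids, training,
                          smoothing) {
  enc <- trf_encode(tape, L, model, src_ids, training)
  n <- length(tgt_ids)
  logp <- trf_decode(tape, L, model, enc, tgt_ids[-n], training)
  targets <- tgt_ids[-1]
  if (smoothing > 0) {
    P <- smoothed_targets(targets, vocab_size(model$vocab), smoothing)
    ce <- ad_cross_entropy_rows(tape, logp, P)
    hp <- entropy_of_smoothed(vocab_size(model$vocab), smoothing)
    ad_add_const(tape, ce, matrix(-hp, 1, 1))
  } else {
    ad_pick_nll(tape, logp, targets + 1L)
  }
}

#' Next-word distribution of a sentence-translation model
#'
#' The autoregressive contract shared by the GRU encoder-decoder and the
#' transformer: given the encoded source sentence and the 0-based indices
#' generated so far, return the model's probability distribution over the
#' vocabulary for the next token. Deterministic given fixed weights.
#'
#' @param model A trained or freshly initialized model.
#' @param src_ids Integer vector: source sentence indices incl. SOS/EOS
#'   (see [encode_sentence()]).
#' @param prefix Integer vector of already generated 0-based token indices
#'   (without SOS); may be empty.
#' @return Numeric probability vector over the vocabulary (sums to 1).
#' @export
next_word_distribution <- function(model, src_ids, prefix = integer(0)) {
  UseMethod("next_word_distribution")
}

#' @export
next_word_distribution.fess_transformer <- function(model, src_ids,
                                                    prefix = integer(0)) {
  if (length(prefix) + 1L > model$config$max_len) {
    stop("prefix longer than the model's maximum length")
  }
  tape <- ad_tape()
  L <- make_leaves(tape, model$params)
  enc <- trf_encode(tape, L, model, src_ids, training = FALSE)
  logp <- trf_decode(tape, L, model, enc, c(SOS_IDX, prefix), training = FALSE)
  p <- exp(ad_value(tape, logp)[length(prefix) + 1L, ])
  p / sum(p)
}

#' Export the attention weight matrices of a transformer for one pair
#'
#' Runs one forward pass and returns every encoder self-attention, decoder
#' self-attention and decoder cross-attention weight matrix per layer and
#' head, suitable for writing as CSV and inspecting which source words a
#' generated word attended to.
#'
#' @param model A `fess_transformer`.
#' @param src_ids,tgt_ids Encoded source and target sentences.
#' @return Named list of weight matrices (rows sum to 1).
#' @export
attention_weights <- function(model, src_ids, tgt_ids) {
  tape <- ad_tape()
  L <- make_leaves(tape, model$params)
  collect <- new.env()
  collect$weights <- list()
  enc <- trf_encode(tape, L, model, src_ids, training = FALSE, collect = collect)
  trf_decode(tape, L, model, enc, tgt_ids[-length(tgt_ids)], training = FALSE,
             collect = collect)
  collect$weights
}
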