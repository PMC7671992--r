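# Shared neural-network plumbing: initialization, optimizer, learning-rate
# schedule, attention primitive, positional encoding, losses.

glorot <- function(nr, nc) {
  a <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -a, a), nr, nc)
}

zeros <- function(nr, nc) matrix(0, nr, nc)

#' Scaled dot-product attention
#'
#' `Attn(Q, K, V) = softmax(Q K^T / sqrt(d_K)) V`: the dot products of the
#' queries with all keys are scaled by `sqrt(d_K)`, turned into row-wise
#' probability weights by a softmax, and used to form weighted sums of the
#' value rows.
#'
#' @param Q Query matrix (n_queries x d_K).
#' @param K Key matrix (n_keys x d_K).
#' @param V Value matrix (n_keys x d_V).
#' @param d_K Key dimension used for scaling; defaults to `ncol(K)`.
#' @param mask Optional additive mask matrix (n_queries x n_keys), typically
#'   0 / -Inf, applied to the scores before the softmax.
#' @return List with `output` (n_queries x d_V) and `weights`
#'   (n_queries x n_keys, rows summing to 1).
#' @export
scaled_dot_product_attention <- function(Q, K, V, d_K = ncol(K), mask = NULL) {
  if (d_K <= 0) stop("d_K must be positive")
  scores <- Q %*% t(K) / sqrt(d_K)
  if (!is.null(mask)) scores <- scores + mask
  m <- scores - apply(scores, 1, max)
  e <- exp(m)
  w <- e / rowSums(e)
  list(output = w %*% V, weights = w)
}

# Sinusoidal positional encoding, rows = positions, columns = channels.
positional_encoding <- function(n_pos, d_model) {
  pos <- seq_len(n_pos) - 1
  i <- seq_len(d_model) - 1
  angle <- outer(pos, 10000^(-(i %/% 2 * 2) / d_model))
  pe <- matrix(0, n_pos, d_model)
  even <- (i %% 2) == 0
  pe[, even] <- sin(angle[, even, drop = FALSE])
  pe[, !even] <- cos(angle[, !even, drop = FALSE])
  pe
}

#' Warm-up learning-rate schedule
#'
#' `lr = d_model^(-0.5) * min(step^(-0.5), step * n_warmup^(-1.5))`: linear
#' growth up to `n_warmup` steps, then proportional to `step^(-0.5)`. The
#' `literal` mode replaces the leading factor with `sqrt(d_model)`,
#' reproducing a formula sometimes printed with the exponent sign flipped;
#' it yields learning rates greater than 1 for realistic model sizes and is
#' kept only for comparison.
#'
#' @param step Training step, >= 1.
#' @param schedule List with `d_model`, `n_warmup` (default 200) and `mode`
#'   (`"standard"` or `"literal"`); see [lr_schedule()].
#' @return Learning rate.
#' @export
lr_at <- function(step, schedule) {
  if (any(step < 1)) stop("step must be >= 1")
  base <- if (identical(schedule$mode, "literal")) {
    sqrt(schedule$d_model)
  } else {
    schedule$d_model^(-0.5)
  }
  base * pmin(step^(-0.5), step * schedule$n_warmup^(-1.5))
}

#' Construct a learning-rate schedule
#' @param d_model Model width the schedule is scaled by.
#' @param n_warmup Warm-up steps (default 200).
#' @param mode `"standard"` (default) or `"literal"`.
#' @return Schedule list for [lr_at()].
#' @export
lr_schedule <- function(d_model, n_warmup = 200L,
                        mode = c("standard", "literal")) {
  list(d_model = d_model, n_warmup = n_warmup, mode = match.arg(mode))
}

# Adam optimizer over a named list of parameter matrices.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, opt, lr, beta1 = 0.9, beta2 = 0.98,
                      eps = 1e-9) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (opt$m[[nm]] / bc1) / (sqrt(opt$v[[nm]] / bc2) + eps)
  }
  list(params = params, opt = opt)
}

# Smoothed target distribution matrix: row i puts 1 - smoothing on target i,
# smoothing / (V - 2) on every other non-PAD token, and 0 on PAD.
smoothed_targets <- function(targets, vocab_size, smoothing) {
  n <- length(targets)
  V <- vocab_size
  P <- matrix(smoothing / (V - 2), n, V)
  P[, PAD_IDX + 1L] <- 0
  P[cbind(seq_len(n), targets + 1L)] <- 1 - smoothing
  P
}

#' Label-smoothed Kullback-Leibler loss
#'
#' The target distribution puts `1 - smoothing` on the true token and spreads
#' `smoothing` uniformly over the remaining non-padding tokens; the loss is
#' the mean over positions of `D_KL(P_truth || P_pred) = H(P_truth, P_pred) -
#' H(P_truth)`, which is zero exactly when the prediction equals the smoothed
#' target. With `smoothing = 0` it reduces to the negative log-likelihood of
#' the target tokens.
#'
#' @param log_probs Matrix of predicted log-probabilities, one row per
#'   position; rows must be normalized.
#' @param targets Integer vector of 0-based target token indices.
#' @param smoothing Smoothing mass in \code{[0, 1)}.
#' @param vocab_size Number of tokens (defaults to `ncol(log_probs)`).
#' @return Scalar mean KL divergence (>= 0 up to numerical noise).
#' @export
label_smoothed_kl_loss <- function(log_probs, targets, smoothing = 0.1,
                                   vocab_size = ncol(log_probs)) {
  if (!is.matrix(log_probs)) log_probs <- matrix(log_probs, nrow = 1)
  stopifnot(length(targets) == nrow(log_probs), smoothing >= 0, smoothing < 1)
  if (any(abs(rowSums(exp(log_probs)) - 1) > 1e-6)) {
    stop("log_probs rows are not normalized probability distributions")
  }
  P <- smoothed_targets(as.integer(targets), vocab_size, smoothing)
  ce <- -sum(P * log_probs) / nrow(P)
  hp <- entropy_of_smoothed(vocab_size, smoothing)
  ce - hp
}

# Entropy of the smoothed target distribution (same for every row).
entropy_of_smoothed <- function(vocab_size, smoothing) {
  if (smoothing == 0) return(0)
  p_other <- smoothing / (vocab_size - 2)
  -( (1 - smoothing) * log(1 - smoothing) +
       smoothing * log(p_other) )
}

#' Cross-entropy loss of predicted log-probabilities
#'
#' Mean over positions of the negative log-likelihood of the target tokens.
#'
#' @inheritParams label_smoothed_kl_loss
#' @return Scalar loss.
#' @export
cross_entropy_loss <- function(log_probs, targets) {
  if (!is.matrix(log_probs)) log_probs <- matrix(log_probs, nrow = 1)
  stopifnot(length(targets) == nrow(log_probs))
  -mean(log_probs[cbind(seq_len(nrow(log_probs)), as.integer(targets) + 1L)])
}

# 0/1 dropout mask drawn from the active RNG.
draw_mask <- function(nr, nc, p) {
  matrix(stats::rbinom(nr * nc, 1L, 1 - p), nr, nc)
}
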