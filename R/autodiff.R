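# Minimal reverse-mode automatic differentiation over dense matrices.
#
# A tape is an environment holding a growing list of nodes. Every node stores
# its value (a numeric matrix), the ids of its parents and a vector-Jacobian
# product closure that maps the incoming gradient to gradients for each
# parent. ad_backward() walks the tape in reverse creation order, which is a
# valid topological order because parents are always created before children.
#
# The engine covers exactly the operations the GRU/LSTM/transformer forward
# passes need; it is not a general-purpose framework. All matrices are
# (positions x features); sequences are rows.

ad_tape <- function() {
  t <- new.env(parent = emptyenv())
  t$nodes <- vector("list", 256L)
  t$n <- 0L
  t
}

ad_node <- function(tape, value, parents = integer(0), vjp = NULL, name = NULL) {
  # force the promises first: evaluating a nested op argument after the
  # counter bump would let the inner node claim (and the outer overwrite)
  # the same slot
  force(value); force(parents); force(vjp)
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[tape$n]] <- list(value = value, parents = parents, vjp = vjp,
                               name = name)
  tape$n
}

ad_value <- function(tape, id) {
  # force id before touching tape$nodes: a nested op call passed as `id`
  # appends to the tape, and the list must be read after that side effect
  force(id)
  tape$nodes[[id]]$value
}

# Leaf holding a trainable parameter; `name` keys the collected gradient.
ad_leaf <- function(tape, x, name = NULL) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ad_node(tape, x, name = name)
}

# Constant input; no gradient is collected for it.
ad_const <- function(tape, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1)
  ad_node(tape, x)
}

ad_matmul <- function(tape, a, b, transpose_b = FALSE) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  val <- if (transpose_b) A %*% t(B) else A %*% B
  ad_node(tape, val, c(a, b), function(g) {
    if (transpose_b) list(g %*% B, t(g) %*% A) else list(g %*% t(B), t(A) %*% g)
  })
}

ad_add <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  if (nrow(B) == 1L && nrow(A) > 1L) {
    # broadcast row vector (bias) over rows of A
    val <- sweep(A, 2, B[1, ], "+")
    ad_node(tape, val, c(a, b), function(g) {
      list(g, matrix(colSums(g), 1))
    })
  } else {
    ad_node(tape, A + B, c(a, b), function(g) list(g, g))
  }
}

ad_sub <- function(tape, a, b) {
  ad_node(tape, ad_value(tape, a) - ad_value(tape, b), c(a, b),
          function(g) list(g, -g))
}

ad_mul <- function(tape, a, b) {
  A <- ad_value(tape, a); B <- ad_value(tape, b)
  ad_node(tape, A * B, c(a, b), function(g) list(g * B, g * A))
}

ad_scale <- function(tape, a, k) {
  ad_node(tape, ad_value(tape, a) * k, a, function(g) list(g * k))
}

ad_add_const <- function(tape, a, X) {
  ad_node(tape, ad_value(tape, a) + X, a, function(g) list(g))
}

ad_tanh <- function(tape, a) {
  v <- tanh(ad_value(tape, a))
  ad_node(tape, v, a, function(g) list(g * (1 - v^2)))
}

ad_sigmoid <- function(tape, a) {
  v <- 1 / (1 + exp(-ad_value(tape, a)))
  ad_node(tape, v, a, function(g) list(g * v * (1 - v)))
}

ad_relu <- function(tape, a) {
  A <- ad_value(tape, a)
  v <- pmax(A, 0)
  ad_node(tape, v, a, function(g) list(g * (A > 0)))
}

# Row-wise softmax.
ad_softmax_rows <- function(tape, a) {
  A <- ad_value(tape, a)
  m <- A - apply(A, 1, max)
  e <- exp(m)
  s <- e / rowSums(e)
  ad_node(tape, s, a, function(g) {
    list((g - rowSums(g * s)) * s)
  })
}

# Row-wise log-softmax.
ad_log_softmax_rows <- function(tape, a) {
  A <- ad_value(tape, a)
  m <- A - apply(A, 1, max)
  lse <- log(rowSums(exp(m)))
  v <- m - lse
  s <- exp(v)
  ad_node(tape, v, a, function(g) list(g - rowSums(g) * s))
}

# Row-wise layer normalization with learned gain/bias (1 x d leaves).
ad_layer_norm <- function(tape, a, gamma, beta, eps = 1e-5) {
  A <- ad_value(tape, a)
  G <- ad_value(tape, gamma)[1, ]
  B <- ad_value(tape, beta)[1, ]
  d <- ncol(A)
  mu <- rowMeans(A)
  xc <- A - mu
  va <- rowMeans(xc^2)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  val <- sweep(sweep(xhat, 2, G, "*"), 2, B, "+")
  ad_node(tape, val, c(a, gamma, beta), function(g) {
    gx <- sweep(g, 2, G, "*")
    # d xhat / d x backward, standard layer-norm gradient
    gi <- inv * (gx - rowMeans(gx) - xhat * rowMeans(gx * xhat))
    list(gi, matrix(colSums(g * xhat), 1), matrix(colSums(g), 1))
  })
}

# Row gather (embedding lookup): rows `idx` (1-based) of a.
ad_rows <- function(tape, a, idx) {
  A <- ad_value(tape, a)
  ad_node(tape, A[idx, , drop = FALSE], a, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    for (k in seq_along(idx)) G[idx[k], ] <- G[idx[k], ] + g[k, ]
    list(G)
  })
}

# Column slice, used to split attention heads.
ad_cols <- function(tape, a, idx) {
  A <- ad_value(tape, a)
  ad_node(tape, A[, idx, drop = FALSE], a, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[, idx] <- g
    list(G)
  })
}

# Column-bind several nodes (concatenate attention heads).
ad_cbind <- function(tape, ids) {
  vals <- lapply(ids, ad_value, tape = tape)
  widths <- vapply(vals, ncol, 0L)
  ad_node(tape, do.call(cbind, vals), as.integer(ids), function(g) {
    out <- vector("list", length(ids))
    at <- 0L
    for (k in seq_along(ids)) {
      out[[k]] <- g[, at + seq_len(widths[k]), drop = FALSE]
      at <- at + widths[k]
    }
    out
  })
}

# Row-bind several nodes (stack per-step outputs).
ad_rbind <- function(tape, ids) {
  vals <- lapply(ids, ad_value, tape = tape)
  heights <- vapply(vals, nrow, 0L)
  ad_node(tape, do.call(rbind, vals), as.integer(ids), function(g) {
    out <- vector("list", length(ids))
    at <- 0L
    for (k in seq_along(ids)) {
      out[[k]] <- g[at + seq_len(heights[k]), , drop = FALSE]
      at <- at + heights[k]
    }
    out
  })
}

# Single row of a node (keeps it differentiable, for per-step RNN slices).
ad_row <- function(tape, a, i) {
  A <- ad_value(tape, a)
  ad_node(tape, A[i, , drop = FALSE], a, function(g) {
    G <- matrix(0, nrow(A), ncol(A))
    G[i, ] <- g
    list(G)
  })
}

# Inverted dropout with an externally drawn 0/1 mask (same shape as a).
ad_dropout <- function(tape, a, mask, p) {
  if (p <= 0) return(a)
  scale <- 1 / (1 - p)
  ad_node(tape, ad_value(tape, a) * mask * scale, a,
          function(g) list(g * mask * scale))
}

# Scalar loss: mean over rows i of -logp[i, target[i]]. `targets` 1-based.
ad_pick_nll <- function(tape, logp, targets) {
  L <- ad_value(tape, logp)
  n <- length(targets)
  sel <- cbind(seq_len(n), targets)
  val <- matrix(-mean(L[sel]), 1, 1)
  ad_node(tape, val, logp, function(g) {
    G <- matrix(0, nrow(L), ncol(L))
    G[sel] <- -g[1, 1] / n
    list(G)
  })
}

# Scalar loss: mean over rows of -sum_j P[i,j] * logq[i,j] for a constant
# target distribution matrix P (rows sum to 1). Cross-entropy H(P, Q).
ad_cross_entropy_rows <- function(tape, logq, P) {
  L <- ad_value(tape, logq)
  n <- nrow(L)
  val <- matrix(-sum(P * L) / n, 1, 1)
  ad_node(tape, val, logq, function(g) list(-g[1, 1] * P / n))
}

# Mean of several scalar nodes.
ad_mean_scalars <- function(tape, ids) {
  n <- length(ids)
  vals <- vapply(ids, function(i) ad_value(tape, i)[1, 1], 0)
  ad_node(tape, matrix(mean(vals), 1, 1), as.integer(ids), function(g) {
    rep(list(g / n), n)
  })
}

#' Reverse-mode gradient sweep over a tape
#'
#' Seeds the gradient of the scalar node `loss_id` with 1 and accumulates
#' vector-Jacobian products down to the leaves.
#'
#' @param tape A tape created by the internal `ad_tape()`.
#' @param loss_id Node id of a 1x1 scalar.
#' @return Named list of gradients for all named leaves.
#' @keywords internal
ad_backward <- function(tape, loss_id) {
  grads <- vector("list", tape$n)
  grads[[loss_id]] <- matrix(1, 1, 1)
  out <- list()
  for (id in seq(loss_id, 1L)) {
    g <- grads[[id]]
    if (is.null(g)) next
    node <- tape$nodes[[id]]
    if (!is.null(node$name)) {
      out[[node$name]] <- if (is.null(out[[node$name]])) g else out[[node$name]] + g
    }
    if (is.null(node$vjp)) next
    pg <- node$vjp(g)
    for (k in seq_along(node$parents)) {
      p <- node$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[[id]] <- NULL  # free memory as we go
  }
  out
}
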