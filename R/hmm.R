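#' Gaussian-emission hidden Markov model configuration
#'
#' The reference baseline uses 12 hidden states with one-dimensional Gaussian
#' emissions over the class encoding (a landmark-combination class id mapped
#' to the real line as its integer index), fitted with Baum-Welch for at most
#' 500 iterations to a log-likelihood convergence threshold of 0.01.
#'
#' @param n_hidden_states Number of hidden states (default 12).
#' @param max_iter Baum-Welch iteration cap (default 500).
#' @param tol Absolute log-likelihood improvement below which fitting stops
#'   (default 0.01).
#' @param var_floor Lower bound on emission variances.
#' @return A `fess_hmm_config`.
#' @export
hmm_config <- function(n_hidden_states = 12L, max_iter = 500L, tol = 0.01,
                       var_floor = 1e-3) {
  stopifnot(n_hidden_states >= 1, max_iter >= 1, tol > 0, var_floor > 0)
  structure(list(n_hidden_states = as.integer(n_hidden_states),
                 max_iter = as.integer(max_iter), tol = tol,
                 var_floor = var_floor),
            class = "fess_hmm_config")
}

# log N(x; mu, var) for vectors x against all states (returns T x S matrix).
hmm_log_emission <- function(x, mu, var) {
  outer(x, mu, function(xx, mm) xx - mm)^2 |>
    sweep(2, -2 * var, "/") |>
    sweep(2, 0.5 * log(2 * pi * var), "-")
}

# Scaled forward pass. Returns list(alpha = T x S scaled, c = scaling
# factors, loglik).
hmm_forward <- function(x, pi0, A, mu, var) {
  Tn <- length(x); S <- length(pi0)
  logB <- hmm_log_emission(x, mu, var)
  B <- exp(logB - apply(logB, 1, max))
  rowmax <- apply(logB, 1, max)
  alpha <- matrix(0, Tn, S)
  cvec <- numeric(Tn)
  a <- pi0 * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  if (Tn > 1) {
    for (t in 2:Tn) {
      a <- (alpha[t - 1, ] %*% A)[1, ] * B[t, ]
      cvec[t] <- sum(a)
      alpha[t, ] <- a / cvec[t]
    }
  }
  list(alpha = alpha, c = cvec, B = B,
       loglik = sum(log(cvec)) + sum(rowmax))
}

hmm_backward <- function(x, A, B, cvec) {
  Tn <- nrow(B); S <- ncol(B)
  beta <- matrix(0, Tn, S)
  beta[Tn, ] <- 1
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      beta[t, ] <- (A %*% (B[t + 1, ] * beta[t + 1, ]))[, 1] / cvec[t + 1]
    }
  }
  beta
}

#' Fit a Gaussian-emission HMM with Baum-Welch
#'
#' Expectation-maximization over one or more observation sequences. The
#' per-iteration total log-likelihood is non-decreasing (an EM guarantee,
#' also recorded in the returned trace); fitting stops when the improvement
#' falls below `config$tol` or after `config$max_iter` iterations.
#'
#' Initialization is deterministic: emission means at evenly spaced quantiles
#' of the pooled observations, a common emission variance, uniform initial
#' and transition distributions. Uniform rows are broken by the E-step
#' because the means differ.
#'
#' @param sequences List of numeric observation vectors (e.g., 0-based class
#'   ids), each of length >= 2; a single vector is accepted.
#' @param config A `fess_hmm_config`.
#' @return A `fess_hmm`: list with `transition` (S x S), `mu`, `var`,
#'   `initial`, `loglik_trace`, `converged`, `classes` (sorted unique
#'   integer observations, when the input was integer-valued).
#' @export
hmm_fit <- function(sequences, config = hmm_config()) {
  if (is.numeric(sequences)) sequences <- list(sequences)
  if (!length(sequences)) stop("need at least one observation sequence")
  lens <- lengths(sequences)
  if (any(lens < 2)) {
    stop("each observation sequence must have length >= 2")
  }
  x_all <- unlist(sequences)
  S <- config$n_hidden_states
  mu <- as.numeric(stats::quantile(x_all, probs = (seq_len(S) - 0.5) / S,
                                   names = FALSE, type = 7))
  # distinct means are needed to break the uniform-responsibility symmetry
  if (any(duplicated(mu))) mu <- mu + (seq_len(S) - (S + 1) / 2) * 1e-3
  v <- max(stats::var(x_all), config$var_floor)
  var <- rep(v, S)
  A <- matrix(1 / S, S, S)
  pi0 <- rep(1 / S, S)
  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(config$max_iter)) {
    ll <- 0
    num_A <- matrix(0, S, S)
    den_A <- numeric(S)
    num_pi <- numeric(S)
    num_mu <- numeric(S); num_m2 <- numeric(S); den_mu <- numeric(S)
    for (x in sequences) {
      fw <- hmm_forward(x, pi0, A, mu, var)
      beta <- hmm_backward(x, A, fw$B, fw$c)
      ll <- ll + fw$loglik
      gamma <- fw$alpha * beta
      gamma <- gamma / rowSums(gamma)
      Tn <- length(x)
      num_pi <- num_pi + gamma[1, ]
      if (Tn > 1) {
        for (t in seq_len(Tn - 1)) {
          xi <- (fw$alpha[t, ] %o% (fw$B[t + 1, ] * beta[t + 1, ])) * A /
            fw$c[t + 1]
          num_A <- num_A + xi
        }
        den_A <- den_A + colSums(gamma[seq_len(Tn - 1), , drop = FALSE])
      }
      num_mu <- num_mu + colSums(gamma * x)
      num_m2 <- num_m2 + colSums(gamma * x^2)
      den_mu <- den_mu + colSums(gamma)
    }
    trace <- c(trace, ll)
    if (iter > 1 && abs(ll - trace[iter - 1]) < config$tol) {
      converged <- TRUE
      break
    }
    # M-step
    pi0 <- num_pi / sum(num_pi)
    A <- num_A / pmax(den_A, .Machine$double.eps)
    A <- A / rowSums(A)
    mu <- num_mu / pmax(den_mu, .Machine$double.eps)
    var <- pmax(num_m2 / pmax(den_mu, .Machine$double.eps) - mu^2,
                config$var_floor)
  }
  classes <- NULL
  if (all(abs(x_all - round(x_all)) < 1e-9)) {
    classes <- sort(unique(as.integer(round(x_all))))
  }
  structure(list(transition = A, mu = mu, var = var, initial = pi0,
                 loglik_trace = trace, converged = converged,
                 classes = classes, config = config),
            class = "fess_hmm")
}

#' @export
print.fess_hmm <- function(x, ...) {
  cat(sprintf("<fess_hmm: %d hidden states, %d BW iterations, %s>\n",
              length(x$mu), length(x$loglik_trace),
              if (x$converged) "converged" else "iteration cap reached"))
  invisible(x)
}

#' Greedy next-class prediction from a fitted HMM
#'
#' Filters the hidden-state distribution over the observed sequence, advances
#' it one step through the transition matrix, and returns the class whose
#' encoding maximizes the predictive observation density (ties broken by the
#' lowest class id).
#'
#' @param fit A `fess_hmm`.
#' @param observed Numeric vector of observed class ids (non-empty).
#' @param classes Candidate class encodings; defaults to the classes seen
#'   during fitting.
#' @return The predicted class (same encoding as the observations).
#' @export
hmm_predict_next <- function(fit, observed, classes = fit$classes) {
  if (!length(observed)) stop("observed sequence must be non-empty")
  if (is.null(classes)) stop("no candidate classes available")
  fw <- hmm_forward(as.numeric(observed), fit$initial, fit$transition,
                    fit$mu, fit$var)
  phi <- (fw$alpha[length(observed), ] %*% fit$transition)[1, ]
  dens <- vapply(classes, function(cl) {
    sum(phi * stats::dnorm(cl, fit$mu, sqrt(fit$var)))
  }, 0)
  classes[which.max(dens)]  # which.max takes the first (lowest id) on ties
}
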