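#' Simulator configuration for FESS-like navigation workflows
#'
#' The simulator draws landmark-combination sequences from a first-order
#' Markov chain, decorates them with log-normal dwell times, and derives
#' movement directions from the ontology. See [default_sim_config()] for the
#' calibrated default.
#'
#' @param states List of landmark combinations (character vectors), one chain
#'   state per combination.
#' @param transition_matrix Row-stochastic C x C matrix over `states`.
#' @param dwell_meanlog,dwell_sdlog Log-normal dwell-time parameters
#'   (seconds); scalars or per-state vectors.
#' @param excursion_prob Per-step probability of an inserted out-of-patient
#'   visit (e.g. lens cleaning) on top of the chain. The default chain already
#'   contains `out_of_patient` as a state, so this defaults to 0.
#' @param steps_mean,steps_sd Truncated-normal parameters for the number of
#'   states per workflow (truncated below at `steps_min`).
#' @param steps_min Minimum states per workflow (>= 2).
#' @param n_workflows Number of workflows in a simulated corpus.
#' @param seed Master seed; per-workflow seeds are derived by fixed offset.
#' @param ont A `fess_ontology`.
#' @return A `fess_sim_config`.
#' @export
sim_config <- function(states, transition_matrix,
                       dwell_meanlog = log(9), dwell_sdlog = 0.8,
                       excursion_prob = 0, steps_mean = 167, steps_sd = 60,
                       steps_min = 20L, n_workflows = 22L, seed = 1L,
                       ont = default_ontology()) {
  C <- length(states)
  transition_matrix <- as.matrix(transition_matrix)
  stopifnot(nrow(transition_matrix) == C, ncol(transition_matrix) == C)
  if (any(transition_matrix < 0)) stop("transition probabilities must be >= 0")
  rs <- rowSums(transition_matrix)
  if (any(abs(rs - 1) > 1e-9)) stop("transition matrix rows must sum to 1")
  if (excursion_prob < 0 || excursion_prob > 1) stop("excursion_prob in [0,1]")
  if (steps_min < 2) stop("workflows need at least 2 steps")
  for (comb in states) combination_rank(comb, ont)  # validates names
  structure(list(
    states = lapply(states, canonical_combination, ont = ont),
    transition_matrix = transition_matrix,
    dwell_meanlog = rep_len(dwell_meanlog, C),
    dwell_sdlog = rep_len(dwell_sdlog, C),
    excursion_prob = excursion_prob,
    steps_mean = steps_mean, steps_sd = steps_sd,
    steps_min = as.integer(steps_min),
    n_workflows = as.integer(n_workflows),
    seed = as.integer(seed), ont = ont
  ), class = "fess_sim_config")
}

# Target long-run fraction of states containing each landmark, matching the
# published accumulated observation fractions of the 22-procedure FESS
# dataset (concha 0.51, meatus 0.27, maxillary orifice 0.18, out of patient
# 0.13, uncinate 0.06, bulla 0.04, recess 0.01).
default_state_targets <- function() {
  list(
    states = list(
      c("out_of_patient"),
      c("middle_nasal_concha"),
      c("middle_nasal_meatus"),
      c("maxillary_sinus_orifice"),
      c("uncinate_process_of_ethmoid"),
      c("spheno_ethmoidal_recess"),
      c("middle_nasal_concha", "middle_nasal_meatus"),
      c("middle_nasal_concha", "maxillary_sinus_orifice"),
      c("middle_nasal_concha", "uncinate_process_of_ethmoid"),
      c("middle_nasal_concha", "ethmoidal_bulla"),
      c("middle_nasal_meatus", "maxillary_sinus_orifice"),
      c("uncinate_process_of_ethmoid", "ethmoidal_bulla")
    ),
    # stationary probabilities chosen so that summing over the states
    # containing each landmark reproduces the accumulated fractions above
    pi = c(0.13, 0.38, 0.17, 0.10, 0.01, 0.01,
           0.06, 0.04, 0.02, 0.01, 0.04, 0.03)
  )
}

#' Stationary distribution of a row-stochastic matrix
#'
#' @param P Row-stochastic matrix.
#' @return Probability vector `pi` with `pi %*% P = pi`.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Calibrate a zero-diagonal transition matrix to a target stationary law
#'
#' Builds a Markov chain without self-transitions (every step is a movement
#' to a different landmark combination) whose stationary distribution matches
#' `pi_target`. Rows share a common destination-weight vector which is
#' iteratively rescaled until the stationary law converges to the target.
#'
#' @param pi_target Target stationary probabilities (sum 1, all > 0).
#' @param tol Max-abs stationary error to reach (default 1e-10).
#' @param max_iter Iteration cap.
#' @return Row-stochastic matrix with zero diagonal.
#' @export
calibrate_transitions <- function(pi_target, tol = 1e-10, max_iter = 500L) {
  stopifnot(all(pi_target > 0), abs(sum(pi_target) - 1) < 1e-8)
  C <- length(pi_target)
  w <- pi_target
  for (it in seq_len(max_iter)) {
    P <- matrix(rep(w, each = C), C, C)
    diag(P) <- 0
    P <- P / rowSums(P)
    q <- stationary_distribution(P)
    if (max(abs(q - pi_target)) < tol) break
    w <- w * (pi_target / q)
    w <- w / sum(w)
  }
  P
}

#' Default simulator configuration
#'
#' Twelve landmark-combination states (six single landmarks, six pairs) with
#' a transition matrix calibrated so that the long-run fraction of states
#' containing each landmark matches the accumulated observation fractions of
#' the published 22-procedure FESS annotation study (middle nasal concha
#' 0.51, meatus 0.27, maxillary sinus orifice 0.18, out of patient 0.13,
#' uncinate process 0.06, ethmoidal bulla 0.04, spheno-ethmoidal recess
#' 0.01), with ~167 states per workflow and log-normal dwell times with a
#' median of about 9 s.
#'
#' @param n_workflows Number of workflows (default 22).
#' @param seed Master seed.
#' @return A `fess_sim_config`.
#' @export
default_sim_config <- function(n_workflows = 22L, seed = 1L) {
  tgt <- default_state_targets()
  P <- calibrate_transitions(tgt$pi)
  sim_config(states = tgt$states, transition_matrix = P,
             n_workflows = n_workflows, seed = seed)
}

#' Landmark marginals implied by a simulator configuration
#'
#' Maps the stationary distribution of the configured chain to per-landmark
#' fractions: the long-run fraction of states whose combination contains each
#' landmark.
#'
#' @param config A `fess_sim_config`.
#' @return Named numeric vector over the ontology's landmarks.
#' @export
config_landmark_marginals <- function(config) {
  q <- stationary_distribution(config$transition_matrix)
  lms <- config$ont$name
  frac <- vapply(lms, function(lm) {
    sum(q[vapply(config$states, function(s) lm %in% s, TRUE)])
  }, 0)
  stats::setNames(frac, lms)
}

#' Simulate one navigation workflow
#'
#' Draws a state count from the truncated normal, walks the Markov chain from
#' its stationary distribution, assigns log-normal dwell times back to back
#' on a 0-based timeline, and fills directions via [infer_direction()]. The
#' same seed always yields the same workflow.
#'
#' @param config A `fess_sim_config`.
#' @param seed Integer seed for this workflow.
#' @param workflow_id Identifier (default derived from the seed).
#' @return A `fess_workflow` that passes [validate_workflow()].
#' @export
simulate_workflow <- function(config, seed, workflow_id = NULL) {
  if (is.null(workflow_id)) workflow_id <- sprintf("sim_%06d", seed %% 1000000L)
  C <- length(config$states)
  rng <- local_rng(seed)
  n <- max(config$steps_min,
           as.integer(round(stats::rnorm(1, config$steps_mean, config$steps_sd))))
  q0 <- stationary_distribution(config$transition_matrix)
  oop_state <- which(vapply(config$states,
                            function(s) identical(s, "out_of_patient"), TRUE))
  path <- integer(n)
  path[1] <- sample.int(C, 1, prob = q0)
  for (k in 2:n) {
    if (config$excursion_prob > 0 && length(oop_state) == 1 &&
        path[k - 1] != oop_state &&
        stats::runif(1) < config$excursion_prob) {
      path[k] <- oop_state
    } else {
      path[k] <- sample.int(C, 1, prob = config$transition_matrix[path[k - 1], ])
    }
  }
  dwell <- stats::rlnorm(n, config$dwell_meanlog[path], config$dwell_sdlog[path])
  end_t <- cumsum(dwell)
  start_t <- c(0, end_t[-n])
  restore_rng(rng)
  states <- vector("list", n)
  prev_comb <- NULL
  for (k in seq_len(n)) {
    comb <- config$states[[path[k]]]
    dir <- infer_direction(prev_comb, comb, config$ont)
    states[[k]] <- navigation_state(k, comb, dir, start_t[k], end_t[k], config$ont)
    prev_comb <- comb
  }
  navigation_workflow(workflow_id, states)
}

#' Simulate a corpus of navigation workflows
#'
#' Per-workflow seeds are `config$seed + 1000 * i`, so corpora are
#' reproducible and individual workflows can be regenerated in isolation.
#'
#' @param config A `fess_sim_config`.
#' @return List with `workflows` (list of `fess_workflow`) and `manifest`
#'   (per-workflow seed and the corpus statistics of
#'   [corpus_statistics()]).
#' @export
simulate_corpus <- function(config) {
  seeds <- config$seed + 1000L * seq_len(config$n_workflows)
  workflows <- lapply(seq_len(config$n_workflows), function(i) {
    simulate_workflow(config, seeds[i], sprintf("wf%02d", i))
  })
  stats <- corpus_statistics(workflows)
  manifest <- list(
    master_seed = config$seed,
    workflow_seeds = stats::setNames(as.list(seeds),
                                     vapply(workflows, `[[`, "", "workflow_id")),
    statistics = stats
  )
  list(workflows = workflows, manifest = manifest)
}

# Seed-scoped RNG helpers: save the caller's RNG state, seed, and restore.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
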