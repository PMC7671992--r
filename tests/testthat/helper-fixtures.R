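# Shared fixtures and independent reference implementations used as oracles.

# --- independent metric oracles (deliberately different algorithms from the
# --- package: token-by-token count consumption and recursive memoized LCS)

oracle_bleu1 <- function(pred, ref) {
  pred <- as.character(pred); ref <- as.character(ref)
  if (!length(pred)) return(0)
  budget <- table(ref)
  hits <- 0
  for (tok in pred) {
    if (!is.na(budget[tok]) && budget[tok] > 0) {
      hits <- hits + 1
      budget[tok] <- budget[tok] - 1
    }
  }
  bp <- if (length(pred) >= length(ref)) 1 else exp(1 - length(ref) / length(pred))
  hits / length(pred) * bp
}

oracle_lcs <- function(a, b) {
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0 || j == 0) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (a[i] == b[j]) rec(i - 1, j - 1) + 1L else max(rec(i - 1, j), rec(i, j - 1))
    memo[[key]] <- v
    v
  }
  rec(length(a), length(b))
}

oracle_rougeL <- function(pred, ref) {
  pred <- as.character(pred); ref <- as.character(ref)
  if (!length(pred)) return(0)
  oracle_lcs(pred, ref) / length(ref)
}

# --- random template sentences over the default ontology

random_template_sentence <- function(ont = default_ontology()) {
  k <- sample(1:3, 1)
  comb <- sample(ont$name, k)
  st <- navigation_state(sample(1:200, 1), comb, sample(c("inwards", "outwards", "dwell"), 1),
                         0, 1, ont)
  state_to_sentence(st)
}

# --- toy workflows built from annotation records

toy_records <- function(combos, dwell = 5) {
  n <- length(combos)
  recs <- data.frame(start_s = (seq_len(n) - 1) * dwell, end_s = seq_len(n) * dwell)
  recs$landmarks <- combos
  recs
}

toy_workflow <- function(combos, id = "toy", ont = default_ontology()) {
  derive_workflow(toy_records(combos), ont, workflow_id = id)
}

# deterministic cyclic corpus: a fixed loop of 8 states (7 distinct single
# landmarks plus one two-landmark combination), closed back to the start
cyclic_sentences <- function(ont = default_ontology()) {
  combos <- list("out_of_patient", "middle_nasal_concha", "middle_nasal_meatus",
                 "uncinate_process_of_ethmoid", "ethmoidal_bulla",
                 "maxillary_sinus_orifice", "spheno_ethmoidal_recess",
                 c("middle_nasal_concha", "middle_nasal_meatus"))
  sents <- list()
  prev <- NULL
  for (i in seq_along(combos)) {
    d <- infer_direction(prev, combos[[i]], ont)
    sents[[i]] <- state_to_sentence(navigation_state(i, combos[[i]], d,
                                                     i - 1, i, ont))
    prev <- combos[[i]]
  }
  sents
}

cyclic_pairs <- function(ont = default_ontology()) {
  sents <- cyclic_sentences(ont)
  make_pairs(c(sents, sents[1]))  # close the loop: 8 pairs over 8 sentences
}

# word accuracy of a decoded sentence list against targets, position-wise
# over the target length
word_accuracy <- function(predicted, target) {
  tot <- 0
  hit <- 0
  for (i in seq_along(target)) {
    tt <- as.character(target[[i]])
    pt <- as.character(predicted[[i]])
    tot <- tot + length(tt)
    n <- min(length(tt), length(pt))
    if (n > 0) hit <- hit + sum(pt[seq_len(n)] == tt[seq_len(n)])
  }
  hit / tot
}

# --- toy autoregressive language model for decoding oracles: `fn(prefix)`
# --- returns the next-token distribution (0-based ids)

toy_lm <- function(fn) structure(list(fn = fn), class = "toy_lm")

next_word_distribution.toy_lm <- function(model, src_ids, prefix = integer(0)) {
  model$fn(prefix)
}

registerS3method("next_word_distribution", "toy_lm", next_word_distribution.toy_lm,
                 envir = asNamespace("fessnav"))

# exhaustive maximizer of sum log p over all id sequences of length len
exhaustive_argmax <- function(fn, V, len) {
  best <- NULL
  best_lp <- -Inf
  grid <- do.call(expand.grid, rep(list(0:(V - 1)), len))
  for (r in seq_len(nrow(grid))) {
    ids <- as.integer(grid[r, ])
    lp <- 0
    for (t in seq_len(len)) {
      p <- fn(ids[seq_len(t - 1)])
      if (p[ids[t] + 1] <= 0) { lp <- -Inf; break }
      lp <- lp + log(p[ids[t] + 1])
    }
    if (lp > best_lp) { best_lp <- lp; best <- ids }
  }
  list(ids = best, log_prob = best_lp)
}
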