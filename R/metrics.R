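#' BLEU-1 of a predicted sentence against a reference
#'
#' Clipped unigram precision times the brevity penalty: each predicted token
#' counts as a match at most as often as it appears in the reference, the
#' match count is divided by the prediction length, and predictions shorter
#' than the reference are penalized by `exp(1 - |ref|/|pred|)`.
#'
#' @param predicted,reference `fess_sentence` or character token vectors.
#' @return Value in \code{[0, 1]}.
#' @export
bleu1 <- function(predicted, reference) {
  pred <- as.character(predicted)
  ref <- as.character(reference)
  if (!length(ref)) stop("reference sentence must be non-empty")
  if (!length(pred)) return(0)
  ref_counts <- table(ref)
  pred_counts <- table(pred)
  shared <- intersect(names(pred_counts), names(ref_counts))
  clipped <- sum(pmin(pred_counts[shared], ref_counts[shared]))
  prec <- clipped / length(pred)
  bp <- if (length(pred) >= length(ref)) 1 else exp(1 - length(ref) / length(pred))
  prec * bp
}

#' ROUGE-L recall of a predicted sentence against a reference
#'
#' Length of the longest common subsequence between prediction and reference,
#' divided by the reference length.
#'
#' @inheritParams bleu1
#' @return Value in \code{[0, 1]}.
#' @export
rougeL_recall <- function(predicted, reference) {
  pred <- as.character(predicted)
  ref <- as.character(reference)
  if (!length(ref)) stop("reference sentence must be non-empty")
  if (!length(pred)) return(0)
  lcs_length(pred, ref) / length(ref)
}

# Dynamic-programming LCS over token vectors.
lcs_length <- function(a, b) {
  n <- length(a); m <- length(b)
  prev <- integer(m + 1)
  for (i in seq_len(n)) {
    cur <- integer(m + 1)
    for (j in seq_len(m)) {
      cur[j + 1] <- if (a[i] == b[j]) prev[j] + 1L else max(cur[j], prev[j + 1])
    }
    prev <- cur
  }
  prev[m + 1]
}

#' Harmonic mean of BLEU-1 and ROUGE-L recall
#'
#' `F1_BR = 2 B R / (B + R)`, an approximated translation accuracy combining
#' n-gram precision and sentence-structure recall; 0 when both inputs are 0.
#'
#' @param b BLEU-1 value in \code{[0, 1]}.
#' @param r ROUGE-L recall value in \code{[0, 1]}.
#' @return Value in \code{[0, 1]}.
#' @export
f1_br <- function(b, r) {
  stopifnot(b >= 0, b <= 1, r >= 0, r <= 1)
  if (b + r == 0) return(0)
  2 * b * r / (b + r)
}

#' Word-level Jaccard distance between two sentences
#'
#' One minus the ratio of the token-set intersection to the token-set union;
#' 0 when both sentences are empty.
#'
#' @inheritParams bleu1
#' @return Value in \code{[0, 1]}.
#' @export
jaccard_distance <- function(predicted, reference) {
  a <- unique(as.character(predicted))
  b <- unique(as.character(reference))
  u <- union(a, b)
  if (!length(u)) return(0)
  1 - length(intersect(a, b)) / length(u)
}

#' Round half-up to a number of decimals
#'
#' Report-level rounding: 0.5 always rounds away from zero (so 0.285 -> 0.29
#' at 2 decimals), unlike [round()]'s round-half-even.
#'
#' @param x Numeric.
#' @param digits Decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# Split a template sentence into its evaluation slots.
sentence_slots <- function(sentence) {
  tok <- as.character(sentence)
  n <- length(tok)
  if (n < 6 || n > 8 || tok[1] != "step") return(NULL)
  list(step_count = tok[2], sinus = tok[3], landmark_group = tok[4],
       landmark_combination = paste(sort(tok[5:(n - 1)]), collapse = "+"),
       direction = tok[n])
}

SLOT_NAMES <- c("step_count", "sinus", "landmark_group",
                "landmark_combination", "direction")

#' Slot-level precision and recall over sentence pairs
#'
#' For each of the five sentence slots (step count, sinus/cavity, landmark
#' group, landmark combination, direction), precision and recall are computed
#' per observed slot value from the prediction/target confusions and
#' macro-averaged over values; the landmark-combination slot compares the
#' landmark set, ignoring order. The overall row is the macro mean across
#' slots and the F1 score is the harmonic mean of overall precision and
#' recall. Predictions that do not follow the sentence template are skipped
#' and counted in `n_malformed`.
#'
#' @param pairs List of `fess_pair` objects where `source` holds the
#'   prediction and `target` the ground truth, or a list of two parallel
#'   sentence lists `list(predicted =, target =)`.
#' @return List with `per_slot` (data.frame slot/precision/recall), `overall`
#'   precision and recall, `f1`, and `n_malformed`.
#' @export
slot_precision_recall <- function(pairs) {
  if (!is.null(pairs$predicted)) {
    preds <- pairs$predicted; targets <- pairs$target
  } else {
    preds <- lapply(pairs, `[[`, "source")
    targets <- lapply(pairs, `[[`, "target")
  }
  stopifnot(length(preds) == length(targets))
  n_malformed <- 0L
  rows <- list()
  for (i in seq_along(preds)) {
    sp <- sentence_slots(preds[[i]])
    st <- sentence_slots(targets[[i]])
    if (is.null(sp) || is.null(st)) {
      n_malformed <- n_malformed + 1L
      next
    }
    rows[[length(rows) + 1]] <- list(pred = sp, target = st)
  }
  per_slot <- data.frame(slot = SLOT_NAMES, precision = NA_real_,
                         recall = NA_real_)
  for (s in seq_along(SLOT_NAMES)) {
    slot <- SLOT_NAMES[s]
    pv <- vapply(rows, function(r) r$pred[[slot]], "")
    tv <- vapply(rows, function(r) r$target[[slot]], "")
    classes <- unique(c(pv, tv))
    prec <- rec <- numeric(0)
    for (cls in classes) {
      tp <- sum(pv == cls & tv == cls)
      npred <- sum(pv == cls)
      ntrue <- sum(tv == cls)
      if (npred > 0) prec <- c(prec, tp / npred)
      if (ntrue > 0) rec <- c(rec, tp / ntrue)
    }
    per_slot$precision[s] <- if (length(prec)) mean(prec) else NA_real_
    per_slot$recall[s] <- if (length(rec)) mean(rec) else NA_real_
  }
  overall_p <- mean(per_slot$precision, na.rm = TRUE)
  overall_r <- mean(per_slot$recall, na.rm = TRUE)
  # all pairs malformed: nothing to score, overalls are undefined
  if (is.nan(overall_p)) overall_p <- NA_real_
  if (is.nan(overall_r)) overall_r <- NA_real_
  f1 <- if (is.na(overall_p) || is.na(overall_r)) NA_real_ else {
    f1_br(overall_p, overall_r)
  }
  list(per_slot = per_slot, overall = c(precision = overall_p, recall = overall_r),
       f1 = f1, n_malformed = n_malformed)
}

#' Landmark-level precision and recall over aligned state sequences
#'
#' A predicted occurrence of a landmark (alone or inside a combination) at
#' step t is a true positive iff the landmark occurs in the target
#' combination at step t. Per-landmark precision is undefined when the
#' landmark is never predicted (and recall when it never occurs in the
#' targets); a landmark undefined on both sides is excluded from the macro
#' mean, otherwise an undefined side is counted as 0. Overall values are
#' unweighted macro means and F1 is their harmonic mean.
#'
#' @param predicted,target Parallel lists of landmark combinations (character
#'   vectors), or of `fess_state` objects.
#' @param landmarks Landmark universe; defaults to all names seen.
#' @return List with `per_landmark` data.frame, `overall`, `f1`.
#' @export
landmark_precision_recall <- function(predicted, target, landmarks = NULL) {
  if (length(predicted) != length(target)) {
    stop("predicted and target sequences differ in length")
  }
  as_comb <- function(x) if (inherits(x, "fess_state")) x$combination else as.character(x)
  preds <- lapply(predicted, as_comb)
  targs <- lapply(target, as_comb)
  if (is.null(landmarks)) landmarks <- sort(unique(unlist(c(preds, targs))))
  per <- data.frame(landmark = landmarks, precision = NA_real_, recall = NA_real_)
  for (k in seq_along(landmarks)) {
    lm <- landmarks[k]
    in_p <- vapply(preds, function(c) lm %in% c, TRUE)
    in_t <- vapply(targs, function(c) lm %in% c, TRUE)
    tp <- sum(in_p & in_t)
    if (sum(in_p) > 0) per$precision[k] <- tp / sum(in_p)
    if (sum(in_t) > 0) per$recall[k] <- tp / sum(in_t)
  }
  defined <- !(is.na(per$precision) & is.na(per$recall))
  pvals <- ifelse(is.na(per$precision[defined]), 0, per$precision[defined])
  rvals <- ifelse(is.na(per$recall[defined]), 0, per$recall[defined])
  overall_p <- if (length(pvals)) mean(pvals) else NA_real_
  overall_r <- if (length(rvals)) mean(rvals) else NA_real_
  f1 <- if (is.na(overall_p) || is.na(overall_r)) NA_real_ else {
    f1_br(overall_p, overall_r)
  }
  list(per_landmark = per,
       overall = c(precision = overall_p, recall = overall_r),
       f1 = f1)
}

#' Translation metrics over a set of prediction/target sentence pairs
#'
#' Mean BLEU-1, ROUGE-L recall, Jaccard distance over the pairs, plus the
#' F1 of the mean BLEU-1 and mean ROUGE-L.
#'
#' @param predicted,target Parallel lists of sentences.
#' @return List of class `fess_metric_report`.
#' @export
translation_metrics <- function(predicted, target) {
  stopifnot(length(predicted) == length(target))
  b <- mapply(bleu1, predicted, target)
  r <- mapply(rougeL_recall, predicted, target)
  j <- mapply(jaccard_distance, predicted, target)
  structure(list(bleu1 = mean(b), rougeL_recall = mean(r),
                 jaccard_distance = mean(j),
                 f1_br = f1_br(mean(b), mean(r)), n = length(b)),
            class = "fess_metric_report")
}

#' @export
print.fess_metric_report <- function(x, ...) {
  cat(sprintf("BLEU-1 %.2f  JD %.2f  ROUGE-L %.2f  F1_BR %.2f  (n=%d)\n",
              round_half_up(x$bleu1), round_half_up(x$jaccard_distance),
              round_half_up(x$rougeL_recall), round_half_up(x$f1_br), x$n))
  invisible(x)
}

#' Corpus summary statistics
#'
#' Per workflow: number of states, duration in seconds, number of unique
#' landmark combinations (LMC) and mean landmark visibility duration (mLMV).
#' Per landmark: counts of states where it was observed individually
#' (combination of size 1), in combination (size >= 2), their accumulated
#' sum, and each as a fraction of the total number of states across all
#' workflows.
#'
#' @param workflows List of `fess_workflow`.
#' @param landmarks Landmark universe; defaults to names observed.
#' @return List with `per_workflow` and `per_landmark` data.frames, `totals`.
#' @export
corpus_statistics <- function(workflows, landmarks = NULL) {
  per_wf <- data.frame(
    workflow_id = vapply(workflows, `[[`, "", "workflow_id"),
    steps = vapply(workflows, function(w) length(w$states), 0L),
    duration_s = vapply(workflows, function(w) {
      if (!length(w$states)) return(0)
      w$states[[length(w$states)]]$end_s - w$states[[1]]$start_s
    }, 0),
    lmc = vapply(workflows, function(w) {
      length(unique(vapply(w$states,
                           function(s) paste(sort(s$combination), collapse = "+"), "")))
    }, 0L),
    mlmv_s = vapply(workflows, function(w) {
      mean(vapply(w$states, function(s) s$end_s - s$start_s, 0))
    }, 0)
  )
  all_states <- unlist(lapply(workflows, `[[`, "states"), recursive = FALSE)
  total_states <- length(all_states)
  combos <- lapply(all_states, `[[`, "combination")
  if (is.null(landmarks)) landmarks <- sort(unique(unlist(combos)))
  sizes <- lengths(combos)
  per_lm <- data.frame(landmark = landmarks)
  per_lm$individual <- vapply(landmarks, function(lm) {
    sum(sizes == 1 & vapply(combos, function(c) lm %in% c, TRUE))
  }, 0L)
  per_lm$in_combination <- vapply(landmarks, function(lm) {
    sum(sizes >= 2 & vapply(combos, function(c) lm %in% c, TRUE))
  }, 0L)
  per_lm$accumulated <- per_lm$individual + per_lm$in_combination
  per_lm$individual_fraction <- per_lm$individual / total_states
  per_lm$in_combination_fraction <- per_lm$in_combination / total_states
  per_lm$accumulated_fraction <- per_lm$accumulated / total_states
  list(per_workflow = per_wf, per_landmark = per_lm,
       totals = list(n_workflows = length(workflows),
                     total_states = total_states,
                     mean_steps = mean(per_wf$steps),
                     mean_duration_s = mean(per_wf$duration_s),
                     mean_lmc = mean(per_wf$lmc),
                     mean_mlmv_s = mean(per_wf$mlmv_s)))
}
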