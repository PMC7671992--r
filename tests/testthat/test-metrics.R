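test_that("BLEU-1 clips unigram matches and applies the brevity penalty", {
  expect_equal(bleu1(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(bleu1(c("x", "y"), c("a", "b")), 0)
  # clipping: 'a' matches at most once, 2/3 matched, prediction not shorter
  expect_equal(bleu1(c("a", "a", "b"), c("a", "b", "c")), 2 / 3)
  # brevity penalty for a shorter prediction
  expect_equal(bleu1(c("a"), c("a", "b")), 1 * exp(1 - 2))
  expect_equal(bleu1(character(0), c("a")), 0)
  expect_error(bleu1(c("a"), character(0)), "non-empty")
})

test_that("ROUGE-L recall is LCS over reference length", {
  expect_equal(rougeL_recall(c("a", "b", "d"), c("a", "b", "c", "d")), 3 / 4)
  expect_equal(rougeL_recall(c("a", "b"), c("a", "b")), 1)
  expect_equal(rougeL_recall(character(0), c("a", "b")), 0)
  expect_equal(rougeL_recall(c("d", "c", "b", "a"), c("a", "b", "c", "d")), 1 / 4)
})

test_that("similarity metrics agree with independent implementations", {
  set.seed(61)
  for (i in 1:100) {
    a <- random_template_sentence()
    b <- if (runif(1) < 0.3) a else random_template_sentence()
    if (runif(1) < 0.3) b <- as_sentence(sample(as.character(b)))  # scramble
    expect_equal(bleu1(a, b), oracle_bleu1(a, b), tolerance = 1e-6)
    expect_equal(rougeL_recall(a, b), oracle_rougeL(a, b), tolerance = 1e-6)
  }
})

test_that("F1_BR is the harmonic mean with its boundary identities", {
  expect_equal(f1_br(0.73, 0.77), 2 * 0.73 * 0.77 / (0.73 + 0.77))
  expect_equal(f1_br(0.4, 0.4), 0.4)
  expect_equal(f1_br(0, 0.9), 0)
  expect_equal(f1_br(0, 0), 0)
  set.seed(62)
  for (i in 1:50) {
    b <- runif(1, 0.01, 1); r <- runif(1, 0.01, 1)
    f <- f1_br(b, r)
    expect_lte(f, max(b, r))
    expect_gte(f, min(b, r))
  }
})

test_that("Jaccard distance is set-based dissimilarity", {
  expect_equal(jaccard_distance(c("a", "b"), c("a", "b")), 0)
  expect_equal(jaccard_distance(c("a"), c("b")), 1)
  expect_equal(jaccard_distance(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_equal(jaccard_distance(character(0), character(0)), 0)
  expect_equal(jaccard_distance(c("a", "a", "b"), c("a", "b")), 0)  # sets
})

test_that("slot precision/recall matches confusion-matrix arithmetic", {
  ont <- default_ontology()
  mk <- function(step, comb, dir) {
    state_to_sentence(navigation_state(step, comb, dir, 0, 1, ont))
  }
  targets <- list(mk(1, "middle_nasal_concha", "dwell"),
                  mk(2, "middle_nasal_meatus", "inwards"),
                  mk(3, "middle_nasal_meatus", "dwell"),
                  mk(4, "ethmoidal_bulla", "inwards"))
  # one direction confusion on the second pair, all else perfect
  preds <- targets
  preds[[2]] <- mk(2, "middle_nasal_meatus", "dwell")
  res <- slot_precision_recall(list(predicted = preds, target = targets))
  ps <- res$per_slot
  expect_equal(ps$precision[ps$slot == "step_count"], 1)
  expect_equal(ps$recall[ps$slot == "landmark_combination"], 1)
  # direction: dwell predicted 3x with 2 correct (P 2/3, R 1), inwards
  # predicted 1x correct (P 1, R 1/2) -> macro P 5/6, macro R 3/4
  expect_equal(ps$precision[ps$slot == "direction"], (2 / 3 + 1) / 2)
  expect_equal(ps$recall[ps$slot == "direction"], (1 + 1 / 2) / 2)
  expect_equal(unname(res$overall["precision"]), mean(ps$precision))
  expect_equal(res$f1, f1_br(mean(ps$precision), mean(ps$recall)))

  perfect <- slot_precision_recall(list(predicted = targets, target = targets))
  expect_true(all(perfect$per_slot$precision == 1))
  expect_true(all(perfect$per_slot$recall == 1))

  # malformed predictions are skipped and counted
  broken <- preds
  broken[[4]] <- as_sentence(c("not", "a", "template"))
  res_b <- slot_precision_recall(list(predicted = broken, target = targets))
  expect_equal(res_b$n_malformed, 1L)
})

test_that("landmark precision/recall scores occurrences in combinations", {
  targ <- list("middle_nasal_concha",
               c("middle_nasal_concha", "middle_nasal_meatus"),
               "ethmoidal_bulla",
               "middle_nasal_meatus")
  pred <- list("middle_nasal_concha",
               "middle_nasal_concha",
               c("ethmoidal_bulla", "middle_nasal_concha"),
               "out_of_patient")
  res <- landmark_precision_recall(pred, targ)
  pl <- res$per_landmark
  row <- function(lm) pl[pl$landmark == lm, ]
  # concha predicted at steps 1,2,3; in target at 1,2 -> P 2/3, R 1
  expect_equal(row("middle_nasal_concha")$precision, 2 / 3)
  expect_equal(row("middle_nasal_concha")$recall, 1)
  # meatus never predicted but present twice -> precision undefined, recall 0
  expect_true(is.na(row("middle_nasal_meatus")$precision))
  expect_equal(row("middle_nasal_meatus")$recall, 0)
  # out_of_patient predicted once, never present -> P 0, recall undefined
  expect_equal(row("out_of_patient")$precision, 0)
  expect_true(is.na(row("out_of_patient")$recall))
  # a landmark absent on both sides is excluded from the macro mean
  res2 <- landmark_precision_recall(pred, targ,
                                    landmarks = c(unique(unlist(c(pred, targ))),
                                                  "spheno_ethmoidal_recess"))
  expect_equal(res2$overall, res$overall)
  expect_error(landmark_precision_recall(pred[1:2], targ), "length")

  perfect <- landmark_precision_recall(targ, targ)
  expect_equal(unname(perfect$overall), c(1, 1))
  expect_equal(perfect$f1, 1)
})

test_that("corpus statistics count landmarks individually and in combination", {
  wfA <- toy_workflow(list("middle_nasal_concha",
                           c("middle_nasal_concha", "middle_nasal_meatus"),
                           "out_of_patient"), id = "A")
  wfB <- toy_workflow(list(c("middle_nasal_concha", "ethmoidal_bulla"),
                           "middle_nasal_meatus"), id = "B")
  st <- corpus_statistics(list(wfA, wfB))
  expect_equal(st$totals$total_states, 5)
  lm <- st$per_landmark
  concha <- lm[lm$landmark == "middle_nasal_concha", ]
  expect_equal(concha$individual, 1L)
  expect_equal(concha$in_combination, 2L)
  expect_equal(concha$accumulated, 3L)
  expect_equal(concha$accumulated_fraction, 3 / 5)
  # accumulated = individual + in-combination for every landmark, same
  # denominator everywhere
  expect_equal(lm$accumulated, lm$individual + lm$in_combination)
  expect_equal(lm$accumulated_fraction * st$totals$total_states, lm$accumulated)
  # per-workflow columns
  pw <- st$per_workflow
  expect_equal(pw$lmc, c(3L, 2L))
  expect_equal(pw$steps, c(3L, 2L))
  expect_equal(pw$mlmv_s, c(5, 5))
})

test_that("reported clinical benchmark tables are arithmetically consistent", {
  ref <- reference_results()
  # translation F1 cells reproduce from the printed BLEU-1 / ROUGE-L cells
  tr <- ref$translation
  expect_equal(round_half_up(f1_br(tr$bleu1[tr$model == "s2s"],
                                   tr$rougeL_recall[tr$model == "s2s"])), 0.75)
  # accumulated counts and fractions
  ld <- ref$landmark_distribution
  expect_equal(ld$accumulated, ld$individual + ld$in_combination)
  total <- attr(ld, "total_activities")
  concha <- ld[ld$landmark == "middle_nasal_concha", ]
  expect_equal(concha$individual + concha$in_combination, 1966L)
  expect_equal(round_half_up(concha$accumulated / total), 0.51)
  expect_equal(round_half_up(ld$accumulated / total), ld$accumulated_fraction)
})
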