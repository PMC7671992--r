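#' Reported benchmark values from the clinical FESS annotation study
#'
#' The evaluation protocol implemented here follows a clinical study of 22
#' annotated FESS procedures (3850 navigation activities). The recordings
#' themselves were never released, but the study's published summary tables
#' are reproduced as machine-readable data so that the arithmetic relations
#' between their cells (accumulated counts, observation fractions, macro
#' means, F1 scores) can be recomputed and checked against this package's
#' metric implementations.
#'
#' @return A list of data.frames:
#' \describe{
#'   \item{landmark_distribution}{per landmark: observation counts
#'     individually, in combination, and the printed fractions; plus the
#'     total activity count (3850).}
#'   \item{translation}{per sentence model: printed BLEU-1, Jaccard distance,
#'     ROUGE-L recall and F1 translation accuracy.}
#'   \item{slot_accuracy}{per model and sentence slot: printed precision and
#'     recall, with the printed overall row and F1.}
#'   \item{landmark_accuracy}{per model and landmark: printed precision and
#'     recall, with the printed overall row and F1.}
#' }
#' @export
reference_results <- function() {
  landmark_distribution <- data.frame(
    landmark = c("middle_nasal_concha", "middle_nasal_meatus",
                 "maxillary_sinus_orifice", "out_of_patient",
                 "uncinate_process_of_ethmoid", "ethmoidal_bulla",
                 "spheno_ethmoidal_recess"),
    individual = c(885L, 539L, 425L, 492L, 60L, 67L, 31L),
    in_combination = c(1081L, 500L, 278L, 0L, 158L, 82L, 9L),
    accumulated = c(1966L, 1039L, 703L, 492L, 218L, 149L, 40L),
    accumulated_fraction = c(0.51, 0.27, 0.18, 0.13, 0.06, 0.04, 0.01)
  )
  attr(landmark_distribution, "total_activities") <- 3850L

  translation <- data.frame(
    model = c("s2s", "transformer"),
    bleu1 = c(0.73, 0.81),
    jaccard_distance = c(0.29, 0.24),
    rougeL_recall = c(0.77, 0.87),
    f1 = c(0.75, 0.83)
  )

  slot_accuracy <- data.frame(
    slot = rep(c("step_count", "sinus", "landmark_group",
                 "landmark_combination", "direction", "overall"), 2),
    model = rep(c("transformer", "s2s"), each = 6),
    precision = c(0.96, 0.74, 0.53, 0.53, 0.58, 0.67,
                  0.96, 0.57, 0.40, 0.32, 0.55, 0.56),
    recall = c(0.96, 0.73, 0.73, 0.60, 0.74, 0.75,
               0.96, 0.51, 0.38, 0.29, 0.75, 0.57)
  )
  attr(slot_accuracy, "f1") <- c(transformer = 0.70, s2s = 0.57)

  lms <- c("middle_nasal_concha", "middle_nasal_meatus",
           "maxillary_sinus_orifice", "out_of_patient",
           "uncinate_process_of_ethmoid", "ethmoidal_bulla",
           "spheno_ethmoidal_recess", "overall")
  landmark_accuracy <- data.frame(
    landmark = rep(lms, 4),
    model = rep(c("transformer", "lstm", "hmm", "s2s"), each = 8),
    precision = c(0.62, 0.81, 0.52, 0.50, 0.38, 0.42, 0.50, 0.53,
                  0.67, 0.69, 0.36, 0.31, 0.19, 0.22, 0.00, 0.34,
                  0.83, 0.94, 0.35, 0.00, 0.00, 0.00, 0.00, 0.30,
                  0.42, 0.36, 0.27, 0.24, 0.22, 0.20, 0.50, 0.31),
    recall = c(0.65, 0.71, 0.59, 0.43, 0.34, 0.49, 0.54, 0.53,
               0.70, 0.65, 0.39, 0.20, 0.22, 0.31, 0.00, 0.35,
               0.62, 0.67, 0.58, 0.00, 0.00, 0.00, 0.00, 0.27,
               0.45, 0.41, 0.35, 0.34, 0.20, 0.24, 0.23, 0.32)
  )
  attr(landmark_accuracy, "f1") <- c(transformer = 0.53, lstm = 0.35,
                                     hmm = 0.28, s2s = 0.32)

  list(landmark_distribution = landmark_distribution,
       translation = translation,
       slot_accuracy = slot_accuracy,
       landmark_accuracy = landmark_accuracy)
}
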