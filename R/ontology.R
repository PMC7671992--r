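#' Spatial ontology of FESS navigation landmarks
#'
#' A spatial ontology is a table of anatomical landmarks, each with a depth
#' rank (its position along the anterior-to-posterior endoscopic approach,
#' larger = deeper), a landmark group and a main cavity. The depth ranks
#' encode the "spatially follows / spatially precedes" relation used to
#' derive movement directions: moving to a deeper landmark is an inwards
#' movement, to a shallower one outwards, and between equally ranked
#' landmarks a dwell.
#'
#' @param landmarks A data.frame with columns `name`, `depth_rank`, `group`,
#'   `cavity`. Names must be unique, ranks non-negative integers.
#' @return An object of class `fess_ontology`: the validated data.frame with
#'   a fast name lookup attached.
#' @seealso [default_ontology()] for the built-in FESS table,
#'   [infer_direction()] for the direction rule.
#' @export
spatial_ontology <- function(landmarks) {
  stopifnot(is.data.frame(landmarks))
  req <- c("name", "depth_rank", "group", "cavity")
  missing_cols <- setdiff(req, names(landmarks))
  if (length(missing_cols)) {
    stop("ontology table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  landmarks <- landmarks[, req]
  landmarks$name <- as.character(landmarks$name)
  landmarks$depth_rank <- as.integer(landmarks$depth_rank)
  landmarks$group <- as.character(landmarks$group)
  landmarks$cavity <- as.character(landmarks$cavity)
  if (anyDuplicated(landmarks$name)) {
    stop("duplicate landmark names in ontology: ",
         paste(unique(landmarks$name[duplicated(landmarks$name)]), collapse = ", "))
  }
  if (any(landmarks$depth_rank < 0)) stop("depth_rank must be >= 0")
  if (any(is.na(landmarks$depth_rank))) stop("depth_rank must be an integer")
  structure(landmarks, class = c("fess_ontology", "data.frame"))
}

#' Built-in FESS landmark ontology
#'
#' Seven landmarks of the standard FESS approach, ranked from the outside of
#' the patient (rank 0) through the middle nasal concha and meatus into the
#' ethmoid, maxillary and sphenoid regions. The uncinate process and the
#' ethmoidal bulla share a rank: they face each other across the ethmoidal
#' infundibulum, so passing between them is neither clearly inwards nor
#' outwards. Ranks are configuration, not anatomy carved in stone; supply
#' your own table to [spatial_ontology()] to change the ordering.
#'
#' @return A `fess_ontology` object with 7 landmarks.
#' @export
default_ontology <- function() {
  spatial_ontology(data.frame(
    name = c("out_of_patient", "middle_nasal_concha", "middle_nasal_meatus",
             "uncinate_process_of_ethmoid", "ethmoidal_bulla",
             "maxillary_sinus_orifice", "spheno_ethmoidal_recess"),
    depth_rank = c(0L, 1L, 2L, 3L, 3L, 4L, 5L),
    group = c("external_group", "concha_group", "meatus_group",
              "ethmoid_group", "ethmoid_group", "maxillary_group",
              "sphenoid_group"),
    cavity = c("external", "nasal_cavity", "nasal_cavity", "ethmoidal_sinus",
               "ethmoidal_sinus", "maxillary_sinus", "sphenoidal_sinus"),
    stringsAsFactors = FALSE
  ))
}

#' Read an ontology from a JSON file
#'
#' The file holds a JSON array of objects with fields `name`, `depth_rank`,
#' `group` and `cavity`.
#'
#' @param path Path to the JSON file.
#' @return A `fess_ontology`.
#' @export
read_ontology <- function(path) {
  spatial_ontology(jsonlite::fromJSON(path))
}

ontology_rank <- function(ont, names) {
  idx <- match(names, ont$name)
  if (anyNA(idx)) {
    stop("unknown landmark name(s): ", paste(names[is.na(idx)], collapse = ", "))
  }
  ont$depth_rank[idx]
}

#' Representative depth rank of a landmark combination
#'
#' The deepest visible landmark determines how far the endoscope has
#' advanced, so the representative rank of a combination is the maximum rank
#' among its members.
#'
#' @param combination Character vector of landmark names (size 1-3).
#' @param ont A `fess_ontology`.
#' @return A single integer rank.
#' @export
combination_rank <- function(combination, ont) {
  if (!length(combination)) stop("landmark combination must be non-empty")
  max(ontology_rank(ont, combination))
}

#' Infer the movement direction between two landmark combinations
#'
#' The direction of endoscope movement between two consecutive states is
#' derived from the spatial ontology: `inwards` when the current combination
#' spatially follows the previous one (deeper representative rank),
#' `outwards` when it spatially precedes it, and `dwell` when the two are
#' spatially equivalent. The first state of a workflow, which has no
#' predecessor, is a `dwell`.
#'
#' @param prev Character vector of landmark names of the previous state, or
#'   `NULL` for the first state.
#' @param curr Character vector of landmark names of the current state.
#' @param ont A `fess_ontology`.
#' @return One of `"inwards"`, `"outwards"`, `"dwell"`.
#' @export
infer_direction <- function(prev, curr, ont) {
  rc <- combination_rank(curr, ont)
  if (is.null(prev) || !length(prev)) return("dwell")
  rp <- combination_rank(prev, ont)
  if (rc > rp) "inwards" else if (rc < rp) "outwards" else "dwell"
}

DIRECTIONS <- c("inwards", "outwards", "dwell")

#' Construct a navigation state
#'
#' One timed endoscope state: the step count within its workflow, the main
#' cavity, the landmark group, the set of simultaneously visible landmarks
#' (1-3 of them), the movement direction relative to the previous state, and
#' the time interval of visibility in seconds.
#'
#' Cavity and group default to the ontology entry of the combination's
#' representative (deepest) landmark.
#'
#' @param step_count Positive integer.
#' @param combination Character vector of 1-3 landmark names.
#' @param direction One of `"inwards"`, `"outwards"`, `"dwell"`.
#' @param start_s,end_s Interval in seconds, `end_s >= start_s`.
#' @param ont A `fess_ontology`.
#' @param cavity,group Optional overrides; default from the ontology.
#' @return A list of class `fess_state`.
#' @export
navigation_state <- function(step_count, combination, direction, start_s, end_s,
                             ont, cavity = NULL, group = NULL) {
  if (length(combination) < 1 || length(combination) > 3) {
    stop("landmark combination must contain 1 to 3 landmarks")
  }
  direction <- match.arg(direction, DIRECTIONS)
  rep_lm <- representative_landmark(combination, ont)
  i <- match(rep_lm, ont$name)
  structure(list(
    step_count = as.integer(step_count),
    cavity = if (is.null(cavity)) ont$cavity[i] else cavity,
    landmark_group = if (is.null(group)) ont$group[i] else group,
    combination = canonical_combination(combination, ont),
    direction = direction,
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s)
  ), class = "fess_state")
}

# Deepest landmark of a combination; rank ties broken alphabetically so the
# representative (and hence cavity/group) is deterministic.
representative_landmark <- function(combination, ont) {
  r <- ontology_rank(ont, combination)
  cand <- combination[r == max(r)]
  sort(cand)[length(cand)]  # deepest, last alphabetically among ties
}

# Canonical order: by depth rank, ties alphabetical.
canonical_combination <- function(combination, ont) {
  r <- ontology_rank(ont, combination)
  combination[order(r, combination)]
}

#' Construct a navigation workflow
#'
#' @param workflow_id Identifier string.
#' @param states List of `fess_state` objects, step counts 1..n.
#' @return A list of class `fess_workflow`.
#' @export
navigation_workflow <- function(workflow_id, states) {
  structure(list(workflow_id = as.character(workflow_id), states = states),
            class = "fess_workflow")
}

#' @export
print.fess_workflow <- function(x, ...) {
  cat(sprintf("<fess_workflow '%s': %d states, %.0f s>\n", x$workflow_id,
              length(x$states),
              if (length(x$states)) x$states[[length(x$states)]]$end_s else 0))
  invisible(x)
}

#' Validate a navigation workflow against its invariants
#'
#' Checks every state invariant (combination size, time ordering, known
#' landmarks, cavity/group consistency with the ontology, direction
#' consistency with the depth-rank rule) plus workflow-level invariants
#' (step counts consecutive from 1, non-decreasing times). Violations are
#' returned, not raised.
#'
#' @param workflow A `fess_workflow`.
#' @param ont A `fess_ontology`.
#' @return Character vector of violation messages; empty if valid.
#' @export
validate_workflow <- function(workflow, ont) {
  v <- character(0)
  states <- workflow$states
  if (!length(states)) return("empty: workflow has no states")
  prev_comb <- NULL
  prev_end <- -Inf
  for (k in seq_along(states)) {
    s <- states[[k]]
    if (s$step_count != k) {
      v <- c(v, sprintf("gap: state %d has step_count %d", k, s$step_count))
    }
    n_lm <- length(s$combination)
    if (n_lm < 1 || n_lm > 3) {
      v <- c(v, sprintf("size: state %d has combination of size %d", k, n_lm))
    }
    unknown <- setdiff(s$combination, ont$name)
    if (length(unknown)) {
      v <- c(v, sprintf("unknown: state %d uses landmark(s) %s", k,
                        paste(unknown, collapse = ", ")))
      prev_comb <- NULL
      next
    }
    if (s$end_s < s$start_s) {
      v <- c(v, sprintf("time: state %d has end_s < start_s", k))
    }
    if (s$start_s < prev_end) {
      v <- c(v, sprintf("time: state %d starts before state %d ends", k, k - 1))
    }
    rep_lm <- representative_landmark(s$combination, ont)
    i <- match(rep_lm, ont$name)
    if (!identical(s$cavity, ont$cavity[i])) {
      v <- c(v, sprintf("cavity: state %d has '%s', ontology says '%s'", k,
                        s$cavity, ont$cavity[i]))
    }
    if (!identical(s$landmark_group, ont$group[i])) {
      v <- c(v, sprintf("group: state %d has '%s', ontology says '%s'", k,
                        s$landmark_group, ont$group[i]))
    }
    expected_dir <- infer_direction(prev_comb, s$combination, ont)
    if (!identical(s$direction, expected_dir)) {
      v <- c(v, sprintf("direction: state %d is '%s', rank rule says '%s'", k,
                        s$direction, expected_dir))
    }
    prev_comb <- s$combination
    prev_end <- s$end_s
  }
  v
}
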