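#' Read timed landmark annotation records
#'
#' Annotation records are timed intervals during which a landmark combination
#' was visible in the endoscopic view. Two on-disk schemas are supported:
#'
#' * `csv`: columns `start_s,end_s,landmarks`, with landmark names joined by
#'   `;` inside the `landmarks` field.
#' * `json`: an object `{"workflow_id": ..., "records": [{"start_s": ...,
#'   "end_s": ..., "landmarks": [...]}, ...]}`.
#'
#' Records are returned sorted by start time. In `strict` mode overlapping
#' records are an error; in `lenient` mode the earlier record is truncated at
#' the start of the later one.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default guessed from the extension.
#' @param ont Ontology used to validate landmark names.
#' @param mode `"strict"` (default) or `"lenient"` overlap handling.
#' @return A data.frame with columns `start_s`, `end_s` and list-column
#'   `landmarks`, plus attribute `workflow_id` when the file provides one.
#' @export
read_annotations <- function(path, format = c("auto", "csv", "json"),
                             ont = default_ontology(),
                             mode = c("strict", "lenient")) {
  format <- match.arg(format)
  mode <- match.arg(mode)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  wf_id <- NULL
  if (format == "csv") {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(raw)) stop("no records in ", path)
    req <- c("start_s", "end_s", "landmarks")
    if (!all(req %in% names(raw))) {
      stop("annotation CSV must have columns start_s, end_s, landmarks")
    }
    recs <- data.frame(start_s = as.numeric(raw$start_s),
                       end_s = as.numeric(raw$end_s))
    recs$landmarks <- strsplit(as.character(raw$landmarks), ";", fixed = TRUE)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    wf_id <- obj$workflow_id
    if (!length(obj$records)) stop("no records in ", path)
    recs <- data.frame(
      start_s = vapply(obj$records, function(r) as.numeric(r$start_s), 0),
      end_s = vapply(obj$records, function(r) as.numeric(r$end_s), 0)
    )
    recs$landmarks <- lapply(obj$records, function(r) as.character(unlist(r$landmarks)))
  }
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    if (is.na(r$start_s) || is.na(r$end_s)) {
      stop(sprintf("malformed record at row %d: non-numeric time", i))
    }
    if (r$end_s < r$start_s) {
      stop(sprintf("malformed record at row %d: end_s < start_s", i))
    }
    lms <- trimws(recs$landmarks[[i]])
    if (!length(lms) || any(!nzchar(lms))) {
      stop(sprintf("malformed record at row %d: empty landmark list", i))
    }
    unknown <- setdiff(lms, ont$name)
    if (length(unknown)) {
      stop(sprintf("row %d: unknown landmark name(s): %s", i,
                   paste(unknown, collapse = ", ")))
    }
    recs$landmarks[[i]] <- lms
  }
  recs <- recs[order(recs$start_s), , drop = FALSE]
  rownames(recs) <- NULL
  if (nrow(recs) > 1) {
    for (i in seq_len(nrow(recs) - 1)) {
      if (recs$end_s[i] > recs$start_s[i + 1]) {
        if (mode == "strict") {
          stop(sprintf("records %d and %d overlap in time", i, i + 1))
        }
        recs$end_s[i] <- recs$start_s[i + 1]
      }
    }
  }
  attr(recs, "workflow_id") <- wf_id
  recs
}

#' Derive a navigation workflow from annotation records
#'
#' Consecutive records showing the same landmark combination are merged into
#' one state (an annotation interval means continuous visibility), step
#' counts are assigned 1..n, and movement directions are filled in via
#' [infer_direction()].
#'
#' @param records Annotation records as returned by [read_annotations()].
#' @param ont A `fess_ontology`.
#' @param workflow_id Identifier; defaults to the records' attribute or "wf".
#' @return A `fess_workflow`.
#' @export
derive_workflow <- function(records, ont = default_ontology(),
                            workflow_id = NULL) {
  if (!nrow(records)) stop("cannot derive a workflow from zero records")
  if (is.null(workflow_id)) {
    workflow_id <- attr(records, "workflow_id")
    if (is.null(workflow_id)) workflow_id <- "wf"
  }
  combos <- lapply(records$landmarks, canonical_combination, ont = ont)
  states <- list()
  prev_comb <- NULL
  for (i in seq_len(nrow(records))) {
    if (length(states) && identical(combos[[i]], prev_comb)) {
      # continuation of the same visibility: extend the open state
      states[[length(states)]]$end_s <- records$end_s[i]
      next
    }
    k <- length(states) + 1L
    dir <- infer_direction(prev_comb, combos[[i]], ont)
    states[[k]] <- navigation_state(k, combos[[i]], dir,
                                    records$start_s[i], records$end_s[i], ont)
    prev_comb <- combos[[i]]
  }
  navigation_workflow(workflow_id, states)
}

#' Expand a workflow back into annotation records
#'
#' Inverse of [derive_workflow()] up to merging: one record per state.
#'
#' @param workflow A `fess_workflow`.
#' @return Annotation records data.frame.
#' @export
workflow_to_records <- function(workflow) {
  recs <- data.frame(
    start_s = vapply(workflow$states, `[[`, 0, "start_s"),
    end_s = vapply(workflow$states, `[[`, 0, "end_s")
  )
  recs$landmarks <- lapply(workflow$states, `[[`, "combination")
  attr(recs, "workflow_id") <- workflow$workflow_id
  recs
}

#' Write a workflow as an annotation JSON file
#'
#' @param workflow A `fess_workflow`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_workflow_json <- function(workflow, path) {
  obj <- list(
    workflow_id = workflow$workflow_id,
    records = lapply(workflow$states, function(s) {
      list(start_s = s$start_s, end_s = s$end_s, landmarks = as.list(s$combination))
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write sentence and pair corpora for a set of workflows
#'
#' For each workflow two files are written into `out_dir`:
#' `<id>.sentences.txt` with one navigation sentence per line (n lines for n
#' states) and `<id>.pairs.tsv` with source TAB target for every two
#' consecutive sentences (n-1 lines).
#'
#' @param workflows List of `fess_workflow` objects.
#' @param out_dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_corpus <- function(workflows, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create directory ", out_dir)
  }
  written <- character(0)
  for (wf in workflows) {
    sents <- vapply(wf$states, function(s) sentence_text(state_to_sentence(s)), "")
    sfile <- file.path(out_dir, paste0(wf$workflow_id, ".sentences.txt"))
    writeLines(sents, sfile, useBytes = TRUE)
    pfile <- file.path(out_dir, paste0(wf$workflow_id, ".pairs.tsv"))
    if (length(sents) > 1) {
      n <- length(sents)
      writeLines(paste(sents[-n], sents[-1], sep = "\t"), pfile, useBytes = TRUE)
    } else {
      writeLines(character(0), pfile, useBytes = TRUE)
    }
    written <- c(written, sfile, pfile)
  }
  invisible(written)
}

#' Read a sentence corpus file
#'
#' @param path One-sentence-per-line UTF-8 text file.
#' @return List of `fess_sentence` objects.
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines, function(l) as_sentence(strsplit(l, " ", fixed = TRUE)[[1]]))
}

#' Read a source/target pair corpus file
#'
#' @param path Two-column TSV file of sentence pairs.
#' @return List of `fess_pair` objects.
#' @export
read_pairs <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed pair line: ", l)
    sentence_pair(as_sentence(strsplit(parts[1], " ", fixed = TRUE)[[1]]),
                  as_sentence(strsplit(parts[2], " ", fixed = TRUE)[[1]]))
  })
}
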