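#' Navigation sentences
#'
#' A navigation sentence is the fixed-slot verbalization of one endoscope
#' state:
#'
#' ```
#' step <count> <cavity> <group> <landmark_1> ... <landmark_k> <direction>
#' ```
#'
#' with 1 <= k <= 3 landmarks, giving 6 to 8 tokens. Landmark tokens are
#' emitted in depth-rank order (ties alphabetical) so that every state has
#' exactly one surface form; any order is accepted on decode.
#'
#' @param tokens Character vector of tokens.
#' @return A `fess_sentence` (character vector with a class attribute).
#' @export
as_sentence <- function(tokens) {
  structure(as.character(tokens), class = "fess_sentence")
}

#' @export
print.fess_sentence <- function(x, ...) {
  cat(sentence_text(x), "\n")
  invisible(x)
}

#' Space-joined surface form of a sentence
#' @param sentence A `fess_sentence` or character vector of tokens.
#' @return A single string.
#' @export
sentence_text <- function(sentence) paste(sentence, collapse = " ")

#' Verbalize a navigation state as a sentence
#'
#' @param state A `fess_state`.
#' @return A `fess_sentence` of 6-8 tokens.
#' @seealso [sentence_to_state()] for the inverse.
#' @export
state_to_sentence <- function(state) {
  if (!length(state$combination)) stop("state has an empty landmark combination")
  as_sentence(c("step", as.character(state$step_count), state$cavity,
                state$landmark_group, state$combination, state$direction))
}

#' Parse a navigation sentence back into a state
#'
#' Inverse of [state_to_sentence()]. The sentence must follow the fixed-slot
#' template; landmark tokens may appear in any order and are canonicalized.
#' Times are not represented in sentences, so `start_s`/`end_s` are 0.
#'
#' @param sentence A `fess_sentence` or character vector of tokens.
#' @param ont A `fess_ontology` used to validate landmarks, cavity and group.
#' @return A `fess_state`.
#' @export
sentence_to_state <- function(sentence, ont = default_ontology()) {
  tok <- as.character(sentence)
  if (length(tok) < 6) stop("sentence too short: expected at least 6 tokens")
  if (length(tok) > 8) stop("sentence too long: expected at most 8 tokens")
  if (tok[1] != "step") stop("malformed step slot: expected literal 'step'")
  count <- suppressWarnings(as.integer(tok[2]))
  if (is.na(count) || count < 1) stop("malformed count slot: '", tok[2], "'")
  direction <- tok[length(tok)]
  if (!direction %in% DIRECTIONS) {
    stop("malformed direction slot: '", direction, "'")
  }
  lms <- tok[5:(length(tok) - 1)]
  unknown <- setdiff(lms, ont$name)
  if (length(unknown)) {
    stop("unknown landmark name(s): ", paste(unknown, collapse = ", "))
  }
  st <- navigation_state(count, lms, direction, 0, 0, ont)
  if (!identical(st$cavity, tok[3])) {
    stop("malformed cavity slot: '", tok[3], "' (ontology says '", st$cavity, "')")
  }
  if (!identical(st$landmark_group, tok[4])) {
    stop("malformed group slot: '", tok[4], "' (ontology says '",
         st$landmark_group, "')")
  }
  st
}

#' A source/target sentence pair
#' @param source,target `fess_sentence` objects from consecutive steps of the
#'   same workflow.
#' @return A `fess_pair`.
#' @export
sentence_pair <- function(source, target) {
  structure(list(source = source, target = target), class = "fess_pair")
}

#' Pair every two consecutive sentences of a workflow
#'
#' Pairs never cross workflow boundaries: call once per workflow (or use
#' [corpus_pairs()] over many workflows).
#'
#' @param sentences List of `fess_sentence` objects in workflow order.
#' @return List of n-1 `fess_pair` objects (empty if fewer than 2 sentences).
#' @export
make_pairs <- function(sentences) {
  n <- length(sentences)
  if (n < 2) return(list())
  lapply(seq_len(n - 1), function(i) sentence_pair(sentences[[i]], sentences[[i + 1]]))
}

#' Sentences of a workflow
#' @param workflow A `fess_workflow`.
#' @return List of `fess_sentence`, one per state.
#' @export
workflow_sentences <- function(workflow) {
  lapply(workflow$states, state_to_sentence)
}

#' All consecutive sentence pairs of a corpus of workflows
#' @param workflows List of `fess_workflow`.
#' @return List of `fess_pair`; sum over workflows of (n_i - 1) pairs.
#' @export
corpus_pairs <- function(workflows) {
  unlist(lapply(workflows, function(wf) make_pairs(workflow_sentences(wf))),
         recursive = FALSE)
}

# reserved vocabulary indices (0-based, as stored in the token table)
PAD_IDX <- 0L
SOS_IDX <- 1L
EOS_IDX <- 2L
UNK_IDX <- 3L

#' Build a token vocabulary from sentences
#'
#' Reserved indices: PAD=0, SOS=1, EOS=2, UNK=3. Step-count numerals are
#' covered up to `max_step` regardless of whether they occur in the corpus;
#' numerals above the cap map to UNK.
#'
#' @param sentences List of `fess_sentence` (typically the training corpus).
#' @param max_step Largest step numeral given its own token (default 999).
#' @return A `fess_vocab`: list with `tokens` (index->token, 0-based offset)
#'   and `index` (token->index lookup).
#' @export
build_vocabulary <- function(sentences, max_step = 999L) {
  toks <- unique(unlist(lapply(sentences, as.character)))
  is_num <- grepl("^[0-9]+$", toks)
  words <- sort(toks[!is_num])
  numerals <- as.character(seq_len(max_step))
  tokens <- c("<pad>", "<sos>", "<eos>", "<unk>", words, numerals)
  index <- stats::setNames(seq_along(tokens) - 1L, tokens)
  structure(list(tokens = tokens, index = index, max_step = as.integer(max_step)),
            class = "fess_vocab")
}

#' @export
print.fess_vocab <- function(x, ...) {
  cat(sprintf("<fess_vocab: %d tokens (max step numeral %d)>\n",
              length(x$tokens), x$max_step))
  invisible(x)
}

#' Vocabulary size
#' @param vocab A `fess_vocab`.
#' @return Integer number of tokens including the reserved ones.
#' @export
vocab_size <- function(vocab) length(vocab$tokens)

#' Encode a sentence as 0-based token indices
#'
#' Prepends SOS and appends EOS; out-of-vocabulary tokens (including step
#' numerals above the cap) become UNK.
#'
#' @param sentence A `fess_sentence` or character vector.
#' @param vocab A `fess_vocab`.
#' @return Integer vector of indices.
#' @export
encode_sentence <- function(sentence, vocab) {
  idx <- vocab$index[as.character(sentence)]
  idx[is.na(idx)] <- UNK_IDX
  c(SOS_IDX, unname(idx), EOS_IDX)
}

#' Decode token indices back into a sentence
#'
#' Strips PAD/SOS/EOS.
#'
#' @param indices Integer vector of 0-based indices.
#' @param vocab A `fess_vocab`.
#' @return A `fess_sentence`.
#' @export
decode_indices <- function(indices, vocab) {
  keep <- !(indices %in% c(PAD_IDX, SOS_IDX, EOS_IDX))
  as_sentence(vocab$tokens[indices[keep] + 1L])
}

#' Write a vocabulary to JSON
#' @param vocab A `fess_vocab`.
#' @param path Output path; written as an object token -> index.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(as.list(vocab$index), path, auto_unbox = TRUE)
  invisible(path)
}

#' Class-id map over landmark combinations
#'
#' Assigns a stable integer id (0-based, first-seen order) to every distinct
#' landmark combination across a corpus. The canonical sorted combination is
#' the key, so the same combination gets the same id in every workflow.
#'
#' @param workflows List of `fess_workflow`.
#' @return A `fess_classmap`: list with `keys` (id -> canonical key string)
#'   and combination lists.
#' @export
build_class_map <- function(workflows) {
  keys <- character(0)
  combos <- list()
  for (wf in workflows) {
    for (s in wf$states) {
      key <- paste(sort(s$combination), collapse = "+")
      if (!key %in% keys) {
        keys <- c(keys, key)
        combos[[length(combos) + 1]] <- sort(s$combination)
      }
    }
  }
  structure(list(keys = keys, combinations = combos), class = "fess_classmap")
}

#' Number of distinct combination classes
#' @param class_map A `fess_classmap`.
#' @return Integer.
#' @export
n_classes <- function(class_map) length(class_map$keys)

#' Class-id sequence of a workflow
#'
#' One integer per state: the id of its landmark combination under
#' `class_map`.
#'
#' @param workflow A `fess_workflow`.
#' @param class_map A `fess_classmap` built over the corpus.
#' @return Integer vector of 0-based class ids.
#' @export
to_class_sequence <- function(workflow, class_map) {
  vapply(workflow$states, function(s) {
    key <- paste(sort(s$combination), collapse = "+")
    id <- match(key, class_map$keys)
    if (is.na(id)) stop("combination not in class map: ", key)
    id - 1L
  }, integer(1))
}
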