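# Negation handling: cue detection, rule-based word-level scope labeling,
# and entity-level aggregation by label-frequency voting.
#
# The word-level labeler is a deterministic clause-boundary rule standing in
# behind the same interface a learned scope model would use; the
# entity-level aggregation (majority vote over word labels) is the part the
# rest of the pipeline depends on.

#' Load the negation cue dictionary
#'
#' @param path plain-text resource, one cue per line; defaults to the
#'   bundled set ("not", "no", "without", "except", "other than", ...).
#' @return character vector of cues, multi-word allowed.
#' @export
default_negation_cues <- function(path = cc_options()$cue_file) {
  cc_read_lines(path)
}

#' Ensure a sentence ends with terminal punctuation
#'
#' Scope detection over list-formatted criteria fails at the missing
#' sentence-final period; this appends one when the text does not already
#' end in `.`, `!`, `?` or `;`. Applied as mandatory preprocessing by
#' [apply_negation()].
#'
#' @param sentence_text input text.
#' @return the text, terminated.
#' @export
ensure_terminal_period <- function(sentence_text) {
  if (grepl("[.!?;]\\s*$", sentence_text)) sentence_text
  else paste0(sentence_text, ".")
}

#' Detect negation cues in a sentence
#'
#' Finds all non-overlapping cue occurrences on word boundaries,
#' case-insensitively; at a given position the longest cue wins ("other
#' than" beats "other").
#'
#' @param sentence_text the sentence.
#' @param cues character vector of cues.
#' @return data.frame with columns cue, start, end (0-based half-open).
#' @export
detect_negation_cues <- function(sentence_text, cues = default_negation_cues()) {
  stopifnot(length(cues) > 0)
  hits <- data.frame(cue = character(), start = integer(), end = integer(),
                     stringsAsFactors = FALSE)
  for (cue in cues[order(-nchar(cues))]) {
    pat <- paste0("(?i)\\b", gsub("\\s+", "\\\\s+", cue), "\\b")
    m <- gregexpr(pat, sentence_text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      s <- as.integer(m[i]) - 1L; e <- s + len[i]
      if (!any(hits$start < e & s < hits$end))  # longest cue claimed first
        hits <- rbind(hits, data.frame(cue = cc_slice(sentence_text, s, e),
                                       start = s, end = e,
                                       stringsAsFactors = FALSE))
    }
  }
  hits[order(hits$start), , drop = FALSE]
}

CLAUSE_CONJ <- c("with", "and", "or", "but", "within", "while", "whereas")

# character position (0-based) of the first clause boundary at or after
# `from`: sentence end, ';', or ',' immediately followed by a conjunction.
next_clause_boundary <- function(text, from) {
  n <- nchar(text)
  i <- from
  while (i < n) {
    ch <- substr(text, i + 1L, i + 1L)
    if (ch == ";") return(i)
    if (ch == ",") {
      rest <- substr(text, i + 2L, n)
      if (grepl(paste0("^\\s*(", paste(CLAUSE_CONJ, collapse = "|"), ")\\b"),
                rest, ignore.case = TRUE))
        return(i)
    }
    i <- i + 1L
  }
  n
}

#' Label word-level negation scope
#'
#' Deterministic rule labeler: every word after a cue up to the next clause
#' boundary is `in_scope`; all other words (including the cue words
#' themselves) are `out_of_scope`. Clause boundaries are the sentence end,
#' a semicolon, or a comma immediately followed by one of
#' with/and/or/but/within/while/whereas.
#'
#' @param sentence_text the (period-terminated) sentence.
#' @param cue_spans cue data.frame from [detect_negation_cues()].
#' @param tokens optional precomputed token table.
#' @return data.frame with columns token, start, end, label (one label per
#'   word).
#' @export
label_word_scope <- function(sentence_text, cue_spans, tokens = NULL) {
  tokens <- tokens %||% cc_tokenize(sentence_text)
  labels <- rep("out_of_scope", nrow(tokens))
  if (!is.null(cue_spans) && nrow(cue_spans)) {
    for (i in seq_len(nrow(cue_spans))) {
      lo <- cue_spans$end[i]
      hi <- next_clause_boundary(sentence_text, lo)
      labels[tokens$start >= lo & tokens$end <= hi] <- "in_scope"
    }
  }
  tokens$label <- labels
  tokens
}

#' Aggregate word labels to an entity-level negation flag
#'
#' The entity is negated iff `in_scope` labels outnumber `out_of_scope`
#' labels among the words its span covers; an exact tie counts as negated
#' (conservative for exclusion criteria).
#'
#' @param word_labels labeled token table from [label_word_scope()].
#' @param entity an [entity_annotation()] (only `start`/`end` are used).
#' @return logical: negated or not. An entity overlapping zero words is a
#'   `scope_alignment_error` (offset/tokenization mismatch).
#' @export
aggregate_entity_scope <- function(word_labels, entity) {
  hit <- word_labels$start < entity$end & entity$start < word_labels$end
  if (!any(hit))
    cc_stop("scope_alignment_error",
            sprintf("entity span [%d,%d) covers no words", entity$start, entity$end))
  n_in <- sum(word_labels$label[hit] == "in_scope")
  n_out <- sum(word_labels$label[hit] == "out_of_scope")
  n_in >= n_out
}

#' Apply negation detection to every criterion
#'
#' Runs terminal-period preprocessing, cue detection, word-level scope
#' labeling and entity-level aggregation over each criterion sentence,
#' setting the `negated` flag of every non-cue entity. Idempotent: the flag
#' is recomputed from scratch each call.
#'
#' @param rep a `criteria_representation` with recognized entities.
#' @param cues cue dictionary.
#' @return the updated representation.
#' @export
apply_negation <- function(rep, cues = default_negation_cues()) {
  for (cr in rep$criteria) {
    key <- criterion_key(cr$section, cr$index)
    anns <- rep$annotations[[key]]
    if (is.null(anns) || !length(anns)) next
    text <- ensure_terminal_period(cr$text)
    cue_spans <- detect_negation_cues(text, cues)
    labels <- label_word_scope(text, cue_spans)
    rep$annotations[[key]] <- lapply(anns, function(a) {
      if (a$category != "Negation_cue")
        a$negated <- aggregate_entity_scope(labels, a)
      a
    })
  }
  rep
}
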