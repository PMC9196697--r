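# Lexicon + pattern entity recognizer. Deterministic by design: the
# recognizer sits behind recognize_entities() so a learned model can be
# substituted without touching downstream modules.

#' Load an entity lexicon
#'
#' @param path CSV with columns surface_form, category, concept_id,
#'   concept_name, domain, vocabulary, standard.
#' @return a `lexicon` object (data.frame); surface forms are lowercased
#'   and must be unique per (surface_form, category).
#' @export
read_lexicon <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_lexicon(d)
}

#' Build a lexicon from a data.frame
#'
#' @param d data.frame with the columns of [read_lexicon()].
#' @return a `lexicon` object.
#' @export
as_lexicon <- function(d) {
  d$surface_form <- tolower(trimws(d$surface_form))
  if (anyDuplicated(d[, c("surface_form", "category")]))
    cc_stop("validation_error", "duplicate (surface_form, category) in lexicon")
  d$n_words <- vapply(strsplit(d$surface_form, "\\s+"), length, 1L)
  structure(d[order(-d$n_words, d$surface_form), ], class = c("lexicon", "data.frame"))
}

# Value expression: optional operator (symbol or phrase), a number, an
# optional dash/"to" range partner, optional %, "+" or unit tail. Word and
# Roman numbers are handled through a second pass.
VALUE_RE <- paste0(
  "(?:(?:≥|≤|>=|<=|<>|[<>=])\\s*|\\b(?:up to|at least|at most|less than|",
  "fewer than|more than|greater than|over|under|between|minimum of|maximum of)\\s+)?",
  "(?<![A-Za-z0-9.-])[0-9]+(?:\\.[0-9]+)?",
  "(?:\\s*(?:-|–|to|and)\\s*[0-9]+(?:\\.[0-9]+)?)?",
  "\\s*(?:%|\\+)?",
  "(?:\\s*[A-Za-z][A-Za-z/%^0-9.-]*)?")

# Temporal expression: optional qualifier, number+unit (optional range),
# optional direction tail.
TEMPORAL_RE <- paste0(
  "(?:\\b(?:at least|within|up to|more than|less than|over|under)\\s+|[<>≤≥]\\s*)?",
  "(?<![/0-9])[0-9]+(?:\\.[0-9]+)?[-–\\s]*", TIME_UNIT_RE, "\\b",
  "(?:\\s*(?:to|-|–)\\s*[0-9]+(?:\\.[0-9]+)?[-–\\s]*", TIME_UNIT_RE, "\\b)?",
  "(?:\\s+(?:prior to|prior|before|preceding|after|post|following|since))?")

regex_spans <- function(text, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer()))
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L, end = as.integer(m) + len - 1L)
}

overlaps_any <- function(start, end, claimed) {
  any(claimed$start < end & start < claimed$end)
}

#' Recognize entities in a criterion sentence
#'
#' Deterministic recognizer: Temporal spans (number + time-unit [+
#' direction] patterns) first, then lexicon matches (case-insensitive, on
#' token boundaries, longest surface form first), then Value spans
#' (operator/number/unit patterns), then negation cues. Spans never
#' overlap; earlier passes claim their characters.
#'
#' @param sentence a [criterion_sentence()] (or plain text).
#' @param lexicon a `lexicon` object.
#' @param cues negation cue dictionary.
#' @return list of [entity_annotation()] sorted by span start, all with
#'   `provenance = "machine"`. Temporal/Value entities carry their
#'   normalized constraint when normalization succeeds.
#' @export
recognize_entities <- function(sentence, lexicon, cues = default_negation_cues()) {
  text <- if (inherits(sentence, "criterion_sentence")) sentence$text else sentence
  claimed <- data.frame(start = integer(), end = integer())
  out <- list()
  add <- function(start, end, category, concepts = list(), constraint = NULL) {
    claimed <<- rbind(claimed, data.frame(start = start, end = end))
    out[[length(out) + 1L]] <<- entity_annotation(
      start, end, cc_slice(text, start, end), category, concepts,
      provenance = "machine", constraint = constraint)
  }

  tsp <- regex_spans(text, TEMPORAL_RE)
  for (i in seq_len(nrow(tsp))) {
    if (overlaps_any(tsp$start[i], tsp$end[i], claimed)) next
    surface <- cc_slice(text, tsp$start[i], tsp$end[i])
    constraint <- tryCatch(normalize_temporal(surface), error = function(e) NULL)
    add(tsp$start[i], tsp$end[i], "Temporal", constraint = constraint)
  }


  # lexicon pass: token n-grams, longest surface form first
  toks <- cc_tokenize(text)
  lowered <- tolower(text)
  if (nrow(toks)) {
    for (r in seq_len(nrow(lexicon))) {
      sf <- lexicon$surface_form[r]
      nw <- lexicon$n_words[r]
      if (nw > nrow(toks)) next
      for (i in seq_len(nrow(toks) - nw + 1L)) {
        s <- toks$start[i]; e <- toks$end[i + nw - 1L]
        if (overlaps_any(s, e, claimed)) next
        if (identical(gsub("\\s+", " ", cc_slice(lowered, s, e)), sf)) {
          concept <- list()
          if (!is.na(lexicon$concept_id[r]) && lexicon$concept_id[r] > 0)
            concept <- list(concept_ref(lexicon$concept_id[r],
                                        lexicon$concept_name[r],
                                        lexicon$domain[r],
                                        lexicon$vocabulary[r],
                                        isTRUE(as.logical(lexicon$standard[r]))))
          add(s, e, lexicon$category[r], concepts = concept)
        }
      }
    }
  }

  vsp <- regex_spans(text, VALUE_RE)
  for (i in seq_len(nrow(vsp))) {
    if (overlaps_any(vsp$start[i], vsp$end[i], claimed)) next
    surface <- cc_slice(text, vsp$start[i], vsp$end[i])
    constraint <- tryCatch(normalize_value(surface), error = function(e) NULL)
    if (is.null(constraint)) next
    add(vsp$start[i], vsp$end[i], "Value", constraint = constraint)
  }

  cs <- detect_negation_cues(text, cues)
  for (i in seq_len(nrow(cs))) {
    if (overlaps_any(cs$start[i], cs$end[i], claimed)) next
    add(cs$start[i], cs$end[i], "Negation_cue")
  }

  out[order(vapply(out, function(a) a$start, 1L))]
}

#' Run the full machine-parsing pipeline
#'
#' [read_criteria_text()] then [recognize_entities()] per criterion, then
#' [apply_negation()]; annotation ids are assigned sequentially.
#'
#' @param text free-text eligibility criteria.
#' @param trial_id trial identifier.
#' @param lexicon a `lexicon` object.
#' @param cues negation cue dictionary.
#' @return a fully annotated `criteria_representation`.
#' @export
parse_criteria <- function(text, trial_id, lexicon, cues = default_negation_cues()) {
  rep <- read_criteria_text(text, trial_id)
  counter <- 0L
  for (cr in rep$criteria) {
    anns <- recognize_entities(cr, lexicon, cues)
    anns <- lapply(anns, function(a) {
      counter <<- counter + 1L
      a$annotation_id <- sprintf("a%04d", counter)
      a
    })
    if (length(anns))
      rep$annotations[[criterion_key(cr$section, cr$index)]] <- anns
  }
  rep <- apply_negation(rep, cues)
  validate_representation(rep)
  rep
}
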