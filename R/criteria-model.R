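# Domain types and the JSON eligibility-criteria representation.
#
# Offsets are 0-based, half-open; declared in the schema and enforced by the
# validators. The representation round-trips losslessly through JSON.

CC_SCHEMA_VERSION <- 1L

CC_CATEGORIES <- c("Condition", "Drug", "Measurement", "Procedure",
                   "Observation", "Person_attribute", "Value", "Temporal",
                   "Negation_cue")
CC_NO_CONCEPT_CATEGORIES <- c("Value", "Temporal", "Negation_cue")

#' Construct a vocabulary concept reference
#'
#' @param concept_id positive integer identifier.
#' @param concept_name concept label.
#' @param domain OMOP domain ("Condition", "Drug", "Measurement",
#'   "Procedure", "Observation", "Person_attribute").
#' @param vocabulary source vocabulary name.
#' @param standard whether the concept is a standard concept.
#' @return a `concept_ref` object.
#' @export
concept_ref <- function(concept_id, concept_name, domain,
                        vocabulary = "SNOMED", standard = TRUE) {
  concept_id <- as.integer(concept_id)
  if (is.na(concept_id) || concept_id <= 0L)
    cc_stop("validation_error", "concept_id must be a positive integer",
            path = "concept_ref/concept_id")
  structure(list(concept_id = concept_id,
                 concept_name = as.character(concept_name),
                 domain = as.character(domain),
                 vocabulary = as.character(vocabulary),
                 standard = isTRUE(standard)),
            class = "concept_ref")
}

#' Construct a criterion sentence
#'
#' @param trial_id trial identifier (NCT-style string).
#' @param section "inclusion" or "exclusion".
#' @param index 0-based position within the section.
#' @param text criterion text (non-empty after whitespace strip).
#' @param selected whether the criterion participates in query generation.
#' @return a `criterion_sentence` object.
#' @export
criterion_sentence <- function(trial_id, section, index, text, selected = TRUE) {
  section <- match.arg(section, c("inclusion", "exclusion"))
  if (!nzchar(trimws(text)))
    cc_stop("validation_error", "criterion text is empty",
            path = "criterion_sentence/text")
  structure(list(trial_id = as.character(trial_id), section = section,
                 index = as.integer(index), text = as.character(text),
                 selected = isTRUE(selected)),
            class = "criterion_sentence")
}

#' Construct an entity annotation
#'
#' A text span over a criterion sentence with its semantic category, mapped
#' concepts, negation status and provenance. Spans are 0-based half-open
#' character offsets; `surface` must equal the corresponding slice.
#'
#' @param start,end character offsets into the criterion text.
#' @param surface the covered text.
#' @param category one of the entity categories (Condition, Drug,
#'   Measurement, Procedure, Observation, Person_attribute, Value, Temporal,
#'   Negation_cue).
#' @param concepts list of [concept_ref()]; must be empty for
#'   Value/Temporal/Negation_cue entities.
#' @param negated logical negation flag.
#' @param provenance "machine" or "human".
#' @param annotation_id stable identifier within the representation.
#' @param constraint optional normalized [temporal_constraint()] or
#'   [value_constraint()] attached to Temporal/Value entities.
#' @return an `entity_annotation` object.
#' @export
entity_annotation <- function(start, end, surface, category,
                              concepts = list(), negated = FALSE,
                              provenance = c("machine", "human"),
                              annotation_id = NA_character_,
                              constraint = NULL) {
  provenance <- match.arg(provenance)
  if (!category %in% CC_CATEGORIES)
    cc_stop("validation_error", sprintf("unknown category '%s'", category),
            path = "entity_annotation/category")
  if (category %in% CC_NO_CONCEPT_CATEGORIES && length(concepts))
    cc_stop("validation_error",
            sprintf("%s entities carry no concepts", category),
            path = "entity_annotation/concepts")
  structure(list(annotation_id = annotation_id,
                 start = as.integer(start), end = as.integer(end),
                 surface = as.character(surface), category = category,
                 concepts = concepts, negated = isTRUE(negated),
                 provenance = provenance, constraint = constraint),
            class = "entity_annotation")
}

#' Construct a temporal window constraint
#'
#' An event must start between `start_days` days before/after and `end_days`
#' days before/after the index start date; offsets are -1 for "before" and
#' +1 for "after". On the signed day axis (before = negative) the window
#' must be non-empty.
#'
#' @param start_days,end_days non-negative day counts.
#' @param start_offset,end_offset -1 (before index) or +1 (after index).
#' @return a `temporal_constraint` object.
#' @export
temporal_constraint <- function(start_days, start_offset, end_days, end_offset) {
  start_days <- as.integer(start_days); end_days <- as.integer(end_days)
  start_offset <- as.integer(start_offset); end_offset <- as.integer(end_offset)
  if (start_days < 0L || end_days < 0L)
    cc_stop("validation_error", "day counts must be >= 0",
            path = "temporal_constraint/days")
  if (!start_offset %in% c(-1L, 1L) || !end_offset %in% c(-1L, 1L))
    cc_stop("validation_error", "offsets must be -1 or +1",
            path = "temporal_constraint/offset")
  if (start_offset * start_days > end_offset * end_days)
    cc_stop("empty_window_error", "temporal window is empty on the signed day axis",
            path = "temporal_constraint")
  structure(list(start_days = start_days, start_offset = start_offset,
                 end_days = end_days, end_offset = end_offset),
            class = "temporal_constraint")
}

#' Construct a value constraint
#'
#' Comparison operator/value pairs joined by a logical relation. A
#' "between a and b" range is `terms = list(c(">=", a), c("<=", b))` with
#' `logic = "and"`.
#'
#' @param terms list of `list(op =, value =)` pairs; operators are one of
#'   `<`, `<=`, `>`, `>=`, `=`, `<>`.
#' @param logic "and", "or", or "single" (exactly when there is one term).
#' @param unit unit string, possibly empty.
#' @return a `value_constraint` object.
#' @export
value_constraint <- function(terms, logic = NULL, unit = "") {
  if (!length(terms))
    cc_stop("validation_error", "value constraint needs at least one term",
            path = "value_constraint/terms")
  terms <- lapply(terms, function(t) {
    op <- as.character(t[["op"]] %||% t[[1]])
    if (!op %in% c("<", "<=", ">", ">=", "=", "<>"))
      cc_stop("validation_error", sprintf("unknown operator '%s'", op),
              path = "value_constraint/terms/op")
    list(op = op, value = as.numeric(t[["value"]] %||% t[[2]]))
  })
  logic <- logic %||% if (length(terms) == 1L) "single" else "and"
  if ((logic == "single") != (length(terms) == 1L))
    cc_stop("validation_error", "logic must be 'single' iff there is one term",
            path = "value_constraint/logic")
  structure(list(terms = terms, logic = logic, unit = as.character(unit)),
            class = "value_constraint")
}

#' Construct an (empty) criteria representation
#'
#' The top-level document: criterion sentences, per-criterion entity
#' annotations, and the append-only edit log.
#'
#' @param trial_id trial identifier.
#' @param criteria list of [criterion_sentence()].
#' @param annotations named list, key `"<section>:<index>"`, each a list of
#'   [entity_annotation()].
#' @param edit_log list of modification events (see [add_concept()]).
#' @param warnings character vector of parse warnings.
#' @return a `criteria_representation` object.
#' @export
criteria_representation <- function(trial_id, criteria = list(),
                                    annotations = NULL, edit_log = list(),
                                    warnings = character()) {
  annotations <- annotations %||% list()
  if (!length(annotations)) annotations <- stats::setNames(list(), character())
  rep <- structure(list(schema_version = CC_SCHEMA_VERSION,
                        trial_id = as.character(trial_id),
                        criteria = criteria, annotations = annotations,
                        edit_log = edit_log, warnings = warnings),
                   class = "criteria_representation")
  validate_representation(rep)
  rep
}

criterion_key <- function(section, index) sprintf("%s:%d", section, as.integer(index))

find_criterion <- function(rep, section, index) {
  for (cr in rep$criteria)
    if (cr$section == section && cr$index == index) return(cr)
  NULL
}

#' Validate a criteria representation
#'
#' Checks every invariant of the schema: unique (trial_id, section, index)
#' triples, in-bounds spans whose surface equals the text slice, positive
#' concept ids, concept-free Value/Temporal/Negation_cue entities, and that
#' every annotation key names an existing criterion.
#'
#' @param rep a `criteria_representation`.
#' @return `rep`, invisibly; signals a `validation_error` naming the
#'   offending path otherwise.
#' @export
validate_representation <- function(rep) {
  keys <- vapply(rep$criteria, function(cr)
    paste(cr$trial_id, cr$section, cr$index), "")
  if (anyDuplicated(keys))
    cc_stop("validation_error", "duplicate (trial_id, section, index)",
            path = "criteria")
  crit_keys <- vapply(rep$criteria, function(cr)
    criterion_key(cr$section, cr$index), "")
  for (key in names(rep$annotations)) {
    if (!key %in% crit_keys)
      cc_stop("validation_error",
              sprintf("annotation key '%s' has no criterion", key),
              path = paste0("annotations/", key))
    cr <- rep$criteria[[match(key, crit_keys)]]
    for (ann in rep$annotations[[key]]) {
      if (ann$start < 0L || ann$end > nchar(cr$text) || ann$start >= ann$end)
        cc_stop("validation_error",
                sprintf("span [%d,%d) out of bounds in '%s'", ann$start, ann$end, key),
                path = paste0("annotations/", key, "/span"))
      if (!identical(cc_slice(cr$text, ann$start, ann$end), ann$surface))
        cc_stop("validation_error",
                sprintf("surface mismatch at [%d,%d) in '%s'", ann$start, ann$end, key),
                path = paste0("annotations/", key, "/surface"))
    }
  }
  invisible(rep)
}

# ---- free-text reader -------------------------------------------------------

SECTION_HEADER_RE <- "(?i)^\\s*(inclusion|exclusion)\\s+criteria\\s*:?\\s*$"
BULLET_RE <- "^\\s*(?:[-*•·]|\\(?\\d{1,2}[.)]|[a-z][.)])\\s+"

split_sentences <- function(block) {
  # period followed by whitespace and a capital; decimals ("12.0 g/dL") and
  # abbreviations stay intact because they are not followed by a capital.
  parts <- strsplit(block, "(?<=[.;!?])\\s+(?=[A-Z])", perl = TRUE)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Parse free-text eligibility criteria
#'
#' Splits plain text into inclusion/exclusion sections on the
#' "Inclusion Criteria" / "Exclusion Criteria" headers (case-insensitive),
#' then into criterion sentences on newlines, bullet markers and
#' sentence-final periods. All criteria start selected with no annotations.
#'
#' @param text the criteria text.
#' @param trial_id trial identifier recorded on every sentence.
#' @return a [criteria_representation()]. If neither header is present the
#'   whole text is treated as inclusion criteria and a warning is recorded
#'   in `$warnings`.
#' @export
read_criteria_text <- function(text, trial_id) {
  if (!nzchar(trimws(text)))
    cc_stop("empty_input_error", "criteria text is empty")
  lines <- strsplit(text, "\r?\n")[[1]]
  warnings <- character()
  section <- NA_character_
  acc <- list(inclusion = character(), exclusion = character())
  for (line in lines) {
    if (grepl(SECTION_HEADER_RE, line, perl = TRUE)) {
      section <- tolower(sub("(?i).*?(inclusion|exclusion).*", "\\1", line, perl = TRUE))
      next
    }
    if (!nzchar(trimws(line))) next
    if (is.na(section)) {
      section <- "inclusion"
      warnings <- c(warnings,
                    "no section header found; treating text as inclusion criteria")
    }
    line <- sub(BULLET_RE, "", line, perl = TRUE)
    acc[[section]] <- c(acc[[section]], split_sentences(line))
  }
  criteria <- list()
  for (sec in c("inclusion", "exclusion")) {
    for (i in seq_along(acc[[sec]])) {
      criteria[[length(criteria) + 1L]] <-
        criterion_sentence(trial_id, sec, i - 1L, acc[[sec]][i])
    }
  }
  criteria_representation(trial_id, criteria, warnings = warnings)
}

# ---- JSON serialization -----------------------------------------------------

rep_to_list <- function(rep) {
  list(
    schema_version = rep$schema_version,
    trial_id = rep$trial_id,
    criteria = lapply(rep$criteria, unclass),
    annotations = lapply(rep$annotations, function(anns)
      lapply(anns, function(a) {
        a <- unclass(a)
        a$concepts <- lapply(a$concepts, unclass)
        if (!is.null(a$constraint)) {
          a$constraint_type <-
            if (inherits(a$constraint, "value_constraint")) "value" else "temporal"
          a$constraint <- unclass(a$constraint)
        }
        a
      })),
    edit_log = lapply(rep$edit_log, unclass),
    warnings = as.list(rep$warnings)
  )
}

#' Write a criteria representation to JSON
#'
#' @param rep a `criteria_representation`.
#' @param path optional file path; when `NULL` the JSON text is returned.
#' @return the JSON string (invisibly when written to a file).
#' @export
write_criteria_json <- function(rep, path = NULL) {
  validate_representation(rep)
  js <- jsonlite::toJSON(rep_to_list(rep), auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path, useBytes = TRUE)
    return(invisible(as.character(js)))
  }
  as.character(js)
}

#' Read a criteria representation from JSON
#'
#' Inverse of [write_criteria_json()]; `read_criteria_json(write_criteria_json(rep))`
#' reproduces `rep` field-for-field. Schema violations raise a
#' `validation_error` naming the offending JSON path.
#'
#' @param json JSON text, or a path to a JSON file.
#' @return a `criteria_representation`.
#' @export
read_criteria_json <- function(json) {
  if (length(json) == 1L && !grepl("[{\\[]", substr(json, 1, 1)) && file.exists(json))
    json <- paste(readLines(json, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  if (is.null(doc$schema_version) || doc$schema_version > CC_SCHEMA_VERSION)
    cc_stop("validation_error", "unsupported schema_version",
            path = "schema_version")
  criteria <- lapply(doc$criteria, function(cr)
    criterion_sentence(cr$trial_id, cr$section, cr$index, cr$text,
                       isTRUE(cr$selected)))
  annotations <- lapply(doc$annotations, function(anns)
    lapply(anns, function(a) {
      concepts <- lapply(a$concepts, function(co)
        concept_ref(co$concept_id, co$concept_name, co$domain,
                    co$vocabulary, isTRUE(co$standard)))
      constraint <- NULL
      if (!is.null(a$constraint)) {
        constraint <- if (identical(a$constraint_type, "value")) {
          value_constraint(a$constraint$terms, a$constraint$logic,
                           a$constraint$unit %||% "")
        } else {
          temporal_constraint(a$constraint$start_days, a$constraint$start_offset,
                              a$constraint$end_days, a$constraint$end_offset)
        }
      }
      entity_annotation(a$start, a$end, a$surface, a$category, concepts,
                        isTRUE(a$negated), a$provenance,
                        a$annotation_id %||% NA_character_, constraint)
    }))
  if (length(annotations) == 0L) annotations <- NULL
  edit_log <- lapply(doc$edit_log, function(ev) {
    ev$seq <- as.integer(ev$seq)
    structure(ev, class = "modification_event")
  })
  criteria_representation(doc$trial_id, criteria, annotations, edit_log,
                          as.character(unlist(doc$warnings)))
}
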