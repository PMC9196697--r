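# Human-in-the-loop modification of the criteria representation. Every
# mutating call is a pure function returning a new representation with one
# event appended to the (append-only, strictly sequenced) edit log, so a
# final state is always reproducible by replaying the log on the machine
# baseline.

new_event <- function(rep, action, section, index, payload, actor) {
  seqno <- if (length(rep$edit_log))
    rep$edit_log[[length(rep$edit_log)]]$seq + 1L else 1L
  structure(list(action = action, section = section, index = as.integer(index),
                 payload = payload, seq = seqno, actor = actor),
            class = "modification_event")
}

require_criterion <- function(rep, section, index) {
  cr <- find_criterion(rep, section, index)
  if (is.null(cr))
    cc_stop("not_found_error",
            sprintf("no criterion %s:%d", section, index))
  cr
}

ann_index <- function(anns, annotation_id) {
  ids <- vapply(anns, function(a) a$annotation_id %||% NA_character_, "")
  match(annotation_id, ids)
}

next_annotation_id <- function(rep) {
  ids <- unlist(lapply(rep$annotations, function(anns)
    vapply(anns, function(a) a$annotation_id %||% NA_character_, "")))
  nums <- suppressWarnings(as.integer(sub("^a", "", ids)))
  sprintf("a%04d", max(0L, nums, na.rm = TRUE) + 1L)
}

#' Load a concept catalog
#'
#' Local stand-in for a terminology-service lookup: a table of vocabulary
#' concepts with optional pipe-delimited synonyms.
#'
#' @param path CSV with columns concept_id, concept_name, domain,
#'   vocabulary, standard, synonyms.
#' @return a `concept_catalog` object (data.frame, unique concept_id).
#' @export
read_concept_catalog <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(d$concept_id))
    cc_stop("validation_error", "duplicate concept_id in catalog")
  d$synonyms[is.na(d$synonyms)] <- ""
  structure(d, class = c("concept_catalog", "data.frame"))
}

catalog_row_to_ref <- function(row) {
  concept_ref(row$concept_id, row$concept_name, row$domain, row$vocabulary,
              isTRUE(as.logical(row$standard)))
}

#' Search the concept catalog
#'
#' `exact` mode: case-insensitive full-string match on the concept name or
#' any synonym. `fuzzy` mode: ranking by normalized edit similarity
#' (`1 - dist/max(nchar)`, best over name and synonyms); at equal
#' similarity standard concepts rank first, then concept_id ascending.
#'
#' @param query search string (non-empty).
#' @param catalog a `concept_catalog`.
#' @param mode "exact" or "fuzzy".
#' @param k maximum number of results.
#' @return list of [concept_ref()], best first (possibly empty).
#' @export
search_concepts <- function(query, catalog, mode = c("exact", "fuzzy"), k = 10L) {
  mode <- match.arg(mode)
  if (!nzchar(trimws(query)))
    cc_stop("validation_error", "empty concept query")
  stopifnot(nrow(catalog) > 0, k >= 1L)
  q <- tolower(trimws(query))
  names_syn <- lapply(seq_len(nrow(catalog)), function(i) {
    syn <- strsplit(catalog$synonyms[i], "|", fixed = TRUE)[[1]]
    tolower(trimws(c(catalog$concept_name[i], syn[nzchar(syn)])))
  })
  if (mode == "exact") {
    hit <- vapply(names_syn, function(v) q %in% v, logical(1))
    rows <- catalog[hit, , drop = FALSE]
    rows <- rows[order(!as.logical(rows$standard), rows$concept_id), , drop = FALSE]
  } else {
    sim <- vapply(names_syn, function(v) {
      d <- utils::adist(q, v)
      max(1 - d / pmax(nchar(q), nchar(v)))
    }, numeric(1))
    ord <- order(-sim, !as.logical(catalog$standard), catalog$concept_id)
    rows <- catalog[ord, , drop = FALSE]
  }
  rows <- utils::head(rows, k)
  lapply(seq_len(nrow(rows)), function(i) catalog_row_to_ref(rows[i, ]))
}

#' Add a concept annotation to a criterion
#'
#' Adds a human-provenance [entity_annotation()] for a span the machine
#' missed or mis-spanned. Machine annotations overlapping the new span are
#' superseded (removed); a *partial* overlap with an existing human
#' annotation is a `conflict_error`, while an identical span is allowed so
#' one span can carry several concepts.
#'
#' @param rep a `criteria_representation`.
#' @param section,index criterion key.
#' @param start,end span (0-based half-open) within the criterion text.
#' @param concept a [concept_ref()].
#' @param category entity category for the new annotation.
#' @param actor actor recorded in the event log.
#' @return the updated representation (event appended).
#' @export
add_concept <- function(rep, section, index, start, end, concept, category,
                        actor = "human") {
  cr <- require_criterion(rep, section, index)
  start <- as.integer(start); end <- as.integer(end)
  if (start < 0L || end > nchar(cr$text) || start >= end)
    cc_stop("validation_error",
            sprintf("span [%d,%d) outside criterion text", start, end))
  key <- criterion_key(section, index)
  anns <- rep$annotations[[key]] %||% list()
  for (a in anns) {
    same_span <- a$start == start && a$end == end
    overlap <- a$start < end && start < a$end
    if (overlap && !same_span && a$provenance == "human")
      cc_stop("conflict_error",
              sprintf("span [%d,%d) overlaps human annotation %s", start, end,
                      a$annotation_id))
  }
  keep <- vapply(anns, function(a) {
    overlap <- a$start < end && start < a$end
    same_span <- a$start == start && a$end == end
    !(overlap && !same_span && a$provenance == "machine")
  }, logical(1))
  anns <- anns[keep]
  ann <- entity_annotation(start, end, cc_slice(cr$text, start, end), category,
                           list(concept), provenance = "human",
                           annotation_id = next_annotation_id(rep))
  rep$annotations[[key]] <- c(anns, list(ann))
  rep$edit_log <- c(rep$edit_log, list(new_event(
    rep, "add_concept", section, index,
    list(annotation_id = ann$annotation_id, start = start, end = end,
         category = category, concept = unclass(concept)), actor)))
  rep
}

#' Replace the concept mapping of an annotation
#'
#' @inheritParams add_concept
#' @param annotation_id id of the annotation to update.
#' @param new_concept replacement [concept_ref()].
#' @return updated representation.
#' @export
update_concept <- function(rep, section, index, annotation_id, new_concept,
                           actor = "human") {
  require_criterion(rep, section, index)
  key <- criterion_key(section, index)
  i <- ann_index(rep$annotations[[key]] %||% list(), annotation_id)
  if (is.na(i))
    cc_stop("not_found_error", sprintf("no annotation '%s' in %s", annotation_id, key))
  rep$annotations[[key]][[i]]$concepts <- list(new_concept)
  rep$edit_log <- c(rep$edit_log, list(new_event(
    rep, "update_concept", section, index,
    list(annotation_id = annotation_id, concept = unclass(new_concept)), actor)))
  rep
}

#' Delete one annotation
#'
#' @inheritParams update_concept
#' @return updated representation.
#' @export
delete_concept <- function(rep, section, index, annotation_id, actor = "human") {
  require_criterion(rep, section, index)
  key <- criterion_key(section, index)
  anns <- rep$annotations[[key]] %||% list()
  i <- ann_index(anns, annotation_id)
  if (is.na(i))
    cc_stop("not_found_error", sprintf("no annotation '%s' in %s", annotation_id, key))
  rep$annotations[[key]] <- anns[-i]
  rep$edit_log <- c(rep$edit_log, list(new_event(
    rep, "delete_concept", section, index,
    list(annotation_id = annotation_id), actor)))
  rep
}

#' Delete every annotation in a criterion
#'
#' @inheritParams add_concept
#' @return updated representation (one event regardless of count).
#' @export
delete_all_in_criterion <- function(rep, section, index, actor = "human") {
  require_criterion(rep, section, index)
  key <- criterion_key(section, index)
  n <- length(rep$annotations[[key]] %||% list())
  rep$annotations[[key]] <- list()
  rep$edit_log <- c(rep$edit_log, list(new_event(
    rep, "delete_all_in_criterion", section, index, list(removed = n), actor)))
  rep
}

#' Select or deselect criteria for query generation
#'
#' Deselected criteria are retained in the document but excluded from
#' cohort query generation.
#'
#' @param rep a `criteria_representation`.
#' @param keys list of `list(section =, index =)` criterion keys.
#' @param selected logical.
#' @param actor actor recorded in the event log.
#' @return updated representation (one event for the whole call).
#' @export
select_criteria <- function(rep, keys, selected, actor = "human") {
  keys <- lapply(keys, function(k)
    list(section = k$section, index = as.integer(k$index)))
  for (k in keys) require_criterion(rep, k$section, k$index)
  rep$criteria <- lapply(rep$criteria, function(cr) {
    for (k in keys)
      if (cr$section == k$section && cr$index == k$index)
        cr$selected <- isTRUE(selected)
    cr
  })
  k1 <- keys[[1]]
  rep$edit_log <- c(rep$edit_log, list(new_event(
    rep, "select_criteria", k1$section, k1$index,
    list(keys = keys, selected = isTRUE(selected)), actor)))
  rep
}

#' Count modification events by action
#'
#' @param rep a `criteria_representation`.
#' @return named list: one count per action type plus `total`.
#' @export
modification_summary <- function(rep) {
  actions <- c("add_concept", "update_concept", "delete_concept",
               "delete_all_in_criterion", "select_criteria")
  got <- vapply(rep$edit_log, function(ev) ev$action, "")
  counts <- lapply(actions, function(a) sum(got == a))
  names(counts) <- actions
  counts$total <- length(got)
  counts
}

#' Replay an edit log on a baseline representation
#'
#' Applies the events of `edit_log` in sequence order to `baseline`
#' (typically the machine-parsed representation). Replaying the log of a
#' final representation on its baseline reproduces it exactly.
#'
#' @param baseline a `criteria_representation` with an empty (or shorter)
#'   edit log.
#' @param edit_log list of modification events.
#' @return the replayed representation.
#' @export
replay_edits <- function(baseline, edit_log) {
  rep <- baseline
  for (ev in edit_log) {
    p <- ev$payload
    rep <- switch(ev$action,
      add_concept = add_concept(rep, ev$section, ev$index, p$start, p$end,
                                concept_ref(p$concept$concept_id, p$concept$concept_name,
                                            p$concept$domain, p$concept$vocabulary,
                                            isTRUE(p$concept$standard)),
                                p$category, ev$actor),
      update_concept = update_concept(rep, ev$section, ev$index, p$annotation_id,
                                      concept_ref(p$concept$concept_id, p$concept$concept_name,
                                                  p$concept$domain, p$concept$vocabulary,
                                                  isTRUE(p$concept$standard)),
                                      ev$actor),
      delete_concept = delete_concept(rep, ev$section, ev$index, p$annotation_id,
                                      ev$actor),
      delete_all_in_criterion = delete_all_in_criterion(rep, ev$section, ev$index,
                                                        ev$actor),
      select_criteria = select_criteria(rep,
                                        lapply(p$keys, function(k)
                                          list(section = k$section,
                                               index = as.integer(k$index))),
                                        isTRUE(p$selected), ev$actor),
      cc_stop("validation_error", sprintf("unknown action '%s'", ev$action)))
  }
  rep
}
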