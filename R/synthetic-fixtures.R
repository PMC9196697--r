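# Deterministic generators: (a) criteria sentences with machine-checkable
# gold normalizations spanning every rule family, (b) OMOP-lite databases
# with planted, exactly-known ground-truth cohorts. Together they stand in
# for the external annotated corpus and the public synthetic claims sample,
# so every stage is testable offline.

MEASUREMENT_TERMS <- c("hemoglobin", "serum creatinine", "alanine aminotransferase",
                       "ejection fraction")
CONDITION_TERMS <- c("diabetes", "hypertension", "thyroiditis", "melanoma",
                     "autoimmune disease")
EVENT_TERMS <- c("screening", "enrollment", "randomization", "informed consent",
                 "hospital discharge")
LAB_UNITS <- c("g/dL", "mg/dL", "IU/L", "mmol/L")

# string builder tracking 0-based half-open spans
sb_new <- function() new.env(parent = emptyenv())
sb_add <- function(sb, s) {
  cur <- sb$text %||% ""
  span <- c(nchar(cur), nchar(cur) + nchar(s))
  sb$text <- paste0(cur, s)
  span
}

unit_mult <- function(unit) {
  opt <- cc_options()
  switch(canonical_unit(unit), hour = NA_integer_, day = 1L,
         week = opt$days_per_week, month = opt$days_per_month,
         year = opt$days_per_year)
}

gold_days <- function(n, unit) {
  if (canonical_unit(unit) == "hour") as.integer(ceiling(n / 24))
  else as.integer(n * unit_mult(unit))
}

value_record <- function(i, phrase, symbol) {
  sb <- sb_new()
  attr_term <- sample(MEASUREMENT_TERMS, 1)
  num <- sample(1:200, 1)
  suffix <- grepl("^or ", phrase)
  sb_add(sb, paste0(attr_term, " "))
  span <- if (suffix) {
    sb_add(sb, paste(num, phrase))
  } else if (grepl("^[A-Za-z]", phrase)) {
    s <- sb_add(sb, paste(phrase, num, sample(LAB_UNITS, 1)))
    s
  } else {
    sb_add(sb, paste0(phrase, " ", num, " ", sample(LAB_UNITS, 1)))
  }
  unit <- if (suffix) "" else sub(paste0(".*", num, " ?"), "", cc_slice(sb$text, span[1], span[2]))
  list(id = i, kind = "value", sentence = sb$text,
       value_span = span,
       gold = list(terms = list(list(op = symbol, value = as.numeric(num))),
                   logic = "single", unit = unit))
}

temporal_record <- function(i, form, unit) {
  sb <- sb_new()
  ev <- sample(EVENT_TERMS, 1)
  opt <- cc_options()
  # magnitudes a protocol would plausibly use for each unit; also keeps
  # every bound well below the unbounded sentinel
  n_max <- switch(canonical_unit(unit), hour = 96L, day = 60L, week = 12L,
                  month = 12L, year = 5L)
  if (form == "at_least") {
    n <- sample(n_max, 1)
    span <- sb_add(sb, sprintf("at least %d %s before", n, unit))
    sb_add(sb, paste0(" ", ev))
    gold <- c(opt$unbounded_days, -1L, gold_days(n, unit), -1L)
  } else if (form == "within") {
    n <- sample(n_max, 1)
    span <- sb_add(sb, sprintf("within %d %s prior to", n, unit))
    sb_add(sb, paste0(" ", ev))
    gold <- c(gold_days(n, unit), -1L, 0L, -1L)
  } else if (form == "range_after") {
    a <- sample(max(1L, n_max %/% 4L), 1); b <- a + sample(n_max %/% 2L + 1L, 1)
    span <- sb_add(sb, sprintf("%d %s to %d %s post", a, unit, b, unit))
    sb_add(sb, paste0(" ", ev))
    gold <- c(gold_days(a, unit), 1L, gold_days(b, unit), 1L)
  } else { # symbol_hours: the ">72 h" unit-format trap
    n <- sample(c(24, 48, 72, 96), 1)
    span <- sb_add(sb, sprintf(">%d h before", n))
    sb_add(sb, paste0(" ", ev))
    gold <- c(opt$unbounded_days, -1L, as.integer(ceiling(n / 24)), -1L)
  }
  list(id = i, kind = "temporal", sentence = sb$text, temporal_span = span,
       gold = list(start_days = gold[1], start_offset = gold[2],
                   end_days = gold[3], end_offset = gold[4]))
}

negation_record <- function(i, cue) {
  sb <- sb_new()
  terms <- sample(CONDITION_TERMS, 3)
  sb_add(sb, "Patients with ")
  span_0 <- sb_add(sb, terms[1])    # before the cue: never in scope
  sb_add(sb, " ")
  sb_add(sb, cue)
  sb_add(sb, " ")
  span_a <- sb_add(sb, terms[2])
  sb_add(sb, ", with ")
  span_b <- sb_add(sb, terms[3])
  # half the sentences ship without terminal punctuation: the
  # ensure_terminal_period preprocessing must make scope come out the same
  if (i %% 2L == 0L) sb_add(sb, ".")
  list(id = i, kind = "negation", sentence = sb$text, cue = cue,
       gold = list(entities = list(
         list(span = span_0, surface = terms[1], negated = FALSE),
         list(span = span_a, surface = terms[2], negated = TRUE),
         list(span = span_b, surface = terms[3], negated = FALSE))))
}

no_cue_record <- function(i) {
  sb <- sb_new()
  terms <- sample(CONDITION_TERMS, 2)
  sb_add(sb, "Patients with ")
  span_a <- sb_add(sb, terms[1])
  sb_add(sb, " and ")
  span_b <- sb_add(sb, terms[2])
  sb_add(sb, ".")
  list(id = i, kind = "negation", sentence = sb$text, cue = NA_character_,
       gold = list(entities = list(
         list(span = span_a, surface = terms[1], negated = FALSE),
         list(span = span_b, surface = terms[2], negated = FALSE))))
}

special_value_record <- function(i, which) {
  sb <- sb_new()
  if (which == "percent_range") {
    a <- sample(10:40, 1); b <- a + sample(5:30, 1)
    sb_add(sb, "ejection fraction ")
    span <- sb_add(sb, sprintf("%d-%d%%", a, b))
    gold <- list(terms = list(list(op = ">=", value = a / 100),
                              list(op = "<=", value = b / 100)),
                 logic = "and", unit = "")
  } else if (which == "roman") {
    n <- sample(2:4, 1)
    sb_add(sb, "NYHA class ")
    span <- sb_add(sb, paste(names(ROMAN_NUMERALS)[n], "or higher"))
    gold <- list(terms = list(list(op = ">=", value = as.numeric(n))), logic = "single",
                 unit = "")
  } else if (which == "plus") {
    n <- sample(c(18, 50, 65), 1)
    sb_add(sb, "age ")
    span <- sb_add(sb, sprintf("%d+", n))
    gold <- list(terms = list(list(op = ">=", value = as.numeric(n))), logic = "single",
                 unit = "")
  } else if (which == "word_number") {
    n <- sample(2:9, 1)
    sb_add(sb, "received ")
    span <- sb_add(sb, paste(names(WORD_NUMBERS)[n + 1L], "or more"))
    sb_add(sb, " prior regimens")
    gold <- list(terms = list(list(op = ">=", value = as.numeric(n))), logic = "single",
                 unit = "")
  } else { # denominator trap: the number inside the unit is not a value
    n <- sample(1:5, 1)
    sb_add(sb, "proteinuria ")
    span <- sb_add(sb, sprintf("%d g/24-hours", n))
    gold <- list(terms = list(list(op = "=", value = as.numeric(n))), logic = "single",
                 unit = "g/24-hours")
  }
  list(id = i, kind = "value", sentence = sb$text, value_span = span,
       gold = gold)
}

negative_record <- function(i, which) {
  if (which == "currently")
    list(id = i, kind = "negative_temporal", sentence = "currently",
         gold = list(error = "no_time_span_error"))
  else
    list(id = i, kind = "negative_temporal",
         sentence = "since January 1, 2020",
         gold = list(error = "date_literal_error"))
}

#' Generate an annotated synthetic criteria corpus
#'
#' Deterministic (same seed, same corpus) sentences with gold labels,
#' spanning every rule family: each comparison-operator phrase, each time
#' unit and temporal template (including the ">72 h" unit-format trap),
#' ranges, Roman numerals, percents, "+" suffixes, the unit-denominator
#' trap ("g/24-hours"), each negation cue with a clause boundary, sentences
#' without terminal punctuation, and the excluded categories (date
#' literals, "currently") as negative cases. With `n >= 100` every operator
#' phrase and negation cue is covered at least once.
#'
#' @param n number of records (>= 1).
#' @param seed integer seed.
#' @return list of records; each has `id`, `kind` ("value", "temporal",
#'   "negation", "negative_temporal"), `sentence`, and a `gold` element
#'   whose shape depends on the kind (value/temporal constraints, entity
#'   negation labels, or an expected error class).
#' @export
generate_criteria_corpus <- function(n, seed) {
  stopifnot(n >= 1)
  set.seed(seed)
  ops <- operator_dictionary()
  cues <- default_negation_cues()
  plan <- list()
  bind1 <- function(f, a) { force(f); force(a); function(i) f(i, a) }
  bind2 <- function(f, a, b) { force(f); force(a); force(b); function(i) f(i, a, b) }
  for (p in names(ops)) plan[[length(plan) + 1L]] <-
    bind2(value_record, p, ops[[p]])
  for (u in c("hours", "days", "weeks", "months", "years"))
    for (f in c("at_least", "within", "range_after"))
      plan[[length(plan) + 1L]] <- bind2(temporal_record, f, u)
  plan[[length(plan) + 1L]] <- function(i) temporal_record(i, "symbol_hours", "hours")
  for (w in c("percent_range", "roman", "plus", "word_number", "denominator"))
    plan[[length(plan) + 1L]] <- bind1(special_value_record, w)
  for (cue in cues) plan[[length(plan) + 1L]] <- bind1(negation_record, cue)
  plan[[length(plan) + 1L]] <- function(i) no_cue_record(i)
  plan[[length(plan) + 1L]] <- function(i) negative_record(i, "currently")
  plan[[length(plan) + 1L]] <- function(i) negative_record(i, "date")
  out <- vector("list", n)
  for (i in seq_len(n)) {
    maker <- plan[[(i - 1L) %% length(plan) + 1L]]
    out[[i]] <- maker(i)
    out[[i]]$seed <- seed
  }
  out
}

#' Write a corpus as JSON lines
#'
#' @param corpus output of [generate_criteria_corpus()].
#' @param path file path; one JSON object per line.
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(corpus, path) {
  lines <- vapply(corpus, function(rec)
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)), "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

empty_clinical <- function(cols) {
  df <- as.data.frame(stats::setNames(replicate(length(cols), character(0),
                                                simplify = FALSE), cols))
  df$person_id <- integer(0)
  df[[grep("concept_id", cols, value = TRUE)]] <- integer(0)
  if ("value_as_number" %in% cols) df$value_as_number <- numeric(0)
  df[, cols]
}

random_dates <- function(n, from, to) {
  format(as.Date(from) + sample.int(as.integer(as.Date(to) - as.Date(from)), n,
                                    replace = TRUE) - 1L)
}

#' Generate a synthetic OMOP-lite database with planted cohorts
#'
#' Builds a small OMOP-CDM-v5-shaped store (person, observation_period and
#' the five clinical-domain tables) in which every planted concept has an
#' exactly known carrier set, with controllable day offsets from each
#' person's index date (= observation_period_start_date) and controllable
#' measurement values/units. Unplanted noise rows use concept ids disjoint
#' from the plan so ground truth is preserved.
#'
#' @param n_persons number of persons (>= 1).
#' @param seed integer seed; same (n, seed, plan) gives an identical store.
#' @param plan list of plants, each
#'   `list(concept_id, domain, carriers, days_from_index = 0, value = NULL,
#'   unit = "")`; carriers are person ids in `1:n_persons`.
#' @param noise_rows extra random rows per clinical table.
#' @return an `omop_lite` object: `$tables` (named data.frames), `$truth`
#'   (concept_id -> carrier id vector), `$seed`. A plant whose carriers are
#'   not a subset of the persons raises a `plan_error`.
#' @export
generate_omop_lite <- function(n_persons, seed, plan = list(), noise_rows = n_persons) {
  stopifnot(n_persons >= 1)
  set.seed(seed)
  person <- data.frame(
    person_id = seq_len(n_persons),
    birth_date = random_dates(n_persons, "1930-01-01", "2000-12-31"),
    gender = sample(c("MALE", "FEMALE"), n_persons, replace = TRUE),
    race = sample(c("White", "Black or African American", "Asian", "Other"),
                  n_persons, replace = TRUE),
    stringsAsFactors = FALSE)
  index_dates <- random_dates(n_persons, "2019-01-01", "2021-06-30")
  observation_period <- data.frame(
    person_id = seq_len(n_persons),
    observation_period_start_date = index_dates,
    observation_period_end_date = format(as.Date(index_dates) + 365L),
    stringsAsFactors = FALSE)
  tables <- list(person = person, observation_period = observation_period)
  for (dom in names(DOMAIN_TABLE_MAP))
    tables[[DOMAIN_TABLE_MAP[[dom]]$table]] <-
      empty_clinical(OMOP_LITE_SCHEMA[[DOMAIN_TABLE_MAP[[dom]]$table]])

  truth <- list()
  for (pl in plan) {
    if (length(pl$carriers) > n_persons || !all(pl$carriers %in% seq_len(n_persons)))
      cc_stop("plan_error",
              sprintf("plant %d references persons outside 1..%d",
                      pl$concept_id, n_persons))
    map <- DOMAIN_TABLE_MAP[[pl$domain]]
    if (is.null(map)) cc_stop("plan_error", sprintf("unknown domain '%s'", pl$domain))
    off <- pl$days_from_index %||% 0L
    carriers <- sort(unique(as.integer(pl$carriers)))
    if (length(carriers)) {
      rows <- data.frame(person_id = carriers, stringsAsFactors = FALSE)
      rows[[map$concept]] <- as.integer(pl$concept_id)
      rows[[map$date]] <- format(as.Date(index_dates[carriers]) + as.integer(off))
      if (map$table == "measurement") {
        rows$value_as_number <- if (is.null(pl$value)) NA_real_ else
          rep_len(pl$value, length(carriers))
        rows$unit <- pl$unit %||% ""
      }
      tables[[map$table]] <- rbind(tables[[map$table]],
                                   rows[, OMOP_LITE_SCHEMA[[map$table]]])
    }
    truth[[as.character(pl$concept_id)]] <-
      sort(unique(c(truth[[as.character(pl$concept_id)]], carriers)))
  }

  if (noise_rows > 0) {
    for (dom in names(DOMAIN_TABLE_MAP)) {
      map <- DOMAIN_TABLE_MAP[[dom]]
      who <- sample.int(n_persons, noise_rows, replace = TRUE)
      rows <- data.frame(person_id = who, stringsAsFactors = FALSE)
      rows[[map$concept]] <- 900000L + sample.int(1000L, noise_rows, replace = TRUE)
      rows[[map$date]] <- format(as.Date(index_dates[who]) +
                                   sample(-400:400, noise_rows, replace = TRUE))
      if (map$table == "measurement") {
        rows$value_as_number <- round(stats::runif(noise_rows, 0, 300), 1)
        rows$unit <- sample(LAB_UNITS, noise_rows, replace = TRUE)
      }
      tables[[map$table]] <- rbind(tables[[map$table]],
                                   rows[, OMOP_LITE_SCHEMA[[map$table]]])
    }
  }
  structure(list(tables = tables, truth = truth, seed = seed),
            class = "omop_lite")
}

#' Dump an OMOP-lite store to per-table CSV files
#'
#' @param db an `omop_lite` object.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_omop_csv <- function(db, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (tb in names(db$tables))
    utils::write.csv(db$tables[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' Load an OMOP-lite store from per-table CSV files
#'
#' @param dir directory produced by [write_omop_csv()].
#' @return named list of data.frames (usable wherever an `omop_lite` is).
#' @export
read_omop_csv <- function(dir) {
  tables <- lapply(names(OMOP_LITE_SCHEMA), function(tb) {
    f <- file.path(dir, paste0(tb, ".csv"))
    if (!file.exists(f)) cc_stop("schema_error", paste("missing table file", f))
    utils::read.csv(f, stringsAsFactors = FALSE)
  })
  stats::setNames(tables, names(OMOP_LITE_SCHEMA))
}

#' Generate a paired end-to-end scenario with a known cohort
#'
#' Produces free-text criteria, a matching lexicon, a planted OMOP-lite
#' store and the exact set of eligible persons, so the whole pipeline
#' (parse, normalize, compile, execute) can be checked against ground
#' truth. The criteria exercise a plain condition, a measurement threshold
#' with units, a drug with a temporal window, and an exclusion condition.
#'
#' @param n_persons store size.
#' @param seed integer seed.
#' @return list with `text`, `trial_id`, `lexicon`, `db` (`omop_lite`) and
#'   `truth` (sorted eligible person ids).
#' @export
generate_planted_scenario <- function(n_persons = 50, seed = 1) {
  set.seed(seed)
  has_dm <- sample(seq_len(n_persons), ceiling(n_persons * 0.6))
  hb_high <- sample(seq_len(n_persons), ceiling(n_persons * 0.7))
  drug_in <- sample(seq_len(n_persons), ceiling(n_persons * 0.6))
  drug_out <- setdiff(sample(seq_len(n_persons), ceiling(n_persons * 0.3)), drug_in)
  pregnant <- sample(seq_len(n_persons), ceiling(n_persons * 0.2))
  plan <- list(
    list(concept_id = 201826, domain = "Condition", carriers = has_dm),
    list(concept_id = 3000963, domain = "Measurement", carriers = hb_high,
         value = 12, unit = "g/dL"),
    list(concept_id = 3000963, domain = "Measurement",
         carriers = setdiff(seq_len(n_persons), hb_high), value = 8, unit = "g/dL"),
    list(concept_id = 1503297, domain = "Drug", carriers = drug_in,
         days_from_index = -7L),
    list(concept_id = 1503297, domain = "Drug", carriers = drug_out,
         days_from_index = -100L),
    list(concept_id = 4299535, domain = "Condition", carriers = pregnant)
  )
  db <- generate_omop_lite(n_persons, seed + 1L, plan)
  truth <- sort(setdiff(Reduce(intersect, list(has_dm, hb_high, drug_in)), pregnant))
  text <- paste(
    "Inclusion Criteria:",
    "- diabetes mellitus",
    "- hemoglobin > 10 g/dL",
    "- metformin within 2 weeks prior to enrollment",
    "Exclusion Criteria:",
    "- pregnancy",
    sep = "\n")
  lexicon <- read_lexicon(system.file("extdata", "demo_lexicon.csv",
                                      package = "cohortcriteria"))
  list(text = text, trial_id = sprintf("NCT%08d", seed), lexicon = lexicon,
       db = db, truth = truth)
}
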