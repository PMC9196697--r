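# Compile a criteria representation into cohort SQL over an OMOP-CDM-v5
# shaped store, execute it, and summarize demographics.

DOMAIN_TABLE_MAP <- list(
  Condition = list(table = "condition_occurrence",
                   concept = "condition_concept_id",
                   date = "condition_start_date"),
  Drug = list(table = "drug_exposure",
              concept = "drug_concept_id",
              date = "drug_exposure_start_date"),
  Measurement = list(table = "measurement",
                     concept = "measurement_concept_id",
                     date = "measurement_date"),
  Procedure = list(table = "procedure_occurrence",
                   concept = "procedure_concept_id",
                   date = "procedure_date"),
  Observation = list(table = "observation",
                     concept = "observation_concept_id",
                     date = "observation_date")
)

OMOP_LITE_SCHEMA <- list(
  person = c("person_id", "birth_date", "gender", "race"),
  observation_period = c("person_id", "observation_period_start_date",
                         "observation_period_end_date"),
  condition_occurrence = c("person_id", "condition_concept_id", "condition_start_date"),
  drug_exposure = c("person_id", "drug_concept_id", "drug_exposure_start_date"),
  measurement = c("person_id", "measurement_concept_id", "measurement_date",
                  "value_as_number", "unit"),
  procedure_occurrence = c("person_id", "procedure_concept_id", "procedure_date"),
  observation = c("person_id", "observation_concept_id", "observation_date")
)

#' Build the query intermediate representation
#'
#' Walks the selected criteria and turns every concept-bearing clinical
#' entity into a clause: the entity's domain picks the OMOP table, Value
#' entities attach to the nearest preceding Measurement entity in the same
#' criterion, and Temporal entities attach to every clinical entity in the
#' criterion. Presence semantics compose section with entity negation:
#' inclusion+plain and exclusion+negated require presence of a matching
#' record; inclusion+negated and exclusion+plain require absence.
#'
#' @param rep an annotated `criteria_representation`.
#' @return a `query_ir` object (list of clauses). A representation with no
#'   queryable annotation in any selected criterion raises an
#'   `empty_query_error`.
#' @export
build_query_ir <- function(rep) {
  clauses <- list()
  for (cr in rep$criteria) {
    if (!cr$selected) next
    anns <- rep$annotations[[criterion_key(cr$section, cr$index)]]
    if (is.null(anns) || !length(anns)) next
    anns <- anns[order(vapply(anns, function(a) a$start, 1L))]
    clinical <- Filter(function(a)
      (a$category %in% names(DOMAIN_TABLE_MAP) && length(a$concepts)) ||
        (a$category == "Person_attribute" && length(a$concepts)), anns)
    values <- Filter(function(a) a$category == "Value" && !is.null(a$constraint), anns)
    temporals <- Filter(function(a) a$category == "Temporal" && !is.null(a$constraint), anns)
    if (!length(clinical)) next
    # nearest preceding Measurement for each Value entity
    value_for <- rep(list(NULL), length(clinical))
    for (v in values) {
      best <- NA_integer_
      for (j in seq_along(clinical)) {
        a <- clinical[[j]]
        if (a$category == "Measurement" && a$start < v$start &&
            (is.na(best) || a$start > clinical[[best]]$start)) best <- j
      }
      if (!is.na(best)) value_for[[best]] <- v$constraint
    }
    temporal <- if (length(temporals)) temporals[[1]]$constraint else NULL
    for (j in seq_along(clinical)) {
      a <- clinical[[j]]
      clauses[[length(clauses) + 1L]] <- list(
        section = cr$section,
        criterion_index = cr$index,
        domain = a$category,
        concept_ids = sort(vapply(a$concepts, function(co) co$concept_id, 1L)),
        concept_names = sort(vapply(a$concepts, function(co) co$concept_name, "")),
        negated = a$negated,
        require_presence = (cr$section == "inclusion") == (!a$negated),
        temporal = if (a$category == "Person_attribute") NULL else temporal,
        value = if (a$category == "Measurement") value_for[[j]] else NULL
      )
    }
  }
  if (!length(clauses))
    cc_stop("empty_query_error",
            "no queryable annotations among the selected criteria")
  structure(list(clauses = clauses), class = "query_ir")
}

sql_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

sql_num <- function(x) {
  # exact, locale-independent numeric literals
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

value_predicate <- function(vc, col) {
  ops <- vapply(vc$terms, function(t)
    sprintf("%s %s %s", col, if (t$op == "<>") "<>" else t$op, sql_num(t$value)), "")
  joiner <- if (vc$logic == "or") " OR " else " AND "
  pred <- paste(ops, collapse = joiner)
  if (length(ops) > 1L) pred <- paste0("(", pred, ")")
  pred
}

day_diff_expr <- function(a, b, dialect) {
  if (dialect == "sqlite")
    sprintf("CAST(julianday(%s) - julianday(%s) AS INTEGER)", a, b)
  else sprintf("(%s - %s)", a, b)
}

age_expr <- function(dialect) {
  d <- day_diff_expr("op.observation_period_start_date", "p.birth_date", dialect)
  if (dialect == "sqlite") sprintf("CAST(%s / 365.25 AS INTEGER)", d)
  else sprintf("FLOOR(%s / 365.25)", d)
}

clause_sql <- function(cl, dialect) {
  if (cl$domain == "Person_attribute") {
    vals <- paste(sql_quote(tolower(cl$concept_names)), collapse = ", ")
    pred <- sprintf("(LOWER(p.gender) IN (%s) OR LOWER(p.race) IN (%s))", vals, vals)
    return(if (cl$require_presence) pred else paste0("NOT ", pred))
  }
  map <- DOMAIN_TABLE_MAP[[cl$domain]]
  conds <- c(
    sprintf("x.person_id = p.person_id"),
    sprintf("x.%s IN (%s)", map$concept,
            paste(sql_num(cl$concept_ids), collapse = ", "))
  )
  if (!is.null(cl$temporal)) {
    tc <- cl$temporal
    lo <- tc$start_offset * tc$start_days
    hi <- tc$end_offset * tc$end_days
    conds <- c(conds, sprintf(
      "%s BETWEEN %d AND %d",
      day_diff_expr(paste0("x.", map$date), "op.observation_period_start_date", dialect),
      lo, hi))
  }
  if (!is.null(cl$value)) {
    conds <- c(conds, value_predicate(cl$value, "x.value_as_number"))
    if (nzchar(cl$value$unit))
      conds <- c(conds, sprintf("LOWER(x.unit) = %s", sql_quote(tolower(cl$value$unit))))
  }
  sub <- sprintf("SELECT 1 FROM %s x WHERE %s", map$table,
                 paste(conds, collapse = " AND "))
  sprintf("%sEXISTS (%s)", if (cl$require_presence) "" else "NOT ", sub)
}

#' Generate cohort SQL from a query IR
#'
#' Emits a single deterministic SELECT over person joined to
#' observation_period (whose start date is the index date), with one
#' EXISTS / NOT EXISTS subquery per clause, ANDed. Demographics (age at
#' index, gender, race) are computed in the statement.
#'
#' @param ir a `query_ir` from [build_query_ir()].
#' @param dialect "sqlite" or "postgresql".
#' @return SQL text; identical IR yields byte-identical SQL.
#' @export
generate_sql <- function(ir, dialect = c("sqlite", "postgresql")) {
  if (!is.character(dialect) || !all(dialect %in% c("sqlite", "postgresql")))
    cc_stop("dialect_error", sprintf("unsupported dialect '%s'", dialect[1]))
  dialect <- match.arg(dialect)
  preds <- vapply(ir$clauses, clause_sql, "", dialect = dialect)
  paste0(
    "SELECT p.person_id,\n       ", age_expr(dialect), " AS age,\n",
    "       p.gender, p.race\n",
    "FROM person p\n",
    "JOIN observation_period op ON op.person_id = p.person_id\n",
    "WHERE ", paste(preds, collapse = "\n  AND "), "\n",
    "ORDER BY p.person_id"
  )
}

check_omop_schema <- function(tables) {
  missing <- character()
  for (tb in names(OMOP_LITE_SCHEMA)) {
    if (!tb %in% names(tables)) {
      missing <- c(missing, tb)
      next
    }
    lack <- setdiff(OMOP_LITE_SCHEMA[[tb]], names(tables[[tb]]))
    if (length(lack))
      missing <- c(missing, paste0(tb, ".", lack))
  }
  if (length(missing))
    cc_stop("schema_error",
            paste("OMOP-lite store is missing:", paste(missing, collapse = ", ")),
            missing = missing)
}

omop_connection <- function(db) {
  if (inherits(db, "DBIConnection")) return(list(con = db, own = FALSE))
  if (is.character(db)) {
    con <- DBI::dbConnect(RSQLite::SQLite(), db)
    return(list(con = con, own = TRUE))
  }
  tables <- if (inherits(db, "omop_lite")) db$tables else db
  check_omop_schema(tables)
  con <- DBI::dbConnect(RSQLite::SQLite(), ":memory:")
  for (tb in names(tables)) {
    df <- tables[[tb]]
    for (cl in names(df))            # julianday() needs ISO-8601 text dates
      if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]])
    DBI::dbWriteTable(con, tb, df)
  }
  list(con = con, own = TRUE)
}

#' Execute a cohort query
#'
#' Loads the OMOP-lite store into SQLite (from an `omop_lite` object, a
#' named list of data.frames, a file path, or an open DBI connection),
#' runs the generated SQL, and returns the eligible persons with their
#' demographics.
#'
#' @param ir a `query_ir`.
#' @param db the store.
#' @return a `cohort_result` data.frame: person_id, age (floor of years at
#'   index), gender, race; sorted by person_id, person_id unique.
#' @export
execute_cohort <- function(ir, db) {
  h <- omop_connection(db)
  on.exit(if (h$own) DBI::dbDisconnect(h$con))
  existing <- DBI::dbListTables(h$con)
  lack <- setdiff(names(OMOP_LITE_SCHEMA), existing)
  if (length(lack))
    cc_stop("schema_error",
            paste("OMOP-lite store is missing:", paste(lack, collapse = ", ")),
            missing = lack)
  res <- DBI::dbGetQuery(h$con, generate_sql(ir, "sqlite"))
  res$person_id <- as.integer(res$person_id)
  res$age <- as.integer(res$age)
  structure(res, class = c("cohort_result", "data.frame"))
}

#' Write a cohort result to CSV
#'
#' @param result a `cohort_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(result, path) {
  utils::write.csv(result, path, row.names = FALSE)
  invisible(path)
}
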