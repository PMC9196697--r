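# Independent brute-force cohort oracle: evaluates a query IR by looping
# over persons and filtering data.frames directly. Shares no code with the
# SQL generation/execution path it checks.

oracle_clause_holds <- function(cl, pid, tables, index_date) {
  if (cl$domain == "Person_attribute") {
    p <- tables$person[tables$person$person_id == pid, ]
    hit <- tolower(p$gender) %in% tolower(cl$concept_names) ||
      tolower(p$race) %in% tolower(cl$concept_names)
    return(if (cl$require_presence) hit else !hit)
  }
  tbmap <- list(
    Condition = c("condition_occurrence", "condition_concept_id", "condition_start_date"),
    Drug = c("drug_exposure", "drug_concept_id", "drug_exposure_start_date"),
    Measurement = c("measurement", "measurement_concept_id", "measurement_date"),
    Procedure = c("procedure_occurrence", "procedure_concept_id", "procedure_date"),
    Observation = c("observation", "observation_concept_id", "observation_date"))[[cl$domain]]
  df <- tables[[tbmap[1]]]
  df <- df[df$person_id == pid & df[[tbmap[2]]] %in% cl$concept_ids, , drop = FALSE]
  if (!is.null(cl$temporal) && nrow(df)) {
    d <- as.integer(as.Date(df[[tbmap[3]]]) - index_date[as.character(pid)])
    lo <- cl$temporal$start_offset * cl$temporal$start_days
    hi <- cl$temporal$end_offset * cl$temporal$end_days
    df <- df[d >= lo & d <= hi, , drop = FALSE]
  }
  if (!is.null(cl$value) && nrow(df)) {
    v <- df$value_as_number
    hits <- lapply(cl$value$terms, function(t)
      switch(t$op,
             "<" = v < t$value, "<=" = v <= t$value, ">" = v > t$value,
             ">=" = v >= t$value, "=" = v == t$value, "<>" = v != t$value))
    keep <- Reduce(if (cl$value$logic == "or") `|` else `&`, hits)
    if (nzchar(cl$value$unit))
      keep <- keep & tolower(df$unit) == tolower(cl$value$unit)
    df <- df[!is.na(keep) & keep, , drop = FALSE]
  }
  if (cl$require_presence) nrow(df) > 0 else nrow(df) == 0
}

oracle_cohort <- function(ir, db) {
  tables <- if (inherits(db, "omop_lite")) db$tables else db
  index_date <- stats::setNames(
    as.Date(tables$observation_period$observation_period_start_date),
    tables$observation_period$person_id)
  ids <- tables$person$person_id
  sort(ids[vapply(ids, function(pid)
    all(vapply(ir$clauses, oracle_clause_holds, logical(1),
               pid = pid, tables = tables, index_date = index_date)),
    logical(1))])
}
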