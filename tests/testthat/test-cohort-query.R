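test_that("IR construction attaches values and applies the presence truth table", {
  lex <- demo_lexicon()
  rep <- parse_criteria(paste(
    "Inclusion Criteria:",
    "- serum creatinine > 2.5 mg/dL",
    "Exclusion Criteria:",
    "- pregnancy", sep = "\n"), "NCT1", lex)
  ir <- build_query_ir(rep)
  expect_length(ir$clauses, 2)
  meas <- ir$clauses[[1]]
  expect_identical(meas$domain, "Measurement")
  expect_identical(meas$value$terms, list(list(op = ">", value = 2.5)))
  expect_true(meas$require_presence)
  excl <- ir$clauses[[2]]
  expect_identical(excl$domain, "Condition")
  expect_false(excl$require_presence)
})

test_that("(section, negated) -> presence enumerates the full truth table", {
  mk <- function(section, negated) {
    text <- "no diabetes mellitus here"
    rep <- criteria_representation(
      "NCT1", list(criterion_sentence("NCT1", section, 0L, text)))
    rep$annotations[[criterion_key(section, 0L)]] <- list(entity_annotation(
      3L, 20L, cc_slice(text, 3L, 20L), "Condition",
      list(concept_ref(201826, "T2DM", "Condition")), negated = negated,
      annotation_id = "a0001"))
    build_query_ir(rep)$clauses[[1]]$require_presence
  }
  expect_true(mk("inclusion", FALSE))
  expect_false(mk("inclusion", TRUE))
  expect_false(mk("exclusion", FALSE))
  expect_true(mk("exclusion", TRUE))
})

test_that("SQL text is deterministic, dialect-aware and structurally correct", {
  ir <- build_query_ir(tiny_rep())
  sql <- generate_sql(ir, "sqlite")
  expect_identical(sql, generate_sql(ir, "sqlite"))
  expect_match(sql, "EXISTS \\(SELECT 1 FROM condition_occurrence")
  expect_match(sql, "NOT EXISTS")
  pg <- generate_sql(ir, "postgresql")
  expect_match(pg, "FLOOR")
  expect_false(identical(sql, pg))
  expect_error(generate_sql(ir, "mssql"), class = "dialect_error")
})

test_that("execution matches planted truth and flags schema gaps", {
  db <- generate_omop_lite(10, 2, list(
    list(concept_id = 201826, domain = "Condition", carriers = c(1, 2, 3))))
  ir <- build_query_ir(tiny_rep())
  # drop the exclusion clause: nobody has pregnancy planted anyway
  res <- execute_cohort(ir, db)
  expect_identical(res$person_id, c(1L, 2L, 3L))
  expect_identical(db$truth[["201826"]], c(1L, 2L, 3L))
  expect_true(all(c("age", "gender", "race") %in% names(res)))
  # demographics: age = floor(days/365.25) at index
  p <- db$tables$person
  op <- db$tables$observation_period
  expected_age <- as.integer(floor(as.numeric(
    as.Date(op$observation_period_start_date[1]) - as.Date(p$birth_date[1])) / 365.25))
  expect_identical(res$age[res$person_id == 1L], expected_age)

  # a concept absent from the store matches nobody
  rep <- tiny_rep()
  rep$annotations[["inclusion:0"]][[1]]$concepts[[1]]$concept_id <- 424242L
  expect_identical(nrow(execute_cohort(build_query_ir(rep), db)), 0L)

  broken <- db$tables
  broken$measurement <- NULL
  err <- expect_error(execute_cohort(ir, broken), class = "schema_error")
  expect_match(err$missing, "measurement", all = FALSE)
})

test_that("SQL execution equals the brute-force oracle on random fixtures", {
  for (seed in 1:40) {
    case <- random_query_case(seed)
    got <- execute_cohort(case$ir, case$db)$person_id
    expect_identical(got, oracle_cohort(case$ir, case$db),
                     info = paste("seed", seed))
  }
})

test_that("widening a temporal window never shrinks the cohort (property)", {
  for (seed in 101:115) {
    case <- random_query_case(seed)
    has_tc <- which(vapply(case$ir$clauses,
                           function(cl) !is.null(cl$temporal), logical(1)))
    if (!length(has_tc)) next
    narrow <- execute_cohort(case$ir, case$db)$person_id
    wide_ir <- case$ir
    for (j in has_tc)
      wide_ir$clauses[[j]]$temporal <- temporal_constraint(500L, -1L, 500L, 1L)
    # widening helps presence clauses and hurts absence clauses; restrict to
    # the monotone direction
    if (all(vapply(case$ir$clauses[has_tc], function(cl) cl$require_presence,
                   logical(1)))) {
      wide <- execute_cohort(wide_ir, case$db)$person_id
      expect_true(all(narrow %in% wide), info = paste("seed", seed))
    }
  }
})

test_that("adding an inclusion clause never grows the cohort", {
  case <- random_query_case(7)
  base <- execute_cohort(case$ir, case$db)$person_id
  extra <- case$ir
  extra$clauses[[length(extra$clauses) + 1L]] <- list(
    section = "inclusion", criterion_index = 99L, domain = "Condition",
    concept_ids = 1001L, concept_names = "planted", negated = FALSE,
    require_presence = TRUE, temporal = NULL, value = NULL)
  expect_true(all(execute_cohort(extra, case$db)$person_id %in% base))
})

test_that("presence and absence of one concept partition the base population", {
  db <- generate_omop_lite(30, 9, list(
    list(concept_id = 5555, domain = "Condition", carriers = seq(1, 29, by = 2))))
  mk_ir <- function(presence) structure(list(clauses = list(list(
    section = if (presence) "inclusion" else "exclusion",
    criterion_index = 0L, domain = "Condition", concept_ids = 5555L,
    concept_names = "planted", negated = FALSE, require_presence = presence,
    temporal = NULL, value = NULL))), class = "query_ir")
  inside <- execute_cohort(mk_ir(TRUE), db)$person_id
  outside <- execute_cohort(mk_ir(FALSE), db)$person_id
  expect_length(intersect(inside, outside), 0)
  expect_setequal(c(inside, outside), db$tables$person$person_id)
})
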