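test_that("exact and fuzzy concept search rank as specified", {
  cat <- demo_catalog()
  hits <- search_concepts("Osteoporosis", cat, "exact")
  expect_length(hits, 1)
  expect_identical(hits[[1]]$concept_name, "Osteoporosis")

  hits <- search_concepts("mixd dementia", cat, "fuzzy", k = 3)
  expect_identical(hits[[1]]$concept_name, "Mixed dementia")
  # independent oracle: best normalized edit similarity over the catalog
  sims <- vapply(seq_len(nrow(cat)), function(i) {
    cand <- tolower(c(cat$concept_name[i],
                      strsplit(cat$synonyms[i], "|", fixed = TRUE)[[1]]))
    cand <- cand[nzchar(cand)]
    max(1 - utils::adist("mixd dementia", cand) /
          pmax(nchar("mixd dementia"), nchar(cand)))
  }, numeric(1))
  expect_identical(hits[[1]]$concept_id, cat$concept_id[which.max(sims)])

  expect_length(search_concepts("zzz-nonexistent", cat, "exact"), 0)
  expect_error(search_concepts("  ", cat), class = "validation_error")
})

test_that("the mixed-dementia edit sequence applies cleanly", {
  lex <- demo_lexicon()
  text <- "Inclusion Criteria:\n- Dementia of mixed type under standard treatment"
  rep <- parse_criteria(text, "NCT04249869", lex)
  hit <- search_concepts("mixed dementia", demo_catalog(), "exact")[[1]]
  start <- regexpr("mixed type", rep$criteria[[1]]$text) - 1L
  rep2 <- add_concept(rep, "inclusion", 0, start, start + nchar("mixed type"),
                      hit, "Condition")
  anns <- rep2$annotations[["inclusion:0"]]
  added <- anns[[length(anns)]]
  expect_identical(added$surface, "mixed type")
  expect_identical(added$concepts[[1]]$concept_name, "Mixed dementia")
  expect_identical(added$provenance, "human")
  expect_identical(rep2$edit_log[[length(rep2$edit_log)]]$action, "add_concept")
})

test_that("two concepts can share one span; partial human overlap conflicts", {
  rep <- tiny_rep()
  liver <- concept_ref(4229881, "Liver finding", "Condition")
  kidney <- concept_ref(198124, "Kidney disease", "Condition")
  rep <- add_concept(rep, "inclusion", 0, 0, 8, liver, "Condition")
  rep <- add_concept(rep, "inclusion", 0, 0, 8, kidney, "Condition")
  anns <- rep$annotations[["inclusion:0"]]
  human <- Filter(function(a) a$provenance == "human", anns)
  expect_length(human, 2)
  expect_length(rep$edit_log, 2)
  expect_error(
    add_concept(rep, "inclusion", 0, 2, 12, liver, "Condition"),
    class = "conflict_error")
  expect_error(
    add_concept(rep, "inclusion", 0, 200, 210, liver, "Condition"),
    class = "validation_error")
})

test_that("update, delete, delete-all and select mutate exactly as named", {
  rep <- tiny_rep()
  rep <- update_concept(rep, "inclusion", 0, "a0001",
                        concept_ref(201820, "Diabetes mellitus", "Condition"))
  expect_identical(
    rep$annotations[["inclusion:0"]][[1]]$concepts[[1]]$concept_id, 201820L)

  rep <- delete_concept(rep, "exclusion", 0, "a0002")
  expect_length(rep$annotations[["exclusion:0"]], 0)
  expect_error(delete_concept(rep, "exclusion", 0, "a9999"),
               class = "not_found_error")

  rep <- add_concept(rep, "inclusion", 0, 0, 8,
                     concept_ref(1, "x", "Condition"), "Condition")
  n_before <- length(rep$annotations[["inclusion:0"]])
  expect_gte(n_before, 1)
  rep <- delete_all_in_criterion(rep, "inclusion", 0)
  expect_length(rep$annotations[["inclusion:0"]], 0)

  rep <- select_criteria(rep, list(list(section = "inclusion", index = 0)), FALSE)
  expect_false(rep$criteria[[1]]$selected)
  expect_error(build_query_ir(rep), class = "empty_query_error")
})

test_that("modification summary counts equal a brute-force tally (property)", {
  set.seed(41)
  rep <- tiny_rep()
  actions_done <- character()
  for (i in 1:30) {
    act <- sample(c("add", "delete_all", "select"), 1)
    if (act == "add") {
      rep <- add_concept(rep, "inclusion", 0, 0, 8,
                         concept_ref(i, paste0("c", i), "Condition"), "Condition")
      actions_done <- c(actions_done, "add_concept")
    } else if (act == "delete_all") {
      rep <- delete_all_in_criterion(rep, "exclusion", 0)
      actions_done <- c(actions_done, "delete_all_in_criterion")
    } else {
      rep <- select_criteria(rep, list(list(section = "exclusion", index = 0)),
                             sample(c(TRUE, FALSE), 1))
      actions_done <- c(actions_done, "select_criteria")
    }
  }
  s <- modification_summary(rep)
  tally <- table(actions_done)
  for (a in names(tally)) expect_identical(s[[a]], as.integer(tally[[a]]))
  expect_identical(s$total, 30L)
  expect_identical(modification_summary(tiny_rep())$total, 0L)
})

test_that("sequence numbers strictly increase and replay reproduces the state", {
  lex <- demo_lexicon()
  rep0 <- parse_criteria(
    "Inclusion Criteria:\n- Severe liver and kidney dysfunction\n- diabetes mellitus",
    "NCT04249869", lex)
  liver <- concept_ref(4229881, "Liver finding", "Condition")
  kidney <- concept_ref(198124, "Kidney disease", "Condition")
  s <- regexpr("liver and kidney dysfunction", rep0$criteria[[1]]$text) - 1L
  e <- s + nchar("liver and kidney dysfunction")
  rep <- add_concept(rep0, "inclusion", 0, s, e, liver, "Condition")
  rep <- add_concept(rep, "inclusion", 0, s, e, kidney, "Condition")
  rep <- select_criteria(rep, list(list(section = "inclusion", index = 1)), FALSE)
  seqs <- vapply(rep$edit_log, function(ev) ev$seq, 1L)
  expect_identical(seqs, seq_along(seqs))

  replayed <- replay_edits(rep0, rep$edit_log)
  expect_identical(replayed, rep)
})
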