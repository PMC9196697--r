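test_that("terminal period preprocessing", {
  expect_identical(
    ensure_terminal_period("Known history of autoimmune disease except prior thyroiditis"),
    "Known history of autoimmune disease except prior thyroiditis.")
  expect_identical(
    ensure_terminal_period("assay within 72 hours prior to informed consent."),
    "assay within 72 hours prior to informed consent.")
  expect_identical(ensure_terminal_period(""), ".")
})

test_that("cue detection finds all cues, longest first, on word boundaries", {
  hits <- detect_negation_cues(covid_sentence())
  expect_identical(hits$cue, "without")

  expect_identical(nrow(detect_negation_cues("patients with diabetes")), 0L)

  hits <- detect_negation_cues("no evidence of disease other than melanoma")
  expect_identical(hits$cue, c("no", "other than"))

  # "nothing" must not fire the "no" cue
  expect_identical(nrow(detect_negation_cues("nothing abnormal")), 0L)
})

test_that("rule labeler scopes rightward up to the clause boundary", {
  text <- ensure_terminal_period(covid_sentence())
  labels <- label_word_scope(text, detect_negation_cues(text))
  in_scope <- labels$token[labels$label == "in_scope"]
  expect_setequal(in_scope, c("signs", "of", "respiratory", "distress"))

  # no cues -> everything out of scope
  l2 <- label_word_scope("patients with diabetes.",
                         detect_negation_cues("patients with diabetes."))
  expect_true(all(l2$label == "out_of_scope"))

  # terminal-period fix brings the trailing entity into scope
  text3 <- ensure_terminal_period(
    "Known history of autoimmune disease except prior thyroiditis")
  l3 <- label_word_scope(text3, detect_negation_cues(text3))
  expect_setequal(l3$token[l3$label == "in_scope"], c("prior", "thyroiditis"))
})

test_that("entity aggregation matches the exhaustive counting oracle", {
  # brute force over every label vector of length 1..6
  for (len in 1:6) {
    grid <- expand.grid(rep(list(c("in_scope", "out_of_scope")), len),
                        stringsAsFactors = FALSE)
    for (r in seq_len(nrow(grid))) {
      labs <- unlist(grid[r, ], use.names = FALSE)
      toks <- data.frame(token = letters[seq_len(len)],
                         start = 2L * (seq_len(len) - 1L),
                         end = 2L * seq_len(len) - 1L,
                         label = labs, stringsAsFactors = FALSE)
      ent <- entity_annotation(0L, 2L * len - 1L, strrep("x", 2L * len - 1L),
                               "Condition")
      expected <- sum(labs == "in_scope") >= sum(labs == "out_of_scope")
      expect_identical(aggregate_entity_scope(toks, ent), expected)
    }
  }
})

test_that("zero-word entities signal an alignment error", {
  toks <- data.frame(token = "a", start = 0L, end = 1L, label = "in_scope")
  ent <- entity_annotation(5L, 8L, "xyz", "Condition")
  expect_error(aggregate_entity_scope(toks, ent), class = "scope_alignment_error")
})

test_that("apply_negation flags exactly the in-scope entity and is idempotent", {
  rep <- parse_criteria(paste0("Inclusion Criteria:\n- ", covid_sentence()),
                        "NCT04246242", demo_lexicon())
  anns <- rep$annotations[["inclusion:0"]]
  flag <- stats::setNames(
    vapply(anns, function(a) a$negated, logical(1)),
    vapply(anns, function(a) a$surface, ""))
  expect_true(flag[["respiratory distress"]])
  expect_false(flag[["symptomatic"]])
  expect_false(flag[["symptoms"]])
  expect_false(flag[["SARS-CoV-2 diagnostic assay"]])

  expect_identical(apply_negation(rep), rep)
})

test_that("entities before the first cue are never negated (property)", {
  corpus <- generate_criteria_corpus(80, 23)
  lex <- demo_lexicon()
  checked <- 0L
  for (rec in corpus) {
    if (rec$kind != "negation") next
    text <- ensure_terminal_period(rec$sentence)
    cues <- detect_negation_cues(text)
    if (!nrow(cues)) next
    labels <- label_word_scope(text, cues)
    for (g in rec$gold$entities) {
      if (g$span[2] <= cues$start[1]) {
        ent <- entity_annotation(g$span[1], g$span[2], g$surface, "Condition")
        expect_false(aggregate_entity_scope(labels, ent))
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 0)
})

test_that("generated negation gold labels are recovered by the scope rules", {
  corpus <- generate_criteria_corpus(120, 5)
  for (rec in corpus) {
    if (rec$kind != "negation") next
    text <- ensure_terminal_period(rec$sentence)
    labels <- label_word_scope(text, detect_negation_cues(text))
    for (g in rec$gold$entities) {
      ent <- entity_annotation(g$span[1], g$span[2], g$surface, "Condition")
      expect_identical(aggregate_entity_scope(labels, ent), g$negated,
                       info = rec$sentence)
    }
  }
})
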