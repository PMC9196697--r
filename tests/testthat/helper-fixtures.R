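# In-code fixtures shared across test files.

demo_lexicon <- function() {
  read_lexicon(system.file("extdata", "demo_lexicon.csv",
                           package = "cohortcriteria"))
}

demo_catalog <- function() {
  read_concept_catalog(system.file("extdata", "demo_concept_catalog.csv",
                                   package = "cohortcriteria"))
}

# the negation worked example sentence
covid_sentence <- function() {
  paste0("If symptomatic, presence of mild to moderate symptoms without ",
         "signs of respiratory distress, with positive for SARS-CoV-2 ",
         "diagnostic assay within 72 hours prior to informed consent.")
}

tiny_rep <- function() {
  text1 <- "diabetes mellitus"
  text2 <- "pregnancy"
  rep <- criteria_representation(
    "NCT01234567",
    list(criterion_sentence("NCT01234567", "inclusion", 0L, text1),
         criterion_sentence("NCT01234567", "exclusion", 0L, text2)))
  rep$annotations[["inclusion:0"]] <- list(entity_annotation(
    0L, nchar(text1), text1, "Condition",
    list(concept_ref(201826, "Type 2 diabetes mellitus", "Condition")),
    annotation_id = "a0001"))
  rep$annotations[["exclusion:0"]] <- list(entity_annotation(
    0L, nchar(text2), text2, "Condition",
    list(concept_ref(4299535, "Pregnancy", "Condition")),
    annotation_id = "a0002"))
  rep
}

# a randomized representation for round-trip property tests
random_representation <- function(seed) {
  set.seed(seed)
  trial <- sprintf("NCT%08d", sample.int(1e7, 1))
  words <- c("diabetes", "insulin", "hemoglobin", "dialysis", "pregnancy",
             "melanoma", "warfarin", "chemotherapy")
  criteria <- list(); annotations <- list()
  for (sec in c("inclusion", "exclusion")) {
    for (i in seq_len(sample(1:3, 1))) {
      text <- paste(sample(words, sample(2:5, 1), replace = TRUE), collapse = " ")
      criteria[[length(criteria) + 1L]] <-
        criterion_sentence(trial, sec, i - 1L, text, sample(c(TRUE, FALSE), 1))
      if (stats::runif(1) < 0.8) {
        toks <- cc_tokenize(text)
        j <- sample.int(nrow(toks), 1)
        constraint <- if (stats::runif(1) < 0.3)
          value_constraint(list(list(op = ">=", value = sample.int(100, 1)))) else
            if (stats::runif(1) < 0.3)
              temporal_constraint(sample.int(30, 1), -1L, 0L, -1L) else NULL
        cat <- if (!is.null(constraint) && inherits(constraint, "value_constraint"))
          "Value" else sample(c("Condition", "Drug", "Measurement"), 1)
        concepts <- if (cat %in% c("Condition", "Drug", "Measurement"))
          list(concept_ref(sample.int(1e6, 1), toks$token[j], cat)) else list()
        annotations[[criterion_key(sec, i - 1L)]] <- list(entity_annotation(
          toks$start[j], toks$end[j], toks$token[j], cat, concepts,
          negated = sample(c(TRUE, FALSE), 1),
          annotation_id = sprintf("a%04d", length(annotations) + 1L),
          constraint = constraint))
      }
    }
  }
  criteria_representation(trial, criteria, annotations)
}

# a random (IR, database) pair with planted concepts for oracle-equivalence
random_query_case <- function(seed) {
  set.seed(seed)
  n <- sample(15:35, 1)
  domains <- sample(c("Condition", "Drug", "Measurement", "Procedure",
                      "Observation"), 3, replace = TRUE)
  plan <- lapply(seq_along(domains), function(k) {
    list(concept_id = 1000L * k + sample.int(99, 1), domain = domains[k],
         carriers = sample(seq_len(n), sample.int(n, 1)),
         days_from_index = sample(-60:60, 1),
         value = if (domains[k] == "Measurement") sample(1:20, 1) * 10 else NULL,
         unit = if (domains[k] == "Measurement") "mg/dL" else "")
  })
  db <- generate_omop_lite(n, seed + 1L, plan, noise_rows = 15L)
  n_clauses <- sample(1:3, 1)
  clauses <- lapply(sample(seq_along(plan), n_clauses, replace = TRUE), function(k) {
    pl <- plan[[k]]
    temporal <- if (stats::runif(1) < 0.5) {
      lo <- sample(-90:0, 1); hi <- sample(0:90, 1)
      temporal_constraint(abs(lo), if (lo < 0) -1L else 1L, abs(hi), 1L)
    } else NULL
    value <- if (pl$domain == "Measurement" && stats::runif(1) < 0.5)
      value_constraint(list(list(op = sample(c("<", "<=", ">", ">=", "="), 1),
                                 value = sample(1:20, 1) * 10)),
                       unit = if (stats::runif(1) < 0.5) "mg/dL" else "") else NULL
    list(section = sample(c("inclusion", "exclusion"), 1),
         criterion_index = 0L, domain = pl$domain,
         concept_ids = pl$concept_id,
         concept_names = "planted", negated = FALSE,
         require_presence = sample(c(TRUE, FALSE), 1),
         temporal = temporal, value = value)
  })
  list(ir = structure(list(clauses = clauses), class = "query_ir"), db = db)
}
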