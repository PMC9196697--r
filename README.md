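# cohortcriteria

Turn free-text clinical-trial eligibility criteria into executable cohort
queries over an OMOP-CDM-shaped database — with a structured, editable,
replayable intermediate representation in between.

## Who this is for

Clinical research informaticians and trial recruitment teams who need to
pre-screen patients in an observational database (OMOP CDM v5 style)
against trial eligibility text, and who want every machine decision —
recognized entities, negation status, normalized time windows and lab
thresholds — to be inspectable and correctable by a human before the SQL
runs.

## What it computes

The pipeline has four stages:

1. **Parsing.** Criteria text is split into inclusion/exclusion sections
   and criterion sentences; a deterministic lexicon + pattern recognizer
   marks entity spans (Condition, Drug, Measurement, Procedure,
   Observation, Person_attribute, Value, Temporal, Negation_cue) with
   mapped vocabulary concepts.
2. **Normalization.**
   - *Negation*: cue detection ("not", "without", "except", "other than",
     …), rule-based word-level scope labeling up to the next clause
     boundary, then entity-level aggregation by majority vote over the
     entity's word labels (ties count as negated).
   - *Temporal*: expressions become day-unit windows relative to the index
     start date, `(start_days, start_offset, end_days, end_offset)` with
     offset −1 = before, +1 = after, and 9999 as the open-ended sentinel.
     "at least 5 days before X" ⇒ event starts between 9999 and 5 days
     before index.
   - *Values*: comparison phrases map through an operator dictionary
     ("up to" ⇒ `<=`, "or higher" ⇒ `>=`), word-form numbers and Roman
     numerals I–X are converted ("III or higher" ⇒ `>= 3`), percents are
     scaled ("34.4-44.6%" ⇒ between 0.344 and 0.446), and numbers inside
     unit denominators ("3 g/24-hours") are never mistaken for values.
3. **Human-in-the-loop editing.** Pure-functional operations — add,
   update, delete a concept, delete all concepts of a criterion, select or
   deselect criteria — each append one event to an edit log; replaying the
   log on the machine baseline reproduces the final state exactly. Concept
   lookup is a local exact/fuzzy (normalized edit distance) search over a
   bundled catalog.
4. **Query generation and execution.** Each concept-bearing entity becomes
   an EXISTS / NOT EXISTS clause on its domain table
   (Condition → condition_occurrence, Drug → drug_exposure, …). Presence
   is the composition of section and negation: inclusion+plain and
   exclusion+negated require a matching record; inclusion+negated and
   exclusion+plain require its absence. SQL is emitted for SQLite
   (executed via RSQLite) and PostgreSQL (text parity), and results report
   person_id, age at index, gender and race.

Deterministic generators build annotated criteria corpora and synthetic
OMOP-lite databases with planted, exactly-known cohorts, so the whole
pipeline is testable offline.

## Worked example

```r
library(cohortcriteria)

normalize_temporal("at least 5 days before the leukapheresis procedure")
#> $start_days   9999      # open-ended lookback
#> $start_offset -1        # before the index date
#> $end_days     5
#> $end_offset   -1

normalize_value("34.4-44.6%")
#> $terms: (>= 0.344), (<= 0.446)   # one "%" scales both bounds
#> $logic: "and"

sc  <- generate_planted_scenario(n_persons = 50, seed = 7)
rep <- parse_criteria(sc$text, sc$trial_id, sc$lexicon)
ir  <- build_query_ir(rep)
cohort <- execute_cohort(ir, sc$db)
head(cohort, 3)
#>   person_id age gender  race
#> 1         6  37 FEMALE White
#> 2        20  73   MALE Other
#> 3        24  53 FEMALE Other
nrow(cohort)                         # 9
identical(cohort$person_id, sc$truth) # TRUE: planted cohort recovered
```

The 9 persons are exactly those planted to satisfy all three inclusion
criteria (diabetes diagnosis, hemoglobin above 10 g/dL, metformin within
the 14-day pre-index window) and not the exclusion criterion (pregnancy).

A command-line interface wraps the same pipeline
(`inst/cli/cohortcriteria.R` with subcommands `parse`, `edit`, `query`,
`gen-fixtures`, `report`; exit codes 0 = success, 2 = invalid input,
3 = empty query).

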