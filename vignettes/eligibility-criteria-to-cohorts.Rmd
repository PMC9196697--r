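---
title: "From eligibility criteria text to executable cohort queries: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From eligibility criteria text to executable cohort queries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cohortcriteria)
```

## The problem

Trial eligibility criteria are written for humans: "Known history of
autoimmune disease except prior thyroiditis", "hemoglobin ≥ 12.0 g/dL",
"within 72 hours prior to informed consent". Screening an observational
database against them requires three translations that are easy to get
subtly wrong: which mentions are *negated* (an exclusion criterion that
itself contains a negation flips polarity); what a *relative time
expression* means as a window on a day axis anchored at an index date; and
what a *threshold or range* means as comparison operators, after unit
suffixes, percent signs, Roman numerals and word-form numbers are dealt
with. This package implements those translations as deterministic,
testable rules, keeps a human review step in the loop, and compiles the
result to SQL over an OMOP-CDM-v5-shaped store.

## Representation

A criteria document holds criterion sentences (section, 0-based index,
text, selected flag), per-criterion entity annotations (0-based half-open
character spans whose surface must equal the text slice — an invariant the
validator enforces on every read), an append-only edit log, and a
`schema_version` so future fields do not break readers. It round-trips
losslessly through JSON; round-trip identity is a property test over
randomly generated documents.

## Negation

Cues come from an editable dictionary (minimum set: not, no, without,
except, other than, free of, absence of, exclude, excluding, neither,
nor; the shipped file adds common clinical cues such as "denies" and
"rather than"). Detection is case-insensitive on word boundaries, longest
cue first.

Scope labeling is a deterministic stand-in for a learned sequence model,
behind the same word-label interface so a model can be substituted later:
every word after a cue up to the next clause boundary is `in_scope`; a
clause boundary is the sentence end, a semicolon, or a comma immediately
followed by one of *with, and, or, but, within, while, whereas*. Scope is
rightward only; constructions like "X is absent" are not resolved
(limitation, below).

Entity-level status is then a frequency vote: an entity is negated iff
its `in_scope` word labels are at least as many as its `out_of_scope`
labels. The exact-tie case is not dictated by any rule we inherit, so we
chose *negated*: for exclusion criteria a false "negated" keeps a patient
out of an automatically proposed cohort, which is the conservative
failure direction for prescreening. The aggregation is verified against
an exhaustive counting oracle for every label vector up to length 6.

Sentences are always terminated before scope detection
(`ensure_terminal_period`): list-formatted criteria frequently lack the
final period, and a missing terminator is precisely the situation where a
trailing entity ("… except prior thyroiditis") loses its scope.

## Temporal normalization

All units are unified to days: weeks ×7, months ×30, years ×365, hours
`ceiling(q/24)`. Month length is a convention (28/30/30.44 are all
defensible); 30 is the common clinical choice and is overridable via
`cc_options(days_per_month =)`. Hours round *up* so that a 72-hour
lookback never shrinks below 3 days — for an eligibility window the safe
error is the wider one.

Windows are `(start_days, start_offset, end_days, end_offset)` with −1 =
before, +1 = after the index start date, and the invariant
`start_offset·start_days ≤ end_offset·end_days` on the signed axis.
The grammar:

| pattern | window |
|---|---|
| at least N *u* before | (9999, −1, N_d, −1) |
| within / up to N *u* before | (N_d, −1, 0, −1) |
| A *u* to B *u* after | (A_d, +1, B_d, +1) |
| A *u* before to B *u* after | (A_d, −1, B_d, +1) |
| `>`N *u* before | as "at least" |

9999 is the open-window sentinel (overridable, `cc_options(unbounded_days =)`).
Two conventions are ours rather than inherited: "within N *u*" with no
direction word defaults to *before* (the dominant clinical usage), and a
bare "N *u* before" is read as a within-style window touching the index
date. Date literals ("since January 1, 2020") are rejected with a
distinct error class instead of guessed: converting them would need an
anchor date the representation does not carry. "currently" and friends
fail with a no-time-span error, mirroring the categories a test-set
builder would exclude.

## Value normalization

Operators come from an editable phrase→symbol dictionary; longest phrase
wins; a bare number defaults to `=`. Ranges ("a-b", "a to b",
"between a and b") become `(>= a, <= b)` joined by *and* — bounds
inclusive, matching the "between" phrasing; a descending range is a
malformed-range error, not silently reordered. `N+` means `>= N`. A
percent sign scales only the adjacent number(s) — one trailing `%` scales
both ends of a range — and scaling is done by shifting the decimal point
in the digit string, not by floating-point division, so "34.4%" is
exactly the printed 0.344. The unit is the text after the last value
number minus operator phrases, with one guard: a number matching
`/<n>-<time-unit>` (as in "g/24-hours") is part of the unit denominator
and never a value. Roman numerals are limited to I–X; clinical grades and
stages rarely exceed X, and beyond that a parse error is more honest than
a guess. Purely qualitative values ("positive") are out of scope by
design and raise a not-a-value error.

## Editing and the event log

All five modification operations are pure functions returning a new
document with one appended event (strictly increasing sequence numbers),
so any final state is reproducible by replaying the log on the machine
baseline — which is also the undo mechanism. Overlap semantics had to be
decided here: a human annotation *supersedes* (removes) machine
annotations it overlaps; two human annotations may share an *identical*
span (one text span, several concepts), while a partial human–human
overlap is a conflict error. Concept search is local: exact is
case-insensitive full-string match on names and synonyms; fuzzy ranks by
normalized edit similarity with standard concepts first at equal
similarity, then ascending concept id for determinism.

## Query compilation

Domain→table mapping follows OMOP CDM v5 conventions. Value constraints
attach to the nearest *preceding* Measurement entity in the criterion;
temporal constraints attach to every clinical entity in their criterion.
Presence composes section with negation — inclusion+plain presence,
inclusion+negated absence, exclusion+plain absence, exclusion+negated
presence; the double-negative cell is stated explicitly because nothing
upstream defines it. Within one entity, multiple concepts are OR
(`IN (...)`); across clauses AND — the standard cohort-definition
reading, flagged as an assumption. The index date is each person's
`observation_period_start_date`; age is `floor(days/365.25)`. Value
comparisons use `value_as_number` with case-insensitive unit string
equality when both sides carry units; unit *conversion* is out of scope.
SQL is deterministic text; SQLite is executed (DBI/RSQLite), PostgreSQL
text is emitted for parity. Correctness is established by equivalence
with an independent brute-force evaluator (plain data-frame filtering,
no shared code) over hundreds of randomized (query, database) pairs, plus
monotonicity and presence/absence partition properties.

## What the generators emulate — and what a green test does not establish

The criteria-corpus generator composes sentences from templates spanning
every rule family (every operator phrase, every time unit and temporal
form including the ">72 h" trap, ranges, Roman numerals, percents, "+"
suffixes, the "g/24-hours" denominator trap, every negation cue with a
clause boundary, sentences with and without terminal punctuation, and
date-literal / no-time-span negative cases), with spans recorded during
construction and magnitudes a protocol would plausibly use (hours ≤ 96,
days ≤ 60, weeks ≤ 12, months ≤ 12, years ≤ 5). The OMOP-lite generator
plants concepts into exactly known carrier sets with controllable day
offsets and measurement values, plus noise rows from a disjoint concept
range.

These fixtures establish *internal* consistency: the rules recover what
the templates encode, and SQL matches brute-force semantics on stores
whose ground truth is known by construction. They do not establish
performance on real eligibility text — no misspellings, no ungrammatical
ellipsis, no vocabulary coverage gaps, no inter-annotator ambiguity — and
no corpus-level accuracy figure is claimed anywhere in this package.

## Known limitations

- The scope labeler is clause-boundary based and rightward-only; it will
  over-scope long conjunction chains a trained model would split.
- Nested constraints ("two or more doses of > 60 mg") are not
  representable and are deliberately excluded.
- Unit conversion (mg/dL ↔ mmol/L) is not attempted; mismatched units
  simply fail the unit-equality predicate.
- Person attributes match on the person table's gender/race strings
  against the concept name, a convention of the bundled OMOP-lite schema.
- One temporal window per criterion is applied (the first), even if
  several temporal entities are present.
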