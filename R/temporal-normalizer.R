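# Temporal normalization: free-text time expressions -> day-unit windows
# relative to the index start date.

TIME_UNIT_TABLE <- list(
  hour = c("hour", "hours", "hr", "hrs", "h"),
  day = c("day", "days", "d"),
  week = c("week", "weeks", "wk", "wks"),
  month = c("month", "months", "mo", "mos"),
  year = c("year", "years", "yr", "yrs")
)

canonical_unit <- function(unit) {
  u <- tolower(trimws(unit))
  for (canon in names(TIME_UNIT_TABLE))
    if (u %in% TIME_UNIT_TABLE[[canon]]) return(canon)
  cc_stop("unit_error", sprintf("unknown time unit '%s'", unit), unit = unit)
}

#' Convert a quantity with a time unit to whole days
#'
#' Unifies every supported unit to days: hours round up
#' (`ceiling(q / 24)`, so a 72-hour lookback is 3 full days and never
#' shrinks), weeks are 7 days, months 30, years 365 (both overridable via
#' [cc_options()]).
#'
#' @param quantity non-negative numeric.
#' @param unit one of hour(s)/h/hr, day(s)/d, week(s)/wk, month(s)/mo,
#'   year(s)/yr; anything else is a `unit_error` naming the unit.
#' @return integer number of days, >= 0.
#' @export
to_days <- function(quantity, unit) {
  if (quantity < 0) cc_stop("validation_error", "quantity must be >= 0")
  opt <- cc_options()
  switch(canonical_unit(unit),
         hour = as.integer(ceiling(quantity / 24)),
         day = as.integer(round(quantity)),
         week = as.integer(round(quantity * opt$days_per_week)),
         month = as.integer(round(quantity * opt$days_per_month)),
         year = as.integer(round(quantity * opt$days_per_year)))
}

#' Load the time-order word dictionary
#'
#' @param path CSV with columns phrase, direction ("before"/"after");
#'   defaults to the bundled dictionary ("prior to" -> before, "post" ->
#'   after, ...).
#' @return named character vector, phrases sorted longest first.
#' @export
time_order_dictionary <- function(path = cc_options()$time_order_file) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  dict <- stats::setNames(d$direction, d$phrase)
  dict[order(-nchar(names(dict)))]
}

#' Normalize a time-order expression to a direction
#'
#' @param text text containing a time-order word ("prior to", "post", ...).
#' @param dict dictionary from [time_order_dictionary()].
#' @return `"before"` or `"after"`; a text with no direction word raises a
#'   `direction_missing_error` (the class of entities "without a specific
#'   reference time point").
#' @export
normalize_time_order <- function(text, dict = time_order_dictionary()) {
  lowered <- tolower(text)
  for (phrase in names(dict)) {
    pat <- paste0("\\b", gsub("([\\W])", "\\\\\\1", phrase, perl = TRUE), "\\b")
    if (grepl(pat, lowered, perl = TRUE)) return(unname(dict[phrase]))
  }
  cc_stop("direction_missing_error",
          sprintf("no time-order word in '%s'", text))
}

DATE_LITERAL_RE <- paste0(
  "(?i)\\b(january|february|march|april|may|june|july|august|september|",
  "october|november|december)\\b\\s+[0-9]|\\b[0-9]{1,2}/[0-9]{1,2}/[0-9]{2,4}\\b")

TEMPORAL_NUM_UNIT_RE <- paste0(
  "([0-9]+(?:\\.[0-9]+)?)[-–\\s]*(", TIME_UNIT_RE, ")\\b")

# number+unit pairs in day units, skipping unit denominators ("g/24-hours")
extract_day_quantities <- function(text) {
  m <- gregexpr(TEMPORAL_NUM_UNIT_RE, text, perl = TRUE, ignore.case = TRUE)[[1]]
  if (m[1] == -1L) return(integer())
  len <- attr(m, "match.length")
  out <- integer()
  for (i in seq_along(m)) {
    piece <- substring(text, m[i], m[i] + len[i] - 1L)
    if (grepl("/\\s*$", substr(text, 1, m[i] - 1L))) next  # denominator
    g <- regmatches(piece, regexec(TEMPORAL_NUM_UNIT_RE, piece,
                                   perl = TRUE, ignore.case = TRUE))[[1]]
    out <- c(out, to_days(as.numeric(g[2]), g[3]))
  }
  out
}

signed_to_constraint <- function(lo, hi, direction_sign) {
  off <- function(s) if (s < 0L) -1L else if (s > 0L) 1L else direction_sign
  temporal_constraint(abs(lo), off(lo), abs(hi), off(hi))
}

#' Normalize a free-text temporal expression to a day window
#'
#' Maps expressions such as "at least 5 days before the leukapheresis
#' procedure" or "Two weeks to 1-year post hospital discharge" to a
#' [temporal_constraint()] on the signed day axis (before the index date =
#' negative):
#' \itemize{
#'   \item "at least N \emph{unit} before" -> starts between UNBOUNDED and N
#'     days before (UNBOUNDED sentinel = 9999, see [cc_options()]);
#'   \item "within/up to N \emph{unit} before" -> between N days before and
#'     the index date; "within" with no direction word defaults to before;
#'   \item "A to B \emph{unit} after" -> between A and B days after;
#'   \item "A \emph{unit} before to B \emph{unit} after" spans the index
#'     date.
#' }
#' Word-form numbers and Roman numerals are accepted; hours are rounded up
#' to whole days.
#'
#' @param text the temporal expression.
#' @return a [temporal_constraint()]. Errors: `date_literal_error` for
#'   calendar dates ("since January 1, 2020"), `no_time_span_error` when no
#'   number+unit is present ("currently"), `direction_missing_error` when no
#'   reference direction can be inferred.
#' @export
normalize_temporal <- function(text) {
  raw <- trimws(text)
  if (grepl(DATE_LITERAL_RE, raw, perl = TRUE))
    cc_stop("date_literal_error",
            sprintf("date-literal expression '%s' cannot be made index-relative", raw))
  work <- digitize_numbers(raw)
  days <- extract_day_quantities(work)
  if (!length(days))
    cc_stop("no_time_span_error", sprintf("no clear time span in '%s'", raw))

  lowered <- tolower(work)
  unbounded <- as.integer(cc_options()$unbounded_days)
  dir <- tryCatch(normalize_time_order(lowered), error = function(e) e)
  if (inherits(dir, "direction_missing_error")) {
    if (grepl("\\bwithin\\b", lowered)) dir <- "before"  # dominant clinical usage
    else stop(dir)
  }
  sgn <- if (dir == "before") -1L else 1L

  at_least <- grepl("\\b(at least|more than|greater than|over|a minimum of|no less than)\\b",
                    lowered, perl = TRUE) || grepl("[>≥]\\s*[0-9]", lowered)
  within <- grepl("\\b(within|up to|less than|under|at most|no more than|inside)\\b",
                  lowered, perl = TRUE) || grepl("[<≤]\\s*[0-9]", lowered)

  if (length(days) >= 2L) {
    # "A ... before ... B ... after" spans the index date
    before_pos <- regexpr("\\b(before|prior|preceding)\\b", lowered, perl = TRUE)
    after_pos <- regexpr("\\b(after|post|following|since)\\b", lowered, perl = TRUE)
    if (before_pos > 0L && after_pos > 0L && before_pos < after_pos) {
      return(signed_to_constraint(-days[1], days[2], sgn))
    }
    lo <- sgn * days[1]; hi <- sgn * days[2]
    return(signed_to_constraint(min(lo, hi), max(lo, hi), sgn))
  }

  n <- days[1]
  if (at_least) {
    if (sgn < 0L) signed_to_constraint(-unbounded, -n, sgn)
    else signed_to_constraint(n, unbounded, sgn)
  } else {
    # "within"-style windows touch the index date; a bare "N unit before"
    # is read the same way (documented convention)
    if (sgn < 0L) signed_to_constraint(-n, 0L, sgn)
    else signed_to_constraint(0L, n, sgn)
  }
}
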