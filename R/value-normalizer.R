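# Value normalization: free-text thresholds and ranges -> operator/value
# terms with a logical connector and a unit string.

WORD_NUMBERS <- c(
  zero = 0, one = 1, two = 2, three = 3, four = 4, five = 5, six = 6,
  seven = 7, eight = 8, nine = 9, ten = 10, eleven = 11, twelve = 12,
  thirteen = 13, fourteen = 14, fifteen = 15, sixteen = 16, seventeen = 17,
  eighteen = 18, nineteen = 19, twenty = 20, thirty = 30, forty = 40,
  fifty = 50, sixty = 60, seventy = 70, eighty = 80, ninety = 90,
  hundred = 100
)
ROMAN_NUMERALS <- c(I = 1, II = 2, III = 3, IV = 4, V = 5,
                    VI = 6, VII = 7, VIII = 8, IX = 9, X = 10)

#' Convert a number token to its numeric value
#'
#' Accepts digit strings ("2.5"), English number words ("two"), and Roman
#' numerals I through X ("III" -> 3). Roman numerals beyond X are a parse
#' error, not a guess.
#'
#' @param text a single number token.
#' @return a numeric scalar.
#' @export
words_to_number <- function(text) {
  tok <- trimws(text)
  if (grepl("^[0-9]+(\\.[0-9]+)?$", tok)) return(as.numeric(tok))
  if (toupper(tok) %in% names(ROMAN_NUMERALS) && grepl("^[IVXivx]+$", tok))
    return(unname(ROMAN_NUMERALS[toupper(tok)]))
  if (tolower(tok) %in% names(WORD_NUMBERS))
    return(unname(WORD_NUMBERS[tolower(tok)]))
  cc_stop("number_parse_error", sprintf("cannot parse number token '%s'", tok),
          token = tok)
}

#' Load the comparison-operator dictionary
#'
#' @param path CSV with columns phrase, symbol; defaults to the bundled
#'   dictionary ("up to" -> `<=`, "or higher" -> `>=`, ...).
#' @return a named character vector, phrases sorted longest first.
#' @export
operator_dictionary <- function(path = cc_options()$operator_file) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  ops <- stats::setNames(d$symbol, d$phrase)
  ops[order(-nchar(names(ops)))]
}

#' Map a comparison phrase to its operator symbol
#'
#' Longest dictionary phrase found anywhere in `text` wins; a text with no
#' operator phrase (a bare number context) defaults to `=`.
#'
#' @param text free text possibly containing a comparison phrase or symbol.
#' @param dict operator dictionary from [operator_dictionary()].
#' @return one of `<`, `<=`, `>`, `>=`, `=`, `<>`.
#' @export
parse_comparison <- function(text, dict = operator_dictionary()) {
  lowered <- tolower(text)
  for (phrase in names(dict)) {
    pat <- if (grepl("^[A-Za-z]", phrase)) {
      paste0("\\b", gsub("([\\W])", "\\\\\\1", phrase, perl = TRUE), "\\b")
    } else {
      gsub("([\\W])", "\\\\\\1", phrase, perl = TRUE)
    }
    if (grepl(pat, lowered, perl = TRUE)) return(unname(dict[phrase]))
  }
  "="
}

# Scale a number string by 1/100 by shifting its decimal point, so that
# "34.4" becomes exactly the printed "0.344" rather than 34.4/100 in binary
# floating point.
shift_percent <- function(numstr) {
  parts <- strsplit(numstr, ".", fixed = TRUE)[[1]]
  int <- parts[1]
  frac <- if (length(parts) > 1) parts[2] else ""
  digits <- paste0(int, frac)
  point <- nchar(int) - 2L
  out <- if (point <= 0L) {
    paste0("0.", strrep("0", -point), digits)
  } else {
    paste0(substr(digits, 1, point), ".", substr(digits, point + 1L, nchar(digits)))
  }
  as.numeric(out)
}

# Replace word-form and Roman numbers with digits, preserving string length
# is NOT required here because the caller re-locates numbers afterwards.
digitize_numbers <- function(text) {
  toks <- cc_tokenize(text)
  if (!nrow(toks)) return(text)
  out <- text
  # replace right-to-left so earlier offsets stay valid
  for (i in rev(seq_len(nrow(toks)))) {
    tk <- toks$token[i]
    val <- NULL
    if (toupper(tk) %in% names(ROMAN_NUMERALS) && grepl("^[IVX]+$", tk)) {
      val <- ROMAN_NUMERALS[toupper(tk)]
    } else if (tolower(tk) %in% names(WORD_NUMBERS)) {
      val <- WORD_NUMBERS[tolower(tk)]
    }
    if (!is.null(val)) {
      out <- paste0(substr(out, 1, toks$start[i]),
                    format(unname(val), scientific = FALSE),
                    substr(out, toks$end[i] + 1L, nchar(out)))
    }
  }
  out
}

# Locate candidate value numbers, excluding numbers that are part of a unit
# denominator ("g/24-hours": the 24 is never a value).
locate_numbers <- function(text) {
  m <- gregexpr("[0-9]+(?:\\.[0-9]+)?", text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(data.frame(start = integer(), end = integer(),
                                     num = character()))
  len <- attr(m, "match.length")
  df <- data.frame(start = as.integer(m) - 1L, end = as.integer(m) + len - 1L,
                   num = substring(text, m, m + len - 1L),
                   stringsAsFactors = FALSE)
  keep <- vapply(seq_len(nrow(df)), function(i) {
    before <- substr(text, 1, df$start[i])
    after <- substr(text, df$end[i] + 1L, nchar(text))
    # denominator guard: "/<number>-?<time-unit>"
    !(grepl("/\\s*$", before) &&
        grepl(paste0("^-?\\s*", TIME_UNIT_RE, "\\b"), after, perl = TRUE, ignore.case = TRUE))
  }, logical(1))
  df[keep, , drop = FALSE]
}

strip_operator_phrases <- function(text, dict) {
  out <- text
  for (phrase in names(dict)) {
    pat <- if (grepl("^[A-Za-z]", phrase)) {
      paste0("(?i)\\b", gsub("([\\W])", "\\\\\\1", phrase, perl = TRUE), "\\b")
    } else {
      gsub("([\\W])", "\\\\\\1", phrase, perl = TRUE)
    }
    out <- gsub(pat, " ", out, perl = TRUE)
  }
  out
}

#' Normalize a free-text value expression
#'
#' Turns expressions such as `"34.4-44.6%"`, `"III or higher"`,
#' `"> 200 IU/L"` or `"3 g/24-hours"` into a [value_constraint()]:
#' \itemize{
#'   \item a `%` adjacent to a number divides it by 100 and clears the unit;
#'     one `%` at the end of a range scales both bounds;
#'   \item hyphen/en-dash/"to"/"between ... and" ranges become
#'     `(>= a, <= b)` with `logic = "and"`; a descending range is a
#'     `malformed_range_error`;
#'   \item `"N+"` means `>= N`;
#'   \item text after the last number that is not an operator phrase is the
#'     unit; numbers inside a `"/<n>-<time-unit>"` denominator are never
#'     extracted as values.
#' }
#'
#' @param text the value expression.
#' @param dict operator dictionary.
#' @return a [value_constraint()].
#' @export
normalize_value <- function(text, dict = operator_dictionary()) {
  raw <- trimws(text)
  work <- digitize_numbers(raw)
  nums <- locate_numbers(work)
  if (!nrow(nums))
    cc_stop("not_a_value_error",
            sprintf("no number found in '%s'; span is not a value entity", raw))

  percent_at <- function(i) {
    after <- substr(work, nums$end[i] + 1L, nchar(work))
    grepl("^\\s*%", after)
  }

  unit_from <- function(end_pos) {
    tail <- substr(work, end_pos + 1L, nchar(work))
    tail <- sub("^\\s*%", "", tail)               # percent is scaling, not unit
    tail <- sub("^\\s*\\+", "", tail)
    tail <- strip_operator_phrases(tail, dict)
    trimws(gsub("\\s+", " ", tail))
  }

  # --- range forms -----------------------------------------------------------
  if (nrow(nums) >= 2L) {
    between_form <- grepl("(?i)\\bbetween\\b", work, perl = TRUE) &&
      grepl("(?i)\\band\\b", work, perl = TRUE)
    sep <- substr(work, nums$end[1] + 1L, nums$start[2])
    dash_form <- grepl("^\\s*[-–—]\\s*$", sep)
    to_form <- grepl("(?i)^\\s*to\\s*$", sep, perl = TRUE)
    if (between_form || dash_form || to_form) {
      a <- as.numeric(nums$num[1]); b <- as.numeric(nums$num[2])
      scaled <- percent_at(2)   # one trailing % scales both bounds
      if (scaled) {
        a <- shift_percent(nums$num[1]); b <- shift_percent(nums$num[2])
      } else if (percent_at(1)) {
        a <- shift_percent(nums$num[1])
      }
      if (a > b)
        cc_stop("malformed_range_error",
                sprintf("descending range %s-%s", nums$num[1], nums$num[2]))
      unit <- if (scaled) "" else unit_from(nums$end[2])
      return(value_constraint(list(list(op = ">=", value = a),
                                   list(op = "<=", value = b)),
                              logic = "and", unit = unit))
    }
    # two full comparisons joined by "or"/"and": "< 3 or > 10"
    joiner <- regmatches(sep, regexpr("(?i)\\b(or|and)\\b", sep, perl = TRUE))
    if (length(joiner) == 1L) {
      left <- substr(work, 1, nums$end[1])
      right <- substr(work, nums$end[1] + 1L, nums$end[2])
      terms <- list(
        list(op = parse_comparison(left, dict), value = as.numeric(nums$num[1])),
        list(op = parse_comparison(right, dict), value = as.numeric(nums$num[2])))
      return(value_constraint(terms, logic = tolower(joiner),
                              unit = unit_from(nums$end[2])))
    }
  }

  # --- single comparison -----------------------------------------------------
  n <- nums[1, , drop = FALSE]
  val <- as.numeric(n$num)
  after <- substr(work, n$end + 1L, nchar(work))
  scaled <- grepl("^\\s*%", after)
  if (scaled) val <- shift_percent(n$num)
  op <- if (grepl("^\\s*\\+", after)) ">=" else parse_comparison(work, dict)
  unit <- if (scaled) "" else unit_from(n$end)
  value_constraint(list(list(op = op, value = val)), logic = "single",
                   unit = unit)
}
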