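#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

# Structured errors: every failure mode carries a condition class so callers
# (and the CLI) can dispatch on it rather than parse messages.
cc_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "cohortcriteria_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

cc_warn <- function(class, msg) {
  warning(structure(
    class = c(class, "cohortcriteria_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# Runtime configuration. Every convention the source material leaves open
# (unbounded sentinel, month length, resource paths) is overridable here and
# from the CLI config file.
.cc_env <- new.env(parent = emptyenv())

cc_default_options <- function() {
  list(
    unbounded_days = 9999L,
    days_per_month = 30L,
    days_per_year  = 365L,
    days_per_week  = 7L,
    cue_file       = system.file("extdata", "negation_cues.txt", package = "cohortcriteria"),
    operator_file  = system.file("extdata", "operator_dictionary.csv", package = "cohortcriteria"),
    time_order_file = system.file("extdata", "time_order.csv", package = "cohortcriteria")
  )
}

#' Get or set package conventions
#'
#' Tunable constants (the unbounded-window sentinel, month/year lengths in
#' days, resource-file paths). Called with no arguments returns the current
#' list; named arguments update values and return the previous list
#' invisibly.
#'
#' @param ... named options to set.
#' @return the option list (current values).
#' @export
cc_options <- function(...) {
  if (is.null(.cc_env$options)) .cc_env$options <- cc_default_options()
  new <- list(...)
  if (!length(new)) return(.cc_env$options)
  old <- .cc_env$options
  stopifnot(!is.null(names(new)), all(names(new) %in% names(old)))
  .cc_env$options[names(new)] <- new
  invisible(old)
}

# Word tokens with 0-based half-open character offsets.
cc_tokenize <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*", text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(
    token = substring(text, m, m + len - 1L),
    start = as.integer(m) - 1L,
    end   = as.integer(m) + len - 1L,
    stringsAsFactors = FALSE
  )
}

# substring by 0-based half-open span
cc_slice <- function(text, start, end) substr(text, start + 1L, end)

cc_read_lines <- function(path) {
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
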