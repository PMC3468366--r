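# Condition helpers. Error classes drive both testing and the CLI exit
# codes: usage/parse/integrity errors are input problems (exit 2),
# undefined-value errors are computational (exit 1).

cogbias_error <- function(msg, class, ...) {
  structure(
    class = c(class, "cogbias_error", "error", "condition"),
    list(message = msg, call = sys.call(-2), ...)
  )
}

stop_parse <- function(msg, ...) stop(cogbias_error(msg, "cogbias_parse_error", ...))
stop_integrity <- function(msg, ...) stop(cogbias_error(msg, "cogbias_integrity_error", ...))
stop_undefined <- function(msg, ...) stop(cogbias_error(msg, "cogbias_undefined_error", ...))
stop_usage <- function(msg, ...) stop(cogbias_error(msg, "cogbias_usage_error", ...))
stop_io <- function(msg, ...) stop(cogbias_error(msg, "cogbias_io_error", ...))

# Scores are rendered with 4 decimals in TSV output; full precision is kept
# in memory.
fmt_score <- function(x) sprintf("%.4f", x)

`%||%` <- function(a, b) if (is.null(a)) b else a

first_bad_char <- function(seq, allowed_regex) {
  pos <- regexpr(allowed_regex, seq)
  as.integer(pos)
}

check_alphabet <- function(seq, bad_regex, what) {
  pos <- regexpr(bad_regex, seq)
  if (pos > 0L) {
    stop_parse(sprintf("invalid %s character '%s' at position %d",
                       what, substr(seq, pos, pos), as.integer(pos)))
  }
  invisible(TRUE)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}
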