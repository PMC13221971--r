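#' Minimal preprocessing of raw medication strings
#'
#' Applies exactly three rules, in order: parenthesized substrings (with
#' their parentheses) are removed, innermost-out so nesting unwinds fully;
#' runs of whitespace collapse to single spaces and leading/trailing
#' whitespace is stripped; the result is uppercased. Nothing else — no
#' spelling correction, abbreviation expansion, or dose parsing — so the
#' original lexical content is preserved for matching and caching.
#'
#' Unbalanced parentheses are treated as truncation artifacts: an unmatched
#' `(` removes everything to the end of the string, an unmatched `)`
#' removes everything from the start. Non-ASCII characters pass through
#' case-folded. An empty or all-parenthetical input yields `""`, which the
#' pipeline flags as unmappable downstream.
#'
#' @param raw character vector of raw medication strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' preprocess_string("GANI-TUSS-DM NR (A.F., S.F., RASPBERRY)")
#' preprocess_string("  potass. cl   10meq @@ ")
preprocess_string <- function(raw) {
  vapply(as.character(raw), preprocess_one, character(1), USE.NAMES = FALSE)
}

preprocess_one <- function(x) {
  if (is.na(x)) return("")
  repeat {
    y <- gsub("\\([^()]*\\)", " ", x)
    if (identical(y, x)) break
    x <- y
  }
  # leftovers are unbalanced: drop from first "(" to end, start to last ")"
  x <- sub("\\(.*$", " ", x)
  x <- sub("^.*\\)", " ", x)
  x <- gsub("\\s+", " ", x)
  toupper(trimws(x))
}
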