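#' Token-set normalization
#'
#' Splits a string on every non-alphanumeric character, drops empty tokens,
#' uppercases, and deduplicates to a set. This is the tokenization used on
#' both sides of the Jaccard comparison in [approximate_match()].
#'
#' @param s a single string.
#' @return Character vector of unique uppercase tokens (possibly empty).
#' @export
#' @examples
#' normalize_tokens("ACETAM CODEINE #3")
#' normalize_tokens("LO/OVRAL 28")
normalize_tokens <- function(s) {
  if (is.na(s) || s == "") return(character(0))
  toks <- strsplit(toupper(s), "[^A-Za-z0-9]+")[[1]]
  unique(toks[toks != ""])
}

#' Jaccard similarity of two token sets
#'
#' \eqn{|a \cap b| / |a \cup b|}, defined as 0 when both sets are empty.
#' Whole tokens only: no partial-token credit, so a single-character
#' misspelling inside a token scores 0 for that token. This deliberately
#' keeps the deterministic path weak on misspellings, which are handed to
#' the parser backend instead.
#'
#' @param a,b character vectors treated as sets.
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(a) + length(b) - sum(a %in% b)
  if (u == 0) return(0)
  sum(a %in% b) / u
}

TTY_PRIORITY <- c(IN = 1, MIN = 2, PIN = 3, BN = 4, SCD = 5, SBD = 6,
                  OTHER = 7)

#' Approximate string matching against the term index
#'
#' Scores every entry of the knowledge base's term index by Jaccard
#' similarity between the normalized token sets of the query and the term,
#' and returns candidates at or above `min_score` ranked by score
#' (descending), then term-type priority (IN > MIN > PIN > BN > SCD > SBD >
#' OTHER), then identifier. The ranking is a total order, so repeated calls
#' return an identical list.
#'
#' @param kb a `med_kb`.
#' @param query a preprocessed string (see [preprocess_string()]).
#' @param min_score minimum Jaccard similarity retained (default 0.5, i.e.
#'   majority token overlap).
#' @return Tibble with columns `rxcui`, `matched_term`, `tty`, `score`,
#'   best match first; zero rows when nothing clears the threshold.
#' @export
approximate_match <- function(kb, query, min_score = 0.5) {
  stopifnot(inherits(kb, "med_kb"))
  q <- normalize_tokens(query)
  scores <- vapply(kb$term_tokens, function(t) jaccard(q, t), numeric(1))
  keep <- which(scores >= min_score)
  out <- tibble(
    rxcui = kb$terms$rxcui[keep],
    matched_term = kb$terms$term[keep],
    tty = unname(kb$tty_of[kb$terms$rxcui[keep]]),
    score = scores[keep]
  )
  if (nrow(out) == 0) return(out)
  num <- grepl("^[0-9]+$", out$rxcui)
  cui_key <- ifelse(num,
                    sprintf("0%020.0f", suppressWarnings(as.numeric(out$rxcui))),
                    paste0("Z", out$rxcui))
  out[order(-out$score, TTY_PRIORITY[out$tty], cui_key), ]
}

# Resolve an arbitrary concept to an active generic (IN or MIN) along the
# default relationship paths: IN/MIN -> self; PIN -> form_of; BN ->
# tradename_of; SCD/SBD -> ingredient set -> covering generic. Returns NULL
# when no active generic is reachable.
resolve_to_generic <- function(kb, rxcui, seen = character(0)) {
  if (rxcui %in% seen) {
    kb_abort(sprintf("relationship cycle at rxcui %s", rxcui),
             "resolution_error")
  }
  seen <- c(seen, rxcui)
  tty <- kb$tty_of[[rxcui]] %||% return(NULL)
  if (tty %in% c("IN", "MIN")) {
    if (!kb$active_of[[rxcui]]) return(NULL)
    return(concept_row(kb, rxcui))
  }
  if (tty %in% c("SCD", "SBD")) {
    ings <- rel_targets(kb, rxcui, "has_ingredient")
    if (length(ings) == 0) return(NULL)
    return(find_generic_by_ingredients(kb, ings))
  }
  step <- switch(tty, PIN = "form_of", BN = "tradename_of", return(NULL))
  for (nxt in rel_targets(kb, rxcui, step)) {
    hit <- resolve_to_generic(kb, nxt, seen)
    if (!is.null(hit)) return(hit)
  }
  NULL
}

#' Deterministic candidate generation
#'
#' Takes the single best [approximate_match()] candidate and resolves its
#' concept through the relationship graph to an active generic (`IN` or
#' `MIN`). Returns `NULL` when nothing clears the score threshold or the
#' resolution dead-ends; paths may traverse inactive or non-generic
#' concepts, but the returned generic is always active.
#'
#' @inheritParams approximate_match
#' @return A `det_candidate` (see [det_candidate()]) or `NULL`.
#' @export
deterministic_candidate <- function(kb, query, min_score = 0.5) {
  hits <- approximate_match(kb, query, min_score = min_score)
  if (nrow(hits) == 0) return(NULL)
  generic <- resolve_to_generic(kb, hits$rxcui[1])
  if (is.null(generic)) return(NULL)
  det_candidate(kb, generic, score = hits$score[1],
                matched_term = hits$matched_term[1])
}

#' Construct a deterministic candidate
#'
#' Bundles an active generic concept with its ingredient identifiers and the
#' ingredient-name set used for tier-1 reconciliation. By default the names
#' are the canonical preferred names of the ingredient concepts; supplying
#' `ingredient_names` lets callers represent candidates whose ingredient
#' names surfaced in a non-canonical form (salt or chemical synonyms).
#'
#' @param kb a `med_kb`.
#' @param generic one-row concept tibble with `tty` IN or MIN, active.
#' @param score Jaccard score of the originating match.
#' @param matched_term the surface term that produced the match.
#' @param ingredient_names uppercase ingredient-name set; defaults to the
#'   preferred names of the ingredient concepts.
#' @return A `det_candidate` list: `generic`, `ingredient_set`,
#'   `ingredient_names`, `score`, `matched_term`.
#' @export
det_candidate <- function(kb, generic, score = 1, matched_term = NA_character_,
                          ingredient_names = NULL) {
  stopifnot(generic$tty %in% c("IN", "MIN"), generic$active == 1L)
  ingredient_set <- ingredients_of(kb, generic$rxcui)
  structure(
    list(
      generic = generic,
      ingredient_set = ingredient_set,
      ingredient_names = toupper(
        ingredient_names %||% unname(kb$name_of[ingredient_set])),
      score = score,
      matched_term = matched_term
    ),
    class = "det_candidate"
  )
}

#' @export
print.det_candidate <- function(x, ...) {
  cat(sprintf("<det_candidate> %s [%s] score=%.3f via '%s'\n",
              x$generic$name, x$generic$tty, x$score, x$matched_term))
  invisible(x)
}
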