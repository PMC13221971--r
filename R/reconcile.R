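MATCH_TYPES <- c("perfect", "normalized_perfect", "subset", "unmapped")
CONFIDENCE_OF <- c(perfect = "high", normalized_perfect = "moderate",
                   subset = "low", unmapped = "none")
CONFIDENCE_LEVELS <- c("none", "low", "moderate", "high")

#' Canonicalize ingredient names to knowledge-base ingredients
#'
#' Each name is independently run through the deterministic matching
#' procedure ([deterministic_candidate()]), accepting the result only when
#' it resolves to a single active `IN` concept; resolved names contribute
#' that ingredient identifier, unresolvable names go to the residue. This is
#' how salt forms and chemical synonyms (e.g. a phosphate salt name, or a
#' chemical name for a common ingredient) collapse onto canonical
#' ingredients before set comparison.
#'
#' @param kb a `med_kb`.
#' @param names character vector of uppercase ingredient names.
#' @param min_score Jaccard threshold passed to the matcher.
#' @return List with `ingredient_set` (character vector of `IN` identifiers,
#'   canonical order, deduplicated) and `residue` (names that failed to
#'   resolve, first-occurrence order).
#' @export
canonicalize_ingredient_names <- function(kb, names, min_score = 0.5) {
  ings <- character(0)
  residue <- character(0)
  for (nm in names) {
    det <- deterministic_candidate(kb, nm, min_score = min_score)
    if (!is.null(det) && det$generic$tty == "IN") {
      ings <- c(ings, det$generic$rxcui)
    } else {
      residue <- c(residue, nm)
    }
  }
  list(ingredient_set = sort_rxcuis(unique(ings)), residue = residue)
}

subset_name_key <- function(kb, members) {
  paste(sort(unname(kb$name_of[members])), collapse = "\x1f")
}

#' Greedy largest-first subset matching
#'
#' Decomposes an ingredient set into knowledge-base concepts: subsets of the
#' remaining set are enumerated in descending size (ties broken by
#' lexicographic order of the sorted member names); the first subset whose
#' ingredient set exactly equals an active `IN`/`MIN` concept's set is
#' finalized, its members are removed from the remaining set, and
#' enumeration restarts, until no subset (including singletons) matches.
#' Finalized concepts therefore partition the input: their ingredient sets
#' are pairwise disjoint and, together with the residual set, reconstruct
#' the input exactly.
#'
#' @param kb a `med_kb`.
#' @param ings non-empty character vector of ingredient (`IN`) identifiers.
#' @param cap maximum set size enumerated exhaustively (default 10); larger
#'   inputs raise a size error, which [reconcile()] downgrades to
#'   singleton-only matching.
#' @return List with `concepts` (concept tibble in selection order, possibly
#'   zero rows) and `residual` (unmatched ingredient identifiers).
#' @export
subset_match <- function(kb, ings, cap = 10) {
  remaining <- sort_rxcuis(unique(ings))
  stopifnot(length(remaining) >= 1)
  if (length(remaining) > cap) {
    kb_abort(sprintf("ingredient set of size %d exceeds subset cap %d",
                     length(remaining), cap), "size_error")
  }
  selected <- list()
  repeat {
    if (length(remaining) == 0) break
    hit <- NULL
    for (k in rev(seq_len(length(remaining)))) {
      subs <- utils::combn(remaining, k, simplify = FALSE)
      keys <- vapply(subs, subset_name_key, character(1), kb = kb)
      for (s in subs[order(keys)]) {
        g <- find_generic_by_ingredients(kb, s)
        if (!is.null(g)) { hit <- list(generic = g, members = s); break }
      }
      if (!is.null(hit)) break
    }
    if (is.null(hit)) break
    selected[[length(selected) + 1]] <- hit$generic
    remaining <- setdiff(remaining, hit$members)
  }
  concepts <- if (length(selected) == 0) kb$concepts[0, ] else
    dplyr::bind_rows(selected)
  list(concepts = concepts, residual = remaining)
}

new_mapping <- function(raw, preprocessed, concepts, match_type, residue,
                        det, parsed) {
  stopifnot(match_type %in% MATCH_TYPES)
  structure(
    list(
      raw = raw, preprocessed = preprocessed, concepts = concepts,
      match_type = match_type,
      confidence = unname(CONFIDENCE_OF[match_type]),
      residue = residue,
      provenance = list(det = det, parsed = parsed)
    ),
    class = "mn_mapping"
  )
}

#' Hierarchical reconciliation of the two candidate sources
#'
#' Fuses the deterministic candidate and the parsed ingredient list into
#' finalized concepts through three tiers:
#'
#' * **Tier 1 — perfect match (high confidence).** The deterministic
#'   candidate's ingredient-name set equals the parsed name set verbatim
#'   (as uppercase sets): the deterministic generic is finalized.
#' * **Tier 2 — normalized perfect match (moderate confidence).** Both name
#'   sets are canonicalized via [canonicalize_ingredient_names()]; if the
#'   resulting ingredient sets are equal and non-empty and an active generic
#'   covers the set exactly, that generic is finalized.
#' * **Tier 3 — subset match (low confidence).** [subset_match()] decomposes
#'   the canonicalized *parsed* set only (no deterministic reconciliation),
#'   finalizing possibly several concepts; unresolved names and unmatched
#'   ingredients are recorded as residue.
#'
#' A parse that is empty (or failed) while a deterministic candidate exists
#' finalizes the deterministic generic at low confidence — agreement of two
#' sources is required for anything higher. When nothing finalizes the
#' result is `unmapped` with confidence `none`.
#'
#' @param kb a `med_kb`.
#' @param det a `det_candidate` or `NULL`.
#' @param parsed a [parse_output()].
#' @param min_score Jaccard threshold used for canonicalization.
#' @param subset_cap maximum set size for exhaustive subset enumeration;
#'   beyond it, tier 3 falls back to singleton-only matching with a warning.
#' @return An `mn_mapping`: finalized `concepts` (active IN/MIN tibble),
#'   `match_type`, `confidence`, `residue`, and `provenance`.
#' @export
reconcile <- function(kb, det, parsed, min_score = 0.5, subset_cap = 10) {
  stopifnot(inherits(parsed, "parse_output"))
  parsed_names <- if (parsed$failed) character(0) else parsed$ingredient_names
  raw <- NA_character_

  # Tier 1: verbatim set agreement between the two sources
  if (!is.null(det) && length(parsed_names) > 0 &&
      setequal(toupper(det$ingredient_names), parsed_names)) {
    return(new_mapping(raw, raw, det$generic, "perfect", character(0),
                       det, parsed))
  }

  can_parsed <- canonicalize_ingredient_names(kb, parsed_names,
                                              min_score = min_score)

  # Tier 2: canonical equivalence of the two sets
  if (!is.null(det) && length(parsed_names) > 0) {
    can_det <- canonicalize_ingredient_names(kb, det$ingredient_names,
                                             min_score = min_score)
    if (length(can_det$ingredient_set) > 0 &&
        setequal(can_det$ingredient_set, can_parsed$ingredient_set)) {
      g <- find_generic_by_ingredients(kb, can_parsed$ingredient_set)
      if (!is.null(g)) {
        return(new_mapping(raw, raw, g, "normalized_perfect",
                           can_parsed$residue, det, parsed))
      }
      # equal sets but no covering generic: fall through to subset matching
    }
  }

  # Parse empty/failed but deterministic candidate present: low-confidence
  # single-source fallback.
  if (length(parsed_names) == 0 && !is.null(det)) {
    return(new_mapping(raw, raw, det$generic, "subset", character(0),
                       det, parsed))
  }

  # Tier 3: greedy subset decomposition of the parsed set only
  if (length(can_parsed$ingredient_set) > 0) {
    sm <- tryCatch(
      subset_match(kb, can_parsed$ingredient_set, cap = subset_cap),
      mednorm_size_error = function(e) {
        warn(conditionMessage(e), class = "mednorm_subset_cap_warning")
        singles <- purrr::map(can_parsed$ingredient_set, function(cui) {
          find_generic_by_ingredients(kb, cui)
        })
        hitmask <- !vapply(singles, is.null, logical(1))
        list(concepts = dplyr::bind_rows(singles[hitmask]),
             residual = can_parsed$ingredient_set[!hitmask])
      }
    )
    if (nrow(sm$concepts) > 0) {
      residue <- c(can_parsed$residue, unname(kb$name_of[sm$residual]))
      return(new_mapping(raw, raw, sm$concepts, "subset", residue,
                         det, parsed))
    }
  }

  new_mapping(raw, raw, kb$concepts[0, ], "unmapped",
              c(can_parsed$residue, unname(kb$name_of[can_parsed$ingredient_set])),
              det, parsed)
}

#' @export
print.mn_mapping <- function(x, ...) {
  cat(sprintf("<mn_mapping> %s/%s\n", x$match_type, x$confidence))
  if (nrow(x$concepts) > 0) {
    cat("  ", paste(sprintf("%s (%s)", x$concepts$name, x$concepts$rxcui),
                    collapse = " | "), "\n", sep = "")
  }
  if (length(x$residue) > 0) {
    cat("  residue:", paste(x$residue, collapse = ", "), "\n")
  }
  invisible(x)
}
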