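#' Drug knowledge base: loading, validation, and graph queries
#'
#' A `med_kb` is a local, RxNorm-like drug knowledge base held as four
#' tibbles: a concept table (`concepts`), a synonym/term index (`terms`), a
#' relationship edge table (`relationships`), and ATC attachments (`atc`).
#' Concepts carry a term type (`tty`): `IN` (single ingredient), `MIN`
#' (multi-ingredient generic), `PIN` (precise ingredient), `BN` (brand name),
#' `SCD`/`SBD` (clinical/branded drug products), or `OTHER`. Normalization
#' targets are always active `IN`/`MIN` concepts; the other types are
#' traversed via relationships but never emitted.
#'
#' @name med_kb
NULL

KB_TTYS <- c("IN", "MIN", "PIN", "BN", "SCD", "SBD", "OTHER")
KB_RELS <- c("has_ingredient", "tradename_of", "form_of", "consists_of")
KB_FILES <- c(
  concepts = "concepts.tsv", terms = "terms.tsv",
  relationships = "relationships.tsv", atc = "atc.tsv"
)
KB_HEADERS <- list(
  concepts = c("rxcui", "name", "tty", "active"),
  terms = c("term", "rxcui"),
  relationships = c("rxcui1", "rel", "rxcui2"),
  atc = c("rxcui", "atc_code", "source")
)
ATC_PATTERN <- "^[A-Z][0-9]{2}[A-Z]{2}[0-9]{2}$"

kb_abort <- function(msg, class) {
  abort(msg, class = c(paste0("mednorm_", class), "mednorm_error"))
}

# Canonical TSV rendering shared by write_kb() and the version hash: rows
# sorted on all columns (rxcui-aware), tab-separated, no quoting.
render_table <- function(df, name) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (nrow(df) > 0) {
    keys <- lapply(names(df), function(col) {
      v <- as.character(df[[col]])
      if (grepl("rxcui", col)) {
        # content-based sort key: all-digit ids numerically, others after
        num <- grepl("^[0-9]+$", v)
        ifelse(num, sprintf("0%020.0f", suppressWarnings(as.numeric(v))),
               paste0("Z", v))
      } else v
    })
    df <- df[do.call(order, keys), , drop = FALSE]
  }
  header <- paste(names(df), collapse = "\t")
  if (nrow(df) == 0) return(paste0(header, "\n"))
  body <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  paste0(header, "\n", paste(body, collapse = "\n"), "\n")
}

kb_version_id <- function(tables) {
  rendered <- vapply(
    names(KB_FILES),
    function(nm) render_table(tables[[nm]], nm),
    character(1)
  )
  rlang::hash(paste(rendered, collapse = "\x1e"))
}

#' Construct and validate a knowledge base from tables
#'
#' Checks every structural invariant: unique non-empty concept identifiers,
#' valid term types, referential integrity of the term index, relationship
#' edges and ATC attachments, no self-loop edges, `has_ingredient` targets of
#' type `IN`, every `MIN` having at least two `has_ingredient` edges and every
#' `IN` having none, level-5 ATC code syntax, and no two `MIN` concepts with
#' identical ingredient sets. A content-hash `version_id` is computed from the
#' canonical rendering of the four tables, so it changes whenever any row
#' changes.
#'
#' @param concepts tibble with columns `rxcui`, `name`, `tty`, `active` (0/1
#'   or logical).
#' @param terms tibble with columns `term`, `rxcui`.
#' @param relationships tibble with columns `rxcui1`, `rel`, `rxcui2`.
#' @param atc tibble with columns `rxcui`, `atc_code`, `source`.
#' @return A `med_kb` object.
#' @export
new_kb <- function(concepts, terms, relationships, atc) {
  concepts <- as_tibble(concepts)
  terms <- as_tibble(terms)
  relationships <- as_tibble(relationships)
  atc <- as_tibble(atc)

  for (nm in names(KB_HEADERS)) {
    tbl <- switch(nm, concepts = concepts, terms = terms,
                  relationships = relationships, atc = atc)
    missing_cols <- setdiff(KB_HEADERS[[nm]], names(tbl))
    if (length(missing_cols) > 0) {
      kb_abort(sprintf("table '%s' lacks column(s): %s", nm,
                       paste(missing_cols, collapse = ", ")), "load_error")
    }
  }

  concepts$rxcui <- as.character(concepts$rxcui)
  concepts$active <- as.integer(as.logical(as.integer(concepts$active)))
  if (any(is.na(concepts$rxcui) | concepts$rxcui == "")) {
    kb_abort("concepts.tsv contains empty rxcui", "integrity_error")
  }
  dup <- concepts$rxcui[duplicated(concepts$rxcui)]
  if (length(dup) > 0) {
    kb_abort(sprintf("duplicate rxcui in concepts: %s",
                     paste(unique(dup), collapse = ", ")), "integrity_error")
  }
  if (any(is.na(concepts$name) | concepts$name == "")) {
    kb_abort("concept with empty name", "integrity_error")
  }
  bad_tty <- setdiff(unique(concepts$tty), KB_TTYS)
  if (length(bad_tty) > 0) {
    kb_abort(sprintf("unknown tty: %s", paste(bad_tty, collapse = ", ")),
             "integrity_error")
  }

  known <- concepts$rxcui
  terms$rxcui <- as.character(terms$rxcui)
  if (any(is.na(terms$term) | terms$term == "")) {
    kb_abort("empty term in term index", "integrity_error")
  }
  if (!all(terms$rxcui %in% known)) {
    kb_abort("term index references unknown rxcui", "integrity_error")
  }

  relationships$rxcui1 <- as.character(relationships$rxcui1)
  relationships$rxcui2 <- as.character(relationships$rxcui2)
  bad_rel <- setdiff(unique(relationships$rel), KB_RELS)
  if (length(bad_rel) > 0) {
    kb_abort(sprintf("unknown relationship type: %s",
                     paste(bad_rel, collapse = ", ")), "integrity_error")
  }
  dangling <- setdiff(c(relationships$rxcui1, relationships$rxcui2), known)
  if (length(dangling) > 0) {
    kb_abort(sprintf("relationship endpoint not in concepts: %s",
                     paste(unique(dangling), collapse = ", ")),
             "integrity_error")
  }
  if (any(relationships$rxcui1 == relationships$rxcui2)) {
    kb_abort("self-loop relationship", "integrity_error")
  }

  tty_of <- stats::setNames(concepts$tty, concepts$rxcui)
  hi <- relationships[relationships$rel == "has_ingredient", , drop = FALSE]
  if (nrow(hi) > 0 && !all(tty_of[hi$rxcui2] == "IN")) {
    kb_abort("has_ingredient target is not an IN concept", "integrity_error")
  }
  n_hi <- table(factor(hi$rxcui1, levels = known))
  if (any(tty_of[known] == "MIN" & n_hi < 2)) {
    kb_abort("MIN concept with fewer than 2 has_ingredient edges",
             "integrity_error")
  }
  if (any(tty_of[known] == "IN" & n_hi > 0)) {
    kb_abort("IN concept with outgoing has_ingredient edges",
             "integrity_error")
  }

  atc$rxcui <- as.character(atc$rxcui)
  if (nrow(atc) > 0) {
    if (!all(grepl(ATC_PATTERN, atc$atc_code))) {
      kb_abort("malformed ATC code (expected level-5 pattern like N02BE01)",
               "integrity_error")
    }
    if (!all(atc$source %in% c("direct", "crosswalk"))) {
      kb_abort("atc source must be 'direct' or 'crosswalk'", "integrity_error")
    }
    if (!all(atc$rxcui %in% known)) {
      kb_abort("atc attachment references unknown rxcui", "integrity_error")
    }
  }

  tables <- list(concepts = concepts, terms = terms,
                 relationships = relationships, atc = atc)

  kb <- structure(
    c(tables, list(version_id = kb_version_id(tables))),
    class = "med_kb"
  )
  kb$tty_of <- tty_of
  kb$name_of <- stats::setNames(concepts$name, concepts$rxcui)
  kb$active_of <- stats::setNames(concepts$active == 1L, concepts$rxcui)

  # Ingredient-set index over active IN/MIN concepts; also rejects duplicate
  # MIN ingredient sets so set -> generic lookup is a function.
  idx <- new.env(parent = emptyenv())
  for (cui in known) {
    if (!(tty_of[[cui]] %in% c("IN", "MIN")) || !kb$active_of[[cui]]) next
    members <- if (tty_of[[cui]] == "IN") cui else
      sort_rxcuis(hi$rxcui2[hi$rxcui1 == cui])
    key <- paste(members, collapse = "\x1f")
    if (!is.null(idx[[key]])) {
      kb_abort(sprintf(
        "concepts %s and %s share an identical ingredient set",
        idx[[key]], cui), "integrity_error")
    }
    idx[[key]] <- cui
  }
  kb$ingset_index <- idx
  kb$term_tokens <- lapply(terms$term, normalize_tokens)
  kb
}

#' Load a knowledge base from a directory of TSV tables
#'
#' Expects `concepts.tsv`, `terms.tsv`, `relationships.tsv`, and `atc.tsv`
#' (UTF-8, tab-separated, one header row, no quoting). All invariants are
#' checked on load; see [new_kb()].
#'
#' @param kb_dir directory path.
#' @return A `med_kb` object.
#' @export
#' @examples
#' dir <- tempfile()
#' kb0 <- generate_kb(forge_params(seed = 1))
#' write_kb(kb0, dir)
#' kb <- load_kb(dir)
#' kb$version_id == kb0$version_id
load_kb <- function(kb_dir) {
  if (!dir.exists(kb_dir)) {
    kb_abort(sprintf("knowledge-base directory not found: %s", kb_dir),
             "load_error")
  }
  paths <- file.path(kb_dir, KB_FILES)
  missing <- KB_FILES[!file.exists(paths)]
  if (length(missing) > 0) {
    kb_abort(sprintf("missing knowledge-base file(s): %s",
                     paste(missing, collapse = ", ")), "load_error")
  }
  read_one <- function(nm) {
    readr::read_tsv(
      file.path(kb_dir, KB_FILES[[nm]]),
      col_types = readr::cols(.default = readr::col_character()),
      quote = "", progress = FALSE, na = character()
    )
  }
  new_kb(
    concepts = read_one("concepts"),
    terms = read_one("terms"),
    relationships = read_one("relationships"),
    atc = read_one("atc")
  )
}

#' Write a knowledge base to canonical TSV files
#'
#' Rows are written in a canonical sort order, so writing the same content
#' always produces byte-identical files.
#'
#' @param kb a `med_kb`.
#' @param kb_dir output directory (created if absent).
#' @return `kb_dir`, invisibly.
#' @export
write_kb <- function(kb, kb_dir) {
  stopifnot(inherits(kb, "med_kb"))
  dir.create(kb_dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(KB_FILES)) {
    writeLines(
      sub("\n$", "", render_table(kb[[nm]], nm)),
      file.path(kb_dir, KB_FILES[[nm]])
    )
  }
  invisible(kb_dir)
}

#' @export
print.med_kb <- function(x, ...) {
  cat(sprintf(
    "<med_kb> %d concepts (%s), %d terms, %d relationships, %d ATC rows\n",
    nrow(x$concepts),
    paste(sprintf("%s:%d", names(table(x$concepts$tty)),
                  as.integer(table(x$concepts$tty))), collapse = " "),
    nrow(x$terms), nrow(x$relationships), nrow(x$atc)
  ))
  cat(sprintf("  version_id: %s\n", x$version_id))
  invisible(x)
}

concept_row <- function(kb, rxcui) {
  i <- match(rxcui, kb$concepts$rxcui)
  if (is.na(i)) {
    kb_abort(sprintf("unknown rxcui: %s", rxcui), "lookup_error")
  }
  kb$concepts[i, ]
}

rel_targets <- function(kb, rxcui, rel) {
  r <- kb$relationships
  sort_rxcuis(r$rxcui2[r$rxcui1 == rxcui & r$rel == rel])
}

#' Expand a concept to its active-ingredient set
#'
#' Resolves any concept to the set of `IN` concepts that constitute it: an
#' `IN` is its own singleton set; a `MIN`, `SCD` or `SBD` expands through its
#' `has_ingredient` edges; a `PIN` follows `form_of`; a `BN` follows
#' `tradename_of`; each followed edge recurses until only `IN` identifiers
#' remain. A cycle guard rejects malformed relationship graphs.
#'
#' @param kb a `med_kb`.
#' @param rxcui concept identifier present in `kb`.
#' @return Character vector of ingredient (`IN`) identifiers, in canonical
#'   order.
#' @export
ingredients_of <- function(kb, rxcui) {
  expand <- function(cui, seen) {
    if (cui %in% seen) {
      kb_abort(sprintf("relationship cycle at rxcui %s", cui),
               "resolution_error")
    }
    seen <- c(seen, cui)
    tty <- kb$tty_of[[cui]] %||%
      kb_abort(sprintf("unknown rxcui: %s", cui), "lookup_error")
    next_cuis <- switch(
      tty,
      IN = return(cui),
      MIN = , SCD = , SBD = rel_targets(kb, cui, "has_ingredient"),
      PIN = rel_targets(kb, cui, "form_of"),
      BN = rel_targets(kb, cui, "tradename_of"),
      OTHER = character(0)
    )
    if (length(next_cuis) == 0) {
      kb_abort(sprintf("concept %s has no path to an ingredient", cui),
               "resolution_error")
    }
    unlist(lapply(next_cuis, expand, seen = seen))
  }
  concept_row(kb, rxcui)  # raises lookup error early for unknown ids
  sort_rxcuis(unique(expand(rxcui, character(0))))
}

#' Find the active generic concept covering an ingredient set exactly
#'
#' For a singleton set, returns the active `IN` concept with that identifier
#' if present; for larger sets, the active `MIN` whose `has_ingredient`
#' targets equal the set exactly. Inactive concepts are never returned;
#' absence of a covering generic is a `NULL` result, not an error.
#'
#' @param kb a `med_kb`.
#' @param ings non-empty character vector of ingredient identifiers.
#' @return A one-row concept tibble, or `NULL`.
#' @export
find_generic_by_ingredients <- function(kb, ings) {
  stopifnot(length(ings) >= 1)
  key <- paste(sort_rxcuis(unique(ings)), collapse = "\x1f")
  cui <- kb$ingset_index[[key]]
  if (is.null(cui)) return(NULL)
  concept_row(kb, cui)
}
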