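#' ATC annotation of a finalized generic concept
#'
#' Post-normalization annotation with Anatomical Therapeutic Chemical
#' (level-5) codes, in strict preference order:
#'
#' 1. **Direct.** ATC entries attached to the concept itself (`source =
#'    "direct"`) — coverage `full`.
#' 2. **Crosswalk.** Entries with `source = "crosswalk"` attached to *any*
#'    concept are accepted only when that concept's active-ingredient set is
#'    identical to the target's — the ingredient-identity validation that
#'    keeps pharmacologically inconsistent class assignments out — coverage
#'    `full`.
#' 3. **Subset/ingredient level.** For multi-ingredient concepts with no
#'    combination-level code, maximal classifiable proper subsets are
#'    annotated greedily (same descending-size, lexicographic-tie
#'    enumeration as [subset_match()]), then remaining individual
#'    ingredients — coverage `partial`.
#' 4. Otherwise coverage `none`.
#'
#' ATC is not one-to-one, so all accepted codes are retained, deduplicated
#' and sorted. Annotation is a pure function of the knowledge base and the
#' concept.
#'
#' @param kb a `med_kb`.
#' @param concept an active IN/MIN concept: identifier string or one-row
#'   concept tibble.
#' @return An `mn_atc` list: `rxcui`, `codes` (sorted unique), `coverage`
#'   (`"full"`, `"partial"`, or `"none"`), and `detail` (tibble of `code`,
#'   `provenance` in `{direct, crosswalk, subset-level, ingredient-level}`).
#' @export
annotate_atc <- function(kb, concept) {
  cui <- if (is.data.frame(concept)) concept$rxcui else as.character(concept)
  row <- concept_row(kb, cui)
  stopifnot(row$tty %in% c("IN", "MIN"), row$active == 1L)

  own <- atc_own_level(kb, cui)
  if (nrow(own$detail) > 0) {
    return(finish_atc(cui, own$detail, "full"))
  }

  detail <- tibble(code = character(0), provenance = character(0))
  if (row$tty == "MIN") {
    target_set <- ingredients_of(kb, cui)
    remaining <- target_set
    repeat {
      hit <- NULL
      sizes <- rev(seq_len(length(remaining)))
      sizes <- sizes[sizes < length(target_set)]  # proper subsets only
      for (k in sizes) {
        subs <- utils::combn(remaining, k, simplify = FALSE)
        keys <- vapply(subs, subset_name_key, character(1), kb = kb)
        for (s in subs[order(keys)]) {
          g <- find_generic_by_ingredients(kb, s)
          if (is.null(g)) next
          sub_own <- atc_own_level(kb, g$rxcui)
          if (nrow(sub_own$detail) > 0) {
            prov <- if (length(s) == 1) "ingredient-level" else "subset-level"
            hit <- list(members = s,
                        detail = tibble(code = sub_own$detail$code,
                                        provenance = prov))
            break
          }
        }
        if (!is.null(hit)) break
      }
      if (is.null(hit)) break
      detail <- dplyr::bind_rows(detail, hit$detail)
      remaining <- setdiff(remaining, hit$members)
      if (length(remaining) == 0) break
    }
  }
  finish_atc(cui, detail, if (nrow(detail) > 0) "partial" else "none")
}

# Direct and ingredient-identity-validated crosswalk codes for one concept.
atc_own_level <- function(kb, cui) {
  direct <- kb$atc[kb$atc$rxcui == cui & kb$atc$source == "direct", ]
  if (nrow(direct) > 0) {
    return(list(detail = tibble(code = direct$atc_code,
                                provenance = "direct")))
  }
  cw <- kb$atc[kb$atc$source == "crosswalk", ]
  if (nrow(cw) == 0) {
    return(list(detail = tibble(code = character(0),
                                provenance = character(0))))
  }
  target_set <- ingredients_of(kb, cui)
  ok <- vapply(unique(cw$rxcui), function(other) {
    other_set <- tryCatch(ingredients_of(kb, other),
                          mednorm_resolution_error = function(e) character(0))
    setequal(other_set, target_set)
  }, logical(1))
  accepted <- cw[cw$rxcui %in% unique(cw$rxcui)[ok], ]
  list(detail = tibble(
    code = accepted$atc_code,
    provenance = rep("crosswalk", nrow(accepted))
  ))
}

finish_atc <- function(cui, detail, coverage) {
  detail <- dplyr::distinct(detail)
  detail <- detail[order(detail$code), ]
  structure(
    list(rxcui = cui, codes = sort(unique(detail$code)),
         coverage = coverage, detail = detail),
    class = "mn_atc"
  )
}

#' @export
print.mn_atc <- function(x, ...) {
  cat(sprintf("<mn_atc> %s: [%s] coverage=%s\n", x$rxcui,
              paste(x$codes, collapse = ";"), x$coverage))
  invisible(x)
}
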