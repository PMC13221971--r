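#' Parameters for the synthetic knowledge-base / benchmark generator
#'
#' The generator emulates the pathology taxonomy of messy survey and
#' dispensing medication strings: brand/generic variation, abbreviations,
#' misspellings, truncation, dose/unit suffixes, parentheticals, separator
#' variation, and multi-ingredient products. Ingredient names are built from
#' syllable templates and are never real drug names, so tests cannot
#' silently depend on real-world knowledge.
#'
#' @param n_ingredients number of active single-ingredient (`IN`) concepts.
#' @param n_combos number of multi-ingredient (`MIN`) concepts, each with a
#'   distinct ingredient set.
#' @param combo_size_range integer `c(min, max)` ingredient count per combo
#'   (min at least 2, max at most the subset cap of 10).
#' @param n_brands number of brand (`BN`) concepts linked by `tradename_of`.
#' @param n_strings number of benchmark strings.
#' @param corruption_rate per-operator corruption probability applied to
#'   each benchmark surface string.
#' @param seed integer seed; everything downstream is deterministic in it.
#' @return A `forge_params` list.
#' @export
forge_params <- function(n_ingredients = 60, n_combos = 25,
                         combo_size_range = c(2, 3), n_brands = 20,
                         n_strings = 200, corruption_rate = 0.15,
                         seed = 1L) {
  p <- list(n_ingredients = as.integer(n_ingredients),
            n_combos = as.integer(n_combos),
            combo_size_range = as.integer(combo_size_range),
            n_brands = as.integer(n_brands),
            n_strings = as.integer(n_strings),
            corruption_rate = corruption_rate,
            seed = as.integer(seed))
  if (any(c(p$n_ingredients, p$n_combos, p$n_brands, p$n_strings) <= 0)) {
    kb_abort("counts must be positive", "parameter_error")
  }
  if (p$combo_size_range[1] < 2 || p$combo_size_range[2] > 10 ||
      p$combo_size_range[1] > p$combo_size_range[2]) {
    kb_abort("combo_size_range must satisfy 2 <= min <= max <= 10",
             "parameter_error")
  }
  if (p$corruption_rate < 0 || p$corruption_rate > 1) {
    kb_abort("corruption_rate must be in [0, 1]", "parameter_error")
  }
  structure(p, class = "forge_params")
}

SYLLABLES <- c("ZA", "VOR", "TIN", "MEX", "LOR", "PHA", "DRO", "NEL", "CAB",
               "RIX", "TOL", "BEN", "QUI", "SAR", "MOL", "FEN", "GLU", "PRA",
               "VEX", "TRI", "OXA", "LUM", "CET", "DAN", "KIR", "SUL", "NAV",
               "POR", "ELM", "YTH")
SALTS <- c("HYDROCHLORIDE", "SODIUM", "SULFATE", "PHOSPHATE", "MALEATE",
           "TARTRATE", "CITRATE", "ACETATE")

# draw unique pronounceable names, resampling on collision with `used`
make_names <- function(n, used, min_syl = 3, max_syl = 4) {
  out <- character(0)
  while (length(out) < n) {
    nm <- paste(sample(SYLLABLES, sample(min_syl:max_syl, 1),
                       replace = TRUE), collapse = "")
    if (!(nm %in% used) && !(nm %in% out)) out <- c(out, nm)
  }
  out
}

random_atc_code <- function() {
  paste0(sample(LETTERS, 1), sprintf("%02d", sample(0:99, 1)),
         paste(sample(LETTERS, 2, replace = TRUE), collapse = ""),
         sprintf("%02d", sample(0:99, 1)))
}

#' Generate a synthetic knowledge base
#'
#' Builds a validated `med_kb` with `n_ingredients` active `IN` concepts
#' (each with one salt-form term and one chemical-synonym term in the term
#' index), `n_combos` `MIN` concepts with distinct ingredient sets,
#' `n_brands` `BN` concepts linked by `tradename_of`, and ATC attachments:
#' a fraction of generics get a direct code, a further fraction get a code
#' only via a crosswalk attached to a clinical-drug (`SCD`) concept sharing
#' the identical ingredient set, and the remainder stay unclassifiable.
#' Combination members are drawn from the first 70% of ingredients; the
#' remaining 30% are reserved so benchmark rows that force subset matching
#' have an unambiguous decomposition. Deterministic for a given seed.
#'
#' @param params a [forge_params()].
#' @return A `med_kb` carrying generator provenance in `$forge` (consumed by
#'   [generate_benchmark()]).
#' @export
generate_kb <- function(params) {
  stopifnot(inherits(params, "forge_params"))
  p <- params
  combo_pool_n <- max(2, floor(p$n_ingredients * 0.7))
  capacity <- sum(vapply(
    p$combo_size_range[1]:min(p$combo_size_range[2], combo_pool_n),
    function(k) choose(combo_pool_n, k), numeric(1)))
  if (p$n_combos > capacity) {
    kb_abort(sprintf(
      "requested %d combos but only %d distinct ingredient sets available",
      p$n_combos, capacity), "parameter_error")
  }

  withr::with_seed(p$seed, {
    next_cui <- 100001L
    take_cuis <- function(n) {
      out <- as.character(seq(next_cui, length.out = n))
      next_cui <<- next_cui + n
      out
    }
    used_names <- character(0)

    in_names <- make_names(p$n_ingredients, used_names)
    used_names <- c(used_names, in_names)
    in_cuis <- take_cuis(p$n_ingredients)

    syn_names <- make_names(p$n_ingredients, used_names)
    used_names <- c(used_names, syn_names)
    salt_terms <- paste(in_names, sample(SALTS, p$n_ingredients,
                                         replace = TRUE))

    combo_pool <- in_cuis[seq_len(combo_pool_n)]
    extra_pool <- setdiff(in_cuis, combo_pool)
    name_of_in <- stats::setNames(in_names, in_cuis)

    combo_sets <- list(); seen_keys <- character(0)
    while (length(combo_sets) < p$n_combos) {
      k <- sample(p$combo_size_range[1]:p$combo_size_range[2], 1)
      members <- sort_rxcuis(sample(combo_pool, min(k, combo_pool_n)))
      key <- paste(members, collapse = "\x1f")
      if (key %in% seen_keys) next
      seen_keys <- c(seen_keys, key)
      combo_sets[[length(combo_sets) + 1]] <- members
    }
    min_cuis <- take_cuis(p$n_combos)
    min_names <- vapply(combo_sets, function(m) {
      paste(sort(name_of_in[m]), collapse = "/")
    }, character(1))

    bn_names <- make_names(p$n_brands, used_names)
    used_names <- c(used_names, bn_names)
    bn_cuis <- take_cuis(p$n_brands)
    bn_targets <- sample(c(in_cuis, min_cuis), p$n_brands, replace = TRUE)

    concepts <- tibble(
      rxcui = c(in_cuis, min_cuis, bn_cuis),
      name = c(in_names, min_names, bn_names),
      tty = c(rep("IN", p$n_ingredients), rep("MIN", p$n_combos),
              rep("BN", p$n_brands)),
      active = 1L
    )
    relationships <- dplyr::bind_rows(
      tibble(rxcui1 = rep(min_cuis, lengths(combo_sets)),
             rel = "has_ingredient", rxcui2 = unlist(combo_sets)),
      tibble(rxcui1 = bn_cuis, rel = "tradename_of", rxcui2 = bn_targets)
    )
    terms <- dplyr::bind_rows(
      tibble(term = concepts$name, rxcui = concepts$rxcui),
      tibble(term = salt_terms, rxcui = in_cuis),
      tibble(term = syn_names, rxcui = in_cuis)
    )

    # ATC: 60% direct, 20% crosswalk-only (via an SCD twin), 20% none
    generics <- c(in_cuis, min_cuis)
    atc_class <- sample(c("direct", "crosswalk", "none"), length(generics),
                        replace = TRUE, prob = c(0.6, 0.2, 0.2))
    atc <- tibble(rxcui = character(0), atc_code = character(0),
                  source = character(0))
    gen_sets <- c(as.list(in_cuis), combo_sets)
    gen_names <- c(in_names, min_names)
    for (i in seq_along(generics)) {
      if (atc_class[i] == "direct") {
        atc <- dplyr::bind_rows(atc, tibble(
          rxcui = generics[i], atc_code = random_atc_code(),
          source = "direct"))
      } else if (atc_class[i] == "crosswalk") {
        scd_cui <- take_cuis(1)
        concepts <- dplyr::bind_rows(concepts, tibble(
          rxcui = scd_cui,
          name = paste(gen_names[i], "10 MG ORAL TABLET"),
          tty = "SCD", active = 1L))
        relationships <- dplyr::bind_rows(relationships, tibble(
          rxcui1 = scd_cui, rel = "has_ingredient",
          rxcui2 = gen_sets[[i]]))
        terms <- dplyr::bind_rows(terms, tibble(
          term = paste(gen_names[i], "10 MG ORAL TABLET"),
          rxcui = scd_cui))
        atc <- dplyr::bind_rows(atc, tibble(
          rxcui = scd_cui, atc_code = random_atc_code(),
          source = "crosswalk"))
      }
    }

    kb <- new_kb(concepts, terms, relationships, atc)
    kb$forge <- list(
      params = p, in_cuis = in_cuis, min_cuis = min_cuis, bn_cuis = bn_cuis,
      extra_pool = extra_pool, combo_sets = combo_sets,
      syn_of = stats::setNames(syn_names, in_cuis),
      salt_of = stats::setNames(salt_terms, in_cuis)
    )
    kb
  })
}

CORRUPT_OPERATORS <- c("separator", "misspelling", "truncation",
                       "abbreviation", "dose_suffix", "parenthetical")

#' Corrupt a clean surface string
#'
#' Applies, each independently with probability `rate` and in a fixed
#' order, the corruption operators that emulate real free-text pathologies:
#' separator variation between ingredient names, a single-character
#' misspelling (adjacent swap or deletion), truncation of trailing
#' characters (minimum length 4), abbreviation of one long token to its
#' first four characters, a synthetic dose/unit suffix, and a trailing
#' parenthetical annotation. Deterministic for a given seed.
#'
#' @param name non-empty surface string.
#' @param operators subset of the operator names to enable.
#' @param rate per-operator probability in \[0, 1\].
#' @param seed integer seed.
#' @return The corrupted string.
#' @export
corrupt_string <- function(name, operators = CORRUPT_OPERATORS, rate,
                           seed = 1L) {
  stopifnot(nzchar(name))
  operators <- match.arg(operators, CORRUPT_OPERATORS, several.ok = TRUE)
  if (rate <= 0) return(name)
  withr::with_seed(seed, {
    x <- name
    for (op in intersect(CORRUPT_OPERATORS, operators)) {
      roll <- stats::runif(1)
      if (roll >= rate) next
      x <- switch(op,
        separator = if (grepl("/", x, fixed = TRUE)) {
          sep <- sample(c(";", " W/ ", "-", " "), 1)
          gsub("/", sep, x, fixed = TRUE)
        } else x,
        misspelling = {
          chars <- strsplit(x, "")[[1]]
          alnum <- which(grepl("[A-Za-z0-9]", chars))
          if (length(alnum) >= 2) {
            i <- sample(alnum[-length(alnum)], 1)
            if (stats::runif(1) < 0.5 && grepl("[A-Za-z0-9]", chars[i + 1])) {
              tmp <- chars[i]; chars[i] <- chars[i + 1]; chars[i + 1] <- tmp
            } else {
              chars <- chars[-i]
            }
            paste(chars, collapse = "")
          } else x
        },
        truncation = {
          if (nchar(x) > 4) {
            keep <- max(4, nchar(x) - sample(seq_len(max(1, nchar(x) %/% 3)), 1))
            substr(x, 1, keep)
          } else x
        },
        abbreviation = {
          toks <- strsplit(x, " ", fixed = TRUE)[[1]]
          long <- which(nchar(gsub("[^A-Za-z]", "", toks)) >= 6)
          if (length(long) > 0) {
            j <- sample(long, 1)
            toks[j] <- substr(toks[j], 1, 4)
            paste(toks, collapse = " ")
          } else x
        },
        dose_suffix = paste(x, sample(c("10MEQ", "500 MG", "0.5 ML",
                                        "XR 20MG", "10-20 MG", "@@"), 1)),
        parenthetical = paste0(x, " (", sample(c("A.F.", "S.F.", "RASPBERRY",
                                                 "EENT", "COMB."), 1), ")")
      )
    }
    x
  })
}

#' Generate a benchmark of messy strings with gold mappings
#'
#' Samples `n_strings` targets from the knowledge base — plain ingredients,
#' salt-form and synonym surface terms, multi-ingredient combos, brands
#' resolving to their generic, and combination-plus-extra-ingredient rows
#' that force subset matching — renders a surface string, corrupts it with
#' [corrupt_string()] at the configured rate, and records the gold concept
#' identifiers (pipe-delimited) plus the gold canonical ingredient-name
#' parse that drives [mock_backend()]. Surface strings are unique;
#' deterministic for a given seed.
#'
#' @param kb a `med_kb` produced by [generate_kb()] (carries provenance).
#' @param params a [forge_params()].
#' @return List of three tibbles: `input` (column `RXNAME`), `gold`
#'   (`raw`, `rxcuis`), `parses` (`raw`, `ingredients`).
#' @export
generate_benchmark <- function(kb, params) {
  stopifnot(inherits(kb, "med_kb"), inherits(params, "forge_params"))
  if (is.null(kb$forge)) {
    kb_abort("benchmark generation needs a knowledge base from generate_kb()",
             "usage_error")
  }
  f <- kb$forge
  p <- params
  types <- c(ingredient = 0.20, salt = 0.15, synonym = 0.15, combo = 0.20,
             brand = 0.15, combo_extra = 0.15)

  withr::with_seed(p$seed + 1L, {
    raws <- character(0); golds <- character(0); parses <- character(0)
    used <- character(0)
    i <- 0L
    while (length(raws) < p$n_strings) {
      i <- i + 1L
      type <- sample(names(types), 1, prob = types)
      row <- switch(type,
        ingredient = {
          cui <- sample(f$in_cuis, 1)
          list(surface = kb$name_of[[cui]], gold = cui,
               parse = kb$name_of[[cui]])
        },
        salt = {
          cui <- sample(f$in_cuis, 1)
          list(surface = f$salt_of[[cui]], gold = cui,
               parse = kb$name_of[[cui]])
        },
        synonym = {
          cui <- sample(f$in_cuis, 1)
          list(surface = f$syn_of[[cui]], gold = cui,
               parse = kb$name_of[[cui]])
        },
        combo = {
          j <- sample(length(f$min_cuis), 1)
          members <- f$combo_sets[[j]]
          list(surface = kb$name_of[[f$min_cuis[j]]], gold = f$min_cuis[j],
               parse = paste(sort(unname(kb$name_of[members])),
                             collapse = " | "))
        },
        brand = {
          cui <- sample(f$bn_cuis, 1)
          generic <- resolve_to_generic(kb, cui)
          members <- ingredients_of(kb, generic$rxcui)
          list(surface = kb$name_of[[cui]], gold = generic$rxcui,
               parse = paste(sort(unname(kb$name_of[members])),
                             collapse = " | "))
        },
        combo_extra = {
          j <- sample(length(f$min_cuis), 1)
          members <- f$combo_sets[[j]]
          extra <- sample(f$extra_pool, 1)
          list(
            surface = paste(c(sort(unname(kb$name_of[members])),
                              kb$name_of[[extra]]), collapse = "/"),
            gold = paste(f$min_cuis[j], extra, sep = " | "),
            parse = paste(sort(unname(kb$name_of[c(members, extra)])),
                          collapse = " | "))
        })
      surface <- corrupt_string(
        row$surface, rate = p$corruption_rate,
        seed = derive_seed(p$seed, paste0("corrupt:", i)))
      if (surface %in% used || preprocess_string(surface) == "") next
      used <- c(used, surface)
      raws <- c(raws, surface)
      golds <- c(golds, row$gold)
      parses <- c(parses, row$parse)
    }
    list(
      input = tibble(RXNAME = raws),
      gold = tibble(raw = raws, rxcuis = golds),
      parses = tibble(raw = raws, ingredients = parses)
    )
  })
}

#' Write a benchmark to disk
#'
#' Emits `input.csv` (raw strings), `gold.csv` (raw, pipe-delimited gold
#' concept identifiers), and `parses.tsv` (raw, pipe-delimited gold
#' ingredient names).
#'
#' @param bench list from [generate_benchmark()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bench$input, file.path(dir, "input.csv"))
  readr::write_csv(bench$gold, file.path(dir, "gold.csv"))
  readr::write_tsv(bench$parses, file.path(dir, "parses.tsv"))
  invisible(dir)
}
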