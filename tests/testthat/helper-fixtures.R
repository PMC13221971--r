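# Hand-built miniature knowledge base used across the unit tests.
# Ingredients: ASPIRIN, CODEINE, IBUPROFEN, ACETAMINOPHEN (+ an inactive
# PHENACETIN and a BENZONATATE for matcher edge cases); combinations
# ASPIRIN/CODEINE, ACETAMINOPHEN/CODEINE, ASPIRIN/CODEINE/IBUPROFEN; a
# brand, a precise-ingredient form, and clinical-drug concepts carrying
# direct, crosswalk, and adversarial ATC attachments.
tiny_kb <- function() {
  concepts <- tibble::tribble(
    ~rxcui,   ~name,                          ~tty,  ~active,
    "1191",   "ASPIRIN",                      "IN",  1L,
    "2670",   "CODEINE",                      "IN",  1L,
    "5640",   "IBUPROFEN",                    "IN",  1L,
    "161",    "ACETAMINOPHEN",                "IN",  1L,
    "99003",  "PHENACETIN",                   "IN",  0L,
    "99010",  "BENZONATATE",                  "IN",  1L,
    "817579", "ASPIRIN/CODEINE",              "MIN", 1L,
    "99007",  "ACETAMINOPHEN/CODEINE",        "MIN", 1L,
    "99011",  "ASPIRIN/CODEINE/IBUPROFEN",    "MIN", 1L,
    "90001",  "BUFFERIN",                     "BN",  1L,
    "90002",  "ASPIRIN ANHYDROUS",            "PIN", 1L,
    "90003",  "ASPIRIN 325 MG ORAL TABLET",   "SCD", 1L,
    "90004",  "CODEINE 30 MG ORAL TABLET",    "SCD", 1L,
    "90005",  "ACETAMINOPHEN/CODEINE TABLET", "SCD", 1L,
    "90006",  "ASPIRIN/IBUPROFEN TABLET",     "SCD", 1L
  )
  relationships <- tibble::tribble(
    ~rxcui1,  ~rel,             ~rxcui2,
    "817579", "has_ingredient", "1191",
    "817579", "has_ingredient", "2670",
    "99007",  "has_ingredient", "161",
    "99007",  "has_ingredient", "2670",
    "99011",  "has_ingredient", "1191",
    "99011",  "has_ingredient", "2670",
    "99011",  "has_ingredient", "5640",
    "90001",  "tradename_of",   "1191",
    "90002",  "form_of",        "1191",
    "90003",  "has_ingredient", "1191",
    "90004",  "has_ingredient", "2670",
    "90005",  "has_ingredient", "161",
    "90005",  "has_ingredient", "2670",
    "90006",  "has_ingredient", "1191",
    "90006",  "has_ingredient", "5640"
  )
  terms <- dplyr::bind_rows(
    tibble::tibble(term = concepts$name, rxcui = concepts$rxcui),
    tibble::tribble(
      ~term,                  ~rxcui,
      "ACETYLSALICYLIC ACID", "1191",
      "CODEINE PHOSPHATE",    "2670",
      "APAP",                 "161"
    )
  )
  atc <- tibble::tribble(
    ~rxcui,  ~atc_code,  ~source,
    "1191",  "N02BA01",  "direct",
    "90004", "R05DA04",  "crosswalk",   # identical set with CODEINE
    "90005", "N02AJ06",  "crosswalk",   # identical set with 99007
    "90006", "M01AE51",  "crosswalk"    # partial overlap: must never attach
  )
  new_kb(concepts, terms, relationships, atc)
}

# Independent brute-force re-scoring of the whole term index, used as the
# oracle for approximate_match() on small knowledge bases.
brute_approx <- function(kb, query, min_score = 0.5) {
  q <- normalize_tokens(query)
  df <- kb$terms
  df$score <- vapply(df$term, function(tm) {
    t <- normalize_tokens(tm)
    i <- length(intersect(q, t)); u <- length(union(q, t))
    if (u == 0) 0 else i / u
  }, numeric(1), USE.NAMES = FALSE)
  df$tty <- unname(kb$tty_of[df$rxcui])
  df <- df[df$score >= min_score, ]
  prio <- c(IN = 1, MIN = 2, PIN = 3, BN = 4, SCD = 5, SBD = 6, OTHER = 7)
  numeric_like <- grepl("^[0-9]+$", df$rxcui)
  key <- ifelse(numeric_like,
                sprintf("0%020.0f", suppressWarnings(as.numeric(df$rxcui))),
                paste0("Z", df$rxcui))
  df <- df[order(-df$score, prio[df$tty], key), ]
  tibble::tibble(rxcui = df$rxcui, matched_term = df$term, tty = df$tty,
                 score = df$score)
}

# Independent brute-force implementation of largest-first greedy subset
# decomposition with lexicographic tie-break on sorted member names.
# Enumerates via bitmasks rather than combn so it shares no code path with
# subset_match().
brute_subset_match <- function(kb, ings) {
  remaining <- sort(unique(ings))
  chosen <- character(0)
  repeat {
    n <- length(remaining)
    if (n == 0) break
    masks <- seq_len(2^n - 1)
    subs <- lapply(masks, function(m) {
      remaining[bitwAnd(m, 2^(seq_len(n) - 1)) > 0]
    })
    sizes <- lengths(subs)
    keys <- vapply(subs, function(s) {
      paste(sort(unname(kb$name_of[s])), collapse = "\x1f")
    }, character(1))
    ord <- order(-sizes, keys)
    hit <- NULL
    for (idx in ord) {
      s <- subs[[idx]]
      g <- find_generic_by_ingredients(kb, s)
      if (!is.null(g)) { hit <- list(cui = g$rxcui, members = s); break }
    }
    if (is.null(hit)) break
    chosen <- c(chosen, hit$cui)
    remaining <- setdiff(remaining, hit$members)
  }
  list(rxcuis = chosen, residual = sort(remaining))
}

# Clean forged benchmark bundle shared by several tests.
forge_bundle <- function(n_strings = 50, corruption_rate = 0, seed = 42,
                         ...) {
  p <- forge_params(n_strings = n_strings, corruption_rate = corruption_rate,
                    seed = seed, ...)
  kb <- generate_kb(p)
  bench <- generate_benchmark(kb, p)
  list(params = p, kb = kb, bench = bench)
}
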