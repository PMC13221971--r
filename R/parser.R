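#' Parser backends
#'
#' The second candidate source is a pluggable parser backend: given a
#' preprocessed medication string (plus, when available, the name of the
#' deterministic candidate as supplementary context), a backend returns a
#' standardized ordered list of uppercase generic active-ingredient names.
#' In production such a backend would be a large language model queried with
#' deterministic decoding; this package ships a fully deterministic mock
#' backend driven by a gold parse table (for offline testing of every
#' reconciliation tier) and unimplemented vendor adapter stubs that document
#' the contract.
#'
#' @name parser-backends
NULL

#' Prompt context for a parser backend
#'
#' @param raw_string the preprocessed medication string.
#' @param det_hint optional preferred name of the deterministic candidate's
#'   generic concept; omit when no deterministic candidate exists.
#' @return A `prompt_context` list.
#' @export
prompt_context <- function(raw_string, det_hint = NULL) {
  stopifnot(is.character(raw_string), length(raw_string) == 1)
  structure(list(raw_string = raw_string, det_hint = det_hint),
            class = "prompt_context")
}

#' Build the instruction text for a parser backend
#'
#' The prompt asks for generic active-ingredient names only, with
#' deterministic decoding. When a deterministic candidate hint is present it
#' is included as supplementary context with an explicit instruction to
#' prioritize the raw string and disregard the hint on inconsistency.
#' Identical contexts yield byte-identical prompts.
#'
#' @param ctx a [prompt_context()].
#' @return A single string.
#' @export
build_prompt <- function(ctx) {
  stopifnot(inherits(ctx, "prompt_context"))
  lines <- c(
    "Extract the generic active ingredient names from the medication string.",
    "Output only a list of uppercase generic ingredient names, one per line.",
    "Use deterministic decoding; do not guess beyond the string's content.",
    paste0("Medication string: ", ctx$raw_string)
  )
  if (!is.null(ctx$det_hint)) {
    lines <- c(lines,
      paste0("Supplementary context (deterministic candidate): ",
             ctx$det_hint),
      paste("Prioritize the raw medication string; disregard the",
            "deterministic candidate if inconsistencies arise."))
  }
  paste(lines, collapse = "\n")
}

#' Construct a parse output
#'
#' Names are uppercased, empty entries dropped, and duplicates removed
#' preserving first occurrence. An empty list is a valid (failed or
#' contentless) parse; `failed = TRUE` marks a backend error the caller
#' downgraded to an empty parse.
#'
#' @param ingredient_names character vector of ingredient names.
#' @param backend_id string identifying backend and mode.
#' @param failed logical; `TRUE` when the backend call itself failed.
#' @return A `parse_output` list.
#' @export
parse_output <- function(ingredient_names, backend_id, failed = FALSE) {
  nm <- toupper(as.character(ingredient_names))
  nm <- nm[!is.na(nm) & nm != ""]
  structure(
    list(ingredient_names = nm[!duplicated(nm)], backend_id = backend_id,
         failed = isTRUE(failed)),
    class = "parse_output"
  )
}

new_backend <- function(id, fn) {
  structure(list(id = id, fn = fn, calls = new.env(parent = emptyenv())),
            class = "mn_backend")
}

#' Number of live calls a backend has served
#'
#' Cache hits do not reach the backend and are not counted.
#'
#' @param backend an `mn_backend`.
#' @return Integer count.
#' @export
backend_calls <- function(backend) {
  backend$calls$n %||% 0L
}

#' Deterministic mock parser backend
#'
#' A data-driven stand-in for an LLM backend: the gold parse table supplies
#' the ideal ingredient-name list for each benchmark string, and three
#' seeded corruption channels perturb it to exercise one reconciliation tier
#' each. `synonym_rate` replaces each name (independently) with a knowledge
#' base synonym of the same ingredient, targeting the normalized-perfect
#' tier; `dropout_rate` removes one ingredient from multi-ingredient parses,
#' targeting subset matching; `noise_rate` injects one random extra
#' knowledge-base ingredient per string. All perturbations are deterministic
#' functions of (`seed`, string), so outputs are stable regardless of batch
#' order.
#'
#' @param kb the `med_kb` the parse table refers to.
#' @param parses gold parse table: a data frame with columns `raw` and
#'   `ingredients` (pipe-delimited canonical ingredient names), as emitted by
#'   [generate_benchmark()].
#' @param mode preset: `"exact"` (all rates 0), `"synonym"`, `"dropout"`,
#'   `"noise"` (the named rate defaults to 1), or `"mixed"` (use the rates as
#'   given).
#' @param synonym_rate,dropout_rate,noise_rate perturbation probabilities.
#' @param seed integer seed for the perturbation channels.
#' @return An `mn_backend`.
#' @export
mock_backend <- function(kb, parses, mode = c("exact", "synonym", "dropout",
                                              "noise", "mixed"),
                         synonym_rate = 0, dropout_rate = 0, noise_rate = 0,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (mode == "synonym" && missing(synonym_rate)) synonym_rate <- 1
  if (mode == "dropout" && missing(dropout_rate)) dropout_rate <- 1
  if (mode == "noise" && missing(noise_rate)) noise_rate <- 1
  stopifnot(all(c("raw", "ingredients") %in% names(parses)))

  gold <- stats::setNames(
    strsplit(parses$ingredients, "\\s*\\|\\s*"),
    preprocess_string(parses$raw)
  )
  in_rows <- kb$concepts[kb$concepts$tty == "IN" & kb$concepts$active == 1L, ]
  # synonym pool per ingredient: index terms other than the preferred name
  syn_pool <- split(kb$terms$term, kb$terms$rxcui)

  id <- sprintf("mock:%s:s%g:d%g:n%g:seed%d", mode, synonym_rate,
                dropout_rate, noise_rate, as.integer(seed))

  fn <- function(ctx) {
    names0 <- gold[[ctx$raw_string]]
    if (is.null(names0)) return(character(0))
    withr::with_seed(derive_seed(seed, ctx$raw_string), {
      out <- vapply(names0, function(nm) {
        if (synonym_rate > 0 && stats::runif(1) < synonym_rate) {
          cui <- in_rows$rxcui[match(nm, in_rows$name)]
          alts <- setdiff(syn_pool[[cui]] %||% character(0), nm)
          if (length(alts) > 0) return(sample(alts, 1))
        }
        nm
      }, character(1), USE.NAMES = FALSE)
      if (dropout_rate > 0 && length(out) >= 2 &&
          stats::runif(1) < dropout_rate) {
        out <- out[-sample(length(out), 1)]
      }
      if (noise_rate > 0 && stats::runif(1) < noise_rate) {
        extra <- setdiff(in_rows$name, out)
        if (length(extra) > 0) out <- c(out, sample(extra, 1))
      }
      out
    })
  }
  new_backend(id, fn)
}

#' Vendor adapter stubs
#'
#' Adapters for hosted LLM services conform to the backend contract but are
#' deliberately unimplemented: this package performs no network calls. They
#' exist so configuration that names them fails loudly rather than silently
#' falling back.
#'
#' @param model model identifier string.
#' @return An `mn_backend` whose invocation raises a parse error.
#' @export
openai_backend <- function(model = "gpt-5-nano") {
  new_backend(paste0("openai:", model), function(ctx) {
    kb_abort("openai backend adapter is a stub: no remote calls are made",
             "parse_error")
  })
}

#' @rdname openai_backend
#' @export
gemini_backend <- function(model = "gemini-2.0-flash") {
  new_backend(paste0("gemini:", model), function(ctx) {
    kb_abort("gemini backend adapter is a stub: no remote calls are made",
             "parse_error")
  })
}

#' Persistent parse cache
#'
#' An append-only key/value store backed by a plain-text file (one
#' `key<TAB>json` line per entry). Keys fold together the preprocessed
#' string, the knowledge-base `version_id`, and the backend id, so editing
#' the knowledge base or switching backends invalidates entries naturally.
#'
#' @param path cache file path; created on first write. `NULL` gives an
#'   in-memory cache.
#' @return An `mn_cache`.
#' @export
mn_cache <- function(path = NULL) {
  env <- new.env(parent = emptyenv())
  stats_env <- new.env(parent = emptyenv())
  stats_env$hits <- 0L; stats_env$misses <- 0L
  if (!is.null(path) && file.exists(path)) {
    for (line in readLines(path, warn = FALSE)) {
      kv <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(kv) == 2) env[[kv[1]]] <- kv[2]
    }
  }
  structure(list(env = env, path = path, stats = stats_env),
            class = "mn_cache")
}

cache_key <- function(preprocessed, kb_version, backend_id) {
  rlang::hash(paste(preprocessed, kb_version, backend_id, sep = "\x1f"))
}

cache_get <- function(cache, key) {
  raw <- cache$env[[key]]
  if (is.null(raw)) return(NULL)
  jsonlite::fromJSON(raw, simplifyVector = TRUE)
}

cache_put <- function(cache, key, value) {
  json <- jsonlite::toJSON(value, auto_unbox = TRUE)
  cache$env[[key]] <- as.character(json)
  if (!is.null(cache$path)) {
    cat(key, "\t", as.character(json), "\n", sep = "",
        file = cache$path, append = TRUE)
  }
  invisible(value)
}

#' Cache hit/miss counters
#'
#' @param cache an `mn_cache`.
#' @return Named integer vector `c(hits = , misses = )`.
#' @export
cache_stats <- function(cache) {
  c(hits = cache$stats$hits, misses = cache$stats$misses)
}

#' Run a parser backend with caching
#'
#' Consults the cache before invoking the backend; a hit returns the stored
#' parse without a backend call. A backend failure raises a classed parse
#' error carrying the backend diagnostics; [mn_batch()] catches it and
#' substitutes an empty parse flagged `failed`.
#'
#' @param backend an `mn_backend`.
#' @param ctx a [prompt_context()].
#' @param cache an [mn_cache()], or `NULL` to bypass caching.
#' @param kb_version the knowledge base `version_id` (part of the cache key).
#' @return A [parse_output()].
#' @export
parse_medication <- function(backend, ctx, cache = NULL, kb_version = "") {
  stopifnot(inherits(backend, "mn_backend"), inherits(ctx, "prompt_context"))
  key <- cache_key(ctx$raw_string, kb_version, backend$id)
  if (!is.null(cache)) {
    hit <- cache_get(cache, key)
    if (!is.null(hit)) {
      cache$stats$hits <- cache$stats$hits + 1L
      return(parse_output(hit$ingredient_names, hit$backend_id,
                          isTRUE(hit$failed)))
    }
    cache$stats$misses <- cache$stats$misses + 1L
  }
  backend$calls$n <- (backend$calls$n %||% 0L) + 1L
  names_out <- tryCatch(
    backend$fn(ctx),
    error = function(e) {
      kb_abort(paste0("parser backend '", backend$id, "' failed: ",
                      conditionMessage(e)), "parse_error")
    }
  )
  out <- parse_output(names_out, backend$id)
  if (!is.null(cache)) {
    cache_put(cache, key, list(ingredient_names = out$ingredient_names,
                               backend_id = out$backend_id,
                               failed = out$failed))
  }
  out
}
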