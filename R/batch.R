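#' Normalize a single medication string
#'
#' Runs the full pipeline on one raw string: preprocessing, deterministic
#' candidate generation, parser-backend invocation (cache-first), and
#' hierarchical reconciliation. A backend failure is downgraded to an empty
#' parse flagged as failed.
#'
#' @param raw raw medication string.
#' @param kb a `med_kb`.
#' @param backend an `mn_backend`.
#' @param cache an [mn_cache()] or `NULL`.
#' @param min_score Jaccard threshold for the deterministic matcher.
#' @param subset_cap maximum set size for exhaustive subset enumeration.
#' @return An `mn_mapping` with `raw`/`preprocessed` filled in.
#' @export
map_string <- function(raw, kb, backend, cache = NULL, min_score = 0.5,
                       subset_cap = 10) {
  pre <- preprocess_string(raw)
  if (pre == "") {
    m <- new_mapping(raw, pre, kb$concepts[0, ], "unmapped", character(0),
                     NULL, parse_output(character(0), backend$id))
    return(m)
  }
  det <- deterministic_candidate(kb, pre, min_score = min_score)
  ctx <- prompt_context(pre, det_hint = if (!is.null(det)) det$generic$name)
  parsed <- tryCatch(
    parse_medication(backend, ctx, cache = cache,
                     kb_version = kb$version_id),
    mednorm_parse_error = function(e) {
      parse_output(character(0), backend$id, failed = TRUE)
    }
  )
  m <- reconcile(kb, det, parsed, min_score = min_score,
                 subset_cap = subset_cap)
  m$raw <- raw
  m$preprocessed <- pre
  m
}

serialize_mapping <- function(kb, m, annotate = TRUE) {
  cuis <- m$concepts$rxcui
  ann <- if (annotate && length(cuis) > 0) {
    lapply(cuis, function(cui) annotate_atc(kb, cui))
  } else list()
  tibble(
    input = m$raw,
    preprocessed = m$preprocessed,
    rxcuis = paste(cuis, collapse = " | "),
    mapped = paste(m$concepts$name, collapse = " | "),
    match_type = m$match_type,
    confidence = m$confidence,
    residue = paste(m$residue, collapse = "; "),
    atc_codes = paste(vapply(ann, function(a) paste(a$codes, collapse = ";"),
                             character(1)), collapse = " | "),
    atc_coverage = paste(vapply(ann, function(a) a$coverage, character(1)),
                         collapse = " | ")
  )
}

#' Batch normalization of a table of medication strings
#'
#' Maps every string in `data[[column]]` through the pipeline, annotates
#' finalized concepts with ATC codes, and returns one output row per input
#' row, in input order. Within a row, `/` joins ingredients inside a
#' multi-ingredient concept name and `|` separates distinct concepts (the
#' convention used throughout: `rxcuis`, `mapped`, `atc_codes`, and
#' `atc_coverage` all share the same pipe arity). The cache is consulted
#' before any backend call, so re-running an identical batch performs zero
#' backend calls and yields byte-identical output.
#'
#' @param data data frame containing the input column.
#' @param kb a `med_kb`.
#' @param backend an `mn_backend` (see [mock_backend()]).
#' @param column name of the raw-string column (default `"RXNAME"`).
#' @param cache an [mn_cache()] or `NULL`.
#' @param min_confidence optional confidence floor (`"low"`, `"moderate"`,
#'   `"high"`); when set, rows below it are dropped from the returned view.
#'   The unfiltered table always remains available via
#'   [filter_confidence()] on an unfiltered run.
#' @param min_score,subset_cap matcher and reconciler tuning knobs.
#' @param annotate set `FALSE` to skip ATC annotation.
#' @return Tibble with columns `input`, `preprocessed`, `rxcuis`, `mapped`,
#'   `match_type`, `confidence`, `residue`, `atc_codes`, `atc_coverage`.
#'   A per-tier summary (plus backend-call and cache counters) is attached
#'   as attribute `"summary"`; see [batch_summary()].
#' @export
mn_batch <- function(data, kb, backend, column = "RXNAME", cache = NULL,
                     min_confidence = NULL, min_score = 0.5, subset_cap = 10,
                     annotate = TRUE) {
  stopifnot(inherits(kb, "med_kb"), inherits(backend, "mn_backend"))
  if (!column %in% names(data)) {
    kb_abort(sprintf("input has no column '%s'", column), "usage_error")
  }
  calls_before <- backend_calls(backend)
  stats_before <- if (is.null(cache)) c(hits = 0L, misses = 0L) else
    cache_stats(cache)

  rows <- purrr::map(as.character(data[[column]]), function(raw) {
    m <- map_string(raw, kb, backend, cache = cache, min_score = min_score,
                    subset_cap = subset_cap)
    serialize_mapping(kb, m, annotate = annotate)
  })
  out <- dplyr::bind_rows(rows)

  stats_after <- if (is.null(cache)) c(hits = 0L, misses = 0L) else
    cache_stats(cache)
  summary <- list(
    n = nrow(out),
    by_confidence = dplyr::count(out, .data$confidence, name = "n"),
    backend_calls = backend_calls(backend) - calls_before,
    cache_hits = unname(stats_after["hits"] - stats_before["hits"]),
    cache_misses = unname(stats_after["misses"] - stats_before["misses"])
  )
  if (!is.null(min_confidence)) {
    out <- filter_confidence(out, min_confidence)
  }
  attr(out, "summary") <- summary
  out
}

#' Filter batch rows by mapping confidence
#'
#' Retains rows at or above the given confidence under the ordering
#' `none < low < moderate < high`.
#'
#' @param data a batch result tibble with a `confidence` column.
#' @param min_confidence one of `"none"`, `"low"`, `"moderate"`, `"high"`.
#' @return The filtered tibble.
#' @export
filter_confidence <- function(data, min_confidence) {
  min_confidence <- match.arg(min_confidence, CONFIDENCE_LEVELS)
  lvl <- match(data$confidence, CONFIDENCE_LEVELS)
  data[lvl >= match(min_confidence, CONFIDENCE_LEVELS), , drop = FALSE]
}

#' Per-tier summary of a batch run
#'
#' @param result tibble returned by [mn_batch()].
#' @return List with `n`, `by_confidence` counts, `backend_calls`,
#'   `cache_hits`, `cache_misses`.
#' @export
batch_summary <- function(result) {
  attr(result, "summary")
}

#' Confidence-tier bar chart for a batch result
#'
#' @param result tibble returned by [mn_batch()].
#' @return A ggplot.
#' @export
plot_confidence <- function(result) {
  df <- dplyr::count(result, .data$confidence, name = "n")
  df$confidence <- factor(df$confidence, levels = rev(CONFIDENCE_LEVELS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$confidence, y = .data$n)) +
    ggplot2::geom_col(fill = "darkseagreen4") +
    ggplot2::labs(title = "Mappings by confidence tier",
                  x = "confidence", y = "strings") +
    ggplot2::theme_minimal()
}

#' File-to-file batch run
#'
#' Thin wrapper for the command-line interface: loads the knowledge base,
#' reads the input CSV, runs [mn_batch()], and writes the output CSV
#' (UTF-8, comma-separated, quoted where needed, header row).
#'
#' @param kb_dir knowledge-base directory.
#' @param input_csv input CSV path.
#' @param output_csv output CSV path.
#' @param backend an `mn_backend`.
#' @param column raw-string column name.
#' @param cache_path parse-cache file path, or `NULL`.
#' @param min_confidence optional confidence floor for the written rows.
#' @param min_score Jaccard threshold.
#' @return The batch tibble, invisibly.
#' @export
run_batch <- function(kb_dir, input_csv, output_csv, backend,
                      column = "RXNAME", cache_path = NULL,
                      min_confidence = NULL, min_score = 0.5) {
  kb <- load_kb(kb_dir)
  data <- readr::read_csv(input_csv,
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  cache <- if (!is.null(cache_path)) mn_cache(cache_path)
  out <- mn_batch(data, kb, backend, column = column, cache = cache,
                  min_confidence = min_confidence, min_score = min_score)
  readr::write_csv(out, output_csv)
  invisible(out)
}
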