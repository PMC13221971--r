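split_rxcuis <- function(x) {
  out <- strsplit(as.character(x %||% ""), "\\s*\\|\\s*")
  lapply(out, function(v) unique(v[!is.na(v) & v != ""]))
}

#' Score predicted mappings against a gold standard
#'
#' Micro-averaged precision, recall, and F1 over (string, concept) pairs at
#' the RxCUI level — exact concept agreement — or over (string, ingredient)
#' pairs at the ingredient level, where both predicted and gold concept sets
#' are first expanded to their ingredient sets via [ingredients_of()] and
#' unioned per string, granting partial credit for multi-ingredient
#' products. For each string, true positives are the intersection of the
#' predicted and gold sets, false positives the predicted excess, false
#' negatives the gold shortfall; counts are pooled across strings before
#' computing the metrics.
#'
#' @param predictions data frame with a raw-string column (`raw` or `input`)
#'   and a `rxcuis` column (pipe-delimited identifiers or a list column).
#'   Typically the output of [mn_batch()]. Unmapped strings have empty
#'   `rxcuis`.
#' @param gold data frame with columns `raw` and `rxcuis` (pipe-delimited).
#'   Raw strings must be unique; every gold string must appear in
#'   `predictions`.
#' @param kb a `med_kb`; required for ingredient-level scoring.
#' @param level `"rxcui"` or `"ingredient"`.
#' @return An `mn_eval` object; see [glance.mn_eval()] and [tidy.mn_eval()].
#' @export
score_mappings <- function(predictions, gold, kb = NULL,
                           level = c("rxcui", "ingredient")) {
  level <- match.arg(level)
  raw_col <- intersect(c("raw", "input"), names(predictions))[1]
  if (is.na(raw_col) || !"rxcuis" %in% names(predictions)) {
    kb_abort("predictions need a raw-string column and a 'rxcuis' column",
             "usage_error")
  }
  if (!all(c("raw", "rxcuis") %in% names(gold))) {
    kb_abort("gold table needs columns 'raw' and 'rxcuis'", "usage_error")
  }
  if (anyDuplicated(gold$raw)) {
    kb_abort("duplicate raw strings in gold table", "usage_error")
  }
  missing <- setdiff(gold$raw, predictions[[raw_col]])
  if (length(missing) > 0) {
    kb_abort(sprintf("gold string(s) missing from predictions: %s",
                     paste(utils::head(missing, 3), collapse = "; ")),
             "join_error")
  }
  if (level == "ingredient" && is.null(kb)) {
    kb_abort("ingredient-level scoring requires a knowledge base",
             "usage_error")
  }

  pred_sets <- if (is.list(predictions$rxcuis)) {
    lapply(predictions$rxcuis, function(v) unique(v[v != ""]))
  } else split_rxcuis(predictions$rxcuis)
  names(pred_sets) <- predictions[[raw_col]]
  gold_sets <- split_rxcuis(gold$rxcuis)

  expand <- function(cuis) {
    if (level == "rxcui" || length(cuis) == 0) return(cuis)
    sort_rxcuis(unique(unlist(lapply(cuis, ingredients_of, kb = kb))))
  }

  per_string <- purrr::map2(gold$raw, gold_sets, function(raw, gset) {
    p <- expand(pred_sets[[raw]] %||% character(0))
    g <- expand(gset)
    tibble(raw = raw,
           tp = sum(p %in% g), fp = sum(!p %in% g), fn = sum(!g %in% p))
  })
  by_string <- dplyr::bind_rows(per_string)

  tp <- sum(by_string$tp); fp <- sum(by_string$fp); fn <- sum(by_string$fn)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)

  structure(
    list(level = level, tp = tp, fp = fp, fn = fn, precision = precision,
         recall = recall, f1 = f1, by_string = by_string),
    class = "mn_eval"
  )
}

#' @export
print.mn_eval <- function(x, ...) {
  cat(sprintf(
    "<mn_eval> level=%s  P=%.3f R=%.3f F1=%.3f  (tp=%d fp=%d fn=%d, n=%d)\n",
    x$level, x$precision, x$recall, x$f1, x$tp, x$fp, x$fn,
    nrow(x$by_string)))
  invisible(x)
}

#' One-row summary of an evaluation
#'
#' @param x an `mn_eval`.
#' @param ... unused.
#' @return A one-row tibble: `level`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @exportS3Method generics::glance
glance.mn_eval <- function(x, ...) {
  tibble(level = x$level, tp = x$tp, fp = x$fp, fn = x$fn,
         precision = x$precision, recall = x$recall, f1 = x$f1)
}

#' Per-string evaluation counts
#'
#' @param x an `mn_eval`.
#' @param ... unused.
#' @return Tibble with one row per gold string: `raw`, `tp`, `fp`, `fn`.
#' @exportS3Method generics::tidy
tidy.mn_eval <- function(x, ...) {
  x$by_string
}

#' Metric bar chart for an evaluation
#'
#' @param object an `mn_eval`.
#' @param ... unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.mn_eval <- function(object, ...) {
  df <- tidyr::pivot_longer(
    glance(object), c("precision", "recall", "f1"),
    names_to = "metric", values_to = "value")
  df$metric <- factor(df$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Mapping performance (%s level)", object$level),
      x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Read a gold-standard mapping CSV
#'
#' @param path CSV with columns `raw` and `rxcuis` (pipe-delimited concept
#'   identifiers).
#' @return Tibble.
#' @export
read_gold <- function(path) {
  readr::read_csv(path, col_types = readr::cols(.default = "c"),
                  progress = FALSE)
}
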