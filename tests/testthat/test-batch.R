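test_that("batch output preserves row count, order, and pipe arity", {
  fb <- forge_bundle(n_strings = 30, seed = 29)
  be <- mock_backend(fb$kb, fb$bench$parses, mode = "exact")
  out <- mn_batch(fb$bench$input, fb$kb, be)
  expect_equal(nrow(out), 30)
  expect_identical(out$input, fb$bench$input$RXNAME)
  expect_named(out, c("input", "preprocessed", "rxcuis", "mapped",
                      "match_type", "confidence", "residue", "atc_codes",
                      "atc_coverage"))
  arity <- function(col) lengths(strsplit(col, " | ", fixed = TRUE))
  mapped_n <- arity(out$mapped)
  expect_equal(arity(out$rxcuis), mapped_n)
  expect_equal(arity(out$atc_coverage), mapped_n)
  s <- batch_summary(out)
  expect_equal(s$n, 30)
  expect_equal(sum(s$by_confidence$n), 30)
})

test_that("a fixture built for tier-1 agreement maps at high confidence", {
  kb <- tiny_kb()
  raws <- c("ASPIRIN", "CODEINE", "ASPIRIN/CODEINE", "BUFFERIN",
            "ACETAMINOPHEN/CODEINE")
  parses <- tibble::tibble(
    raw = raws,
    ingredients = c("ASPIRIN", "CODEINE", "ASPIRIN | CODEINE", "ASPIRIN",
                    "ACETAMINOPHEN | CODEINE"))
  be <- mock_backend(kb, parses, mode = "exact")
  out <- mn_batch(tibble::tibble(RXNAME = raws), kb, be)
  expect_equal(nrow(out), 5)
  expect_true(all(out$confidence == "high"))
  expect_equal(out$rxcuis,
               c("1191", "2670", "817579", "1191", "99007"))
})

test_that("confidence filtering retains rows at or above the floor", {
  fb <- forge_bundle(n_strings = 40, seed = 37)
  be <- mock_backend(fb$kb, fb$bench$parses, mode = "mixed",
                     synonym_rate = 0.5, noise_rate = 0.3, seed = 37)
  out <- mn_batch(fb$bench$input, fb$kb, be, annotate = FALSE)
  filt <- filter_confidence(out, "moderate")
  expect_true(all(filt$confidence %in% c("moderate", "high")))
  expect_setequal(
    setdiff(out$input, filt$input),
    out$input[out$confidence %in% c("low", "none")])
  # the filtered view from mn_batch matches post-hoc filtering
  out2 <- mn_batch(fb$bench$input, fb$kb, be, annotate = FALSE,
                   min_confidence = "moderate")
  expect_equal(as.data.frame(out2), as.data.frame(filt))
})

test_that("warm caches give byte-identical reruns with zero backend calls", {
  fb <- forge_bundle(n_strings = 25, seed = 41)
  cache_path <- withr::local_tempfile()
  be <- mock_backend(fb$kb, fb$bench$parses, mode = "exact")
  c1 <- mn_cache(cache_path)
  out1 <- mn_batch(fb$bench$input, fb$kb, be, cache = c1)
  expect_equal(batch_summary(out1)$backend_calls, 25)

  c2 <- mn_cache(cache_path)
  out2 <- mn_batch(fb$bench$input, fb$kb, be, cache = c2)
  expect_equal(batch_summary(out2)$backend_calls, 0)
  expect_equal(batch_summary(out2)$cache_hits, 25)
  strip <- function(x) { attr(x, "summary") <- NULL; as.data.frame(x) }
  expect_identical(strip(out1), strip(out2))
})

test_that("editing the knowledge base invalidates cache entries", {
  fb <- forge_bundle(n_strings = 10, seed = 43)
  cache_path <- withr::local_tempfile()
  be <- mock_backend(fb$kb, fb$bench$parses, mode = "exact")
  mn_batch(fb$bench$input, fb$kb, be, cache = mn_cache(cache_path),
           annotate = FALSE)
  calls0 <- backend_calls(be)

  kb2 <- new_kb(fb$kb$concepts,
                dplyr::bind_rows(fb$kb$terms,
                                 tibble::tibble(term = "NEW SYNONYM",
                                                rxcui = fb$kb$terms$rxcui[1])),
                fb$kb$relationships, fb$kb$atc)
  kb2$forge <- fb$kb$forge
  mn_batch(fb$bench$input, kb2, be, cache = mn_cache(cache_path),
           annotate = FALSE)
  expect_equal(backend_calls(be) - calls0, 10)  # stale entries bypassed
})

test_that("file-level batch runs round-trip through CSV", {
  fb <- forge_bundle(n_strings = 12, seed = 47)
  d <- withr::local_tempdir()
  write_kb(fb$kb, file.path(d, "kb"))
  readr::write_csv(fb$bench$input, file.path(d, "input.csv"))
  be <- mock_backend(fb$kb, fb$bench$parses, mode = "exact")
  out <- run_batch(file.path(d, "kb"), file.path(d, "input.csv"),
                   file.path(d, "out.csv"), be,
                   cache_path = file.path(d, "cache.tsv"))
  back <- readr::read_csv(file.path(d, "out.csv"),
                          col_types = readr::cols(.default = "c"),
                          progress = FALSE)
  expect_equal(nrow(back), 12)
  expect_equal(back$input, fb$bench$input$RXNAME)
  expect_error(
    mn_batch(fb$bench$input, fb$kb, be, column = "NOPE"),
    class = "mednorm_usage_error")
})

test_that("unmappable inputs yield an explicit unmapped row", {
  kb <- tiny_kb()
  be <- mock_backend(kb, tibble::tibble(raw = "ASPIRIN",
                                        ingredients = "ASPIRIN"),
                     mode = "exact")
  out <- mn_batch(tibble::tibble(RXNAME = c("(note)", "ASPIRIN")), kb, be)
  expect_equal(out$match_type, c("unmapped", "perfect"))
  expect_equal(out$rxcuis[1], "")
})
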