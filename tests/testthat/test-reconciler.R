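test_that("ingredient names canonicalize independently with residue", {
  kb <- tiny_kb()
  out <- canonicalize_ingredient_names(kb, c("ASPIRIN", "CODEINE"))
  expect_equal(out$ingredient_set, c("1191", "2670"))
  expect_equal(out$residue, character(0))

  # salt and chemical synonyms collapse to the same canonical ingredients
  out2 <- canonicalize_ingredient_names(
    kb, c("ACETYLSALICYLIC ACID", "CODEINE PHOSPHATE"))
  expect_equal(out2$ingredient_set, c("1191", "2670"))

  out3 <- canonicalize_ingredient_names(kb, "UNOBTAINIUM")
  expect_equal(out3$ingredient_set, character(0))
  expect_equal(out3$residue, "UNOBTAINIUM")
})

test_that("greedy subset matching prefers the largest covered subset", {
  kb <- tiny_kb()
  # combination + extra ingredient decomposes as [MIN, IN]
  sm <- subset_match(kb, c("1191", "2670", "99010"))
  expect_equal(sm$concepts$rxcui, c("817579", "99010"))
  expect_equal(sm$residual, character(0))
  # equal-size ties break on lexicographic order of sorted member names:
  # {ACETAMINOPHEN, CODEINE} is scanned before {ASPIRIN, CODEINE}
  smt <- subset_match(kb, c("1191", "2670", "161"))
  expect_equal(smt$concepts$rxcui, c("99007", "1191"))
  # singleton base case
  sm1 <- subset_match(kb, "1191")
  expect_equal(sm1$concepts$rxcui, "1191")
  # partially matchable pair: active IN kept, inactive partner left over
  sm2 <- subset_match(kb, c("5640", "99003"))
  expect_equal(sm2$concepts$rxcui, "5640")
  expect_equal(sm2$residual, "99003")
  # a full triple that is itself a MIN is taken whole
  sm3 <- subset_match(kb, c("1191", "2670", "5640"))
  expect_equal(sm3$concepts$rxcui, "99011")
  expect_error(subset_match(kb, as.character(1:11), cap = 10),
               class = "mednorm_size_error")
})

test_that("subset matching partitions its input (soundness property)", {
  fb <- forge_bundle(n_strings = 5, seed = 9)
  kb <- fb$kb
  ins <- kb$concepts$rxcui[kb$concepts$tty == "IN"]
  withr::with_seed(21, {
    for (i in 1:40) {
      ings <- sample(ins, sample(1:6, 1))
      sm <- subset_match(kb, ings)
      sets <- lapply(sm$concepts$rxcui, ingredients_of, kb = kb)
      all_members <- unlist(sets)
      expect_equal(anyDuplicated(all_members), 0)        # pairwise disjoint
      expect_true(all(all_members %in% ings))            # soundness
      expect_setequal(c(all_members, sm$residual), ings) # partition
    }
  })
})

test_that("tier 1 finalizes verbatim agreement as perfect/high", {
  kb <- tiny_kb()
  det <- deterministic_candidate(kb, "ASPIRIN/CODEINE")
  m <- reconcile(kb, det, parse_output(c("ACETAMINOPHEN", "CODEINE"), "t"))
  expect_false(m$match_type == "perfect")
  m2 <- reconcile(kb, det, parse_output(c("CODEINE", "ASPIRIN"), "t"))
  expect_equal(m2$match_type, "perfect")
  expect_equal(m2$confidence, "high")
  expect_equal(m2$concepts$rxcui, "817579")
})

test_that("tier 2 reconciles lexical discrepancies through canonical names", {
  kb <- tiny_kb()
  det <- det_candidate(
    kb, find_generic_by_ingredients(kb, c("1191", "2670")),
    ingredient_names = c("ACETYLSALICYLIC ACID", "CODEINE"))
  m <- reconcile(kb, det,
                 parse_output(c("ASPIRIN", "CODEINE PHOSPHATE"), "t"))
  expect_equal(m$match_type, "normalized_perfect")
  expect_equal(m$confidence, "moderate")
  expect_equal(m$concepts$rxcui, "817579")
  expect_setequal(ingredients_of(kb, m$concepts$rxcui), c("1191", "2670"))
})

test_that("tier 3 decomposes the parsed set only, with residue", {
  kb <- tiny_kb()
  m <- reconcile(kb, NULL,
                 parse_output(c("ASPIRIN", "CODEINE", "BENZONATATE"), "t"))
  expect_equal(m$match_type, "subset")
  expect_equal(m$confidence, "low")
  expect_equal(m$concepts$rxcui, c("817579", "99010"))
  expect_equal(m$residue, character(0))

  m2 <- reconcile(kb, NULL, parse_output(c("IBUPROFEN", "UNOBTAINIUM"), "t"))
  expect_equal(m2$concepts$rxcui, "5640")
  expect_equal(m2$residue, "UNOBTAINIUM")
})

test_that("degenerate inputs fall through the documented paths", {
  kb <- tiny_kb()
  det <- deterministic_candidate(kb, "ASPIRIN")
  # empty parse + deterministic candidate: single-source, low confidence
  m <- reconcile(kb, det, parse_output(character(0), "t"))
  expect_equal(m$confidence, "low")
  expect_equal(m$concepts$rxcui, "1191")
  # failed parse behaves like an empty one
  mf <- reconcile(kb, det, parse_output(character(0), "t", failed = TRUE))
  expect_equal(mf$concepts$rxcui, "1191")
  # nothing from either source
  m0 <- reconcile(kb, NULL, parse_output("UNOBTAINIUM", "t"))
  expect_equal(m0$match_type, "unmapped")
  expect_equal(m0$confidence, "none")
  expect_equal(nrow(m0$concepts), 0)
})

test_that("confidence strictly tracks match type on every result", {
  fb <- forge_bundle(n_strings = 60, seed = 13)
  be <- mock_backend(fb$kb, fb$bench$parses, mode = "mixed",
                     synonym_rate = 0.4, dropout_rate = 0.2,
                     noise_rate = 0.2, seed = 13)
  want <- c(perfect = "high", normalized_perfect = "moderate",
            subset = "low", unmapped = "none")
  for (raw in fb$bench$input$RXNAME) {
    m <- map_string(raw, fb$kb, be)
    expect_equal(m$confidence, unname(want[m$match_type]))
    if (m$match_type != "unmapped") expect_gt(nrow(m$concepts), 0)
    if (nrow(m$concepts) > 0) {
      expect_true(all(m$concepts$tty %in% c("IN", "MIN")))
      expect_true(all(m$concepts$active == 1L))
    }
  }
})
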