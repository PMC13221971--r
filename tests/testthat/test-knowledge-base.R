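test_that("a knowledge base round-trips through TSV files byte-identically", {
  kb <- tiny_kb()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_kb(kb, d1)
  kb2 <- load_kb(d1)
  expect_equal(nrow(kb2$concepts), nrow(kb$concepts))
  expect_equal(nrow(kb2$relationships), nrow(kb$relationships))
  expect_identical(kb2$version_id, kb$version_id)
  write_kb(kb2, d2)
  for (f in c("concepts.tsv", "terms.tsv", "relationships.tsv", "atc.tsv")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("loading a minimal hand-built directory yields the declared counts", {
  d <- withr::local_tempdir()
  writeLines(c("rxcui\tname\ttty\tactive",
               "1\tALPHA\tIN\t1", "2\tBETA\tIN\t1", "3\tALPHA/BETA\tMIN\t1"),
             file.path(d, "concepts.tsv"))
  writeLines(c("term\trxcui", "ALPHA\t1", "BETA\t2", "ALPHA/BETA\t3"),
             file.path(d, "terms.tsv"))
  writeLines(c("rxcui1\trel\trxcui2",
               "3\thas_ingredient\t1", "3\thas_ingredient\t2"),
             file.path(d, "relationships.tsv"))
  writeLines("rxcui\tatc_code\tsource", file.path(d, "atc.tsv"))
  kb <- load_kb(d)
  expect_equal(nrow(kb$concepts), 3)
  expect_equal(nrow(kb$relationships), 2)
  expect_equal(ingredients_of(kb, "3"), c("1", "2"))
})

test_that("load errors name the problem: missing file, duplicate id, dangling edge", {
  kb <- tiny_kb()
  d <- withr::local_tempdir()
  write_kb(kb, d)
  file.remove(file.path(d, "atc.tsv"))
  expect_error(load_kb(d), "atc.tsv", class = "mednorm_load_error")

  dup <- kb$concepts[c(seq_len(nrow(kb$concepts)), 1), ]
  expect_error(new_kb(dup, kb$terms, kb$relationships, kb$atc),
               class = "mednorm_integrity_error")
  bad_rel <- dplyr::bind_rows(
    kb$relationships,
    tibble::tibble(rxcui1 = "817579", rel = "has_ingredient",
                   rxcui2 = "424242"))
  expect_error(new_kb(kb$concepts, kb$terms, bad_rel, kb$atc),
               class = "mednorm_integrity_error")
})

test_that("structural invariants are enforced at load", {
  kb <- tiny_kb()
  # MIN with a single has_ingredient edge
  rel <- kb$relationships[!(kb$relationships$rxcui1 == "817579" &
                              kb$relationships$rxcui2 == "2670"), ]
  expect_error(new_kb(kb$concepts, kb$terms, rel, kb$atc),
               "MIN", class = "mednorm_integrity_error")
  # two MINs with identical ingredient sets
  con <- dplyr::bind_rows(kb$concepts, tibble::tibble(
    rxcui = "555", name = "DUP", tty = "MIN", active = 1L))
  rel2 <- dplyr::bind_rows(kb$relationships, tibble::tibble(
    rxcui1 = "555", rel = "has_ingredient", rxcui2 = c("1191", "2670")))
  expect_error(new_kb(con, kb$terms, rel2, kb$atc),
               "identical ingredient set", class = "mednorm_integrity_error")
  # has_ingredient pointing at a non-IN concept
  rel3 <- dplyr::bind_rows(kb$relationships, tibble::tibble(
    rxcui1 = "99011", rel = "has_ingredient", rxcui2 = "90001"))
  expect_error(new_kb(kb$concepts, kb$terms, rel3, kb$atc),
               class = "mednorm_integrity_error")
  # malformed ATC code
  atc2 <- dplyr::bind_rows(kb$atc, tibble::tibble(
    rxcui = "1191", atc_code = "XX99", source = "direct"))
  expect_error(new_kb(kb$concepts, kb$terms, kb$relationships, atc2),
               class = "mednorm_integrity_error")
})

test_that("version_id is content-determined and changes with any row", {
  kb <- tiny_kb()
  expect_identical(kb$version_id, tiny_kb()$version_id)
  terms2 <- dplyr::bind_rows(kb$terms, tibble::tibble(
    term = "EXTRA SYNONYM", rxcui = "1191"))
  kb2 <- new_kb(kb$concepts, terms2, kb$relationships, kb$atc)
  expect_false(identical(kb2$version_id, kb$version_id))
})

test_that("ingredients_of expands every term type to its IN set", {
  kb <- tiny_kb()
  expect_equal(ingredients_of(kb, "1191"), "1191")                 # IN
  expect_equal(ingredients_of(kb, "817579"), c("1191", "2670"))    # MIN
  expect_equal(ingredients_of(kb, "90002"), "1191")                # PIN
  expect_equal(ingredients_of(kb, "90001"), "1191")                # BN
  expect_equal(ingredients_of(kb, "90005"), c("161", "2670"))      # SCD
  expect_error(ingredients_of(kb, "999999"),
               class = "mednorm_lookup_error")
})

test_that("ingredients_of is idempotent: members re-expand to themselves", {
  kb <- forge_bundle(n_strings = 5)$kb
  generics <- kb$concepts[kb$concepts$tty %in% c("IN", "MIN"), ]
  for (cui in generics$rxcui[seq_len(min(20, nrow(generics)))]) {
    members <- ingredients_of(kb, cui)
    re <- unlist(lapply(members, ingredients_of, kb = kb))
    expect_setequal(re, members)
  }
})

test_that("find_generic_by_ingredients inverts ingredients_of on generics", {
  kb <- tiny_kb()
  expect_equal(find_generic_by_ingredients(kb, "1191")$rxcui, "1191")
  expect_equal(find_generic_by_ingredients(kb, c("2670", "1191"))$rxcui,
               "817579")
  expect_null(find_generic_by_ingredients(kb, c("1191", "5640")))
  expect_null(find_generic_by_ingredients(kb, "99003"))  # inactive IN

  fkb <- forge_bundle(n_strings = 5)$kb
  generics <- fkb$concepts[fkb$concepts$tty %in% c("IN", "MIN") &
                             fkb$concepts$active == 1L, ]
  for (cui in generics$rxcui) {
    expect_equal(
      find_generic_by_ingredients(fkb, ingredients_of(fkb, cui))$rxcui, cui)
  }
})
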