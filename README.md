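# mednorm

Normalization of free-text medication strings to ingredient-level drug
concepts, with ATC annotation and evaluation tooling.

## The problem

Medication data collected from surveys, dispensing systems, and clinical
databases arrives as free text: brand names (`UNIVASC`), abbreviations
(`ACETAM CODEINE #3`), misspellings (`BENZONATE`), truncations
(`SULFAMET`), dose clutter (`POTASS. CL 10MEQ @@`), and combination
products that map to several concepts at once. Before any
pharmacoepidemiologic analysis, each string must be resolved to
standardized generic concepts — single-ingredient (IN) or multi-ingredient
(MIN) entries of an RxNorm-style vocabulary, identified by RxCUIs — and,
for class-level analyses, annotated with Anatomical Therapeutic Chemical
(ATC) codes.

`mednorm` implements this normalization pipeline against a local,
RxNorm-like knowledge base (four TSV tables: concepts, term index,
relationship edges, ATC attachments), for researchers who need offline,
reproducible batch mapping rather than a hosted service.

## The method

For a preprocessed string *q* (parentheticals removed, whitespace
collapsed, uppercased), two candidate ingredient sets are generated:

1. **Deterministic**: every term *t* in the synonym index is scored by
   token-set Jaccard similarity
   *J(q, t) = |T(q) ∩ T(t)| / |T(q) ∪ T(t)|*, where *T(·)* splits on
   non-alphanumerics; the best match at or above a threshold (default 0.5)
   is resolved through the relationship graph (`tradename_of`, `form_of`,
   `has_ingredient`) to an active generic concept.
2. **Parsed**: a pluggable parser backend (an LLM in production; a
   deterministic data-driven mock here) emits a list of generic
   active-ingredient names from the raw string.

The two sets are fused by three-tier hierarchical reconciliation:

| Tier | Condition | Match type | Confidence |
|---|---|---|---|
| 1 | name sets agree verbatim | perfect | high |
| 2 | sets agree after canonicalizing each name to its IN concept | normalized perfect | moderate |
| 3 | greedy largest-first decomposition of the parsed set into exact IN/MIN subsets | subset | low |

Subset matching enumerates subsets in descending size (lexicographic
tie-break), finalizes any subset that exactly equals a knowledge-base
concept's ingredient set, removes its members, and repeats — so a
combination product plus a stray ingredient maps to `MIN | IN` instead of
collapsing. Finalized concepts are then ATC-annotated: direct codes first,
then crosswalk codes accepted only from concepts with an *identical*
ingredient set, then classifiable subsets/ingredients labeled partial
coverage.

Mappings are scored against a gold standard with micro-averaged
precision/recall/F1 at the RxCUI level (exact concept) and the ingredient
level (expanded sets, partial credit for combinations).

## Worked example

Everything below is generated in code — the fixture forge builds a seeded
synthetic knowledge base (syllable-template ingredient names, never real
drugs) and a benchmark of messy strings with gold mappings:

```r
library(mednorm)

params  <- forge_params(n_strings = 200, corruption_rate = 0, seed = 42)
kb      <- generate_kb(params)
bench   <- generate_benchmark(kb, params)
kb
#> <med_kb> 124 concepts (BN:20 IN:60 MIN:25 SCD:19), 244 terms, 101 relationships, 70 ATC rows
#>   version_id: b2dbbd4631bc901f32d4b2a915eb4844

backend <- mock_backend(kb, bench$parses, mode = "exact")
res     <- mn_batch(bench$input, kb, backend)
dplyr::count(res, match_type, confidence)
#>   match_type confidence     n
#> 1 perfect    high         152
#> 2 subset     low           48
```

152 strings reconcile at tier 1 (both sources agree); 48 are
combination-plus-extra rows that require subset decomposition, e.g.:

```r
res[grepl(" | ", res$rxcuis, fixed = TRUE), c("input", "rxcuis", "mapped")][1, ]
#>                                    input          rxcuis                                   mapped
#> 1 MOLDANDROMEX/PORNELTINSUL/KIRPORTOLELM 100085 | 100045 MOLDANDROMEX/PORNELTINSUL | KIRPORTOLELM
```

The slash joins ingredients inside one multi-ingredient concept; the pipe
separates distinct concepts mapped from a single input. Scoring against
the gold standard:

```r
glance(score_mappings(res, bench$gold, kb, "rxcui"))
#>   level    tp    fp    fn precision recall    f1
#> 1 rxcui   248     0     0         1      1     1
glance(score_mappings(res, bench$gold, kb, "ingredient"))
#>   level         tp    fp    fn precision recall    f1
#> 1 ingredient   356     0     0         1      1     1
```

On an uncorrupted benchmark with exact parses the pipeline recovers every
mapping at both levels — the end-to-end soundness property the test suite
asserts. `autoplot()` on an evaluation and `plot_confidence()` on a batch
result give the corresponding ggplot summaries.

A thin CLI wraps the same functions:

```sh
exec/mednorm forge --out demo --seed 5 --n-strings 20 --corruption-rate 0.3
exec/mednorm batch --kb demo/kb --input demo/input.csv --output demo/out.csv \
    --parses demo/parses.tsv --llm-backend mock:exact --cache demo/cache.tsv
exec/mednorm evaluate --kb demo/kb --predictions demo/out.csv --gold demo/gold.csv
```

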