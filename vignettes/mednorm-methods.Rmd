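---
title: "Methods: hybrid medication-string normalization in mednorm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid medication-string normalization in mednorm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mednorm)
```

## The normalization problem and the model

`mednorm` maps free-text medication strings to active generic drug
concepts — single-ingredient (IN) and multi-ingredient (MIN) entries of a
local RxNorm-like knowledge base. The design assumption is that two
complementary, individually fallible candidate generators can be fused
into a reliable one:

* a **deterministic matcher** that is precise on well-formed surface
  strings (preferred names, salts, synonyms, brands) but brittle to
  misspellings and truncations, because it compares whole tokens only;
* a **parser backend** (an LLM with deterministic decoding in production,
  a data-driven mock here) that is robust to lexical noise but may emit
  non-canonical names, drop an ingredient, or hallucinate one.

Reconciliation is rule-based and hierarchical rather than probabilistic.
Tier 1 accepts verbatim agreement of the two ingredient-name sets
(perfect match, high confidence). Tier 2 canonicalizes each name on both
sides — running it independently through the deterministic matcher,
restricted to IN resolution — and accepts equality of the resulting
ingredient sets when a single active generic covers the set exactly
(normalized perfect match, moderate confidence). Tier 3 abandons
deterministic corroboration and greedily decomposes the canonicalized
*parsed* set into exact-set IN/MIN concepts (subset match, low
confidence). The confidence label is therefore a statement about *how*
agreement was reached, not a calibrated probability; the test suite and
the acceptance script verify empirically (on synthetic data) that
exact-concept accuracy is monotone across the tiers.

Preprocessing is deliberately minimal — parenthetical removal, whitespace
normalization, uppercasing — preserving the original lexical content for
both matching and caching. No spelling correction or abbreviation
expansion is applied; those pathologies are the parser backend's job.

## Tunable parameters

* `min_score` (Jaccard threshold, default **0.5**): a candidate term must
  share a majority of tokens with the query. The production approximate
  matcher this emulates is not fully specified by its public interface,
  so whole-token Jaccard with majority overlap is used as a conservative
  stand-in; it intentionally keeps the deterministic path weak on
  misspellings (a one-character error in a token yields zero credit for
  that token).
* `subset_cap` (default **10** ingredients): subset decomposition
  enumerates up to 2^10 subsets; beyond the cap the reconciler falls back
  to singleton-only matching with a warning. Real combination products
  rarely exceed a handful of ingredients.
* Term-type priority for rank ties (`IN > MIN > PIN > BN > SCD > SBD >
  OTHER`), then identifier order (numeric ascending for all-digit ids,
  lexicographic otherwise): makes the candidate ranking a total order, so
  matching is deterministic across runs and platforms.
* Mock-backend rates (`synonym_rate` per name, `dropout_rate` and
  `noise_rate` per string): each channel targets one reconciliation tier;
  all perturbations are seeded per string, so batch order cannot change a
  parse.

## Numerical and design choices

Several behaviors were genuinely open and are fixed here as package
policy:

* **Tie-break among equal-size subsets** is lexicographic on the sorted
  member names. Any fixed total order preserves the partition property
  (finalized sets are pairwise disjoint and, with the residue,
  reconstruct the input); lexicographic is reproducible and
  human-predictable. A consequence worth knowing: for an input like
  {ASPIRIN, CODEINE, ACETAMINOPHEN} where two pair-combinations exist,
  the alphabetically earlier pair (ACETAMINOPHEN/CODEINE) is selected.
* **Nested parentheticals** are removed recursively, innermost-out;
  unbalanced parentheses (common in truncated pharmacy strings) remove
  from the unmatched opener to the end of the string, or from the start
  to the unmatched closer.
* **Empty or failed parses with a deterministic candidate present**
  finalize the deterministic generic at *low* confidence: the high tier
  is reserved for agreement of two independent sources. A failed backend
  call is treated exactly like an empty parse at reconciliation time, so
  a string with no deterministic candidate and a failed parse is reported
  unmapped with confidence none.
* **Tier 2 emits a single covering concept.** If the canonicalized sets
  agree but no one IN/MIN covers the set, the case falls through to
  subset matching; multi-concept output is always a tier-3 outcome.
* **Inactive concepts** are loadable and traversable (resolution paths
  may pass through them) but are never returned as finalized generics and
  never matched by ingredient-set lookup.
* **Crosswalk ATC acceptance** requires an identical active-ingredient
  set between the attached concept and the annotation target. This is the
  substantive safety rule: a clinical-drug concept sharing only some
  ingredients can never donate its class code. Partial coverage reuses
  the same descending-size, lexicographic-tie enumeration as subset
  matching — one enumeration discipline across the codebase.
* **Duplicate MIN ingredient sets are a load-time integrity error**, which
  makes set-to-generic lookup a function rather than a relation.
* **Evaluation is micro-averaged** over (string, concept) or
  (string, ingredient) pairs — "proportion of predicted mappings that are
  correct" read literally. Duplicate raw strings in a gold table are
  rejected.
* **Knowledge-base relationships** are modeled with a minimal sufficient
  set of four edge types (`has_ingredient`, `tradename_of`, `form_of`,
  `consists_of`); real vocabularies have richer graphs, and this is an
  explicit approximation of the "default paths" a full terminology
  service would traverse.

## What the synthetic data emulates — and what it does not

`forge_params()` / `generate_kb()` / `generate_benchmark()` produce
seeded, fully reproducible fixtures. Ingredient names come from syllable
templates, never real drug names, so no test can silently lean on
real-world pharmacologic knowledge. The generator emulates the pathology
taxonomy of survey/dispensing strings: brand vs generic surface forms,
salt and chemical synonyms, misspellings, truncation, abbreviation, dose
and unit suffixes, parenthetical annotations, separator variation, and
combination products (including combination-plus-extra rows whose gold
mapping is two concepts). Defaults — 60 ingredients, 25 combinations of
size 2–3, 20 brands, 200 strings, per-operator corruption 0.15 — are
chosen to resemble a small formulary slice with realistic messiness while
keeping the whole suite fast; benchmark rows mix target types at fixed
proportions (20% plain ingredients, 15% salt forms, 15% synonyms, 20%
combinations, 15% brands, 15% combination-plus-extra).

Two structural choices keep gold labels unambiguous: combination members
are drawn from the first 70% of ingredients while "extra" ingredients in
subset-forcing rows come from the reserved remainder (so the greedy
decomposition of the union is provably the combination plus the extra
IN), and the dropout channel of the mock parser only removes an
ingredient when at least two are present (removing the sole name would be
a parse failure, not the subset-tier behavior the channel exists to
exercise).

What passing tests on these fixtures does **not** show: performance on
real vocabularies (hundreds of thousands of concepts, richer relationship
types, genuinely ambiguous surface forms shared across products), real
LLM behavior (the mock's error channels are clean and independent;
real parsers make correlated, semantically plausible errors such as
collapsing a salt to the wrong base ingredient), or corpus-level metric
values — the synthetic F1 of 1.0 on a clean benchmark is a soundness
check of the machinery, not a performance claim.

## Problem sizes and runtime

The shipped suites use knowledge bases of 60–124 concepts and benchmarks
of 50–300 strings; the subset-match oracle comparison runs 100 seeded
knowledge bases with 7-ingredient universes (126 ingredient sets each,
implementation vs an independent brute-force enumeration). These sizes
exercise every code path — including cache invalidation and the
adversarial crosswalk fixtures — while the full test suite completes in a
few minutes on one CPU.

## Known limitations

* The deterministic matcher scores the entire term index per query
  (linear scan); fine at fixture scale, but a real deployment would want
  an inverted token index.
* Live terminology and parser services are out of scope by design: the
  vendor backend adapters are contract stubs, and the knowledge base is a
  local snapshot with a content-hash version id used for cache
  invalidation.
* ATC handling stores level-5 codes as given; hierarchy-aware analyses
  (rolling up to ATC-3, multi-level queries) are left to downstream code.
* English, uppercase-canonical inputs are assumed; non-ASCII characters
  pass through case-folded but no transliteration is attempted.
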