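---
title: "Tuning a patent search engine: models, benchmarks and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tuning a patent search engine: models, benchmarks and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patret)
```

## The retrieval problem

Patent search in the biomedical domain splits into tasks with very
different query shapes. In *prior-art (PA) search* the query is an
entire filed patent — its title, abstract and claims, hundreds of terms
— and the relevant documents are the earlier patents it cites. In a
*technical survey (TS)* the query is a few keywords and many patents may
be relevant; the *known-item (KI)* variant targets exactly one patent.
`patret` implements the full pipeline for these tasks and treats every
engineering decision that affects effectiveness — field selection,
normalization metadata, weighting model, citation re-ranking, IPC
augmentation — as an explicit, testable configuration.

## Document model and indexing

A patent document carries four text fields (title, abstract, claims,
description), IPC classification codes and outbound citations. Two
field scopes recur everywhere: **TAC** (title+abstract+claims) and
**TACD** (TAC plus description). The description is by far the longest
field and the most expensive to process; whether it helps or hurts
retrieval is an empirical question the tuning grid answers.

Indexing processes text as: tokenize (lowercase, split on any
non-alphanumeric character, keep digit tokens — chemical names fragment
into digit runs and dropping them is an unforced loss), remove
stopwords (a deliberately minimal ~130-word English list; the list is a
parameter of `index_config()`), then stem with a from-scratch
implementation of the classic Porter (1980) algorithm, verified against
the published example vectors. Two kinds of pseudo-tokens join the text
tokens unstemmed, since they are identifiers rather than words:
`CONCEPT_<source>_<id>` for normalized concepts and `IPC_<code>` for
classification codes (both the 4-character subclass and the full code,
so matching can happen at either granularity).

Concept metadata comes from dictionary normalization
(`annotate_corpus()`): greedy leftmost-longest, non-overlapping matching
of terminology synonyms over the scoped token sequence. Matching is
exact on lowercased tokens, without stemming or fuzzy matching — the
standard gazetteer strategy, chosen because it is deterministic and
auditable; disambiguation and approximate matching are explicitly out
of scope. Concepts are stored as a bag (duplicates kept) so that, once
indexed, metadata competes with text tokens under term-frequency-based
models rather than as binary flags. Annotation over the concatenated
scope text means a phrase could in principle straddle a field boundary;
with realistic dictionaries this is vanishingly rare and the structural
invariants (idempotence, TAC ⊆ TACD as concept bags) are asserted in
the test suite on generated corpora.

## Weighting models

Both rankers score a document as the query-term-frequency-weighted sum
of per-term contributions.

**Okapi BM25** with defaults `k1 = 1.2`, `b = 0.75` — the standard
defaults of the platform family this engine descends from; neither
value is task-tuned here, and both are exposed as parameters. The idf
component is floored at zero so that terms occurring in more than half
the collection contribute nothing rather than negative scores.

**PL2** — divergence from randomness with a Poisson random model,
Laplace after-effect and length normalization 2 (`c = 1.0` by
default). The Stirling-corrected form is kept exactly as published,
including the possibility of negative contributions for very common
terms; whether production systems suppress those is not documented
anywhere authoritative, so `patret` keeps the faithful formula and
documents the choice rather than guessing. BM25 uses natural log in its
idf, PL2 uses base-2 logs throughout, matching their respective source
formulations.

Ties in the final ranking are broken by ascending document id, making
run files byte-reproducible. Retrieval correctness is not taken on
faith: the test suite checks posting-list accumulation against a
per-document brute-force scorer (`score_document_bruteforce()`) to
1e-9 relative tolerance for both models.

## Co-citation re-ranking and IPC augmentation

The citation network supplies a query-independent popularity signal:
each patent's in-collection citation count. Re-ranking linearly
combines this with the retrieval score *within the retrieved list*:
both components are min-max normalized over the list (a constant
component normalizes to all-zero), the citation count is log-damped
(`log1p`) because citation counts are heavy-tailed and raw counts would
let a single blockbuster patent saturate the scale, and the final score
is `(1 − α)·s_ir + α·s_cit`. The combination weight defaults to
`α = 0.2` — a modest boost consistent with the moderate improvements
this strategy yields; it is exposed as a parameter everywhere.
Score-space combination (rather than rank-space) was chosen as the
stable, common reading of linear combination in this setting; a
rank-based variant is deliberately not implemented so there is exactly
one audited code path. Re-ranking never injects documents that the
query did not retrieve — it is a pure permutation of the result list,
and the `α = 0` boundary is the identity.

IPC augmentation simply adds the topic's classification codes to the
query as `IPC_` tokens with query term frequency 1. For prior-art
queries (hundreds of text terms) the two extra tokens are a drop in the
bucket; for short survey queries they act as a strong topical filter —
which is exactly the asymmetry the tuning grid measures.

## Benchmarks

`build_prior_art_benchmark()` turns a corpus into PA topics: candidate
topics are patents citing at least one in-corpus patent; judgments are
the cited in-corpus patents, never the topic patent itself. Citations
to patents outside the collection are dropped from the judgments —
they cannot be retrieved, so scoring them would only add noise. Each
topic's own patent is removed from its result list by default
(`exclude_self`), since it trivially matches itself.

`build_known_item_benchmark()` samples, per topic, ten distinct words
from one patent's TAC text; that patent is the sole relevant document.
Eligible words exclude stopwords and single characters — without this
filter a topic could be ten occurrences of "the", which tests nothing.
Whether the original known-item methodology filtered stopwords is
unstated in the literature this follows; the filter here is a
documented choice, configurable through the stopword list.

Benchmark sizes are parameters, not constants: the default desk-scale
experiment uses 300 patents, 50 PA topics and 100 KI topics, sizes
chosen so that the full tuning grid runs in minutes on one CPU while
keeping the metric estimates stable enough for directional
conclusions.

## Evaluation

P0 is the mean reciprocal rank — the tuning criterion, since users
rarely look past the top handful of results; MAP (non-interpolated, to
depth 1000) and P@1 are reported alongside. For single-relevant topics
AP equals RR identically, which the tests assert over whole KI
benchmarks. Metrics use 1-based positions internally; run *files* store
a 0-based rank column, the convention of the engine family this
follows. Topics with an empty relevant set are excluded from the means
(AP is undefined at R = 0) but counted in the report.

Paired comparisons use a two-sided sign-flip randomization test on the
mean per-topic difference: exact enumeration of all 2^n sign
assignments for n ≤ 20, seeded Monte Carlo (observed assignment always
counted) above. It is distribution-free and exact at small n, which
matters because desk-scale grids have few topics.

## What the synthetic generator emulates — and what it does not

`generate_corpus()` produces corpora with the statistical structure the
tuning experiments rely on:

* **topical vocabulary clusters** (default 10 topics, 80 Zipf-weighted
  words each): citing and cited patents share a topic 90% of the time,
  so citation-derived judgments are learnable from text;
* **noise-diluted descriptions**: description tokens come from a shared
  400-word noise vocabulary with probability 0.8 (TAC fields: 0.1),
  making the description the mechanism by which full-body indexing
  hurts precision;
* **field lengths** of roughly 8/60/120/600 tokens
  (title/abstract/claims/description), so TAC is an order of magnitude
  shorter than TACD;
* **citation network**: ~3 outbound citations per patent to earlier
  patents only (acyclic), chosen by topic bias (0.9) and preferential
  attachment (exponent 1.0) on in-degree — frequently cited patents
  become more likely to be cited again, and hence more likely to appear
  in some topic's judgments, which is precisely the premise of
  co-citation boosting;
* **IPC codes** drawn from a deterministic per-topic pool, so
  classification correlates with topic.

The defaults above are the package's study conditions; where a value
had no external anchor (topic count, vocabulary sizes, the 0.1 TAC
noise fraction) it was set once to what makes the corpus qualitatively
patent-like — short dense TAC, long diffuse description — and left
alone.

What the generator does *not* emulate: real claim grammar and chemical
nomenclature, multilingual text, n-gram structure (it is a unigram
mixture), time-varying citation practices, and the sheer scale and
vocabulary skew of million-patent collections. Consequently, passing
the directional tests shows the *machinery* behaves as designed — that
dropping a noise-heavy field helps known-item precision, that a
citation prior helps citation-derived judgments, that classification
codes sharpen short queries. Absolute P0/MAP values on synthetic
corpora say nothing about absolute effectiveness on a real collection,
and the package makes no such claim. On the synthetic corpora, concept
metadata (`CONCEPT_` tokens) typically adds little over the text it was
matched from — the grid reports whatever the corpus yields for those
rows without asserting a direction, mirroring the open question of
whether terminological normalization pays off in practice.

## Degenerate inputs and numerical corners

* Empty queries, and queries whose every term is out of vocabulary,
  raise distinct errors rather than returning empty lists silently.
* Documents with score ≤ 0 are omitted from result lists (relevant for
  PL2, whose contributions can be negative).
* Min-max normalization of a constant vector is defined as all-zero.
* The sign-flip test compares |mean| with a 1e-12 absolute guard so
  that floating-point noise cannot flip an enumeration count.
* Patent ids are uppercased with whitespace stripped at every entry
  point, so citation matching is exact string equality.
* The stemmer leaves tokens of one or two characters unchanged and
  treats digits as consonants; both choices are deterministic and
  covered by tests.

## The tuning grid

```{r grid, eval = FALSE}
grid <- run_tuning_grid("pa", synth_config(seed = 42))
grid[, c("name", "p0", "map", "p_value")]
```

`run_tuning_grid()` evaluates the strategy ladder — description in/out,
metadata TAC/TACD, PL2 vs BM25, co-citation re-ranking, IPC codes — on
identical topics and judgments, with a sign-flip p-value against the
first (baseline) row. The TS task here is a stand-in built from 5-word
known-item topics carrying the source patent's IPC codes, since real
survey topic sets are external data; its purpose is to expose the
short-query regime where IPC augmentation helps.

## Known limitations

Incremental indexing is not supported (rebuild from the corpus);
postings are uncompressed in-memory structures suitable for desk-scale
corpora, not millions of documents; relevance is binary; and the
normalization module ships only toy terminologies — the TSV format
accepts real MeSH/GO-scale dictionaries, but none are bundled.
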