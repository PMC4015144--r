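# patret — field-selective patent retrieval in R

`patret` is a self-contained search engine for patent collections, built
for the two retrieval tasks that dominate drug-discovery competitive
intelligence:

* **prior-art (PA) search** — given a filed patent, find the earlier
  patents it should cite; the query is the patent's own title, abstract
  and claims, and relevance is defined by its citations;
* **technical survey (TS)** — ad-hoc retrieval from a short keyword
  query, including the **known-item (KI)** variant where exactly one
  patent is the target.

The engine's effectiveness depends less on the weighting model than on
how it is tuned to the task, and `patret` exposes every tuning axis as
configuration: which fields are indexed (the long `description` field is
cheap to drop and often harmful), whether dictionary-normalized concept
metadata is indexed, BM25 vs PL2 weighting, co-citation re-ranking, and
IPC-code query augmentation.

## What is inside

* **Corpus I/O** — a simple patent XML dialect (`read_patent_corpus()`,
  `write_patent_corpus()`) and terminology TSV dictionaries
  (`read_terminology()`).
* **Synthetic corpus generator** (`generate_corpus()`) — seeded corpora
  with topical vocabulary clusters, noise-diluted descriptions,
  topic-linked IPC codes and a preferential-attachment citation network,
  so every experiment in the package is reproducible from a seed.
* **Normalization** (`annotate_corpus()`) — greedy leftmost-longest
  dictionary matching of terminology synonyms over TAC or TACD text,
  stored as concept metadata and indexable as `CONCEPT_*` pseudo-tokens.
* **Indexing** (`build_index()`) — tokenization, stopword removal and a
  from-scratch classic Porter (1980) stemmer feeding an inverted index
  with field selection and full collection statistics.
* **Ranking** (`retrieve()`) — Okapi BM25,

  `w(t, d) = idf(t) · (k1 + 1)·tf / (k1·((1 − b) + b·dl/avdl) + tf)`,
  `idf(t) = max(0, ln((N − df + 0.5)/(df + 0.5)))`,

  and PL2 divergence-from-randomness (Poisson randomness, Laplace
  after-effect, length normalization 2),

  `tfn = tf · log2(1 + c·avdl/dl)`, `λ = cf/N`,
  `w(t, d) = (tfn·log2(tfn/λ) + (λ + 1/(12·tfn) − tfn)·log2 e +
  0.5·log2(2π·tfn)) / (tfn + 1)`.

* **Pipeline** — prior-art and ad-hoc query builders, IPC augmentation
  (`augment_query_with_ipc()`), and co-citation re-ranking
  (`rerank_with_citations()`): the retrieval score and the (log-damped)
  in-collection citation count are min-max normalized within the result
  list and combined as `(1 − α)·s_ir + α·s_cit`.
* **Benchmarks & evaluation** — prior-art and known-item benchmark
  construction, TREC-style topic/qrels/run I/O, P0 (mean reciprocal
  rank), MAP and P@1 (`evaluate_run()`), and a paired sign-flip
  randomization test (`paired_randomization_test()`), exact up to 20
  topics.
* **Experiments** — `run_tuning_grid()` wires everything into the
  strategy ladder (description in/out, metadata scope, BM25/PL2,
  re-ranking, IPC) with per-row significance against a baseline.

## Worked example

```r
library(patret)

syn    <- synth_config(n_patents = 150, seed = 42)
corpus <- generate_corpus(syn)
index  <- build_index(corpus, index_config(include_description = FALSE))
index
#> <inverted_index> 150 docs, 1196 terms, avdl 190.1

pa <- build_prior_art_benchmark(corpus, n_topics = 30, seed = 42)
run_plain <- run_search(index, corpus, pa$topics, ranking_params("BM25"))
run_boost <- run_search(index, corpus, pa$topics, ranking_params("BM25"),
                        rerank_alpha = 0.2)
evaluate_run(run_plain, pa$qrels)
#> <eval_report> 30 topics (cutoff 1000)
#>   P0 (MRR): 0.3389   MAP: 0.3003   P@1: 0.1667
evaluate_run(run_boost, pa$qrels)
#> <eval_report> 30 topics (cutoff 1000)
#>   P0 (MRR): 0.7563   MAP: 0.6897   P@1: 0.6333
```

Each prior-art topic is one synthetic patent; its query is the patent's
processed title+abstract+claims, and its relevant set is the patents it
cites (restricted to the corpus, excluding itself). Without boosting,
the first relevant patent sits on average around rank 3 (P0 0.34);
adding 20% of the co-citation score lifts it to P0 0.76 — frequently
cited patents are, by construction of the citation network, more likely
to be relevant. The improvement is significant under the paired
sign-flip test on per-topic reciprocal ranks:

```r
rr_a <- evaluate_run(run_boost, pa$qrels)$per_topic$rr
rr_b <- evaluate_run(run_plain, pa$qrels)$per_topic$rr
paired_randomization_test(rr_a, rr_b, seed = 42)
#> [1] 9.999e-05
```

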