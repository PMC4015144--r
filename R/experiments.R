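#' Default tuning-grid configurations
#'
#' The strategy ladder explored by the tuning experiments: starting from
#' a PL2 index of the whole patent, successively drop the description
#' field, switch concept metadata on (TAC and TACD scopes), switch to
#' BM25, enable co-citation re-ranking, and enable IPC query
#' augmentation. Each row is compared against the declared baseline
#' (first row) with a paired sign-flip test.
#'
#' @return A list of configuration lists with fields `name`,
#'   `include_description`, `metadata_mode`, `model`, `rerank_alpha`
#'   (`NULL` = off) and `ipc_boost`.
#' @export
default_grid_configurations <- function() {
  list(
    list(name = "desc+PL2", include_description = TRUE,
         metadata_mode = "NONE", model = "PL2", rerank_alpha = NULL,
         ipc_boost = FALSE),
    list(name = "nodesc+PL2", include_description = FALSE,
         metadata_mode = "NONE", model = "PL2", rerank_alpha = NULL,
         ipc_boost = FALSE),
    list(name = "nodesc+PL2+metaTAC", include_description = FALSE,
         metadata_mode = "TAC", model = "PL2", rerank_alpha = NULL,
         ipc_boost = FALSE),
    list(name = "nodesc+PL2+metaTACD", include_description = FALSE,
         metadata_mode = "TACD", model = "PL2", rerank_alpha = NULL,
         ipc_boost = FALSE),
    list(name = "nodesc+BM25", include_description = FALSE,
         metadata_mode = "NONE", model = "BM25", rerank_alpha = NULL,
         ipc_boost = FALSE),
    list(name = "nodesc+BM25+rerank", include_description = FALSE,
         metadata_mode = "NONE", model = "BM25", rerank_alpha = 0.2,
         ipc_boost = FALSE),
    list(name = "nodesc+BM25+rerank+IPC", include_description = FALSE,
         metadata_mode = "NONE", model = "BM25", rerank_alpha = 0.2,
         ipc_boost = TRUE)
  )
}

#' Run a tuning grid on a synthetic benchmark
#'
#' Generates a synthetic corpus, builds one benchmark of the requested
#' task, evaluates every configuration of the grid on the identical
#' topics and qrels, and reports P0, MAP and P@1 per configuration,
#' together with a paired sign-flip p-value of the per-topic reciprocal
#' ranks against the baseline (first) configuration. The run is a pure
#' function of the synthetic config's seed.
#'
#' Tasks: `"pa"` uses a prior-art benchmark (long TAC queries, citation
#' qrels); `"ki"` a known-item benchmark (10 sampled words, one relevant
#' patent); `"ts"` a technical-survey stand-in — short 5-word known-item
#' style topics carrying the source patent's IPC codes, mimicking ad-hoc
#' keyword queries.
#'
#' @param task `"pa"`, `"ts"` or `"ki"`.
#' @param synth A [synth_config()]; its seed drives corpus, benchmark
#'   and terminology generation.
#' @param n_topics Topics in the benchmark (default 50 for PA, 100
#'   otherwise).
#' @param configurations Grid rows; see [default_grid_configurations()].
#' @param cutoff Evaluation depth (default 1000).
#' @param out_tsv Optional path: write the results table as TSV.
#' @return data.frame with one row per configuration: `name`, `model`,
#'   `description`, `metadata`, `rerank`, `ipc`, `p0`, `map`, `p_at_1`,
#'   `p_value` (NA for the baseline row). The per-topic reciprocal
#'   ranks are attached as attribute `per_topic_rr`.
#' @export
run_tuning_grid <- function(task = c("pa", "ts", "ki"),
                            synth = synth_config(),
                            n_topics = NULL,
                            configurations = default_grid_configurations(),
                            cutoff = 1000L,
                            out_tsv = NULL) {
  task <- match.arg(task)
  if (is.null(n_topics)) n_topics <- if (task == "pa") 50L else 100L
  corpus <- generate_corpus(synth)
  bench <- switch(task,
    pa = build_prior_art_benchmark(corpus, n_topics, seed = synth$seed),
    ki = build_known_item_benchmark(corpus, n_topics,
                                    words_per_topic = 10L,
                                    seed = synth$seed),
    ts = build_known_item_benchmark(corpus, n_topics,
                                    words_per_topic = 5L,
                                    seed = synth$seed)
  )
  if (task == "ts") {
    bench$topics <- lapply(bench$topics, function(t) {
      t$kind <- "TS"
      t$topic_id <- sub("^KI-", "TS-", t$topic_id)
      t
    })
    names(bench$qrels) <- sub("^KI-", "TS-", names(bench$qrels))
  }

  scopes_needed <- unique(vapply(configurations,
                                 function(cf) cf$metadata_mode, ""))
  scopes_needed <- setdiff(scopes_needed, "NONE")
  annotated <- list()
  if (length(scopes_needed)) {
    term <- generate_terminology(synth, corpus)
    for (scope in scopes_needed) {
      annotated[[scope]] <- annotate_corpus(corpus, term, scope)
    }
  }

  indexes <- list()
  rows <- vector("list", length(configurations))
  baseline_rr <- NULL
  for (i in seq_along(configurations)) {
    cf <- configurations[[i]]
    key <- paste(cf$include_description, cf$metadata_mode)
    if (is.null(indexes[[key]])) {
      src <- if (cf$metadata_mode == "NONE") corpus else {
        annotated[[cf$metadata_mode]]
      }
      indexes[[key]] <- build_index(src, index_config(
        include_description = cf$include_description,
        metadata_mode = cf$metadata_mode))
    }
    run <- run_search(indexes[[key]], corpus, bench$topics,
                      params = ranking_params(cf$model, k = cutoff),
                      ipc_boost = cf$ipc_boost,
                      rerank_alpha = cf$rerank_alpha,
                      tag = cf$name)
    report <- evaluate_run(run, bench$qrels, cutoff)
    rr <- stats::setNames(report$per_topic$rr, report$per_topic$topic_id)
    if (i == 1L) baseline_rr <- rr
    p_value <- if (i == 1L) NA_real_ else {
      common <- intersect(names(baseline_rr), names(rr))
      paired_randomization_test(rr[common], baseline_rr[common],
                                seed = synth$seed)
    }
    rows[[i]] <- data.frame(
      name = cf$name, model = cf$model,
      description = cf$include_description,
      metadata = cf$metadata_mode,
      rerank = !is.null(cf$rerank_alpha),
      ipc = cf$ipc_boost,
      p0 = report$p0, map = report$map, p_at_1 = report$p_at_1,
      p_value = p_value, stringsAsFactors = FALSE
    )
    attr(rows[[i]], "rr") <- rr
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_topic_rr") <- lapply(rows, attr, "rr")
  if (!is.null(out_tsv)) {
    utils::write.table(out, out_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
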