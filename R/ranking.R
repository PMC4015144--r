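#' Ranking parameters
#'
#' Parameters of the two weighting models. BM25 uses `k1` (term-frequency
#' saturation) and `b` (length normalization); PL2 — the
#' divergence-from-randomness model with Poisson randomness, Laplace
#' after-effect and length normalization 2 — uses `c` (normalization
#' strength). `k` caps the result list.
#'
#' @param model `"BM25"` or `"PL2"`.
#' @param k1 Positive real, default 1.2.
#' @param b Real in `[0, 1]`, default 0.75.
#' @param c Positive real, default 1.0.
#' @param k Result cutoff, default 1000.
#' @return Object of class `ranking_params`.
#' @export
ranking_params <- function(model = c("BM25", "PL2"), k1 = 1.2, b = 0.75,
                           c = 1.0, k = 1000L) {
  model <- match.arg(model)
  stopifnot(k1 > 0, b >= 0, b <= 1, c > 0, k >= 1)
  structure(list(model = model, k1 = k1, b = b, c = c, k = as.integer(k)),
            class = "ranking_params")
}

#' Construct a query from a bag of processed tokens
#'
#' @param terms Character vector of processed tokens (stems and/or
#'   `IPC_*` / `CONCEPT_*` pseudo-tokens); repeated tokens raise the
#'   query term frequency.
#' @return Object of class `patent_query`: a named integer vector of
#'   query term frequencies.
#' @export
patent_query <- function(terms) {
  tab <- table(terms)
  structure(stats::setNames(as.integer(tab), names(tab)),
            class = "patent_query")
}

query_terms <- function(query) names(unclass(query))

#' BM25 contribution of one term occurrence profile
#'
#' Computes `idf * ((k1 + 1) * tf) / (k1 * ((1 - b) + b * dl / avdl) + tf)`
#' with `idf = max(0, ln((N - df + 0.5) / (df + 0.5)))`. The idf floor at
#' zero prevents very common terms (df > N/2) from contributing negative
#' scores. Vectorized over `tf`, `df` and `dl`.
#'
#' @param tf In-document term frequency (>= 1).
#' @param df Document frequency, `1 <= df <= N`.
#' @param dl Document length in tokens.
#' @param stats List with collection size `N` and mean length `avdl`.
#' @param params A [ranking_params()].
#' @return Numeric score contribution (>= 0).
#' @export
bm25_term_weight <- function(tf, df, dl, stats, params = ranking_params()) {
  if (stats$avdl <= 0) stop("avdl must be positive")
  if (any(df > stats$N)) stop("df cannot exceed N")
  idf <- pmax(0, log((stats$N - df + 0.5) / (df + 0.5)))
  idf * ((params$k1 + 1) * tf) /
    (params$k1 * ((1 - params$b) + params$b * dl / stats$avdl) + tf)
}

#' PL2 divergence-from-randomness contribution of one term
#'
#' Normalization 2 rescales the term frequency to
#' `tfn = tf * log2(1 + c * avdl / dl)`; with Poisson mean
#' `lambda = cf / N` the score is
#' `(1 / (tfn + 1)) * (tfn * log2(tfn / lambda)
#'   + (lambda + 1/(12 tfn) - tfn) * log2(e) + 0.5 * log2(2 pi tfn))`
#' (Poisson randomness with Stirling's correction, Laplace after-effect).
#' No floor is applied: very common terms may contribute negatively.
#' Vectorized over `tf`, `cf` and `dl`.
#'
#' @param tf In-document term frequency (>= 1).
#' @param cf Collection frequency of the term (>= 1).
#' @param dl Document length in tokens (> 0).
#' @inheritParams bm25_term_weight
#' @return Numeric score contribution (may be negative).
#' @export
pl2_term_weight <- function(tf, cf, dl, stats, params = ranking_params("PL2")) {
  if (any(dl <= 0)) stop("document length must be positive")
  tfn <- tf * log2(1 + params$c * stats$avdl / dl)
  lambda <- cf / stats$N
  (1 / (tfn + 1)) * (
    tfn * log2(tfn / lambda) +
      (lambda + 1 / (12 * tfn) - tfn) * log2(exp(1)) +
      0.5 * log2(2 * pi * tfn)
  )
}

term_weight_for_postings <- function(p, dl, index, params) {
  if (params$model == "BM25") {
    bm25_term_weight(p$tf, df = length(p$doc_ids), dl = dl,
                     stats = index$stats, params = params)
  } else {
    pl2_term_weight(p$tf, cf = sum(p$tf), dl = dl,
                    stats = index$stats, params = params)
  }
}

#' Score one document against a query by direct lookup
#'
#' Reference scorer used as a testing oracle for [retrieve()]: sums, over
#' query terms, `qtf * term_weight` with the term frequency looked up for
#' this single document — no accumulation over posting lists.
#'
#' @param query A [patent_query()].
#' @param doc_id Document id present in the index.
#' @param index An `inverted_index`.
#' @param params A [ranking_params()].
#' @return Numeric score (0 if no query term occurs in the document).
#' @export
score_document_bruteforce <- function(query, doc_id, index,
                                      params = ranking_params()) {
  if (!doc_id %in% names(index$doc_lengths)) {
    stop("unknown document: ", doc_id)
  }
  dl <- index$doc_lengths[[doc_id]]
  total <- 0
  qtf <- unclass(query)
  for (term in names(qtf)) {
    p <- get0(term, envir = index$postings, inherits = FALSE)
    if (is.null(p)) next
    pos <- match(doc_id, p$doc_ids)
    if (is.na(pos)) next
    w <- if (params$model == "BM25") {
      bm25_term_weight(p$tf[[pos]], df = length(p$doc_ids), dl = dl,
                       stats = index$stats, params = params)
    } else {
      pl2_term_weight(p$tf[[pos]], cf = sum(p$tf), dl = dl,
                      stats = index$stats, params = params)
    }
    total <- total + qtf[[term]] * w
  }
  total
}

#' Retrieve the top-k documents for a query
#'
#' Term-at-a-time accumulation over the posting lists of the query terms.
#' Documents with total score <= 0 are omitted; the survivors are sorted
#' by descending score with ties broken by ascending document id, and cut
#' at `params$k`.
#'
#' @param index An `inverted_index`.
#' @param query A [patent_query()]; must contain at least one term, and at
#'   least one term must occur in the index vocabulary.
#' @param params A [ranking_params()].
#' @param query_id Optional query identifier attached to the result.
#' @return Object of class `ranked_results`: a data.frame with columns
#'   `doc_id` and `score`, ordered, with attribute `query_id`.
#' @export
retrieve <- function(index, query, params = ranking_params(),
                     query_id = "Q1") {
  qtf <- unclass(query)
  if (!length(qtf)) stop("empty query: no terms after processing")
  id_chunks <- list(); w_chunks <- list(); n_hit <- 0L
  for (term in names(qtf)) {
    p <- get0(term, envir = index$postings, inherits = FALSE)
    if (is.null(p)) next
    n_hit <- n_hit + 1L
    dl <- unname(index$doc_lengths[p$doc_ids])
    id_chunks[[n_hit]] <- p$doc_ids
    w_chunks[[n_hit]] <- qtf[[term]] * term_weight_for_postings(p, dl, index, params)
  }
  if (!n_hit) {
    stop("all query terms are out of vocabulary for this index")
  }
  all_ids <- unlist(id_chunks, use.names = FALSE)
  totals <- rowsum(unlist(w_chunks, use.names = FALSE), all_ids)
  ids <- rownames(totals)
  scores <- as.numeric(totals)
  keep <- scores > 0
  ids <- ids[keep]; scores <- unname(scores[keep])
  ord <- order(-scores, ids, method = "radix")
  ord <- ord[seq_len(min(length(ord), params$k))]
  ranked_results(data.frame(doc_id = ids[ord], score = scores[ord],
                            stringsAsFactors = FALSE),
                 query_id = query_id)
}

ranked_results <- function(df, query_id = "Q1") {
  rownames(df) <- NULL
  structure(df, class = c("ranked_results", "data.frame"),
            query_id = query_id)
}

#' @export
print.ranked_results <- function(x, ...) {
  cat("<ranked_results> query", attr(x, "query_id"), "-", nrow(x), "docs\n")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}
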