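# direct formula evaluations used as independent oracles
oracle_bm25 <- function(tf, df, dl, N, avdl, k1 = 1.2, b = 0.75) {
  idf <- max(0, log((N - df + 0.5) / (df + 0.5)))
  idf * ((k1 + 1) * tf) / (k1 * ((1 - b) + b * dl / avdl) + tf)
}

oracle_pl2 <- function(tf, cf, dl, N, avdl, c = 1) {
  tfn <- tf * log2(1 + c * avdl / dl)
  lambda <- cf / N
  (1 / (tfn + 1)) * (tfn * log2(tfn / lambda) +
                       (lambda + 1 / (12 * tfn) - tfn) * log2(exp(1)) +
                       0.5 * log2(2 * pi * tfn))
}

test_that("BM25 weight matches direct formula evaluation", {
  stats <- list(N = 10, avdl = 100)
  got <- bm25_term_weight(tf = 3, df = 2, dl = 100, stats = stats)
  expect_equal(got, log(8.5 / 2.5) * 6.6 / 4.2, tolerance = 1e-12)
  expect_equal(got, 1.9231, tolerance = 1e-4)
  # idf floor: df = N/2 gives ln(1) = 0 and anything commoner stays at 0
  expect_equal(bm25_term_weight(5, df = 1, dl = 10,
                                stats = list(N = 2, avdl = 10)), 0)
  expect_equal(bm25_term_weight(5, df = 9, dl = 10,
                                stats = list(N = 10, avdl = 10)), 0)
  # random profiles against the oracle
  set.seed(101)
  for (i in 1:50) {
    N <- sample(5:5000, 1); df <- sample.int(N, 1)
    tf <- sample(1:30, 1); avdl <- runif(1, 10, 500)
    dl <- runif(1, 1, 3 * avdl)
    expect_equal(
      bm25_term_weight(tf, df, dl, list(N = N, avdl = avdl)),
      oracle_bm25(tf, df, dl, N, avdl), tolerance = 1e-12
    )
  }
})

test_that("BM25 saturates in tf, decreases in df, never negative", {
  stats <- list(N = 1000, avdl = 50)
  tfs <- c(1, 2, 5, 10, 100, 1000)
  w <- bm25_term_weight(tfs, df = 10, dl = 50, stats = stats)
  expect_true(all(diff(w) > 0))
  idf <- log((1000 - 10 + 0.5) / 10.5)
  expect_true(all(w < idf * 2.2))  # (k1+1) * idf bound
  wd <- bm25_term_weight(3, df = c(1, 10, 100, 600, 999), dl = 50,
                         stats = stats)
  expect_true(all(diff(wd) <= 0))
  expect_true(all(wd >= 0))
})

test_that("PL2 weight matches direct formula evaluation", {
  stats <- list(N = 100, avdl = 80)
  got <- pl2_term_weight(tf = 2, cf = 4, dl = 80, stats = stats)
  lambda <- 0.04
  want <- (1 / 3) * (2 * log2(2 / lambda) +
                       (lambda + 1 / 24 - 2) * log2(exp(1)) +
                       0.5 * log2(4 * pi))
  expect_equal(got, want, tolerance = 1e-12)
  expect_equal(got, 3.4486, tolerance = 1e-4)
  set.seed(202)
  for (i in 1:50) {
    N <- sample(5:5000, 1); cf <- sample(1:200, 1)
    tf <- sample(1:30, 1); avdl <- runif(1, 10, 500)
    dl <- runif(1, 1, 3 * avdl)
    expect_equal(
      pl2_term_weight(tf, cf, dl, list(N = N, avdl = avdl)),
      oracle_pl2(tf, cf, dl, N, avdl), tolerance = 1e-12
    )
  }
})

test_that("PL2 normalization: tfn = tf at dl = avdl, shrinks as dl grows", {
  stats <- list(N = 50, avdl = 120)
  # at dl = avdl and c = 1, log2(2) = 1 so tfn = tf exactly: compare with
  # the un-normalized Poisson form computed directly
  tf <- 4; cf <- 9
  lambda <- cf / 50
  plain <- (1 / (tf + 1)) * (tf * log2(tf / lambda) +
                               (lambda + 1 / (12 * tf) - tf) * log2(exp(1)) +
                               0.5 * log2(2 * pi * tf))
  expect_equal(pl2_term_weight(tf, cf, dl = 120, stats = stats), plain,
               tolerance = 1e-12)
  # monotone length effect on tfn
  dls <- c(30, 60, 120, 240, 480)
  tfns <- tf * log2(1 + 120 / dls)
  expect_true(all(diff(tfns) < 0))
})

test_that("retrieve equals brute-force scoring and respects cutoff/ties", {
  corpus <- generate_corpus(synth_config(n_patents = 60, seed = 5))
  idx <- build_index(corpus, index_config(include_description = FALSE))
  set.seed(99)
  vocab <- ls(idx$postings)
  for (model in c("BM25", "PL2")) {
    params <- ranking_params(model, k = 30)
    for (i in 1:10) {
      q <- patent_query(sample(vocab, sample(2:6, 1)))
      r <- retrieve(idx, q, params)
      expect_lte(nrow(r), 30)
      expect_false(is.unsorted(rev(r$score)))
      for (j in sample(nrow(r), min(5, nrow(r)))) {
        expect_equal(r$score[j],
                     score_document_bruteforce(q, r$doc_id[j], idx, params),
                     tolerance = 1e-9)
      }
      # ties (if any) are broken by ascending doc id
      same <- split(r$doc_id, r$score)
      for (grp in same) expect_false(is.unsorted(grp))
    }
  }
})

test_that("retrieve error cases and determinism", {
  corpus <- tiny_corpus()
  idx <- build_index(corpus, index_config())
  expect_error(retrieve(idx, patent_query(character())), "empty query")
  expect_error(retrieve(idx, patent_query(c("zzzz", "qqqq"))),
               "out of vocabulary")
  q <- build_adhoc_query("kinase assay activity", idx$config)
  r1 <- retrieve(idx, q, ranking_params("BM25"))
  r2 <- retrieve(idx, q, ranking_params("BM25"))
  expect_identical(r1, r2)
  # a term unique to one document puts that document first
  qq <- patent_query(porter_stem("monoclonal"))
  expect_identical(retrieve(idx, qq)$doc_id[1], "EP0000002")
  r1 <- retrieve(idx, q, ranking_params("BM25", k = 1))
  expect_lte(nrow(r1), 1L)
})
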