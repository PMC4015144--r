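test_that("reciprocal rank and P@1 follow their definitions", {
  ids <- paste0("D", 1:10)
  expect_equal(reciprocal_rank(ids, "D4"), 0.25)
  expect_equal(reciprocal_rank(ids, "D1"), 1)
  expect_equal(reciprocal_rank(ids, "ZZ"), 0)
  expect_equal(precision_at_1(ids, "D1"), 1)
  expect_equal(precision_at_1(ids, "D4"), 0)
})

test_that("average precision matches the worked prior-art example", {
  # two relevant patents initially retrieved at 1-based positions 39 and
  # 97: AP = (1/39 + 2/97) / 2 = 2.31%; after co-citation boosting they
  # sit at positions 2 and 3: AP = (1/2 + 2/3) / 2 = 58.33%
  ids <- sprintf("D%03d", 1:200)
  rel <- c("D039", "D097")
  expect_equal(100 * average_precision(ids, rel), 2.31, tolerance = 0.005)
  boosted <- c("D100", "D039", "D097",
               setdiff(ids, c("D100", "D039", "D097")))
  expect_equal(100 * average_precision(boosted, rel), 58.33,
               tolerance = 0.005)
  # perfect ranking: all R relevant in the top R positions
  expect_equal(average_precision(ids, c("D001", "D002", "D003")), 1)
  # cutoff: relevant docs below it contribute nothing
  expect_equal(average_precision(ids, rel, cutoff = 50),
               (1 / 39) / 2, tolerance = 1e-12)
  expect_error(average_precision(ids, character()), "undefined")
})

test_that("metrics agree with an exhaustive oracle on random lists", {
  set.seed(123)
  for (i in 1:1000) {
    n <- sample(1:20, 1)
    ids <- sample(paste0("D", 1:30), n)
    relevant <- sample(paste0("D", 1:30), sample(1:5, 1))
    cutoff <- sample(c(3L, 10L, 1000L), 1)
    expect_identical(reciprocal_rank(ids, relevant),
                     oracle_rr(ids, relevant))
    expect_equal(average_precision(ids, relevant, cutoff),
                 oracle_ap(ids, relevant, cutoff), tolerance = 1e-12)
    expect_identical(precision_at_1(ids, relevant),
                     oracle_p1(ids, relevant))
    # with a single relevant document, AP = RR exactly
    one <- relevant[[1]]
    expect_identical(average_precision(ids, one), reciprocal_rank(ids, one))
  }
})

test_that("run evaluation averages per-topic metrics and checks qrels", {
  run <- structure(data.frame(
    topic_id = c("T1", "T1", "T2", "T2", "T2", "T3"),
    doc_id = c("A", "B", "C", "D", "E", "F"),
    rank = c(0L, 1L, 0L, 1L, 2L, 0L),
    score = c(2, 1, 3, 2, 1, 1), tag = "t",
    stringsAsFactors = FALSE), class = c("trec_run", "data.frame"))
  qrels <- structure(list(T1 = "B", T2 = "C", T3 = character(0)),
                     class = "qrels")
  rep <- evaluate_run(run, qrels)
  expect_equal(rep$p0, mean(c(0.5, 1)))
  expect_equal(rep$p_at_1, 0.5)
  expect_identical(rep$n_topics, 2L)
  expect_identical(rep$n_excluded, 1L)  # T3: empty qrels, counted
  # single relevant doc at position 1: all metrics are 1
  r1 <- evaluate_run(run[run$topic_id == "T2", ],
                     structure(list(T2 = "C"), class = "qrels"))
  expect_equal(c(r1$p0, r1$map, r1$p_at_1), c(1, 1, 1))
  expect_error(evaluate_run(run, structure(list(T1 = "B"), class = "qrels")),
               "absent from qrels")
})

test_that("on a known-item benchmark MAP equals P0 exactly", {
  corpus <- generate_corpus(synth_config(n_patents = 60, seed = 19))
  idx <- build_index(corpus, index_config(include_description = FALSE))
  ki <- build_known_item_benchmark(corpus, 30, seed = 19)
  run <- run_search(idx, corpus, ki$topics, ranking_params("BM25"))
  rep <- evaluate_run(run, ki$qrels)
  expect_identical(rep$map, rep$p0)
  expect_identical(rep$per_topic$ap, rep$per_topic$rr)
})

test_that("sign-flip test reproduces exact enumeration", {
  # all differences zero: every assignment reaches the observed mean
  expect_equal(paired_randomization_test(rep(1, 6), rep(1, 6)), 1)
  # n = 5 equal positive deltas: only the two all-same assignments
  expect_equal(paired_randomization_test(rep(0.3, 5), rep(0.1, 5)),
               2 / 32)
  # n = 1: both sign patterns reach |observed|
  expect_equal(paired_randomization_test(2, 1), 1)
  expect_error(paired_randomization_test(1:3, 1:2), "same length")
  # random small cases against explicit sign-matrix enumeration
  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:12, 1)
    a <- round(runif(n), 3)
    b <- round(runif(n), 3)
    expect_equal(paired_randomization_test(a, b),
                 oracle_signflip_p(a - b), tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p-values agree with exact ones within 3 SE", {
  set.seed(55)
  for (i in 1:5) {
    n <- sample(8:12, 1)
    a <- runif(n); b <- runif(n)
    exact <- paired_randomization_test(a, b)
    # force the Monte-Carlo path by padding with zero-difference pairs
    # (zeros leave the mean difference distribution unchanged only if
    # flipped zeros are no-ops, which they are)
    a2 <- c(a, rep(0.5, 15)); b2 <- c(b, rep(0.5, 15))
    mc <- paired_randomization_test(a2, b2, n_permutations = 4000L,
                                    seed = i)
    se <- sqrt(exact * (1 - exact) / 4000)
    expect_lt(abs(mc - exact), 3 * se + 1e-3)
  }
})
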