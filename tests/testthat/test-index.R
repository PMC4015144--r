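test_that("tokenizer lowercases and splits on non-alphanumerics", {
  expect_identical(tokenize("Pyrimidine-2,4-diamine derivatives!"),
                   c("pyrimidine", "2", "4", "diamine", "derivatives"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize("TNF-α"), c("tnf", "α"))
})

test_that("porter stemmer reproduces the published example vectors", {
  vectors <- c(
    caresses = "caress", ponies = "poni", ties = "ti", caress = "caress",
    cats = "cat", feed = "feed", agreed = "agre", plastered = "plaster",
    bled = "bled", motoring = "motor", sing = "sing",
    conflated = "conflat", troubled = "troubl", sized = "size",
    hopping = "hop", tanned = "tan", falling = "fall", hissing = "hiss",
    failing = "fail", filing = "file", happy = "happi", sky = "sky",
    relational = "relat", rational = "ration", valenci = "valenc",
    digitizer = "digit", radicalli = "radic", differentli = "differ",
    vileli = "vile", analogousli = "analog", vietnamization = "vietnam",
    predication = "predic", operator = "oper", feudalism = "feudal",
    decisiveness = "decis", hopefulness = "hope", callousness = "callous",
    formaliti = "formal", sensitiviti = "sensit", sensibiliti = "sensibl",
    triplicate = "triplic", formative = "form", formalize = "formal",
    electriciti = "electr", electrical = "electr", hopeful = "hope",
    goodness = "good", revival = "reviv", allowance = "allow",
    inference = "infer", airliner = "airlin", gyroscopic = "gyroscop",
    adjustable = "adjust", defensible = "defens", irritant = "irrit",
    replacement = "replac", adjustment = "adjust", dependent = "depend",
    adoption = "adopt", communism = "commun", activate = "activ",
    effective = "effect", probate = "probat", rate = "rate",
    cease = "ceas", controlling = "control", rolling = "roll"
  )
  got <- vapply(names(vectors), porter_stem, "")
  expect_identical(got, vectors)
})

test_that("collection statistics match brute-force counts", {
  corpus <- patent_corpus(list(
    patent_document("D1", title = "gene therapy gene"),
    patent_document("D2", title = "therapy")
  ))
  idx <- build_index(corpus, index_config())
  expect_identical(idx$stats$N, 2L)
  expect_identical(unname(idx$doc_lengths[c("D1", "D2")]), c(3L, 1L))
  expect_equal(idx$stats$avdl, 2)
  expect_equal(term_stats(idx, "gene"), c(df = 1, cf = 2))
  expect_equal(term_stats(idx, porter_stem("therapy")), c(df = 2, cf = 2))
  expect_equal(term_stats(idx, "unseen"), c(df = 0, cf = 0))
  # purity
  expect_identical(term_stats(idx, "gene"), term_stats(idx, "gene"))
})

test_that("per-term posting totals equal cf and list lengths equal df", {
  corpus <- generate_corpus(synth_config(n_patents = 40, seed = 11))
  idx <- build_index(corpus, index_config())
  # recount from the documents themselves
  bags <- lapply(corpus, function(d) {
    patret:::process_text_tokens(extract_field_text(d, "TACD"))
  })
  for (term in sample(ls(idx$postings), 25)) {
    p <- get(term, envir = idx$postings)
    expect_false(is.unsorted(p$doc_ids))
    if (!startsWith(term, "IPC_")) {
      truth <- vapply(bags, function(b) sum(b == term), 0L)
      expect_identical(sum(p$tf), sum(truth), info = term)
      expect_identical(length(p$doc_ids), sum(truth > 0L), info = term)
    }
  }
  expect_equal(
    sum(idx$doc_lengths),
    sum(vapply(ls(idx$postings),
               function(t) sum(get(t, envir = idx$postings)$tf), 0L))
  )
})

test_that("field selection: a TAC index ignores description content", {
  corpus <- tiny_corpus()
  stripped <- patent_corpus(lapply(corpus, function(d) {
    d$description <- ""
    d
  }))
  cfg <- index_config(include_description = FALSE)
  a <- build_index(corpus, cfg)
  b <- build_index(stripped, cfg)
  expect_setequal(ls(a$postings), ls(b$postings))
  expect_identical(a$doc_lengths, b$doc_lengths)
  # and description stems are absent from the TAC postings
  expect_equal(unname(term_stats(a, porter_stem("background"))["df"]), 0)
})

test_that("metadata indexing obeys the configured scope", {
  corpus <- tiny_corpus()
  term <- terminology("MESH", concept_id = "D009369", term = "cancer")
  annotated <- annotate_corpus(corpus, term, "TAC")
  idx <- build_index(annotated, index_config(metadata_mode = "TAC"))
  expect_gt(term_stats(idx, "CONCEPT_MESH_D009369")[["df"]], 0)
  # NONE mode: no concept pseudo-tokens at all
  idx0 <- build_index(annotated, index_config(metadata_mode = "NONE"))
  expect_length(grep("^CONCEPT_", ls(idx0$postings)), 0L)
  # requesting a scope the corpus lacks is a configuration error
  expect_error(build_index(annotated, index_config(metadata_mode = "TACD")),
               "scope")
  expect_error(build_index(corpus, index_config(metadata_mode = "TAC")),
               "metadata")
})

test_that("index persists to flat files and reloads identically", {
  corpus <- generate_corpus(synth_config(n_patents = 20, seed = 3))
  idx <- build_index(corpus, index_config(include_description = FALSE))
  dir <- withr::local_tempdir()
  write_index(idx, dir)
  back <- read_index(dir)
  expect_equal(back$stats$N, idx$stats$N)
  expect_equal(back$stats$avdl, idx$stats$avdl)
  expect_identical(back$doc_lengths[names(idx$doc_lengths)],
                   idx$doc_lengths)
  expect_setequal(ls(back$postings), ls(idx$postings))
  for (term in sample(ls(idx$postings), 20)) {
    expect_identical(get(term, envir = back$postings),
                     get(term, envir = idx$postings), info = term)
  }
  expect_identical(back$config$metadata_mode, idx$config$metadata_mode)
})
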