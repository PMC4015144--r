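#' Indexing configuration
#'
#' Controls which document content enters the inverted index: whether the
#' description field is included (TACD vs TAC text), whether concept
#' metadata produced by [annotate_corpus()] is indexed, and the stopword
#' filter. Concept and IPC pseudo-tokens (`CONCEPT_*`, `IPC_*`) are never
#' stemmed: they are identifiers, not words.
#'
#' @param include_description Logical; if `TRUE` the index covers
#'   title+abstract+claims+description (TACD), else TAC only.
#' @param metadata_mode `"NONE"`, `"TAC"` or `"TACD"`; when not `"NONE"`,
#'   every document must carry metadata annotated at exactly that scope.
#' @param stopword_list Character vector of lowercase words removed before
#'   stemming; defaults to [default_stopwords()].
#' @param min_token_length Minimum token length in characters (default 1).
#' @return An object of class `index_config`.
#' @export
index_config <- function(include_description = TRUE,
                         metadata_mode = c("NONE", "TAC", "TACD"),
                         stopword_list = default_stopwords(),
                         min_token_length = 1L) {
  metadata_mode <- match.arg(metadata_mode)
  structure(list(
    include_description = isTRUE(include_description),
    metadata_mode = metadata_mode,
    stopword_list = as.character(stopword_list),
    min_token_length = as.integer(min_token_length)
  ), class = "index_config")
}

# all indexed tokens of one document under a config (a bag)
document_index_tokens <- function(doc, config) {
  scope <- if (config$include_description) "TACD" else "TAC"
  toks <- process_text_tokens(extract_field_text(doc, scope),
                              stopwords = config$stopword_list,
                              min_token_length = config$min_token_length)
  if (config$metadata_mode != "NONE") {
    meta <- doc$metadata
    if (is.null(meta) || !identical(attr(meta, "scope"), config$metadata_mode)) {
      stop("document ", doc$patent_id, " lacks metadata with scope ",
           config$metadata_mode, "; run annotate_corpus() first")
    }
    if (nrow(meta)) {
      toks <- c(toks, paste0("CONCEPT_", meta$source, "_", meta$concept_id))
    }
  }
  if (length(doc$ipc_codes)) {
    ipc <- unique(unlist(lapply(doc$ipc_codes, normalize_ipc_code),
                         use.names = FALSE))
    toks <- c(toks, ipc)
  }
  toks
}

#' Build an inverted index over a patent corpus
#'
#' Per document, the indexed bag of tokens is the stemmed, stopword-
#' filtered text of the selected fields, plus unstemmed `CONCEPT_*`
#' pseudo-tokens when metadata is indexed and `IPC_*` pseudo-tokens for
#' the document's classification codes. Collection statistics (N, average
#' document length, per-term document and collection frequencies) are
#' computed over exactly these tokens.
#'
#' @param corpus A non-empty `patent_corpus`.
#' @param config An [index_config()].
#' @return An object of class `inverted_index` with components `postings`
#'   (environment mapping term to a list with `doc_ids` sorted ascending
#'   and parallel integer `tf`), `doc_lengths` (named numeric), `stats`
#'   (list with `N`, `avdl`) and `config`.
#' @export
build_index <- function(corpus, config = index_config()) {
  if (!length(corpus)) stop("cannot index an empty corpus")
  ids <- corpus_ids(corpus)
  per_doc <- lapply(corpus, document_index_tokens, config = config)
  doc_lengths <- stats::setNames(vapply(per_doc, length, 0L), ids)

  term_vec <- character(0); doc_vec <- character(0); tf_vec <- integer(0)
  acc_t <- vector("list", length(ids)); acc_d <- acc_t; acc_f <- acc_t
  for (i in seq_along(ids)) {
    toks <- per_doc[[i]]
    if (!length(toks)) next
    tab <- table(toks)
    acc_t[[i]] <- names(tab)
    acc_d[[i]] <- rep(ids[[i]], length(tab))
    acc_f[[i]] <- as.integer(tab)
  }
  term_vec <- unlist(acc_t, use.names = FALSE)
  doc_vec <- unlist(acc_d, use.names = FALSE)
  tf_vec <- unlist(acc_f, use.names = FALSE)

  postings <- new.env(parent = emptyenv(), hash = TRUE)
  if (length(term_vec)) {
    idx_by_term <- split(seq_along(term_vec), term_vec)
    for (term in names(idx_by_term)) {
      sel <- idx_by_term[[term]]
      ord <- order(doc_vec[sel], method = "radix")
      assign(term,
             list(doc_ids = doc_vec[sel][ord], tf = tf_vec[sel][ord]),
             envir = postings)
    }
  }
  structure(list(
    postings = postings,
    doc_lengths = doc_lengths,
    stats = list(N = length(ids), avdl = mean(doc_lengths)),
    config = config
  ), class = "inverted_index")
}

#' @export
print.inverted_index <- function(x, ...) {
  cat("<inverted_index>", x$stats$N, "docs,",
      length(ls(x$postings)), "terms, avdl",
      round(x$stats$avdl, 1), "\n")
  invisible(x)
}

#' Document frequency and collection frequency of a term
#'
#' @param index An `inverted_index`.
#' @param term A processed token (stem or pseudo-token).
#' @return Named numeric vector `c(df = , cf = )`; `c(0, 0)` for terms
#'   absent from the index.
#' @export
term_stats <- function(index, term) {
  p <- get0(term, envir = index$postings, inherits = FALSE)
  if (is.null(p)) return(c(df = 0, cf = 0))
  c(df = length(p$doc_ids), cf = sum(p$tf))
}

index_terms <- function(index) ls(index$postings)

#' Persist an inverted index as flat text files
#'
#' Writes a small versioned directory layout: `meta.tsv` (format version,
#' N, avdl, config), `docs.tsv` (doc id, length) and `postings.tsv`
#' (term, then `doc:tf` pairs). Reading it back reproduces the index
#' exactly.
#'
#' @param index An `inverted_index`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, `dir`.
#' @export
write_index <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- index$config
  meta <- c(
    "patret-index\t1",
    paste0("N\t", index$stats$N),
    paste0("avdl\t", format(index$stats$avdl, digits = 17)),
    paste0("include_description\t", cfg$include_description),
    paste0("metadata_mode\t", cfg$metadata_mode),
    paste0("min_token_length\t", cfg$min_token_length),
    paste0("stopwords\t", paste(cfg$stopword_list, collapse = " "))
  )
  writeLines(meta, file.path(dir, "meta.tsv"), useBytes = TRUE)
  writeLines(paste(names(index$doc_lengths), index$doc_lengths, sep = "\t"),
             file.path(dir, "docs.tsv"), useBytes = TRUE)
  terms <- sort(index_terms(index), method = "radix")
  lines <- vapply(terms, function(term) {
    p <- get(term, envir = index$postings)
    paste(term, paste(p$doc_ids, p$tf, sep = ":", collapse = " "), sep = "\t")
  }, "")
  writeLines(lines, file.path(dir, "postings.tsv"), useBytes = TRUE)
  invisible(dir)
}

#' Load an inverted index written by [write_index()]
#'
#' @param dir Directory produced by [write_index()].
#' @return An `inverted_index`.
#' @export
read_index <- function(dir) {
  meta <- strsplit(readLines(file.path(dir, "meta.tsv")), "\t", fixed = TRUE)
  kv <- stats::setNames(vapply(meta, function(x) if (length(x) > 1L) x[[2L]] else "", ""),
                        vapply(meta, `[[`, "", 1L))
  if (!identical(names(kv)[[1L]], "patret-index")) {
    stop("not a patret index directory: ", dir)
  }
  docs <- strsplit(readLines(file.path(dir, "docs.tsv")), "\t", fixed = TRUE)
  doc_lengths <- stats::setNames(
    as.integer(vapply(docs, `[[`, "", 2L)),
    vapply(docs, `[[`, "", 1L)
  )
  postings <- new.env(parent = emptyenv(), hash = TRUE)
  for (line in readLines(file.path(dir, "postings.tsv"))) {
    parts <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    pairs <- strsplit(strsplit(parts[[2L]], " ", fixed = TRUE)[[1L]], ":", fixed = TRUE)
    assign(parts[[1L]], list(
      doc_ids = vapply(pairs, `[[`, "", 1L),
      tf = as.integer(vapply(pairs, `[[`, "", 2L))
    ), envir = postings)
  }
  cfg <- index_config(
    include_description = as.logical(kv[["include_description"]]),
    metadata_mode = kv[["metadata_mode"]],
    stopword_list = strsplit(kv[["stopwords"]], " ", fixed = TRUE)[[1L]],
    min_token_length = as.integer(kv[["min_token_length"]])
  )
  structure(list(
    postings = postings,
    doc_lengths = doc_lengths,
    stats = list(N = as.integer(kv[["N"]]), avdl = as.numeric(kv[["avdl"]])),
    config = cfg
  ), class = "inverted_index")
}
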