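#' Construct a patent document
#'
#' A patent document holds the four textual fields (title, abstract, claims,
#' description), its IPC classification codes, its outbound prior-art
#' citations and, after normalization, concept metadata.
#'
#' @param patent_id Character scalar. Normalized to uppercase with all
#'   whitespace stripped, so that citation matching is exact.
#' @param title,abstract,claims,description Character scalars; may be empty
#'   but never `NA`.
#' @param ipc_codes Character vector of raw IPC code strings (e.g.
#'   `"C07D 239/47"`).
#' @param cited_ids Character vector of patent ids cited as prior art.
#'   Citations may reference ids absent from the corpus; they are kept.
#' @param metadata A data.frame with columns `source`, `concept_id`, or
#'   `NULL`. Filled by [annotate_corpus()]; carries a `scope` attribute
#'   (`"TAC"` or `"TACD"`). Stored as a bag: duplicates are meaningful and
#'   become term frequencies when indexed.
#' @return An object of class `patent_document`.
#' @seealso [patent_corpus()], [read_patent_corpus()]
#' @export
patent_document <- function(patent_id, title = "", abstract = "",
                            claims = "", description = "",
                            ipc_codes = character(), cited_ids = character(),
                            metadata = NULL) {
  patent_id <- normalize_patent_id(patent_id)
  if (!nzchar(patent_id)) stop("patent_id must be non-empty")
  for (f in list(title, abstract, claims, description)) {
    if (length(f) != 1L || is.na(f)) stop("text fields must be length-1, non-NA")
  }
  structure(list(
    patent_id   = patent_id,
    title       = as.character(title),
    abstract    = as.character(abstract),
    claims      = as.character(claims),
    description = as.character(description),
    ipc_codes   = as.character(ipc_codes),
    cited_ids   = vapply(as.character(cited_ids), normalize_patent_id, ""),
    metadata    = metadata
  ), class = "patent_document")
}

normalize_patent_id <- function(id) {
  toupper(gsub("[[:space:]]+", "", as.character(id)))
}

#' @export
print.patent_document <- function(x, ...) {
  cat("<patent_document>", x$patent_id, "\n")
  cat("  title:", substr(x$title, 1, 60), "\n")
  cat("  ipc:", paste(x$ipc_codes, collapse = ", "), "\n")
  cat("  cites:", length(x$cited_ids), " concepts:",
      if (is.null(x$metadata)) 0L else nrow(x$metadata), "\n")
  invisible(x)
}

#' Construct a patent corpus
#'
#' An ordered collection of [patent_document()] objects with lookup by id.
#' Iteration order is insertion order and is preserved by I/O.
#'
#' @param docs List of `patent_document` objects.
#' @return An object of class `patent_corpus`; essentially a named list of
#'   documents (names are patent ids, in insertion order).
#' @export
patent_corpus <- function(docs = list()) {
  ids <- vapply(docs, function(d) d$patent_id, "")
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate patent id: ", dup[[1L]])
  structure(stats::setNames(docs, ids), class = "patent_corpus")
}

#' @export
print.patent_corpus <- function(x, ...) {
  cat("<patent_corpus> of", length(x), "patents\n")
  invisible(x)
}

#' @export
`[.patent_corpus` <- function(x, i) {
  patent_corpus(unclass(x)[i])
}

corpus_ids <- function(corpus) names(corpus)

#' Extract the scoped text of a patent document
#'
#' Concatenates the document fields covered by a scope, in the fixed order
#' title, abstract, claims and (for `"TACD"`) description, separated by
#' single newlines. `"TAC"` is the title+abstract+claims view used for
#' queries and the description-free index; `"TACD"` adds the description.
#'
#' @param doc A `patent_document`.
#' @param scope `"TAC"` or `"TACD"`.
#' @return A character scalar.
#' @export
extract_field_text <- function(doc, scope = c("TAC", "TACD")) {
  scope <- match.arg(scope)
  fields <- c(doc$title, doc$abstract, doc$claims)
  if (scope == "TACD") fields <- c(fields, doc$description)
  paste(fields, collapse = "\n")
}

xml_child_text <- function(node, name) {
  child <- xml2::xml_find_first(node, name)
  if (inherits(child, "xml_missing")) "" else xml2::xml_text(child)
}

#' Read a patent corpus from its XML dialect
#'
#' The dialect has a `<patents>` root with one `<patent>` element per
#' document; element order inside `<patent>` is irrelevant. Missing optional
#' elements become empty values. Patent ids are uppercased and
#' whitespace-stripped on load.
#'
#' @param path Path to an XML file.
#' @return A `patent_corpus`.
#' @seealso [write_patent_corpus()] for the inverse; the two round-trip
#'   exactly, including metadata and citations.
#' @export
read_patent_corpus <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "/patents/patent")
  docs <- lapply(nodes, function(node) {
    id <- xml_child_text(node, "id")
    ipc <- xml2::xml_text(xml2::xml_find_all(node, "ipc/code"))
    cits <- xml2::xml_text(xml2::xml_find_all(node, "citations/patcit"))
    meta_node <- xml2::xml_find_first(node, "metadata")
    metadata <- NULL
    if (!inherits(meta_node, "xml_missing")) {
      concepts <- xml2::xml_find_all(meta_node, "concept")
      metadata <- data.frame(
        source     = xml2::xml_attr(concepts, "source"),
        concept_id = xml2::xml_text(concepts),
        stringsAsFactors = FALSE
      )
      attr(metadata, "scope") <- xml2::xml_attr(meta_node, "scope")
    }
    patent_document(
      patent_id   = id,
      title       = xml_child_text(node, "title"),
      abstract    = xml_child_text(node, "abstract"),
      claims      = xml_child_text(node, "claims"),
      description = xml_child_text(node, "description"),
      ipc_codes   = ipc,
      cited_ids   = cits,
      metadata    = metadata
    )
  })
  patent_corpus(docs)
}

#' Write a patent corpus to its XML dialect
#'
#' Emits UTF-8 XML with one `<patent>` element per document in corpus
#' order; element order within a patent is fixed, so two writes of the same
#' corpus are byte-identical.
#'
#' @param corpus A `patent_corpus`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_patent_corpus <- function(corpus, path) {
  root <- xml2::xml_new_root("patents")
  for (doc in corpus) {
    p <- xml2::xml_add_child(root, "patent")
    xml2::xml_add_child(p, "id", doc$patent_id)
    xml2::xml_add_child(p, "title", doc$title)
    xml2::xml_add_child(p, "abstract", doc$abstract)
    xml2::xml_add_child(p, "claims", doc$claims)
    xml2::xml_add_child(p, "description", doc$description)
    if (length(doc$ipc_codes)) {
      ipc <- xml2::xml_add_child(p, "ipc")
      for (code in doc$ipc_codes) xml2::xml_add_child(ipc, "code", code)
    }
    if (length(doc$cited_ids)) {
      cit <- xml2::xml_add_child(p, "citations")
      for (id in doc$cited_ids) xml2::xml_add_child(cit, "patcit", id)
    }
    if (!is.null(doc$metadata)) {
      meta <- xml2::xml_add_child(p, "metadata",
                                  scope = attr(doc$metadata, "scope"))
      if (nrow(doc$metadata)) {
        for (i in seq_len(nrow(doc$metadata))) {
          xml2::xml_add_child(meta, "concept", doc$metadata$concept_id[[i]],
                              source = doc$metadata$source[[i]])
        }
      }
    }
  }
  xml2::write_xml(root, path, encoding = "UTF-8")
  invisible(path)
}

#' Construct a terminology
#'
#' A terminology maps synonym terms (lowercased, whitespace-normalized) to
#' concepts. Within one terminology a term maps to exactly one concept; a
#' concept may have many synonym terms. Stand-in for resources such as
#' MeSH, the Gene Ontology or Caloha.
#'
#' @param name Terminology name (becomes the annotation `source`).
#' @param concept_id,source,term Parallel character vectors, one row per
#'   synonym entry. `source` defaults to `name`.
#' @return Object of class `terminology`: a list with `name` and `entries`
#'   (a data.frame keyed by normalized term).
#' @export
terminology <- function(name, concept_id = character(),
                        source = rep(name, length(concept_id)),
                        term = character()) {
  term_norm <- normalize_term(term)
  keep <- !duplicated(paste(term_norm, source, concept_id, sep = "\r"))
  term_norm <- term_norm[keep]
  source <- source[keep]
  concept_id <- concept_id[keep]
  if (any(!nzchar(term_norm))) stop("terminology terms must be non-empty")
  if (anyDuplicated(term_norm)) {
    bad <- term_norm[duplicated(term_norm)][[1L]]
    stop("term maps to more than one concept: '", bad, "'")
  }
  entries <- data.frame(term = term_norm, source = as.character(source),
                        concept_id = as.character(concept_id),
                        stringsAsFactors = FALSE)
  structure(list(name = name, entries = entries), class = "terminology")
}

normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' @export
print.terminology <- function(x, ...) {
  cat("<terminology>", x$name, "-", nrow(x$entries), "terms,",
      length(unique(x$entries$concept_id)), "concepts\n")
  invisible(x)
}

#' Read a terminology from TSV
#'
#' Expects UTF-8 lines `concept_id<TAB>source<TAB>term` with no header.
#' Terms are lowercased and whitespace-normalized on load; duplicate
#' identical rows are collapsed, but a term mapped to two different
#' concepts is an error. An empty file yields an empty terminology.
#'
#' @param path Path to a TSV file.
#' @param name Terminology name; defaults to the file name without
#'   extension.
#' @return A `terminology`.
#' @export
read_terminology <- function(path, name = NULL) {
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(terminology(name))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) stop("malformed terminology line ", bad[[1L]], " in ", path)
  m <- do.call(rbind, parts)
  terminology(name, concept_id = m[, 1L], source = m[, 2L], term = m[, 3L])
}

#' Write a terminology to TSV
#'
#' @param term A `terminology`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_terminology <- function(term, path) {
  lines <- paste(term$entries$concept_id, term$entries$source,
                 term$entries$term, sep = "\t")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
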