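# Tiny corpora and oracles shared across test files. Everything is built
# in code; no stored fixtures.

tiny_corpus <- function() {
  patent_corpus(list(
    patent_document("EP0000001",
      title = "Kinase inhibitor compounds",
      abstract = "Pyrimidine derivatives inhibiting tyrosine kinase",
      claims = "A compound wherein the kinase is inhibited",
      description = "Long description of breast cancer therapy background",
      ipc_codes = c("C07D 239/47", "A61K 31/00"),
      cited_ids = character()),
    patent_document("EP0000002",
      title = "Antibody therapy",
      abstract = "Monoclonal antibody for cancer treatment",
      claims = "The antibody of claim one",
      description = "Details on antibody production",
      ipc_codes = "C07K 16/00",
      cited_ids = "EP0000001"),
    patent_document("EP0000003",
      title = "Kinase assay",
      abstract = "Assay for kinase activity",
      claims = "Measuring kinase activity in vitro",
      description = "",
      ipc_codes = character(),
      cited_ids = c("EP0000001", "EP9999999"))
  ))
}

# exhaustive-definition metric oracles, independent of the package's code
# paths: walk the list position by position
oracle_rr <- function(ids, relevant) {
  for (p in seq_along(ids)) if (ids[[p]] %in% relevant) return(1 / p)
  0
}

oracle_ap <- function(ids, relevant, cutoff = 1000L) {
  ids <- ids[seq_len(min(length(ids), cutoff))]
  hits <- 0
  total <- 0
  for (p in seq_along(ids)) {
    if (ids[[p]] %in% relevant) {
      hits <- hits + 1
      total <- total + hits / p
    }
  }
  total / length(relevant)
}

oracle_p1 <- function(ids, relevant) {
  as.numeric(length(ids) >= 1 && ids[[1]] %in% relevant)
}

# exact sign-flip p-value by explicit enumeration over sign matrices
oracle_signflip_p <- function(d) {
  n <- length(d)
  obs <- abs(mean(d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  means <- abs(signs %*% d / n)
  mean(means >= obs - 1e-12)
}
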