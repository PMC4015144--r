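#' Configuration of the synthetic patent corpus generator
#'
#' The generator emulates the statistical structure that patent retrieval
#' tuning experiments rely on: latent topical vocabulary clusters shared
#' between citing and cited patents, short content-bearing TAC fields and
#' a long description heavily diluted with a shared noise vocabulary, IPC
#' codes determined by topic, and an acyclic citation network with
#' topic-biased, preferentially attached citations (frequently cited
#' patents accumulate further citations).
#'
#' @param n_patents Number of patents (default 300, a desk-scale corpus).
#' @param n_topics Number of latent topical clusters (default 10).
#' @param vocab_size_topic Words per topic vocabulary (default 80).
#' @param vocab_size_noise Size of the shared noise vocabulary (default
#'   400).
#' @param field_lengths Named expected token counts for the four fields
#'   (defaults title 8, abstract 60, claims 120, description 600).
#' @param description_noise_frac Fraction of description tokens drawn from
#'   the noise vocabulary (default 0.8).
#' @param tac_noise_frac Fraction of title/abstract/claims tokens drawn
#'   from the noise vocabulary (default 0.1).
#' @param citation_rate Expected outbound citations per patent (default 3).
#' @param citation_topic_bias Probability that a citation targets an
#'   earlier patent of the same topic (default 0.9).
#' @param preferential_attachment Exponent (>= 0) on `1 + in-degree` when
#'   choosing citation targets (default 1.0).
#' @param ipc_per_patent IPC codes per patent, drawn from the topic's code
#'   pool (default 2).
#' @param seed Integer seed; the same config and seed give byte-identical
#'   corpora.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(n_patents = 300L, n_topics = 10L,
                         vocab_size_topic = 80L, vocab_size_noise = 400L,
                         field_lengths = c(title = 8, abstract = 60,
                                           claims = 120, description = 600),
                         description_noise_frac = 0.8,
                         tac_noise_frac = 0.1,
                         citation_rate = 3,
                         citation_topic_bias = 0.9,
                         preferential_attachment = 1.0,
                         ipc_per_patent = 2L,
                         seed = 42L) {
  cfg <- list(
    n_patents = as.integer(n_patents), n_topics = as.integer(n_topics),
    vocab_size_topic = as.integer(vocab_size_topic),
    vocab_size_noise = as.integer(vocab_size_noise),
    field_lengths = field_lengths,
    description_noise_frac = description_noise_frac,
    tac_noise_frac = tac_noise_frac,
    citation_rate = citation_rate,
    citation_topic_bias = citation_topic_bias,
    preferential_attachment = preferential_attachment,
    ipc_per_patent = as.integer(ipc_per_patent),
    seed = as.integer(seed)
  )
  with(cfg, {
    stopifnot(n_topics >= 1, vocab_size_topic >= 1, vocab_size_noise >= 1,
              all(field_lengths > 0),
              description_noise_frac >= 0, description_noise_frac <= 1,
              tac_noise_frac >= 0, tac_noise_frac <= 1,
              citation_rate >= 0, citation_topic_bias >= 0,
              citation_topic_bias <= 1, preferential_attachment >= 0,
              ipc_per_patent >= 0)
  })
  if (cfg$n_patents < 2L && cfg$citation_rate > 0) {
    stop("citation_rate > 0 requires at least 2 patents")
  }
  structure(cfg, class = "synth_config")
}

# pronounceable pseudo-words, distinct, drawn from the current RNG stream
synth_make_words <- function(n) {
  cons <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n",
            "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  words <- character(0)
  while (length(words) < n) {
    need <- n - length(words)
    syl <- matrix(paste0(sample(cons, 4L * need * 2L, replace = TRUE),
                         sample(vow, 4L * need * 2L, replace = TRUE)),
                  nrow = 4L)
    cand <- apply(syl, 2L, paste, collapse = "")
    words <- unique(c(words, cand))
  }
  words[seq_len(n)]
}

synth_topic_ipc_pool <- function(topic) {
  section <- LETTERS[((topic - 1L) %% 8L) + 1L]
  class4 <- paste0(section, sprintf("%02d", topic %% 100L),
                   LETTERS[(topic %% 26L) + 1L])
  vapply(1:3, function(j) {
    paste0(class4, " ", 100L + 37L * j, "/", sprintf("%02d", 2L * j))
  }, "")
}

synth_field <- function(topic_words, topic_prob, noise_words, noise_prob,
                        noise_frac, expected_len) {
  len <- max(2L, stats::rpois(1L, expected_len))
  from_noise <- stats::runif(len) < noise_frac
  out <- character(len)
  n_noise <- sum(from_noise)
  if (n_noise) {
    out[from_noise] <- sample(noise_words, n_noise, replace = TRUE,
                              prob = noise_prob)
  }
  if (len - n_noise) {
    out[!from_noise] <- sample(topic_words, len - n_noise, replace = TRUE,
                               prob = topic_prob)
  }
  paste(out, collapse = " ")
}

#' Generate a synthetic patent corpus
#'
#' Patents are assigned a latent topic; title, abstract and claims are
#' drawn mostly from the topic's vocabulary (Zipf-weighted), the
#' description is diluted with noise-vocabulary tokens at
#' `description_noise_frac`. Each patent cites only earlier patents
#' (acyclic by construction), with targets chosen by topic bias and
#' preferential attachment on the current in-degree. IPC codes come from
#' a deterministic per-topic pool.
#'
#' @param config A [synth_config()].
#' @return A `patent_corpus`; documents carry a `topic` attribute.
#' @export
generate_corpus <- function(config = synth_config()) {
  set.seed(config$seed)
  n <- config$n_patents
  K <- config$n_topics
  topic_vocab <- lapply(seq_len(K), function(k) {
    synth_make_words(config$vocab_size_topic)
  })
  noise_vocab <- synth_make_words(config$vocab_size_noise)
  zipf <- function(m) (1 / seq_len(m)) / sum(1 / seq_len(m))
  topic_prob <- zipf(config$vocab_size_topic)
  noise_prob <- zipf(config$vocab_size_noise)

  topics <- sample.int(K, n, replace = TRUE)
  ids <- sprintf("SP%06d", seq_len(n))
  fl <- config$field_lengths

  indeg <- stats::setNames(integer(n), ids)
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    tw <- topic_vocab[[topics[[i]]]]
    title <- synth_field(tw, topic_prob, noise_vocab, noise_prob,
                         config$tac_noise_frac, fl[["title"]])
    abstract <- synth_field(tw, topic_prob, noise_vocab, noise_prob,
                            config$tac_noise_frac, fl[["abstract"]])
    claims <- synth_field(tw, topic_prob, noise_vocab, noise_prob,
                          config$tac_noise_frac, fl[["claims"]])
    description <- synth_field(tw, topic_prob, noise_vocab, noise_prob,
                               config$description_noise_frac,
                               fl[["description"]])

    cited <- character(0)
    if (i > 1L && config$citation_rate > 0) {
      n_cit <- min(stats::rpois(1L, config$citation_rate), i - 1L)
      if (n_cit > 0L) {
        earlier <- seq_len(i - 1L)
        same_topic <- earlier[topics[earlier] == topics[[i]]]
        for (j in seq_len(n_cit)) {
          pool <- earlier
          if (length(same_topic) &&
              stats::runif(1L) < config$citation_topic_bias) {
            pool <- same_topic
          }
          w <- (1 + indeg[pool])^config$preferential_attachment
          pick <- if (length(pool) == 1L) pool else {
            pool[sample.int(length(pool), 1L, prob = w)]
          }
          cited <- c(cited, ids[[pick]])
        }
        cited <- unique(cited)
        indeg[cited] <- indeg[cited] + 1L
      }
    }

    pool <- synth_topic_ipc_pool(topics[[i]])
    ipc <- if (config$ipc_per_patent > 0L) {
      pool[sort(sample.int(length(pool),
                           min(config$ipc_per_patent, length(pool))))]
    } else character(0)

    doc <- patent_document(ids[[i]], title = title, abstract = abstract,
                           claims = claims, description = description,
                           ipc_codes = ipc, cited_ids = cited)
    attr(doc, "topic") <- topics[[i]]
    docs[[i]] <- doc
  }
  patent_corpus(docs)
}

#' Generate a toy terminology over a synthetic corpus
#'
#' Concepts are built over 1-3 token phrases sampled from the corpus' own
#' title/abstract/claims text, so every concept has at least one synonym
#' findable in some patent's TAC fields; additional synonyms are
#' generated pseudo-words (present in the dictionary but not necessarily
#' in the text, like rarely used entry terms of a real thesaurus).
#'
#' @param config The [synth_config()] used to generate `corpus` (its seed
#'   feeds a dedicated substream, so corpus and terminology are jointly
#'   reproducible).
#' @param corpus The corpus returned by [generate_corpus()].
#' @param n_concepts Number of concepts.
#' @param terms_per_concept Synonyms per concept (>= 1).
#' @param name Terminology name (default `"SYNTH"`).
#' @return A [terminology()].
#' @export
generate_terminology <- function(config, corpus, n_concepts = 20L,
                                 terms_per_concept = 2L, name = "SYNTH") {
  set.seed(config$seed + 1000003L)
  phrases <- character(0)
  for (doc in corpus) {
    toks <- tokenize(extract_field_text(doc, "TAC"))
    if (length(toks) < 3L) next
    starts <- sample.int(length(toks) - 2L, min(5L, length(toks) - 2L))
    for (s in starts) {
      len <- sample.int(3L, 1L)
      phrases <- c(phrases, paste(toks[s:(s + len - 1L)], collapse = " "))
    }
    if (length(unique(phrases)) >= 4L * n_concepts) break
  }
  phrases <- unique(phrases)
  if (length(phrases) < n_concepts) {
    stop("not enough distinct phrases in the corpus for ", n_concepts,
         " concepts")
  }
  chosen <- phrases[sample.int(length(phrases), n_concepts)]
  concept_id <- character(0); term <- character(0)
  extra <- synth_make_words(n_concepts * max(0L, terms_per_concept - 1L))
  e <- 0L
  for (i in seq_len(n_concepts)) {
    cid <- sprintf("C%05d", i)
    concept_id <- c(concept_id, cid)
    term <- c(term, chosen[[i]])
    for (j in seq_len(terms_per_concept - 1L)) {
      e <- e + 1L
      concept_id <- c(concept_id, cid)
      term <- c(term, paste0("syn", extra[[e]]))
    }
  }
  terminology(name, concept_id = concept_id, term = term)
}
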