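ranked_ids <- function(ranked) {
  if (is.data.frame(ranked)) ranked$doc_id else as.character(ranked)
}

#' Reciprocal rank
#'
#' `1 / r` where `r` is the 1-based position of the first relevant
#' document in the ranked list; 0 when no relevant document is
#' retrieved. The mean of this over topics is the P0 / mean reciprocal
#' rank used for tuning: it measures the precision of the first useful
#' result.
#'
#' @param ranked A `ranked_results`, run slice, or character vector of
#'   doc ids in rank order.
#' @param relevant Character vector of relevant doc ids.
#' @return A number in `[0, 1]`.
#' @export
reciprocal_rank <- function(ranked, relevant) {
  ids <- ranked_ids(ranked)
  pos <- which(ids %in% relevant)
  if (!length(pos)) return(0)
  1 / pos[[1L]]
}

#' Non-interpolated average precision
#'
#' `(1/R) * sum over relevant docs retrieved at positions p <= cutoff of
#' precision@p`, with `R` the total number of relevant documents;
#' relevant documents not retrieved within the cutoff contribute 0.
#'
#' @inheritParams reciprocal_rank
#' @param relevant Non-empty character vector of relevant doc ids.
#' @param cutoff Evaluation depth (default 1000).
#' @return A number in `[0, 1]`.
#' @export
average_precision <- function(ranked, relevant, cutoff = 1000L) {
  if (!length(relevant)) {
    stop("average precision is undefined for an empty relevant set")
  }
  ids <- utils::head(ranked_ids(ranked), cutoff)
  hits <- which(ids %in% relevant)
  if (!length(hits)) return(0)
  sum(seq_along(hits) / hits) / length(relevant)
}

#' Precision at rank 1
#'
#' @inheritParams reciprocal_rank
#' @return 1 if the top-ranked document is relevant, else 0.
#' @export
precision_at_1 <- function(ranked, relevant) {
  ids <- ranked_ids(ranked)
  as.numeric(length(ids) >= 1L && ids[[1L]] %in% relevant)
}

#' Evaluate a run against qrels
#'
#' Computes per-topic reciprocal rank, average precision and P@1 for
#' every topic in the run, and their arithmetic means: P0 (mean
#' reciprocal rank), MAP and mean P@1. Topics whose qrels entry is empty
#' are excluded from the means (average precision is undefined there)
#' but counted. A run topic with no qrels entry at all is an error.
#'
#' @param run A `trec_run` data.frame.
#' @param qrels A qrels object.
#' @param cutoff Evaluation depth for average precision (default 1000).
#' @return Object of class `eval_report`: list with `per_topic`
#'   (data.frame of topic_id, rr, ap, p1), `p0`, `map`, `p_at_1`,
#'   `n_topics`, `n_excluded` and `cutoff`.
#' @export
evaluate_run <- function(run, qrels, cutoff = 1000L) {
  tids <- unique(run$topic_id)
  missing <- setdiff(tids, names(qrels))
  if (length(missing)) {
    stop("run topic absent from qrels: ", missing[[1L]])
  }
  per <- lapply(tids, function(tid) {
    relevant <- qrels[[tid]]
    if (!length(relevant)) return(NULL)
    slice <- run[run$topic_id == tid, , drop = FALSE]
    slice <- slice[order(slice$rank), , drop = FALSE]
    data.frame(topic_id = tid,
               rr = reciprocal_rank(slice, relevant),
               ap = average_precision(slice, relevant, cutoff),
               p1 = precision_at_1(slice, relevant),
               stringsAsFactors = FALSE)
  })
  n_excluded <- sum(vapply(per, is.null, TRUE))
  per <- do.call(rbind, per)
  if (is.null(per)) {
    stop("no topic with non-empty qrels to evaluate")
  }
  structure(list(
    per_topic = per,
    p0 = mean(per$rr),
    map = mean(per$ap),
    p_at_1 = mean(per$p1),
    n_topics = nrow(per),
    n_excluded = n_excluded,
    cutoff = cutoff
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> %d topics (cutoff %d)%s\n", x$n_topics,
              x$cutoff,
              if (x$n_excluded) {
                sprintf(", %d excluded (empty qrels)", x$n_excluded)
              } else ""))
  cat(sprintf("  P0 (MRR): %.4f   MAP: %.4f   P@1: %.4f\n",
              x$p0, x$map, x$p_at_1))
  invisible(x)
}

#' Paired sign-flip randomization test
#'
#' Two-sided test of the mean per-topic difference between two systems.
#' For `n <= 20` topics all `2^n` sign assignments are enumerated and
#' the p-value is exact; for larger `n`, `n_permutations` random sign
#' vectors are drawn (seeded) and the observed assignment is always
#' counted, so the p-value is at least `1 / (n_permutations + 1)`.
#'
#' @param per_topic_a,per_topic_b Numeric vectors of a per-topic metric,
#'   aligned by topic, same length.
#' @param n_permutations Monte-Carlo sample size (default 10000).
#' @param seed Integer seed for the Monte-Carlo mode.
#' @return The two-sided p-value.
#' @export
paired_randomization_test <- function(per_topic_a, per_topic_b,
                                      n_permutations = 10000L, seed = 1L) {
  if (length(per_topic_a) != length(per_topic_b)) {
    stop("per-topic vectors must have the same length")
  }
  d <- per_topic_a - per_topic_b
  n <- length(d)
  if (n < 1L) stop("need at least one paired observation")
  obs <- abs(mean(d))
  eps <- 1e-12
  if (n <= 20L) {
    sums <- 0
    for (di in d) sums <- c(sums + di, sums - di)
    return(mean(abs(sums / n) >= obs - eps))
  }
  set.seed(seed)
  hits <- 1L
  for (i in seq_len(n_permutations)) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    if (abs(mean(signs * d)) >= obs - eps) hits <- hits + 1L
  }
  hits / (n_permutations + 1)
}
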