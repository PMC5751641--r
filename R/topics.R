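# Word topic distributions by latent Dirichlet allocation, and the
# windowed topic-product sentence feature.
#
# The topic block is a fixed (non-trainable) auxiliary feature: each word
# carries p(topic | word), and a candidate's sentence-topic feature is the
# renormalized product of the distributions of the words in its context
# window, computed in log space for numerical stability.

#' Fit per-word topic distributions
#'
#' Runs a seeded collapsed Gibbs sampler for latent Dirichlet allocation
#' over the training sentences (each sentence is one pseudo-document of
#' normalized surface forms) and returns, for every word, the posterior
#' topic distribution p(topic | word) estimated from the final topic
#' assignment counts with additive smoothing. Out-of-vocabulary queries
#' fall back to the uniform distribution.
#'
#' @param sentences Training sentences from [attach_parse()].
#' @param d_top Number of topics (>= 2).
#' @param seed RNG seed; fits with the same seed are identical.
#' @param iterations Gibbs sweeps (default 100).
#' @param alpha,beta Dirichlet hyperparameters for document-topic and
#'   topic-word distributions.
#' @return A `topic_table` with a `dist` matrix (vocabulary x `d_top`).
#' @export
fit_topics <- function(sentences, d_top, seed = 1L, iterations = 100L,
                       alpha = 0.1, beta = 0.01) {
  if (d_top < 2) stop("d_top must be at least 2")
  if (!length(sentences)) stop("cannot fit topics on an empty corpus")
  docs <- lapply(sentences, function(s) norm_word(s$tokens$surface))
  vocab <- sort(unique(unlist(docs)))
  wid <- setNames(seq_along(vocab), vocab)

  w <- unlist(lapply(docs, function(d) unname(wid[d])))
  d <- rep(seq_along(docs), lengths(docs))
  N <- length(w); V <- length(vocab); D <- length(docs); K <- as.integer(d_top)

  with_seed(seed, {
    z <- sample.int(K, N, replace = TRUE)
    cwt <- matrix(0L, V, K); cdt <- matrix(0L, D, K); ct <- integer(K)
    for (i in seq_len(N)) {
      cwt[w[i], z[i]] <- cwt[w[i], z[i]] + 1L
      cdt[d[i], z[i]] <- cdt[d[i], z[i]] + 1L
      ct[z[i]] <- ct[z[i]] + 1L
    }
    for (it in seq_len(iterations)) {
      for (i in seq_len(N)) {
        k <- z[i]
        cwt[w[i], k] <- cwt[w[i], k] - 1L
        cdt[d[i], k] <- cdt[d[i], k] - 1L
        ct[k] <- ct[k] - 1L
        p <- (cwt[w[i], ] + beta) / (ct + V * beta) * (cdt[d[i], ] + alpha)
        k <- sample.int(K, 1L, prob = p)
        z[i] <- k
        cwt[w[i], k] <- cwt[w[i], k] + 1L
        cdt[d[i], k] <- cdt[d[i], k] + 1L
        ct[k] <- ct[k] + 1L
      }
    }
    dist <- (cwt + beta) / rowSums(cwt + beta)
    rownames(dist) <- vocab
    structure(list(dist = dist, d_top = K), class = "topic_table")
  })
}

#' @export
print.topic_table <- function(x, ...) {
  cat("<topic_table> ", nrow(x$dist), " words x ", x$d_top, " topics\n",
      sep = "")
  invisible(x)
}

# p(topic | word) rows for a word vector, uniform for OOV.
topic_rows <- function(topic_table, words) {
  words <- norm_word(words)
  idx <- match(words, rownames(topic_table$dist))
  out <- matrix(1 / topic_table$d_top, length(words), topic_table$d_top)
  hit <- !is.na(idx)
  out[hit, ] <- topic_table$dist[idx[hit], , drop = FALSE]
  out
}

#' Windowed sentence-topic feature
#'
#' Multiplies the topic distributions of the words in a context window
#' elementwise and renormalizes the product to sum to one. The product is
#' taken in log space so long windows cannot underflow.
#'
#' @param words Character vector of window words (>= 1).
#' @param topic_table A [fit_topics()] result.
#' @return A probability vector of length `d_top`.
#' @export
sentence_topic <- function(words, topic_table) {
  if (!length(words)) stop("sentence_topic needs at least one word")
  lp <- colSums(log(topic_rows(topic_table, words)))
  lp <- lp - max(lp)
  p <- exp(lp)
  p / sum(p)
}
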