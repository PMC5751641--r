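# Shortest paths on the (undirected) dependency tree of a sentence.

adjacency_list <- function(tokens) {
  n <- nrow(tokens)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    h <- tokens$head[i]
    if (h > 0L) {
      adj[[i]] <- c(adj[[i]], h)
      adj[[h]] <- c(adj[[h]], i)
    }
  }
  adj
}

# Breadth-first search from `from`; returns list(dist=, parent=).
bfs_tree <- function(adj, from) {
  n <- length(adj)
  dist <- rep(NA_integer_, n); parent <- rep(NA_integer_, n)
  dist[from] <- 0L
  queue <- from
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L; parent[w] <- v
        queue <- c(queue, w)
      }
    }
  }
  list(dist = dist, parent = parent)
}

#' Dependency-tree distance between two tokens
#'
#' Length of the shortest path between two tokens in the undirected
#' dependency tree, clipped to `max_distance`; a pair with no connecting
#' path (or `clip = FALSE` for the raw value) gets the dedicated
#' unreachable bucket `max_distance + 1`.
#'
#' @param sentence A `sentence`.
#' @param a,b 1-based token indices.
#' @param max_distance Clipping bound (default 10).
#' @param clip If `FALSE`, return the raw unclipped distance (`NA` when
#'   unreachable) instead of the bucket value.
#' @return Integer distance bucket (or raw distance).
#' @export
dependency_distance <- function(sentence, a, b, max_distance = 10L,
                                clip = TRUE) {
  tok <- sentence$tokens
  n <- nrow(tok)
  if (a < 1 || a > n || b < 1 || b > n)
    stop("token index outside sentence (", a, ", ", b, " vs n=", n, ")")
  if (a == b) return(0L)
  d <- bfs_tree(adjacency_list(tok), a)$dist[b]
  if (!clip) return(d)
  if (is.na(d)) max_distance + 1L else min(d, max_distance)
}

#' Dependency path between two tokens
#'
#' The token-index sequence of the shortest path from `a` to `b` in the
#' undirected dependency tree, endpoints included. When the two tokens sit
#' in distinct parse components the linear token sequence between them is
#' returned instead, flagged by the `"fallback"` attribute.
#'
#' @inheritParams dependency_distance
#' @return Integer vector of token indices from `a` to `b`.
#' @export
dependency_path <- function(sentence, a, b) {
  tok <- sentence$tokens
  n <- nrow(tok)
  if (a < 1 || a > n || b < 1 || b > n)
    stop("token index outside sentence")
  if (a == b) return(a)
  res <- bfs_tree(adjacency_list(tok), a)
  if (is.na(res$dist[b])) {
    path <- seq(min(a, b), max(a, b))
    if (a > b) path <- rev(path)
    attr(path, "fallback") <- TRUE
    return(path)
  }
  path <- b
  while (path[1] != a) path <- c(res$parent[path[1]], path)
  path
}
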