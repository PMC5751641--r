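# Embedding tables, topic features and dependency-tree distances.

dict_from_words <- function(words) {
  doc <- annotated_document("D", paste(words, collapse = " "))
  blk <- data.frame(index = seq_along(words), surface = words, pos = "NN",
                    head = c(0L, rep(1L, length(words) - 1L)),
                    deprel = "dep", stringsAsFactors = FALSE)
  list(dict = build_dictionary(attach_parse(doc, list(blk))),
       sentences = attach_parse(doc, list(blk)))
}

test_that("word2vec text files load with seeded random fallback rows", {
  f <- withr::local_tempfile(lines = c(
    "2 4", "apple 0.1 0.2 0.3 0.4", "banana 1 2 3 4"))
  dd <- dict_from_words(c("apple", "banana", "cherry"))
  tab <- load_word_embeddings(f, dd$dict, seed = 7)
  expect_equal(tab$dim, 4L)
  expect_equal(unname(tab$mat[tab$map[["apple"]], ]),
               c(0.1, 0.2, 0.3, 0.4))
  expect_equal(unname(tab$mat[tab$map[["banana"]], ]), c(1, 2, 3, 4))
  # the miss gets a uniform(-0.25, 0.25) row, identical across same-seed loads
  cherry <- tab$mat[tab$map[["cherry"]], ]
  expect_true(all(abs(cherry) <= 0.25))
  tab2 <- load_word_embeddings(f, dd$dict, seed = 7)
  expect_identical(tab$mat, tab2$mat)
  tab3 <- load_word_embeddings(f, dd$dict, seed = 8)
  expect_false(identical(tab$mat[tab$map[["cherry"]], ],
                         tab3$mat[tab3$map[["cherry"]], ]))
})

test_that("malformed embedding files raise format errors", {
  dd <- dict_from_words(c("apple", "banana"))
  bad_row <- withr::local_tempfile(lines = c("1 4", "apple 0.1 0.2 0.3"))
  expect_error(load_word_embeddings(bad_row, dd$dict), "format error")
  bad_head <- withr::local_tempfile(lines = c("apple 1 2", "x 1 2"))
  expect_error(load_word_embeddings(bad_head, dd$dict), "format error")
  f <- withr::local_tempfile(lines = c("1 4", "apple 1 2 3 4"))
  expect_error(load_word_embeddings(f, dd$dict, dim = 5), "format error")
})

test_that("topic fits are proper distributions, seeded, with uniform OOV", {
  corp <- tiny_corpus(seed = 3, n_docs = 3L)
  flat <- unlist(preprocess_corpus(corp), recursive = FALSE)
  tt <- fit_topics(flat, d_top = 4, seed = 11)
  expect_true(all(abs(rowSums(tt$dist) - 1) < 1e-9))
  expect_true(all(tt$dist >= 0))
  expect_equal(unname(bioevent:::topic_rows(tt, "never-seen-word")[1, ]),
               rep(0.25, 4))
  tt2 <- fit_topics(flat, d_top = 4, seed = 11)
  expect_identical(tt$dist, tt2$dist)
  expect_error(fit_topics(flat, d_top = 1), "at least 2")
})

test_that("the windowed topic product matches the direct-product oracle", {
  set.seed(42)
  d_top <- 6
  dist <- matrix(stats::rexp(5 * d_top), 5)
  dist <- dist / rowSums(dist)
  rownames(dist) <- paste0("w", 1:5)
  tt <- structure(list(dist = dist, d_top = d_top), class = "topic_table")
  got <- sentence_topic(paste0("w", 1:5), tt)
  direct <- apply(dist, 2, prod)
  expect_equal(got, direct / sum(direct), tolerance = 1e-12)
  expect_equal(sum(got), 1, tolerance = 1e-12)
  # invariant under word order within the window
  expect_equal(got, sentence_topic(paste0("w", c(3, 1, 5, 2, 4)), tt),
               tolerance = 1e-12)
  # a single word returns its own distribution
  expect_equal(sentence_topic("w2", tt), unname(dist[2, ]),
               tolerance = 1e-12)
  # two uniform words stay uniform
  u <- structure(list(dist = matrix(0.5, 2, 2,
                                    dimnames = list(c("a", "b"), NULL)),
                      d_top = 2), class = "topic_table")
  expect_equal(sentence_topic(c("a", "b"), u), c(0.5, 0.5))
  expect_error(sentence_topic(character(), tt), "at least one")
})

test_that("dependency distances equal the graph-library oracle", {
  skip_if_not_installed("igraph")
  set.seed(7)
  for (rep in 1:20) {
    n <- 12L
    tok <- random_tree_tokens(n)
    s <- make_sentence(tok)
    g <- igraph::graph_from_edgelist(
      cbind(which(tok$head > 0), tok$head[tok$head > 0]), directed = FALSE)
    D <- igraph::distances(g)
    for (a in 1:n) for (b in 1:n) {
      expect_equal(dependency_distance(s, a, b, clip = FALSE),
                   unname(D[a, b]), info = paste(rep, a, b))
    }
  }
})

test_that("distances are clipped, symmetric and triangle-consistent", {
  set.seed(8)
  tok <- random_tree_tokens(15L)
  s <- make_sentence(tok)
  expect_equal(dependency_distance(s, 4, 4), 0L)
  child <- which(tok$head == 1L)[1]
  expect_equal(dependency_distance(s, child, 1L), 1L)
  for (i in 1:10) {
    abc <- sample(15L, 3L)
    dab <- dependency_distance(s, abc[1], abc[2], clip = FALSE)
    dba <- dependency_distance(s, abc[2], abc[1], clip = FALSE)
    dbc <- dependency_distance(s, abc[2], abc[3], clip = FALSE)
    dac <- dependency_distance(s, abc[1], abc[3], clip = FALSE)
    expect_equal(dab, dba)
    expect_lte(dac, dab + dbc)
  }
  # clipping bound and out-of-sentence errors
  expect_lte(dependency_distance(s, 1, 15, max_distance = 2L), 3L)
  expect_error(dependency_distance(s, 1, 99), "outside sentence")
})

test_that("dependency paths equal the graph-library shortest path", {
  skip_if_not_installed("igraph")
  set.seed(9)
  for (rep in 1:10) {
    tok <- random_tree_tokens(10L)
    s <- make_sentence(tok)
    g <- igraph::graph_from_edgelist(
      cbind(which(tok$head > 0), tok$head[tok$head > 0]), directed = FALSE)
    ab <- sample(10L, 2L)
    want <- as.integer(igraph::shortest_paths(g, ab[1], ab[2])$vpath[[1]])
    expect_equal(as.integer(dependency_path(s, ab[1], ab[2])), want)
  }
})

test_that("disconnected token pairs fall back to the linear sequence", {
  tok <- data.frame(index = 1:4, surface = paste0("w", 1:4), pos = "NN",
                    head = c(0L, 1L, 4L, 3L), deprel = "dep",
                    stringsAsFactors = FALSE)
  # heads 3<->4 form a two-node cycle detached from the root: build the
  # sentence directly (attach_parse would reject it)
  s <- make_sentence(tok)
  p <- dependency_path(s, 1L, 4L)
  expect_true(isTRUE(attr(p, "fallback")))
  expect_equal(as.integer(p), 1:4)
})
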