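# Candidate pairs, dependency-path matrices and the CNN role classifier.

setup_argument <- function(seed = 2, n_docs = 6L,
                           cfg = small_argument_config()) {
  corp <- tiny_corpus(seed = seed, n_docs = n_docs)
  flat <- unlist(preprocess_corpus(corp), recursive = FALSE)
  dict <- build_dictionary(flat, bioevent:::annotation_types(corp$documents))
  tabs <- argument_tables(dict, cfg, seed = seed)
  list(corp = corp, flat = flat, dict = dict, tabs = tabs, cfg = cfg,
       ex = make_argument_examples(flat, tabs, cfg, corp$documents, dict))
}

fake_sentence_with <- function(n_trig, n_ent) {
  n <- n_trig + n_ent + 1L
  tok <- data.frame(index = seq_len(n), surface = paste0("w", seq_len(n)),
                    pos = "NN", head = c(0L, rep(1L, n - 1L)),
                    deprel = "dep", stringsAsFactors = FALSE)
  s <- make_sentence(tok)
  tok <- s$tokens
  mk <- function(pre, k, off) {
    if (!k) return(bioevent:::empty_spans())
    data.frame(id = paste0("T", off + seq_len(k)), type = "X",
               start = tok$start[1 + off + seq_len(k)],
               end = tok$end[1 + off + seq_len(k)],
               text = tok$surface[1 + off + seq_len(k)],
               stringsAsFactors = FALSE)
  }
  ent <- mk("E", n_ent, 0L)
  trig <- mk("T", n_trig, n_ent)
  s$entity_ids <- ent$id; s$trigger_ids <- trig$id
  list(s = s, trig = trig, ent = ent)
}

test_that("candidate pair counts follow |T|(|T|-1) + |T||E|", {
  f <- fake_sentence_with(1L, 2L)
  expect_equal(nrow(candidate_pairs(f$s, f$trig, f$ent)), 2L)
  f <- fake_sentence_with(2L, 1L)
  p <- candidate_pairs(f$s, f$trig, f$ent)
  expect_equal(sum(p$target_kind == "entity"), 2L)
  expect_equal(sum(p$target_kind == "trigger"), 2L)
  expect_false(any(p$source_id == p$target_id))
  set.seed(12)
  for (i in 1:10) {
    nt <- sample(0:4, 1); ne <- sample(0:4, 1)
    f <- fake_sentence_with(nt, ne)
    expect_equal(nrow(candidate_pairs(f$s, f$trig, f$ent)),
                 nt * (nt - 1) + nt * ne)
  }
})

test_that("psi(S) has (d + d_pos + 2 d_dis) rows and n + 2 columns", {
  st <- setup_argument()
  cfg <- st$cfg
  s <- st$flat[[1]]
  M <- build_path_matrix(s, 1L, nrow(s$tokens) - 1L, "Regulation", "Cell",
                         st$tabs, cfg, st$dict)
  n <- length(attr(M, "path"))
  expect_equal(dim(M), c(cfg$dim + cfg$d_pos + 2 * cfg$d_dis, n + 2L))
  # distance blocks encode positional offsets 0,1,... and mirrored
  r0 <- cfg$dim + cfg$d_pos
  d_keys <- as.character(pmin(seq_len(n) - 1L, cfg$max_distance))
  want1 <- t(st$tabs$dis$mat[bioevent:::lookup_index(st$dict$dist, d_keys), ])
  expect_equal(unname(M[r0 + seq_len(cfg$d_dis), seq_len(n)]),
               unname(want1))
  d_keys2 <- as.character(pmin(n - seq_len(n), cfg$max_distance))
  want2 <- t(st$tabs$dis$mat[bioevent:::lookup_index(st$dict$dist, d_keys2), ])
  expect_equal(unname(M[r0 + cfg$d_dis + seq_len(cfg$d_dis), seq_len(n)]),
               unname(want2))
  # the two appended columns carry the endpoint type embeddings
  t_rows <- bioevent:::lookup_index(st$dict$type, c("Regulation", "Cell"))
  expect_equal(unname(M[seq_len(cfg$dim), n + 1L]),
               unname(st$tabs$type$mat[t_rows[1], ]))
  expect_equal(unname(M[seq_len(cfg$dim), n + 2L]),
               unname(st$tabs$type$mat[t_rows[2], ]))
})

test_that("path extraction matches the tree shortest path and truncates", {
  st <- setup_argument()
  s <- st$flat[[1]]
  M <- build_path_matrix(s, 2L, 3L, "Growth", "Cell", st$tabs, st$cfg,
                         st$dict)
  expect_equal(attr(M, "path"),
               as.integer(dependency_path(s, 2L, 3L)))
  cfg <- small_argument_config(max_path_len = 3L)
  tok <- data.frame(index = 1:8, surface = paste0("w", 1:8), pos = "NN",
                    head = c(0L, 1:7), deprel = "dep",
                    stringsAsFactors = FALSE) # a chain: path 1..8
  s2 <- make_sentence(tok)
  M2 <- build_path_matrix(s2, 1L, 8L, "Growth", "Cell", st$tabs, cfg,
                          st$dict)
  expect_equal(length(attr(M2, "path")), 3L)
  expect_equal(attr(M2, "path"), c(1L, 2L, 8L)) # symmetric truncation
})

test_that("pooled width is independent of path length", {
  st <- setup_argument()
  m <- train_argument_model(st$ex, st$cfg, seed = 1)
  lens <- st$ex$len
  short_i <- which.min(lens); long_i <- which.max(lens)
  expect_false(lens[short_i] == lens[long_i])
  pooled_of <- function(i) {
    A <- bioevent:::argument_input_array(st$ex, m$tables, i)
    ncol(bioevent:::cnn_forward(m$cnn, A, st$cfg)$pooled)
  }
  expect_equal(pooled_of(short_i), pooled_of(long_i))
  expect_equal(pooled_of(short_i),
               length(st$cfg$filters) * st$cfg$n_maps)
})

test_that("training is deterministic per seed", {
  st <- setup_argument(n_docs = 4L)
  m1 <- train_argument_model(st$ex, st$cfg, seed = 9)
  m2 <- train_argument_model(st$ex, st$cfg, seed = 9)
  expect_identical(m1$cnn, m2$cnn)
  expect_identical(m1$tables$type$mat, m2$tables$type$mat)
})

test_that("the CNN overfits the planted role signal", {
  cfg <- small_argument_config(dim = 16L, n_maps = 16L, dense = 64L,
                               epochs = 30L)
  st <- setup_argument(seed = 19, n_docs = 12L, cfg = cfg)
  m <- train_argument_model(st$ex, cfg, seed = 3)
  h <- m$loss_history
  expect_lt(mean(utils::tail(h, 3)), mean(utils::head(h, 3)))
  pred <- predict(m, st$ex)
  expect_gte(micro_f_labels(st$ex$label, pred), 0.95)
})

test_that("probabilities are simplex and invariant to batch composition", {
  st <- setup_argument(n_docs = 4L)
  m <- train_argument_model(st$ex, st$cfg, seed = 2)
  P <- predict(m, st$ex, type = "prob")
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  # single-example forward equals its row from the batched forward
  for (i in c(1L, 3L, length(st$ex$label))) {
    Pi <- predict(m, subset_argument_examples(st$ex, i), type = "prob")
    expect_equal(unname(Pi[1, ]), unname(P[i, ]), tolerance = 1e-10)
  }
})

test_that("zero pairs predict zero relations", {
  st <- setup_argument(n_docs = 3L)
  m <- train_argument_model(st$ex, st$cfg, seed = 2)
  empty <- subset_argument_examples(st$ex, integer(0))
  expect_equal(nrow(predict_arguments(m, empty)), 0L)
})
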