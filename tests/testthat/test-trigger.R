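# Trigger representation geometry, training and prediction.

setup_trigger <- function(seed = 2, n_docs = 6L, cfg = small_trigger_config()) {
  corp <- tiny_corpus(seed = seed, n_docs = n_docs)
  sents <- preprocess_corpus(corp)
  flat <- unlist(sents, recursive = FALSE)
  dict <- build_dictionary(flat, bioevent:::annotation_types(corp$documents))
  tabs <- trigger_tables(dict, cfg, seed = seed, sentences = flat)
  list(corp = corp, flat = flat, dict = dict, tabs = tabs, cfg = cfg,
       ex = make_trigger_examples(flat, tabs, cfg, corp$documents, dict))
}

test_that("the feature vector width follows the block arithmetic", {
  st <- setup_trigger()
  set.seed(31)
  for (i in 1:20) {
    cfg <- trigger_config(
      dim = sample(4:24, 1), d_win = sample(1:3, 1),
      d_top = sample(2:10, 1), d_pos = sample(2:10, 1),
      d_dis = sample(2:10, 1),
      use_topic = runif(1) < 0.7, use_pos = runif(1) < 0.7,
      use_distance = runif(1) < 0.7, hidden = 8L, epochs = 1L)
    want <- (2 * cfg$d_win + 1) * cfg$dim +
      cfg$use_topic * cfg$d_top + cfg$use_pos * cfg$d_pos +
      cfg$use_distance * cfg$d_dis
    expect_equal(trigger_feature_width(cfg), want)
    tabs <- trigger_tables(st$dict, cfg, seed = i, sentences = st$flat)
    ex <- make_trigger_examples(st$flat[1:3], tabs, cfg,
                                st$corp$documents, st$dict)
    X <- bioevent:::trigger_design(ex, tabs, seq_along(ex$label))
    expect_equal(ncol(X), want)
  }
})

test_that("disabling a feature block shrinks the vector by its width", {
  base <- small_trigger_config()
  for (block in c("use_topic", "use_pos", "use_distance")) {
    args <- list(); args[[block]] <- FALSE
    cfg <- do.call(small_trigger_config, args)
    shrink <- c(use_topic = base$d_top, use_pos = base$d_pos,
                use_distance = base$d_dis)[[block]]
    expect_equal(trigger_feature_width(base) - trigger_feature_width(cfg),
                 shrink)
  }
})

test_that("the context block equals manual row lookups", {
  st <- setup_trigger()
  tok <- st$flat[[1]]$tokens
  i <- min(3L, nrow(tok))
  row_of <- function(j) {
    if (j < 1 || j > nrow(tok)) return(st$tabs$word$mat[2L, ])
    st$tabs$word$mat[bioevent:::lookup_index(
      st$dict$word, bioevent:::norm_word(tok$surface[j])), ]
  }
  manual <- c(row_of(i - 2), row_of(i - 1), row_of(i), row_of(i + 1),
              row_of(i + 2))
  X <- bioevent:::trigger_design(st$ex, st$tabs, seq_along(st$ex$label))
  mine <- X[st$ex$meta$sentence == st$flat[[1]]$index &
              st$ex$meta$doc_id == st$flat[[1]]$doc_id &
              st$ex$meta$token == i,
            seq_len(5 * st$cfg$dim)]
  expect_equal(unname(mine), unname(manual))
})

test_that("sentences without entities use the unreachable distance bucket", {
  doc <- annotated_document("D", "nothing regulates anything.")
  blk <- data.frame(index = 1:4,
                    surface = c("nothing", "regulates", "anything", "."),
                    pos = c("NN", "VBZ", "NN", "."),
                    head = c(2L, 0L, 2L, 2L), deprel = "dep",
                    stringsAsFactors = FALSE)
  s <- attach_parse(doc, list(blk))
  dict <- build_dictionary(s, types = "Cell")
  cfg <- small_trigger_config(use_topic = FALSE)
  tabs <- trigger_tables(dict, cfg, seed = 1)
  ex <- make_trigger_examples(s, tabs, cfg, list(D = doc), dict)
  unreachable <- unname(dict$dist[[as.character(cfg$max_distance + 1L)]])
  expect_true(all(ex$dis_idx == unreachable))
})

test_that("training is deterministic per seed and needs two classes", {
  st <- setup_trigger(n_docs = 4L)
  m1 <- train_trigger_model(st$ex, st$cfg, seed = 5)
  m2 <- train_trigger_model(st$ex, st$cfg, seed = 5)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$tables$word$mat, m2$tables$word$mat)
  m3 <- train_trigger_model(st$ex, st$cfg, seed = 6)
  expect_false(identical(m1$params, m3$params))

  neg_only <- st$ex
  neg_only$label <- rep("<neg>", length(neg_only$label))
  expect_error(train_trigger_model(neg_only, st$cfg, seed = 1),
               "two classes")
})

test_that("training loss decreases and the model overfits planted signal", {
  cfg <- small_trigger_config(dim = 24L, hidden = 64L, epochs = 40L)
  st <- setup_trigger(seed = 17, n_docs = 12L, cfg = cfg)
  m <- train_trigger_model(st$ex, cfg, seed = 3)
  h <- m$loss_history
  expect_lt(mean(utils::tail(h, 3)), mean(utils::head(h, 3)))
  pred <- predict(m, st$ex)
  expect_gte(micro_f_labels(st$ex$label, pred), 0.95)
})

test_that("softmax rows are simplex and prediction is order-invariant", {
  st <- setup_trigger(n_docs = 4L)
  m <- train_trigger_model(st$ex, st$cfg, seed = 2)
  P <- predict(m, st$ex, type = "prob")
  expect_true(all(abs(rowSums(P) - 1) < 1e-6))
  ord <- rev(seq_along(st$ex$label))
  P2 <- predict(m, permute_trigger_examples(st$ex, ord), type = "prob")
  expect_equal(P2, P[ord, ], tolerance = 1e-12)
})

test_that("all-negative predictions materialize zero triggers", {
  st <- setup_trigger(n_docs = 3L)
  m <- train_trigger_model(st$ex, st$cfg, seed = 2)
  # force the negative class by rigging the output bias
  K <- length(m$classes)
  L <- length(m$params$b)
  m$params$b[[L]] <- rep(-50, K); m$params$b[[L]][K] <- 50
  trig <- predict_triggers(m, st$flat, st$corp$documents, st$dict)
  expect_equal(nrow(trig), 0L)
})

test_that("predicted triggers carry valid spans and fresh ids", {
  cfg <- small_trigger_config(dim = 24L, hidden = 64L, epochs = 30L)
  st <- setup_trigger(seed = 23, n_docs = 10L, cfg = cfg)
  m <- train_trigger_model(st$ex, cfg, seed = 4)
  trig <- predict_triggers(m, st$flat, st$corp$documents, st$dict)
  expect_gt(nrow(trig), 0L)
  for (i in seq_len(nrow(trig))) {
    doc <- st$corp$documents[[trig$doc_id[i]]]
    expect_identical(substr(doc$text, trig$start[i] + 1L, trig$end[i]),
                     trig$text[i])
    expect_false(trig$id[i] %in% doc$entities$id)
  }
})
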