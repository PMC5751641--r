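# Approximate span matching, recursive event matching and P/R/F scoring.

eval_fixture <- function() {
  text <- "the tumor cells grow under regulation now."
  doc <- annotated_document("D", text)
  blk <- data.frame(
    index = 1:8,
    surface = c("the", "tumor", "cells", "grow", "under", "regulation",
                "now", "."),
    pos = c("DT", "NN", "NNS", "VBP", "IN", "NN", "RB", "."),
    head = c(3L, 3L, 4L, 0L, 4L, 5L, 4L, 4L), deprel = "dep",
    stringsAsFactors = FALSE)
  list(doc = doc, sents = attach_parse(doc, list(blk)))
}

span_at <- function(sents, from_tok, to_tok = from_tok, type = "Growth") {
  tok <- sents[[1]]$tokens
  data.frame(id = "T1", type = type, start = tok$start[from_tok],
             end = tok$end[to_tok], text = "x", stringsAsFactors = FALSE)
}

test_that("approximate span matching allows one token of slack", {
  f <- eval_fixture()
  gold <- span_at(f$sents, 2, 3, "Cell")         # "tumor cells"
  expect_true(span_match(gold, gold, f$sents))
  # any predicted span inside the one-token extension matches
  for (from in 1:4) for (to in from:4) {
    pred <- span_at(f$sents, from, to, "Cell")
    expect_true(span_match(gold, pred, f$sents), info = paste(from, to))
  }
  # beyond the extension window or with another type it does not
  expect_false(span_match(gold, span_at(f$sents, 2, 5, "Cell"), f$sents))
  expect_false(span_match(gold, span_at(f$sents, 5, 5, "Cell"), f$sents))
  expect_false(span_match(gold, span_at(f$sents, 2, 3, "Tissue"), f$sents))
})

# Build a document with a nested regulation chain for event matching.
nested_doc <- function(role2 = "Theme") {
  text <- "gene1 regulationates the growthation of cell1 ."
  ents <- data.frame(id = c("T1", "T2"), type = c("Gene", "Cell"),
                     start = c(0L, 40L), end = c(5L, 45L),
                     text = c("gene1", "cell1"), stringsAsFactors = FALSE)
  trig <- data.frame(
    id = c("T3", "T4"), type = c("Regulation", "Growth"),
    start = c(6L, 25L), end = c(20L, 36L),
    text = c("regulationates", "growthation"),
    stringsAsFactors = FALSE)
  evs <- list(
    list(id = "E1", type = "Growth", trigger_id = "T4",
         args = data.frame(role = "Theme", filler = "T2",
                           stringsAsFactors = FALSE)),
    list(id = "E2", type = "Regulation", trigger_id = "T3",
         args = data.frame(role = c("Theme", role2),
                           filler = c("E1", "T1"),
                           stringsAsFactors = FALSE)))
  doc <- annotated_document("D", text, ents, trig, evs)
  blk <- data.frame(
    index = 1:7,
    surface = c("gene1", "regulationates", "the", "growthation", "of",
                "cell1", "."),
    pos = c("NN", "VBZ", "DT", "NN", "IN", "NN", "."),
    head = c(2L, 0L, 4L, 2L, 4L, 5L, 2L), deprel = "dep",
    stringsAsFactors = FALSE)
  list(doc = doc, sents = attach_parse(doc, list(blk)))
}

test_that("flat and nested event matching behave as specified", {
  g <- nested_doc()
  ctx <- match_context(g$doc, g$doc, g$sents)
  e1 <- g$doc$events[[1]]; e2 <- g$doc$events[[2]]
  expect_true(event_match(e1, e1, ctx))
  expect_true(event_match(e2, e2, ctx))
  expect_false(event_match(e1, e2, ctx))
  # a missing argument breaks the match
  e2_short <- e2
  e2_short$args <- e2$args[1, , drop = FALSE]
  expect_false(event_match(e2, e2_short, ctx))
  # a role swap breaks it
  p <- nested_doc(role2 = "Cause")
  ctx2 <- match_context(g$doc, p$doc, g$sents)
  expect_false(event_match(g$doc$events[[2]], p$doc$events[[2]], ctx2))
})

test_that("event matching agrees with the exhaustive-bijection oracle", {
  corp <- tiny_corpus(seed = 41, n_docs = 8L)
  sents <- preprocess_corpus(corp)
  n_nested <- 0L
  for (id in names(corp$documents)) {
    doc <- corp$documents[[id]]
    ctx <- match_context(doc, doc, sents[[id]])
    for (g in doc$events) for (p in doc$events) {
      expect_equal(event_match(g, p, ctx), oracle_event_match(g, p, ctx),
                   info = paste(id, g$id, p$id))
      if (any(grepl("^E", g$args$filler))) n_nested <- n_nested + 1L
    }
  }
  expect_gt(n_nested, 0L) # the fixture set really contains nested events
})

test_that("scoring reproduces the closed-form P/R/F", {
  f <- eval_fixture()
  tok <- f$sents[[1]]$tokens
  mk_doc <- function(starts) {
    tr <- data.frame(id = paste0("T", seq_along(starts)), type = "Growth",
                     start = tok$start[starts], end = tok$end[starts],
                     text = tok$surface[starts], stringsAsFactors = FALSE)
    annotated_document("D", f$doc$text, triggers = tr)
  }
  gold <- list(D = mk_doc(c(2L, 4L, 6L)))
  pred <- list(D = mk_doc(c(2L, 4L)))
  # tokens 2 and 4 match; token 7 is far from every unmatched gold
  pred$D$triggers <- rbind(pred$D$triggers,
                           data.frame(id = "T3", type = "Tissue",
                                      start = tok$start[7], end = tok$end[7],
                                      text = tok$surface[7],
                                      stringsAsFactors = FALSE))
  r <- score_predictions(gold, pred, list(D = f$sents), mode = "trigger")
  m <- micro_scores(r)
  expect_equal(unname(m["precision"]), 200 / 3, tolerance = 1e-10)
  expect_equal(unname(m["recall"]), 200 / 3, tolerance = 1e-10)
  expect_equal(unname(m["fscore"]), 200 / 3, tolerance = 1e-10)
  micro <- r[r$class == "micro", ]
  expect_equal(c(micro$tp, micro$fp, micro$fn), c(2, 1, 1))
})

test_that("empty predictions score zero, not NaN", {
  f <- eval_fixture()
  tok <- f$sents[[1]]$tokens
  gold <- list(D = annotated_document(
    "D", f$doc$text,
    triggers = data.frame(id = "T1", type = "Growth", start = tok$start[4],
                          end = tok$end[4], text = tok$surface[4],
                          stringsAsFactors = FALSE)))
  pred <- list(D = annotated_document("D", f$doc$text))
  m <- micro_scores(score_predictions(gold, pred, list(D = f$sents),
                                      mode = "trigger"))
  expect_equal(unname(m), c(0, 0, 0))
})

test_that("gold scored against itself is 100% in both modes", {
  corp <- tiny_corpus(seed = 51, n_docs = 6L)
  sents <- preprocess_corpus(corp)
  for (mode in c("trigger", "event")) {
    m <- micro_scores(score_predictions(corp$documents, corp$documents,
                                        sents, mode = mode))
    expect_equal(unname(m), c(100, 100, 100), info = mode)
  }
})

test_that("micro scores are invariant to document order", {
  corp <- tiny_corpus(seed = 52, n_docs = 5L)
  sents <- preprocess_corpus(corp)
  ord <- rev(names(corp$documents))
  m1 <- micro_scores(score_predictions(corp$documents, corp$documents,
                                       sents, mode = "event"))
  m2 <- micro_scores(score_predictions(corp$documents[ord],
                                       corp$documents[ord], sents[ord],
                                       mode = "event"))
  expect_identical(m1, m2)
  expect_error(score_predictions(corp$documents[1:2], corp$documents[2:3],
                                 sents, mode = "event"), "mismatch")
})
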