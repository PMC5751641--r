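# Shared fixture builders: all fixtures are generated in code.

tiny_corpus <- function(seed, n_docs = 8L, spd = 4L, noise = 0) {
  generate_corpus(syn_config(n_documents = n_docs, sentences_per_doc = spd,
                             noise_rate = noise, seed = seed))
}

small_trigger_config <- function(...) {
  args <- utils::modifyList(
    list(dim = 16L, hidden = 32L, d_top = 4L, d_pos = 6L, d_dis = 6L,
         epochs = 5L, batch = 64L, patience = 0L),
    list(...))
  do.call(trigger_config, args)
}

small_argument_config <- function(...) {
  args <- utils::modifyList(
    list(dim = 12L, n_maps = 8L, dense = 24L, d_pos = 6L, d_dis = 6L,
         epochs = 5L, batch = 32L, patience = 0L, max_path_len = 10L),
    list(...))
  do.call(argument_config, args)
}

# A bare sentence object around a token table (for graph/path tests).
make_sentence <- function(tok, doc_id = "X", index = 1L) {
  n <- nrow(tok)
  if (is.null(tok$start)) {
    tok$start <- cumsum(c(0L, nchar(tok$surface[-n]) + 1L))
    tok$end <- tok$start + nchar(tok$surface)
  }
  structure(list(doc_id = doc_id, index = index, tokens = tok,
                 sent_start = min(tok$start), sent_end = max(tok$end),
                 entity_ids = character(), trigger_ids = character()),
            class = "sentence")
}

# Random labeled tree on n nodes (node 1 is the root).
random_tree_tokens <- function(n) {
  head <- c(0L, vapply(2:n, function(i) sample.int(i - 1L, 1L), 1L))
  data.frame(index = seq_len(n), surface = paste0("w", seq_len(n)),
             pos = "NN", head = head, deprel = "dep",
             stringsAsFactors = FALSE)
}

# Write a standoff document fixture to a temp dir; returns the paths.
write_standoff_fixture <- function(text, a1_lines, a2_lines = NULL,
                                   doc_id = "DOC1") {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  paths <- file.path(dir, paste0(doc_id, c(".txt", ".a1", ".a2")))
  writeLines(text, paths[1])
  writeLines(a1_lines, paths[2])
  if (!is.null(a2_lines)) writeLines(a2_lines, paths[3])
  paths
}

# Micro precision/recall/F over positive classes for parallel label
# vectors (negatives carry the "<neg>" label).
micro_f_labels <- function(gold, pred, neg = "<neg>") {
  cls <- setdiff(unique(c(gold, pred)), neg)
  tp <- sum(vapply(cls, function(c) sum(gold == c & pred == c), 1))
  fp <- sum(vapply(cls, function(c) sum(pred == c & gold != c), 1))
  fn <- sum(vapply(cls, function(c) sum(gold == c & pred != c), 1))
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

# Exhaustive-bijection event matcher: an oracle independent of the
# package's backtracking implementation (tries every permutation of the
# predicted argument list).
perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

oracle_event_match <- function(gold, pred, ctx, nested = FALSE) {
  if (!identical(gold$type, pred$type)) return(FALSE)
  gt <- bioevent:::ann_by_id(ctx$gold_doc, gold$trigger_id)
  pt <- bioevent:::ann_by_id(ctx$pred_doc, pred$trigger_id)
  if (is.null(gt) || is.null(pt) || !span_match(gt, pt, ctx$sentences))
    return(FALSE)
  ga <- gold$args; pa <- pred$args
  if (nested && ctx$recursive_core_only) {
    ga <- ga[ga$role %in% ctx$core_roles, , drop = FALSE]
    pa <- pa[pa$role %in% ctx$core_roles, , drop = FALSE]
  }
  if (nrow(ga) != nrow(pa)) return(FALSE)
  if (!nrow(ga)) return(TRUE)
  ok_filler <- function(gid, pid) {
    ge <- grepl("^E", gid); pe <- grepl("^E", pid)
    if (ge != pe) return(FALSE)
    if (ge) {
      gev <- bioevent:::ann_by_id(ctx$gold_doc, gid)
      pev <- bioevent:::ann_by_id(ctx$pred_doc, pid)
      if (is.null(gev) || is.null(pev)) return(FALSE)
      return(oracle_event_match(gev, pev, ctx, nested = TRUE))
    }
    gs <- bioevent:::ann_by_id(ctx$gold_doc, gid)
    ps <- bioevent:::ann_by_id(ctx$pred_doc, pid)
    if (is.null(gs) || is.null(ps)) return(FALSE)
    span_match(gs, ps, ctx$sentences)
  }
  for (p in perms(seq_len(nrow(pa)))) {
    ok <- TRUE
    for (i in seq_len(nrow(ga))) {
      j <- p[i]
      if (ga$role[i] != pa$role[j] ||
          !ok_filler(ga$filler[i], pa$filler[j])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# Reorder a trigger_examples object (for order-invariance checks).
permute_trigger_examples <- function(ex, ord) {
  ex$ctx_idx <- ex$ctx_idx[ord, , drop = FALSE]
  if (!is.null(ex$topic)) ex$topic <- ex$topic[ord, , drop = FALSE]
  ex$pos_idx <- ex$pos_idx[ord]; ex$dis_idx <- ex$dis_idx[ord]
  ex$label <- ex$label[ord]; ex$meta <- ex$meta[ord, , drop = FALSE]
  ex
}

subset_argument_examples <- function(ex, idx) {
  for (f in c("widx", "pidx", "d1", "d2"))
    ex[[f]] <- ex[[f]][idx, , drop = FALSE]
  for (f in c("len", "t1", "t2", "label"))
    ex[[f]] <- ex[[f]][idx]
  ex$meta <- ex$meta[idx, , drop = FALSE]
  ex
}
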