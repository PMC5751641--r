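# Trigger identification: every token of every sentence is a candidate,
# classified into an event type or the negative class from the
# concatenation psi = [context window embeddings | sentence-topic |
# POS embedding | distance-to-nearest-entity embedding] by a feed-forward
# softmax network.

NEG_LABEL <- "<neg>"

#' Trigger-model configuration
#'
#' Defaults follow the reference setting for the trigger network: word
#' embedding dimension 100, three hidden layers of 1000 rectified units,
#' minibatch 512, dropout 0.2, Adadelta. The context window `d_win` is 2
#' (five word vectors), the topic block has `d_top` topics and the POS and
#' distance embeddings are `d_pos`- and `d_dis`-dimensional trainable
#' tables. Feature switches (`use_topic`, `use_pos`, `use_distance`)
#' support ablation runs; the context block is always on.
#'
#' @param dim Word embedding dimension.
#' @param hidden Hidden layer widths.
#' @param batch Minibatch size.
#' @param dropout Dropout rate on hidden layers.
#' @param d_win Context window half-width.
#' @param d_top,d_pos,d_dis Topic, POS and distance feature widths.
#' @param epochs Maximum training epochs.
#' @param patience Early-stopping patience on validation loss; 0 disables.
#' @param validation_frac Fraction of examples held out for early stopping.
#' @param use_topic,use_pos,use_distance Feature ablation switches.
#' @param max_distance Dependency-distance clipping bound.
#' @param train_embeddings Update the word table during training (the POS
#'   and distance tables are always trainable).
#' @param topic_scope `"window"` (the context window, following the
#'   feature's defining product formula) or `"sentence"`.
#' @param candidate_filter `"all"` tokens (default) or `"content"` words
#'   only (POS starting N/V/J).
#' @return A list of class `trigger_config`.
#' @export
trigger_config <- function(dim = 100L, hidden = c(1000L, 1000L, 1000L),
                           batch = 512L, dropout = 0.2, d_win = 2L,
                           d_top = 50L, d_pos = 20L, d_dis = 20L,
                           epochs = 30L, patience = 5L,
                           validation_frac = 0.1,
                           use_topic = TRUE, use_pos = TRUE,
                           use_distance = TRUE, max_distance = 10L,
                           train_embeddings = TRUE,
                           topic_scope = c("window", "sentence"),
                           candidate_filter = c("all", "content")) {
  structure(list(
    dim = as.integer(dim), hidden = as.integer(hidden),
    batch = as.integer(batch), dropout = dropout, d_win = as.integer(d_win),
    d_top = as.integer(d_top), d_pos = as.integer(d_pos),
    d_dis = as.integer(d_dis), epochs = as.integer(epochs),
    patience = as.integer(patience), validation_frac = validation_frac,
    use_topic = use_topic, use_pos = use_pos, use_distance = use_distance,
    max_distance = as.integer(max_distance),
    train_embeddings = train_embeddings,
    topic_scope = match.arg(topic_scope),
    candidate_filter = match.arg(candidate_filter)),
    class = "trigger_config")
}

#' Feature width of the trigger representation
#'
#' `(2 d_win + 1) * dim` for the context block plus `d_top`, `d_pos` and
#' `d_dis` for each enabled auxiliary block.
#'
#' @param config A [trigger_config()].
#' @return Integer vector width.
#' @export
trigger_feature_width <- function(config) {
  (2L * config$d_win + 1L) * config$dim +
    (if (config$use_topic) config$d_top else 0L) +
    (if (config$use_pos) config$d_pos else 0L) +
    (if (config$use_distance) config$d_dis else 0L)
}

#' Build the lookup tables for the trigger model
#'
#' @param dictionary A [build_dictionary()] result.
#' @param config A [trigger_config()].
#' @param seed Run seed; table initializations are derived from it.
#' @param word_table Optional pre-built word `embedding_table` (e.g. from
#'   [load_word_embeddings()]); its width must equal `config$dim`.
#' @param topic_table Optional pre-fitted [fit_topics()] table.
#' @param sentences Training sentences, required to fit topics when no
#'   `topic_table` is given and `use_topic` is on.
#' @return A list of tables (`word`, `topic`, `pos`, `dis`).
#' @export
trigger_tables <- function(dictionary, config, seed = 1L, word_table = NULL,
                           topic_table = NULL, sentences = NULL) {
  if (is.null(word_table))
    word_table <- load_word_embeddings(NULL, dictionary, dim = config$dim,
                                       seed = derive_seed(seed, "word"),
                                       trainable = config$train_embeddings)
  if (word_table$dim != config$dim)
    stop("word table width ", word_table$dim, " != config dim ", config$dim)
  word_table$trainable <- config$train_embeddings
  if (is.null(topic_table) && config$use_topic) {
    if (is.null(sentences))
      stop("sentences are required to fit the topic table")
    topic_table <- fit_topics(sentences, config$d_top,
                              seed = derive_seed(seed, "topics"))
  }
  if (!is.null(topic_table) && topic_table$d_top != config$d_top)
    stop("topic table has ", topic_table$d_top, " topics, config wants ",
         config$d_top)
  list(
    word = word_table,
    topic = topic_table,
    pos = embedding_table(dictionary$pos, config$d_pos,
                          derive_seed(seed, "pos")),
    dis = embedding_table(dictionary$dist, config$d_dis,
                          derive_seed(seed, "dis")))
}

# Gold trigger type anchored at each token of a sentence (NEG elsewhere).
gold_token_labels <- function(sentence, doc) {
  lab <- rep(NEG_LABEL, nrow(sentence$tokens))
  tr <- doc$triggers[doc$triggers$id %in% sentence$trigger_ids, , drop = FALSE]
  if (nrow(tr)) {
    tr <- tr[order(numeric_id(tr$id)), , drop = FALSE]
    for (i in seq_len(nrow(tr))) {
      a <- anchor_annotation(sentence, tr$start[i], tr$end[i])
      if (lab[a] == NEG_LABEL) lab[a] <- tr$type[i]
    }
  }
  lab
}

# Min dependency distance from every token to the nearest entity anchor,
# clipped; the unreachable bucket when the sentence has no entities.
entity_distance_buckets <- function(sentence, doc, max_distance) {
  n <- nrow(sentence$tokens)
  ents <- doc$entities[doc$entities$id %in% sentence$entity_ids, , drop = FALSE]
  if (!nrow(ents)) return(rep(max_distance + 1L, n))
  anchors <- vapply(seq_len(nrow(ents)), function(i)
    anchor_annotation(sentence, ents$start[i], ents$end[i]), 1L)
  adj <- adjacency_list(sentence$tokens)
  dmat <- vapply(unique(anchors), function(a) bfs_tree(adj, a)$dist,
                 integer(n))
  d <- apply(dmat, 1, function(r) suppressWarnings(min(r, na.rm = TRUE)))
  d[!is.finite(d)] <- max_distance + 1L
  pmin(as.integer(d), max_distance + 1L)
}

#' Build trigger classification examples
#'
#' One example per candidate token, holding the index structure of its
#' multiple distributed representation: context-window word rows (padded
#' outside the sentence edge), the windowed sentence-topic vector, the POS
#' row and the distance bucket of the nearest entity in the dependency
#' tree, plus the gold label when the documents carry gold triggers.
#'
#' @param sentences Sentences from [attach_parse()] (possibly from several
#'   documents).
#' @param tables [trigger_tables()] output.
#' @param config A [trigger_config()].
#' @param docs Named list of [annotated_document()]s (names = doc ids);
#'   provides entities (always required) and gold trigger labels.
#' @param dictionary The [build_dictionary()] used for the tables.
#' @return A `trigger_examples` object.
#' @export
make_trigger_examples <- function(sentences, tables, config, docs,
                                  dictionary) {
  w <- config$d_win
  ctx_idx <- list(); topic <- list(); pos_idx <- list(); dis_idx <- list()
  label <- list(); meta <- list()
  for (s in sentences) {
    doc <- docs[[s$doc_id]]
    if (is.null(doc)) stop("no document ", s$doc_id, " for sentence")
    tok <- s$tokens
    n <- nrow(tok)
    keep <- if (config$candidate_filter == "content")
      grepl("^[NVJ]", tok$pos) else rep(TRUE, n)
    if (!any(keep)) next
    words <- norm_word(tok$surface)
    widx <- lookup_index(dictionary$word, words)
    ctx <- vapply(-w:w, function(o) {
      j <- seq_len(n) + o
      out <- rep(2L, n) # padding row outside the sentence
      ok <- j >= 1 & j <= n
      out[ok] <- widx[j[ok]]
      out
    }, integer(n))
    tvec <- NULL
    if (config$use_topic) {
      tvec <- t(vapply(seq_len(n), function(i) {
        win <- if (config$topic_scope == "window")
          tok$surface[max(1, i - w):min(n, i + w)] else tok$surface
        sentence_topic(win, tables$topic)
      }, numeric(config$d_top)))
    }
    db <- entity_distance_buckets(s, doc, config$max_distance)
    labs <- gold_token_labels(s, doc)
    ctx_idx[[length(ctx_idx) + 1L]] <- ctx[keep, , drop = FALSE]
    if (!is.null(tvec)) topic[[length(topic) + 1L]] <- tvec[keep, , drop = FALSE]
    pos_idx[[length(pos_idx) + 1L]] <-
      lookup_index(dictionary$pos, tok$pos)[keep]
    dis_idx[[length(dis_idx) + 1L]] <-
      lookup_index(dictionary$dist, as.character(db))[keep]
    label[[length(label) + 1L]] <- labs[keep]
    meta[[length(meta) + 1L]] <- data.frame(
      doc_id = s$doc_id, sentence = s$index, token = which(keep),
      start = tok$start[keep], end = tok$end[keep],
      surface = tok$surface[keep], stringsAsFactors = FALSE)
  }
  structure(list(
    ctx_idx = do.call(rbind, ctx_idx),
    topic = if (config$use_topic) do.call(rbind, topic) else NULL,
    pos_idx = unlist(pos_idx), dis_idx = unlist(dis_idx),
    label = unlist(label), meta = do.call(rbind, meta),
    tables = tables, config = config),
    class = "trigger_examples")
}

#' @export
print.trigger_examples <- function(x, ...) {
  cat("<trigger_examples> ", length(x$label), " candidates, ",
      sum(x$label != NEG_LABEL), " positive\n", sep = "")
  invisible(x)
}

# Materialize the design matrix for a subset of examples from the current
# tables. Block order: context | topic | pos | distance.
trigger_design <- function(ex, tables, idx) {
  cfg <- ex$config
  blocks <- lapply(seq_len(ncol(ex$ctx_idx)), function(j)
    tables$word$mat[ex$ctx_idx[idx, j], , drop = FALSE])
  if (cfg$use_topic) blocks <- c(blocks, list(ex$topic[idx, , drop = FALSE]))
  if (cfg$use_pos)
    blocks <- c(blocks, list(tables$pos$mat[ex$pos_idx[idx], , drop = FALSE]))
  if (cfg$use_distance)
    blocks <- c(blocks, list(tables$dis$mat[ex$dis_idx[idx], , drop = FALSE]))
  do.call(cbind, blocks)
}

#' Train the trigger identification network
#'
#' Fits the feed-forward softmax classifier by minibatch Adadelta with
#' dropout; the POS and distance tables (and, by default, the word table)
#' receive gradient updates alongside the dense layers. With
#' `patience > 0` a validation split drives early stopping. Training is
#' deterministic for a fixed seed.
#'
#' @param examples A [make_trigger_examples()] result with gold labels.
#' @param config A [trigger_config()]; defaults to the examples' config.
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout.
#' @return A `trigger_model` object.
#' @export
train_trigger_model <- function(examples, config = examples$config,
                                seed = 1L) {
  labels <- examples$label
  classes <- c(sort(setdiff(unique(labels), NEG_LABEL)), NEG_LABEL)
  if (length(classes) < 2)
    stop("training needs at least two classes; got only ",
         paste(classes, collapse = ", "))
  y <- match(labels, classes)
  n <- length(y)
  width <- trigger_feature_width(config)
  tables <- examples$tables

  with_seed(derive_seed(seed, "trigger-train"), {
    params <- dense_init(c(width, config$hidden, length(classes)))
    opt <- adadelta_state(params)
    opt_word <- adadelta_state(tables$word$mat)
    opt_pos <- adadelta_state(tables$pos$mat)
    opt_dis <- adadelta_state(tables$dis$mat)

    val_idx <- integer(0)
    if (config$patience > 0 && config$validation_frac > 0 && n >= 20) {
      val_idx <- sample.int(n, max(1L, floor(config$validation_frac * n)))
    }
    train_idx <- setdiff(seq_len(n), val_idx)

    history <- numeric(0); best_val <- Inf; best <- NULL; bad <- 0L
    w_ctx <- (2L * config$d_win + 1L) * config$dim
    off_pos <- w_ctx + (if (config$use_topic) config$d_top else 0L)
    off_dis <- off_pos + (if (config$use_pos) config$d_pos else 0L)

    for (epoch in seq_len(config$epochs)) {
      ep_loss <- 0; nb <- 0L
      for (b in minibatches(length(train_idx), config$batch)) {
        idx <- train_idx[b]
        X <- trigger_design(examples, tables, idx)
        fwd <- dense_forward(params, X, config$dropout, train = TRUE)
        sx <- softmax_xent(fwd$logits, y[idx])
        ep_loss <- ep_loss + sx$loss; nb <- nb + 1L
        bwd <- dense_backward(params, fwd, sx$dlogits)
        up <- adadelta_step(params, list(W = bwd$W, b = bwd$b), opt)
        params <- up$params; opt <- up$state
        # scatter input gradient into the lookup tables
        if (tables$word$trainable) {
          G <- tables$word$mat * 0
          for (j in seq_len(ncol(examples$ctx_idx))) {
            cols <- ((j - 1L) * config$dim + 1L):(j * config$dim)
            G <- accumulate_rows(G, examples$ctx_idx[idx, j],
                                 bwd$dX[, cols, drop = FALSE])
          }
          r <- adadelta_apply(tables$word$mat, G, opt_word)
          tables$word$mat <- r$param; opt_word <- r$state
        }
        if (config$use_pos) {
          G <- accumulate_rows(tables$pos$mat * 0, examples$pos_idx[idx],
                               bwd$dX[, off_pos + seq_len(config$d_pos),
                                      drop = FALSE])
          r <- adadelta_apply(tables$pos$mat, G, opt_pos)
          tables$pos$mat <- r$param; opt_pos <- r$state
        }
        if (config$use_distance) {
          G <- accumulate_rows(tables$dis$mat * 0, examples$dis_idx[idx],
                               bwd$dX[, off_dis + seq_len(config$d_dis),
                                      drop = FALSE])
          r <- adadelta_apply(tables$dis$mat, G, opt_dis)
          tables$dis$mat <- r$param; opt_dis <- r$state
        }
      }
      history <- c(history, ep_loss / max(nb, 1L))
      if (length(val_idx)) {
        Xv <- trigger_design(examples, tables, val_idx)
        vl <- softmax_xent(dense_forward(params, Xv)$logits, y[val_idx])$loss
        if (vl < best_val - 1e-6) {
          best_val <- vl; bad <- 0L
          best <- list(params = params, tables = tables)
        } else {
          bad <- bad + 1L
          if (bad >= config$patience) break
        }
      }
    }
    if (!is.null(best)) { params <- best$params; tables <- best$tables }

    structure(list(
      params = params, tables = tables, classes = classes,
      config = config, width = width, loss_history = history,
      seed = seed),
      class = "trigger_model")
  })
}

#' @export
print.trigger_model <- function(x, ...) {
  cat("<trigger_model> input width ", x$width, ", layers ",
      paste(c(x$config$hidden, length(x$classes)), collapse = "-"),
      ", ", length(x$classes) - 1L, " trigger types\n", sep = "")
  invisible(x)
}

#' @export
summary.trigger_model <- function(object, ...) {
  cat("Trigger identification network\n")
  cat("  feature width:", object$width, "\n")
  cat("  hidden layers:", paste(object$config$hidden, collapse = ", "), "\n")
  cat("  classes:", length(object$classes), "(incl. negative)\n")
  cat("  epochs run:", length(object$loss_history),
      " final loss:", signif(utils::tail(object$loss_history, 1), 4), "\n")
  invisible(object)
}

#' Predict trigger classes for examples
#'
#' @param object A `trigger_model`.
#' @param examples A [make_trigger_examples()] result built against the
#'   model's dictionary and config.
#' @param type `"class"` for labels, `"prob"` for the softmax matrix.
#' @param ... Unused.
#' @return Character labels or a probability matrix (rows sum to one).
#' @export
predict.trigger_model <- function(object, examples,
                                  type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (trigger_feature_width(examples$config) != object$width)
    stop("feature width mismatch: examples have ",
         trigger_feature_width(examples$config), ", model expects ",
         object$width)
  n <- length(examples$label)
  P <- matrix(numeric(0), 0, length(object$classes))
  for (b in split(seq_len(n), ceiling(seq_len(n) / 4096))) {
    X <- trigger_design(examples, object$tables, b)
    P <- rbind(P, softmax_rows(dense_forward(object$params, X)$logits))
  }
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Predict trigger annotations for documents
#'
#' Classifies every candidate token and materializes the non-negative
#' predictions as trigger annotations spanning the anchor token, with ids
#' numbered after each document's entities.
#'
#' @param model A `trigger_model`.
#' @param sentences Sentences of the documents to annotate.
#' @param docs Named list of documents (entities are needed for the
#'   distance feature).
#' @param dictionary The dictionary the model was built with.
#' @return A data frame of predicted triggers (`doc_id`, `id`, `type`,
#'   `start`, `end`, `text`).
#' @export
predict_triggers <- function(model, sentences, docs, dictionary) {
  ex <- make_trigger_examples(sentences, model$tables, model$config, docs,
                              dictionary)
  cls <- predict(model, ex)
  hit <- cls != NEG_LABEL
  out <- ex$meta[hit, , drop = FALSE]
  out$type <- cls[hit]
  if (!nrow(out)) {
    return(data.frame(doc_id = character(), id = character(),
                      type = character(), start = integer(),
                      end = integer(), text = character(),
                      stringsAsFactors = FALSE))
  }
  res <- lapply(split(out, out$doc_id), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    base <- if (nrow(docs[[d$doc_id[1]]]$entities))
      max(numeric_id(docs[[d$doc_id[1]]]$entities$id)) else 0L
    data.frame(doc_id = d$doc_id, id = id_seq("T", nrow(d), offset = base),
               type = d$type, start = d$start, end = d$end,
               text = d$surface, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
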