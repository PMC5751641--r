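# Argument detection: every ordered (trigger, entity-or-trigger) pair in a
# sentence is a candidate relation. The pair's dependency path is rendered
# as a feature matrix psi(S) — word-embedding columns for the path tokens
# with the two endpoint type embeddings appended, stacked over POS and two
# positional-distance blocks — and classified into a role or the negative
# class by a CNN (parallel filter widths, max-pooling over positions, one
# dense layer, softmax).

#' Argument-model configuration
#'
#' Defaults follow the reference CNN setting: word embedding dimension 50,
#' filter widths 3, 5 and 7, a 1000-unit dense layer, minibatch 128,
#' dropout 0.2, Adadelta. `n_maps` feature maps are learned per filter
#' width. The type embedding width equals `dim` (the type columns live in
#' the word-embedding block). Feature switches support ablation runs; the
#' dependency-path context block is always on.
#'
#' @param dim Word (and type) embedding dimension.
#' @param filters Convolution filter widths (columns covered).
#' @param n_maps Feature maps per filter width.
#' @param dense Dense layer width.
#' @param batch Minibatch size.
#' @param dropout Dropout rate on the dense layer.
#' @param d_pos,d_dis POS and distance embedding widths.
#' @param epochs,patience,validation_frac As in [trigger_config()].
#' @param use_pos,use_distance,use_type Feature ablation switches.
#' @param max_path_len Paths longer than this are truncated symmetrically
#'   around their midpoint.
#' @param max_distance Positional offsets along the path are clipped here.
#' @param train_embeddings Update the word table during training.
#' @return A list of class `argument_config`.
#' @export
argument_config <- function(dim = 50L, filters = c(3L, 5L, 7L),
                            n_maps = 100L, dense = 1000L, batch = 128L,
                            dropout = 0.2, d_pos = 20L, d_dis = 20L,
                            epochs = 30L, patience = 5L,
                            validation_frac = 0.1,
                            use_pos = TRUE, use_distance = TRUE,
                            use_type = TRUE, max_path_len = 20L,
                            max_distance = 10L, train_embeddings = TRUE) {
  structure(list(
    dim = as.integer(dim), filters = as.integer(filters),
    n_maps = as.integer(n_maps), dense = as.integer(dense),
    batch = as.integer(batch), dropout = dropout,
    d_pos = as.integer(d_pos), d_dis = as.integer(d_dis),
    epochs = as.integer(epochs), patience = as.integer(patience),
    validation_frac = validation_frac,
    use_pos = use_pos, use_distance = use_distance, use_type = use_type,
    max_path_len = as.integer(max_path_len),
    max_distance = as.integer(max_distance),
    train_embeddings = train_embeddings),
    class = "argument_config")
}

# Row count of psi(S) under the ablation switches.
argument_feature_rows <- function(config) {
  config$dim +
    (if (config$use_pos) config$d_pos else 0L) +
    (if (config$use_distance) 2L * config$d_dis else 0L)
}

#' Build the lookup tables for the argument model
#'
#' @inheritParams trigger_tables
#' @param config An [argument_config()].
#' @return A list of tables (`word`, `pos`, `dis`, `type`); the type table
#'   width equals the word embedding width.
#' @export
argument_tables <- function(dictionary, config, seed = 1L,
                            word_table = NULL) {
  if (is.null(word_table))
    word_table <- load_word_embeddings(NULL, dictionary, dim = config$dim,
                                       seed = derive_seed(seed, "arg-word"),
                                       trainable = config$train_embeddings)
  if (word_table$dim != config$dim)
    stop("word table width ", word_table$dim, " != config dim ", config$dim)
  word_table$trainable <- config$train_embeddings
  list(
    word = word_table,
    pos = embedding_table(dictionary$pos, config$d_pos,
                          derive_seed(seed, "arg-pos")),
    dis = embedding_table(dictionary$dist, config$d_dis,
                          derive_seed(seed, "arg-dis")),
    type = embedding_table(dictionary$type, config$dim,
                           derive_seed(seed, "arg-type")))
}

#' Enumerate candidate trigger-argument pairs in a sentence
#'
#' All ordered pairs with a trigger as source and an entity or another
#' trigger as target; self-pairs are excluded.
#'
#' @param sentence A `sentence`.
#' @param triggers,entities Data frames of annotations (id, type, start,
#'   end) restricted to this sentence's document; only rows whose ids
#'   appear in the sentence are used.
#' @return A data frame with columns `source_id`, `source_type`,
#'   `target_id`, `target_type`, `target_kind`.
#' @export
candidate_pairs <- function(sentence, triggers, entities) {
  tr <- triggers[triggers$id %in% sentence$trigger_ids, , drop = FALSE]
  en <- entities[entities$id %in% sentence$entity_ids, , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(tr))) {
    tgt_t <- tr[tr$id != tr$id[i], , drop = FALSE]
    if (nrow(en))
      out[[length(out) + 1L]] <- data.frame(
        source_id = tr$id[i], source_type = tr$type[i],
        target_id = en$id, target_type = en$type, target_kind = "entity",
        stringsAsFactors = FALSE)
    if (nrow(tgt_t))
      out[[length(out) + 1L]] <- data.frame(
        source_id = tr$id[i], source_type = tr$type[i],
        target_id = tgt_t$id, target_type = tgt_t$type,
        target_kind = "trigger", stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(source_id = character(), source_type = character(),
                      target_id = character(), target_type = character(),
                      target_kind = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Symmetric-around-midpoint truncation of an over-long path.
truncate_path <- function(path, maxlen) {
  n <- length(path)
  if (n <= maxlen) return(path)
  head_n <- ceiling(maxlen / 2)
  c(path[seq_len(head_n)], path[(n - (maxlen - head_n) + 1L):n])
}

#' Build the dependency-path feature matrix psi(S) for one pair
#'
#' Rows stack the word-embedding block (width `dim`, with the two endpoint
#' type-embedding columns appended), the POS block and the two positional
#' distance blocks; every non-word block carries padding entries in the
#' two type columns, so the matrix is `(dim + d_pos + 2 d_dis)` rows by
#' `n + 2` columns for a path of `n` tokens. Disconnected parses fall back
#' to the linear token sequence (flagged `"fallback"`).
#'
#' @param sentence A `sentence`.
#' @param a_idx,b_idx Anchor token indices of the source trigger and the
#'   target.
#' @param a_type,b_type Annotation types of the two endpoints.
#' @param tables [argument_tables()] output.
#' @param config An [argument_config()].
#' @param dictionary The dictionary in use.
#' @return A numeric matrix; attribute `"path"` holds the token indices.
#' @export
build_path_matrix <- function(sentence, a_idx, b_idx, a_type, b_type,
                              tables, config, dictionary) {
  path <- dependency_path(sentence, a_idx, b_idx)
  fb <- isTRUE(attr(path, "fallback"))
  path <- truncate_path(as.integer(path), config$max_path_len)
  n <- length(path)
  words <- norm_word(sentence$tokens$surface[path])
  widx <- lookup_index(dictionary$word, words)
  tidx <- lookup_index(dictionary$type, c(a_type, b_type))
  word_block <- cbind(t(tables$word$mat[widx, , drop = FALSE]),
                      if (config$use_type)
                        t(tables$type$mat[tidx, , drop = FALSE])
                      else t(tables$word$mat[c(2L, 2L), , drop = FALSE]))
  blocks <- list(word_block)
  pad2 <- function(tab, idx) {
    cbind(t(tab$mat[idx, , drop = FALSE]), tab$mat[2L, ], tab$mat[2L, ])
  }
  if (config$use_pos) {
    pidx <- lookup_index(dictionary$pos, sentence$tokens$pos[path])
    blocks <- c(blocks, list(pad2(tables$pos, pidx)))
  }
  if (config$use_distance) {
    d1 <- pmin(seq_len(n) - 1L, config$max_distance)
    d2 <- pmin(n - seq_len(n), config$max_distance)
    blocks <- c(blocks,
                list(pad2(tables$dis, lookup_index(dictionary$dist,
                                                   as.character(d1)))),
                list(pad2(tables$dis, lookup_index(dictionary$dist,
                                                   as.character(d2)))))
  }
  out <- do.call(rbind, blocks)
  dimnames(out) <- NULL
  attr(out, "path") <- path
  attr(out, "fallback") <- fb
  out
}

# Gold (trigger_id, filler_id) -> role relations implied by a document's
# events; event-valued fillers are resolved to the filler event's trigger.
gold_relations <- function(doc) {
  ev_trig <- setNames(vapply(doc$events, `[[`, "", "trigger_id"),
                      vapply(doc$events, `[[`, "", "id"))
  rel <- list()
  for (ev in doc$events) {
    if (!nrow(ev$args)) next
    filler <- ifelse(ev$args$filler %in% names(ev_trig),
                     ev_trig[ev$args$filler], ev$args$filler)
    rel[[length(rel) + 1L]] <- data.frame(
      source_id = ev$trigger_id, target_id = unname(filler),
      role = ev$args$role, stringsAsFactors = FALSE)
  }
  if (!length(rel))
    return(data.frame(source_id = character(), target_id = character(),
                      role = character(), stringsAsFactors = FALSE))
  unique(do.call(rbind, rel))
}

#' Build argument classification examples
#'
#' Enumerates candidate pairs per sentence (gold or predicted triggers),
#' extracts each pair's dependency path and stores the index structure of
#' psi(S); labels come from the documents' gold events (relations whose
#' role is not annotated are negative).
#'
#' @param sentences Sentences from [attach_parse()].
#' @param tables [argument_tables()] output.
#' @param config An [argument_config()].
#' @param docs Named list of documents (entities + gold events).
#' @param dictionary The dictionary in use.
#' @param triggers Optional data frame of predicted triggers (`doc_id`,
#'   `id`, `type`, `start`, `end`); defaults to each document's gold
#'   triggers.
#' @return An `argument_examples` object.
#' @export
make_argument_examples <- function(sentences, tables, config, docs,
                                   dictionary, triggers = NULL) {
  L <- config$max_path_len
  rows <- list(); meta <- list()
  for (s in sentences) {
    doc <- docs[[s$doc_id]]
    trig <- if (is.null(triggers)) doc$triggers
            else triggers[triggers$doc_id == s$doc_id, , drop = FALSE]
    s_local <- s
    # recompute in-sentence trigger ids against the trigger set in use
    s_local$trigger_ids <- trig$id[trig$start < s$sent_end &
                                   trig$end > s$sent_start]
    pairs <- candidate_pairs(s_local, trig, doc$entities)
    if (!nrow(pairs)) next
    gold <- gold_relations(doc)
    span_of <- function(id, kind) {
      src <- if (kind == "entity") doc$entities else trig
      src[src$id == id, , drop = FALSE]
    }
    for (i in seq_len(nrow(pairs))) {
      p <- pairs[i, ]
      sa <- span_of(p$source_id, "trigger")
      sb <- span_of(p$target_id, p$target_kind)
      a <- anchor_annotation(s, sa$start, sa$end)
      b <- anchor_annotation(s, sb$start, sb$end)
      path <- truncate_path(as.integer(dependency_path(s, a, b)), L)
      n <- length(path)
      widx <- rep(2L, L); pidx <- rep(2L, L)
      d1 <- rep(2L, L); d2 <- rep(2L, L)
      widx[seq_len(n)] <- lookup_index(dictionary$word,
                                       norm_word(s$tokens$surface[path]))
      pidx[seq_len(n)] <- lookup_index(dictionary$pos, s$tokens$pos[path])
      d1[seq_len(n)] <- lookup_index(dictionary$dist,
        as.character(pmin(seq_len(n) - 1L, config$max_distance)))
      d2[seq_len(n)] <- lookup_index(dictionary$dist,
        as.character(pmin(n - seq_len(n), config$max_distance)))
      lab <- gold$role[gold$source_id == p$source_id &
                       gold$target_id == p$target_id]
      rows[[length(rows) + 1L]] <- list(
        widx = widx, pidx = pidx, d1 = d1, d2 = d2, len = n,
        t1 = lookup_index(dictionary$type, p$source_type),
        t2 = lookup_index(dictionary$type, p$target_type),
        label = if (length(lab)) lab[1] else NEG_LABEL)
      meta[[length(meta) + 1L]] <- data.frame(
        doc_id = s$doc_id, sentence = s$index,
        source_id = p$source_id, source_type = p$source_type,
        target_id = p$target_id, target_type = p$target_type,
        target_kind = p$target_kind, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(structure(list(
      widx = matrix(integer(), 0, L), pidx = matrix(integer(), 0, L),
      d1 = matrix(integer(), 0, L), d2 = matrix(integer(), 0, L),
      len = integer(), t1 = integer(), t2 = integer(), label = character(),
      meta = data.frame(), tables = tables, config = config),
      class = "argument_examples"))
  structure(list(
    widx = do.call(rbind, lapply(rows, `[[`, "widx")),
    pidx = do.call(rbind, lapply(rows, `[[`, "pidx")),
    d1 = do.call(rbind, lapply(rows, `[[`, "d1")),
    d2 = do.call(rbind, lapply(rows, `[[`, "d2")),
    len = vapply(rows, `[[`, 1L, "len"),
    t1 = vapply(rows, `[[`, 1L, "t1"),
    t2 = vapply(rows, `[[`, 1L, "t2"),
    label = vapply(rows, `[[`, "", "label"),
    meta = do.call(rbind, meta),
    tables = tables, config = config),
    class = "argument_examples")
}

#' @export
print.argument_examples <- function(x, ...) {
  cat("<argument_examples> ", length(x$label), " pairs, ",
      sum(x$label != NEG_LABEL), " positive\n", sep = "")
  invisible(x)
}

# Assemble the (R, L, B) input array for a batch from the current tables.
# Internal column layout: path columns 1..L-2 (padded), type columns at
# L-1 and L — a fixed-position rearrangement of the canonical psi(S).
argument_input_array <- function(ex, tables, idx) {
  cfg <- ex$config
  Lp <- cfg$max_path_len       # path columns
  L <- Lp + 2L                 # + two type columns
  B <- length(idx)
  gather <- function(tab, im) {
    M <- tab$mat[as.vector(t(im[idx, , drop = FALSE])), , drop = FALSE]
    array(t(M), c(ncol(tab$mat), Lp, B))
  }
  R <- argument_feature_rows(cfg)
  A <- array(0, c(R, L, B))
  A[seq_len(cfg$dim), seq_len(Lp), ] <- gather(tables$word, ex$widx)
  if (cfg$use_type) {
    A[seq_len(cfg$dim), Lp + 1L, ] <- t(tables$type$mat[ex$t1[idx], ,
                                                        drop = FALSE])
    A[seq_len(cfg$dim), Lp + 2L, ] <- t(tables$type$mat[ex$t2[idx], ,
                                                        drop = FALSE])
  } else {
    A[seq_len(cfg$dim), Lp + 1L, ] <- tables$word$mat[2L, ]
    A[seq_len(cfg$dim), Lp + 2L, ] <- tables$word$mat[2L, ]
  }
  r0 <- cfg$dim
  if (cfg$use_pos) {
    A[r0 + seq_len(cfg$d_pos), seq_len(Lp), ] <- gather(tables$pos, ex$pidx)
    A[r0 + seq_len(cfg$d_pos), Lp + 1L, ] <- tables$pos$mat[2L, ]
    A[r0 + seq_len(cfg$d_pos), Lp + 2L, ] <- tables$pos$mat[2L, ]
    r0 <- r0 + cfg$d_pos
  }
  if (cfg$use_distance) {
    for (blk in list(ex$d1, ex$d2)) {
      A[r0 + seq_len(cfg$d_dis), seq_len(Lp), ] <- gather(tables$dis, blk)
      A[r0 + seq_len(cfg$d_dis), Lp + 1L, ] <- tables$dis$mat[2L, ]
      A[r0 + seq_len(cfg$d_dis), Lp + 2L, ] <- tables$dis$mat[2L, ]
      r0 <- r0 + cfg$d_dis
    }
  }
  A
}

# CNN forward over the column axis: for each filter width k, ReLU(conv)
# then max over positions, giving B x n_maps per width; widths are
# concatenated into the pooled representation.
cnn_forward <- function(cnn, A, cfg, dropout = 0, train = FALSE) {
  R <- dim(A)[1]; L <- dim(A)[2]; B <- dim(A)[3]
  pooled <- NULL; caches <- vector("list", length(cfg$filters))
  for (f in seq_along(cfg$filters)) {
    k <- cfg$filters[f]
    p <- L - k + 1L
    Z <- matrix(0, B * p, cfg$n_maps)
    Ms <- vector("list", p)
    for (j in seq_len(p)) {
      Mj <- t(matrix(A[, j:(j + k - 1L), , drop = FALSE], R * k, B))
      Ms[[j]] <- Mj
      Z[(j - 1L) * B + seq_len(B), ] <-
        Mj %*% cnn$F[[f]] + rep(cnn$bF[[f]], each = B)
    }
    Zr <- relu(Z)
    # positions run over rows in blocks of B; reshape to B x p per map
    pool <- matrix(-Inf, B, cfg$n_maps); amax <- matrix(1L, B, cfg$n_maps)
    for (j in seq_len(p)) {
      Zj <- Zr[(j - 1L) * B + seq_len(B), , drop = FALSE]
      upd <- Zj > pool
      amax[upd] <- j
      pool[upd] <- Zj[upd]
    }
    caches[[f]] <- list(Ms = Ms, Z = Z, amax = amax, p = p, k = k)
    pooled <- cbind(pooled, pool)
  }
  fwd <- dense_forward(cnn$dense, pooled, dropout, train)
  list(logits = fwd$logits, dense_cache = fwd, pooled = pooled,
       conv = caches)
}

# Backward pass; returns grads for filters and dense stack plus dA.
cnn_backward <- function(cnn, cache, A, dlogits, cfg) {
  R <- dim(A)[1]; L <- dim(A)[2]; B <- dim(A)[3]
  dn <- dense_backward(cnn$dense, cache$dense_cache, dlogits)
  dpooled <- dn$dX
  dF <- vector("list", length(cfg$filters))
  dbF <- vector("list", length(cfg$filters))
  dA <- array(0, dim(A))
  col0 <- 0L
  for (f in seq_along(cfg$filters)) {
    cc <- cache$conv[[f]]
    dp <- dpooled[, col0 + seq_len(cfg$n_maps), drop = FALSE]
    col0 <- col0 + cfg$n_maps
    dFf <- matrix(0, R * cc$k, cfg$n_maps); dbf <- numeric(cfg$n_maps)
    for (j in seq_len(cc$p)) {
      sel <- cc$amax == j
      if (!any(sel)) next
      Zj <- cc$Z[(j - 1L) * B + seq_len(B), , drop = FALSE]
      dZj <- dp * sel * (Zj > 0)
      dFf <- dFf + crossprod(cc$Ms[[j]], dZj)
      dbf <- dbf + colSums(dZj)
      dMj <- dZj %*% t(cnn$F[[f]])                   # B x (R k)
      dA[, j:(j + cc$k - 1L), ] <- dA[, j:(j + cc$k - 1L), , drop = FALSE] +
        array(t(dMj), c(R, cc$k, B))
    }
    dF[[f]] <- dFf; dbF[[f]] <- dbf
  }
  list(F = dF, bF = dbF, dense = list(W = dn$W, b = dn$b), dA = dA)
}

#' Train the argument detection CNN
#'
#' Fits the convolutional role classifier by minibatch Adadelta with
#' dropout on the dense layer; the POS, distance and type tables (and, by
#' default, the word table) receive gradient updates through the
#' convolution. Deterministic for a fixed seed.
#'
#' @param examples A [make_argument_examples()] result with gold labels.
#' @param config An [argument_config()]; defaults to the examples' config.
#' @param seed Integer seed.
#' @return An `argument_model` object.
#' @export
train_argument_model <- function(examples, config = examples$config,
                                 seed = 1L) {
  labels <- examples$label
  classes <- c(sort(setdiff(unique(labels), NEG_LABEL)), NEG_LABEL)
  if (length(classes) < 2)
    stop("training needs at least two classes")
  y <- match(labels, classes)
  n <- length(y)
  tables <- examples$tables
  cfg <- config
  R <- argument_feature_rows(cfg)

  with_seed(derive_seed(seed, "argument-train"), {
    cnn <- list(
      F = lapply(cfg$filters, function(k) {
        r <- sqrt(6 / (R * k + cfg$n_maps))
        matrix(stats::runif(R * k * cfg$n_maps, -r, r), R * k, cfg$n_maps)
      }),
      bF = lapply(cfg$filters, function(k) numeric(cfg$n_maps)),
      dense = dense_init(c(length(cfg$filters) * cfg$n_maps, cfg$dense,
                           length(classes))))
    opt <- adadelta_state(cnn)
    opt_tab <- lapply(tables[c("word", "pos", "dis", "type")],
                      function(tb) adadelta_state(tb$mat))

    val_idx <- integer(0)
    if (cfg$patience > 0 && cfg$validation_frac > 0 && n >= 20)
      val_idx <- sample.int(n, max(1L, floor(cfg$validation_frac * n)))
    train_idx <- setdiff(seq_len(n), val_idx)

    history <- numeric(0); best_val <- Inf; best <- NULL; bad <- 0L
    Lp <- cfg$max_path_len

    scatter <- function(name, G) {
      r <- adadelta_apply(tables[[name]]$mat, G, opt_tab[[name]])
      tables[[name]]$mat <<- r$param; opt_tab[[name]] <<- r$state
    }

    for (epoch in seq_len(cfg$epochs)) {
      ep_loss <- 0; nb <- 0L
      for (b in minibatches(length(train_idx), cfg$batch)) {
        idx <- train_idx[b]; B <- length(idx)
        A <- argument_input_array(examples, tables, idx)
        fwd <- cnn_forward(cnn, A, cfg, cfg$dropout, train = TRUE)
        sx <- softmax_xent(fwd$logits, y[idx])
        ep_loss <- ep_loss + sx$loss; nb <- nb + 1L
        bwd <- cnn_backward(cnn, fwd, A, sx$dlogits, cfg)
        up <- adadelta_step(cnn, list(F = bwd$F, bF = bwd$bF,
                                      dense = bwd$dense), opt)
        cnn <- up$params; opt <- up$state
        # table gradients from dA; the path block indexes vary per example
        dA <- bwd$dA
        flat <- function(rows, cols)
          t(matrix(dA[rows, cols, , drop = FALSE],
                   length(rows) * length(cols), B))
        path_grad <- function(rows, im) {
          # (B*Lp) x width contribution matrix aligned with im[idx, ] rows
          Gc <- matrix(aperm(dA[rows, seq_len(Lp), , drop = FALSE],
                             c(1, 3, 2)), length(rows), B * Lp)
          # columns ordered b fastest then j -> align with t(im) vector?
          # aperm dims: rows x B x Lp; flatten cols iterate b then j
          t(Gc)
        }
        if (tables$word$trainable) {
          rows <- seq_len(cfg$dim)
          contrib <- path_grad(rows, examples$widx)
          wids <- as.vector(examples$widx[idx, , drop = FALSE]) # b fastest
          G <- accumulate_rows(tables$word$mat * 0, wids, contrib)
          scatter("word", G)
        }
        if (cfg$use_type) {
          rows <- seq_len(cfg$dim)
          G <- accumulate_rows(tables$type$mat * 0, examples$t1[idx],
                               flat(rows, Lp + 1L))
          G <- accumulate_rows(G, examples$t2[idx], flat(rows, Lp + 2L))
          scatter("type", G)
        }
        r0 <- cfg$dim
        if (cfg$use_pos) {
          rows <- r0 + seq_len(cfg$d_pos)
          G <- accumulate_rows(tables$pos$mat * 0,
                               as.vector(examples$pidx[idx, , drop = FALSE]),
                               path_grad(rows, examples$pidx))
          scatter("pos", G)
          r0 <- r0 + cfg$d_pos
        }
        if (cfg$use_distance) {
          G <- tables$dis$mat * 0
          for (blk in list(examples$d1, examples$d2)) {
            rows <- r0 + seq_len(cfg$d_dis)
            G <- accumulate_rows(G, as.vector(blk[idx, , drop = FALSE]),
                                 path_grad(rows, blk))
            r0 <- r0 + cfg$d_dis
          }
          scatter("dis", G)
        }
      }
      history <- c(history, ep_loss / max(nb, 1L))
      if (length(val_idx)) {
        Av <- argument_input_array(examples, tables, val_idx)
        vl <- softmax_xent(cnn_forward(cnn, Av, cfg)$logits,
                           y[val_idx])$loss
        if (vl < best_val - 1e-6) {
          best_val <- vl; bad <- 0L
          best <- list(cnn = cnn, tables = tables)
        } else {
          bad <- bad + 1L
          if (bad >= cfg$patience) break
        }
      }
    }
    if (!is.null(best)) { cnn <- best$cnn; tables <- best$tables }

    structure(list(
      cnn = cnn, tables = tables, classes = classes, config = cfg,
      rows = R, loss_history = history, seed = seed),
      class = "argument_model")
  })
}

#' @export
print.argument_model <- function(x, ...) {
  cat("<argument_model> psi(S) rows ", x$rows, ", filters [",
      paste(x$config$filters, collapse = ", "), "] x ", x$config$n_maps,
      " maps, ", length(x$classes) - 1L, " roles\n", sep = "")
  invisible(x)
}

#' @export
summary.argument_model <- function(object, ...) {
  cat("Argument detection CNN\n")
  cat("  feature rows:", object$rows, " filters:",
      paste(object$config$filters, collapse = ","),
      " maps/width:", object$config$n_maps, "\n")
  cat("  roles:", paste(setdiff(object$classes, NEG_LABEL),
                        collapse = ", "), "\n")
  cat("  epochs run:", length(object$loss_history),
      " final loss:", signif(utils::tail(object$loss_history, 1), 4), "\n")
  invisible(object)
}

#' Predict role labels for argument examples
#'
#' @param object An `argument_model`.
#' @param examples A [make_argument_examples()] result.
#' @param type `"class"` or `"prob"`.
#' @param ... Unused.
#' @return Character labels or a softmax probability matrix.
#' @export
predict.argument_model <- function(object, examples,
                                   type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (argument_feature_rows(examples$config) != object$rows)
    stop("feature row mismatch: examples have ",
         argument_feature_rows(examples$config), ", model expects ",
         object$rows)
  n <- length(examples$label)
  if (!n) {
    P <- matrix(numeric(0), 0, length(object$classes),
                dimnames = list(NULL, object$classes))
    return(if (type == "prob") P else character(0))
  }
  P <- NULL
  for (b in split(seq_len(n), ceiling(seq_len(n) / 1024))) {
    A <- argument_input_array(examples, object$tables, b)
    P <- rbind(P, softmax_rows(cnn_forward(object$cnn, A,
                                           object$config)$logits))
  }
  colnames(P) <- object$classes
  if (type == "prob") return(P)
  object$classes[max.col(P, ties.method = "first")]
}

#' Predict labeled relations for documents
#'
#' @param model An `argument_model`.
#' @param examples A [make_argument_examples()] result (built with gold or
#'   predicted triggers).
#' @return A data frame of positive relations: `doc_id`, `source_id`,
#'   `target_id`, `target_kind`, `role`, `prob`.
#' @export
predict_arguments <- function(model, examples) {
  if (!length(examples$label))
    return(data.frame(doc_id = character(), source_id = character(),
                      target_id = character(), target_kind = character(),
                      role = character(), prob = numeric(),
                      stringsAsFactors = FALSE))
  P <- predict(model, examples, type = "prob")
  cls <- model$classes[max.col(P, ties.method = "first")]
  hit <- cls != NEG_LABEL
  out <- examples$meta[hit, c("doc_id", "source_id", "target_id",
                              "target_kind"), drop = FALSE]
  out$role <- cls[hit]
  out$prob <- P[cbind(which(hit), match(cls[hit], model$classes))]
  rownames(out) <- NULL
  out
}
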