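# Scoring against gold: approximate span matching for triggers and
# approximate recursive matching for events, aggregated into per-class and
# micro precision/recall/F-score.

# Token-extension window of a gold span: the span widened to the start of
# the token preceding it and the end of the token following it, within the
# sentence that contains it.
extended_span <- function(start, end, sentences) {
  for (s in sentences) {
    tok <- s$tokens
    hit <- which(tok$start < end & tok$end > start)
    if (!length(hit)) next
    lo <- if (hit[1] > 1) tok$start[hit[1] - 1L] else tok$start[hit[1]]
    hi <- if (hit[length(hit)] < nrow(tok)) tok$end[hit[length(hit)] + 1L]
          else tok$end[length(tok$end)]
    return(c(lo, hi))
  }
  c(start, end)
}

#' Approximate span match between a gold and a predicted annotation
#'
#' True iff the types are equal and the predicted span lies within the
#' gold span extended by one token on each side (tokenization taken from
#' the document's parsed sentences).
#'
#' @param gold,pred Single-row span records with `type`, `start`, `end`.
#' @param sentences The document's sentences from [attach_parse()].
#' @return `TRUE` or `FALSE`.
#' @export
span_match <- function(gold, pred, sentences) {
  if (!identical(gold$type, pred$type)) return(FALSE)
  ext <- extended_span(gold$start, gold$end, sentences)
  pred$start >= ext[1] && pred$end <= ext[2]
}

#' Matching context for event comparison
#'
#' @param gold_doc,pred_doc The two documents.
#' @param sentences Parsed sentences of the document (shared text).
#' @param core_roles Roles treated as core when recursing into an
#'   event-valued filler (the BioNLP convention restricts the recursive
#'   comparison to Theme).
#' @param recursive_core_only Apply that restriction (default `TRUE`).
#' @return A `match_context` list.
#' @export
match_context <- function(gold_doc, pred_doc, sentences,
                          core_roles = "Theme",
                          recursive_core_only = TRUE) {
  structure(list(gold_doc = gold_doc, pred_doc = pred_doc,
                 sentences = sentences, core_roles = core_roles,
                 recursive_core_only = recursive_core_only),
            class = "match_context")
}

ann_by_id <- function(doc, id) {
  if (grepl("^E", id)) {
    for (ev in doc$events) if (ev$id == id) return(ev)
    return(NULL)
  }
  sp <- rbind(doc$entities, doc$triggers)
  r <- sp[sp$id == id, , drop = FALSE]
  if (nrow(r)) r else NULL
}

filler_match <- function(gold_id, pred_id, ctx) {
  g_ev <- grepl("^E", gold_id); p_ev <- grepl("^E", pred_id)
  if (g_ev != p_ev) return(FALSE)
  if (g_ev) {
    ge <- ann_by_id(ctx$gold_doc, gold_id)
    pe <- ann_by_id(ctx$pred_doc, pred_id)
    if (is.null(ge) || is.null(pe)) return(FALSE)
    return(event_match(ge, pe, ctx, nested = TRUE))
  }
  gs <- ann_by_id(ctx$gold_doc, gold_id)
  ps <- ann_by_id(ctx$pred_doc, pred_id)
  if (is.null(gs) || is.null(ps)) return(FALSE)
  span_match(gs, ps, ctx$sentences)
}

#' Approximate recursive event match
#'
#' True iff the event types are equal, the triggers match under
#' [span_match()], and there is a one-to-one correspondence between the
#' gold and predicted argument lists under which roles are equal and
#' fillers match — entities by type and approximate span, event fillers
#' recursively (restricted to core arguments of the filler when the
#' context says so). The correspondence is found by backtracking search
#' over role-compatible assignments.
#'
#' @param gold,pred Events (lists with `type`, `trigger_id`, `args`).
#' @param ctx A [match_context()].
#' @param nested Internal: `TRUE` when matching an event-valued filler.
#' @return `TRUE` or `FALSE`.
#' @export
event_match <- function(gold, pred, ctx, nested = FALSE) {
  if (!identical(gold$type, pred$type)) return(FALSE)
  gt <- ann_by_id(ctx$gold_doc, gold$trigger_id)
  pt <- ann_by_id(ctx$pred_doc, pred$trigger_id)
  if (is.null(gt) || is.null(pt) || !span_match(gt, pt, ctx$sentences))
    return(FALSE)
  ga <- gold$args; pa <- pred$args
  if (nested && ctx$recursive_core_only) {
    ga <- ga[ga$role %in% ctx$core_roles, , drop = FALSE]
    pa <- pa[pa$role %in% ctx$core_roles, , drop = FALSE]
  }
  if (nrow(ga) != nrow(pa)) return(FALSE)
  if (!nrow(ga)) return(TRUE)
  if (!identical(sort(ga$role), sort(pa$role))) return(FALSE)
  # backtracking search for a perfect argument bijection
  used <- logical(nrow(pa))
  assign_arg <- function(i) {
    if (i > nrow(ga)) return(TRUE)
    for (j in seq_len(nrow(pa))) {
      if (used[j] || ga$role[i] != pa$role[j]) next
      if (filler_match(ga$filler[i], pa$filler[j], ctx)) {
        used[j] <<- TRUE
        if (assign_arg(i + 1L)) return(TRUE)
        used[j] <<- FALSE
      }
    }
    FALSE
  }
  assign_arg(1L)
}

prf <- function(tp, fp, fn) {
  tp <- unname(tp); fp <- unname(fp); fn <- unname(fn)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = 100 * p, recall = 100 * r, fscore = 100 * f)
}

#' Score predicted documents against gold
#'
#' Within each document, predictions (sorted by offset, ties by id) are
#' greedily matched one-to-one to gold annotations — each gold item is
#' consumed by at most one prediction. Matching uses [span_match()] in
#' `"trigger"` mode and [event_match()] in `"event"` mode. Counts are
#' aggregated per class (trigger/event type) and micro-averaged;
#' precision, recall and F-score are reported as percentages, with an
#' undefined ratio reported as 0.
#'
#' @param gold_docs,pred_docs Named lists of documents with identical
#'   names (document ids).
#' @param parses Named list of parsed sentence lists (one per document).
#' @param mode `"trigger"` or `"event"`.
#' @param recursive_core_only Passed to [match_context()].
#' @return An `eval_report`: data frame of per-class and micro rows.
#' @export
score_predictions <- function(gold_docs, pred_docs, parses,
                              mode = c("trigger", "event"),
                              recursive_core_only = TRUE) {
  mode <- match.arg(mode)
  if (!setequal(names(gold_docs), names(pred_docs)))
    stop("document id mismatch between gold and predicted sets")
  counts <- list()
  bump <- function(cls, slot) {
    if (is.null(counts[[cls]])) counts[[cls]] <<- c(tp = 0, fp = 0, fn = 0)
    counts[[cls]][slot] <<- counts[[cls]][slot] + 1
  }
  for (id in names(gold_docs)) {
    g <- gold_docs[[id]]; p <- pred_docs[[id]]
    ctx <- match_context(g, p, parses[[id]],
                         recursive_core_only = recursive_core_only)
    if (mode == "trigger") {
      gi <- g$triggers; pi <- p$triggers
      pi <- pi[order(pi$start, pi$end, numeric_id(pi$id)), , drop = FALSE]
      taken <- logical(nrow(gi))
      for (i in seq_len(nrow(pi))) {
        hit <- FALSE
        for (j in seq_len(nrow(gi))) {
          if (!taken[j] && span_match(gi[j, ], pi[i, ], ctx$sentences)) {
            taken[j] <- TRUE; hit <- TRUE; break
          }
        }
        bump(pi$type[i], if (hit) "tp" else "fp")
      }
      for (j in which(!taken)) bump(gi$type[j], "fn")
    } else {
      gi <- g$events; pi <- p$events
      tr_start <- function(doc, ev)
        doc$triggers$start[doc$triggers$id == ev$trigger_id][1]
      ord <- order(vapply(pi, function(e) tr_start(p, e), 0),
                   numeric_id(vapply(pi, `[[`, "", "id")))
      pi <- pi[ord]
      taken <- logical(length(gi))
      for (pe in pi) {
        hit <- FALSE
        for (j in seq_along(gi)) {
          if (!taken[j] && event_match(gi[[j]], pe, ctx)) {
            taken[j] <- TRUE; hit <- TRUE; break
          }
        }
        bump(pe$type, if (hit) "tp" else "fp")
      }
      for (j in which(!taken)) bump(gi[[j]]$type, "fn")
    }
  }
  cls <- sort(names(counts))
  rows <- lapply(cls, function(k) {
    ct <- counts[[k]]
    data.frame(class = k, tp = ct["tp"], fp = ct["fp"], fn = ct["fn"],
               t(prf(ct["tp"], ct["fp"], ct["fn"])), row.names = NULL)
  })
  tot <- if (length(counts)) colSums(do.call(rbind, counts))
         else c(tp = 0, fp = 0, fn = 0)
  rows <- c(rows, list(data.frame(
    class = "micro", tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]],
    t(prf(tot[["tp"]], tot[["fp"]], tot[["fn"]])), row.names = NULL)))
  rep <- do.call(rbind, rows)
  structure(rep, mode = mode, class = c("eval_report", "data.frame"))
}

#' @export
print.eval_report <- function(x, digits = 2, ...) {
  cat("Evaluation report (", attr(x, "mode"), " mode, approximate ",
      if (attr(x, "mode") == "event") "recursive " else "span ",
      "matching)\n", sep = "")
  y <- as.data.frame(x)
  y$precision <- round(y$precision, digits)
  y$recall <- round(y$recall, digits)
  y$fscore <- round(y$fscore, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Micro-averaged scores of a report
#'
#' @param report An `eval_report`.
#' @return Named numeric vector (`precision`, `recall`, `fscore`).
#' @export
micro_scores <- function(report) {
  m <- report[report$class == "micro", ]
  c(precision = m$precision, recall = m$recall, fscore = m$fscore)
}
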