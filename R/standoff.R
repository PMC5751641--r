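# BioNLP Shared Task standoff annotation I/O.
#
# A corpus document is three files sharing a basename: <id>.txt holds the
# raw text, <id>.a1 the given entities (one "Tn<TAB>TYPE START END<TAB>TEXT"
# line each), and <id>.a2 the predicted/gold analysis: further T-lines for
# event triggers plus E-lines "En<TAB>TYPE:Tm ROLE1:ID1 ...". Character
# offsets are 0-based, half-open [start, end). Discontinuous spans
# (semicolon-separated offsets) are out of scope and rejected.

#' Construct an annotated document
#'
#' Bundles a document's text with its standoff annotations and validates
#' them: every span must slice the text to exactly its surface string,
#' identifiers must be unique, every event's trigger and argument fillers
#' must resolve, and no event may (transitively) contain itself.
#'
#' @param doc_id Document identifier (file basename).
#' @param text Full document text, a single string.
#' @param entities,triggers Data frames with columns `id`, `type`, `start`,
#'   `end`, `text`; offsets 0-based half-open. Triggers use the event-type
#'   inventory.
#' @param events List of events, each a list with `id`, `type`,
#'   `trigger_id`, and `args`, a data frame with columns `role` and
#'   `filler` (entity `T*` or event `E*` identifiers).
#' @return An object of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, text, entities = empty_spans(),
                               triggers = empty_spans(), events = list()) {
  doc <- structure(
    list(doc_id = doc_id, text = text,
         entities = as_span_frame(entities),
         triggers = as_span_frame(triggers),
         events = events),
    class = "annotated_document")
  validate_document(doc)
  doc
}

empty_spans <- function() {
  data.frame(id = character(), type = character(), start = integer(),
             end = integer(), text = character(), stringsAsFactors = FALSE)
}

as_span_frame <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("id", "type", "start", "end", "text")
  if (!all(need %in% names(x)))
    stop("span table must have columns ", paste(need, collapse = ", "))
  x <- x[need]
  x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  rownames(x) <- NULL
  x
}

slice_text <- function(text, start, end) substr(text, start + 1L, end)

validate_spans <- function(spans, text, what) {
  if (nrow(spans) == 0) return(invisible(TRUE))
  n <- nchar(text)
  for (i in seq_len(nrow(spans))) {
    s <- spans[i, ]
    if (is.na(s$start) || is.na(s$end) || s$start < 0 || s$start >= s$end ||
        s$end > n)
      stop("span validation failed for ", what, " ", s$id,
           ": offsets [", s$start, ",", s$end, ") invalid for text of length ", n)
    got <- slice_text(text, s$start, s$end)
    if (!identical(got, s$text))
      stop("span validation failed for ", what, " ", s$id, ": text slice ",
           dQuote(got), " != annotated surface ", dQuote(s$text))
  }
  invisible(TRUE)
}

validate_document <- function(doc) {
  ids <- c(doc$entities$id, doc$triggers$id,
           vapply(doc$events, `[[`, "", "id"))
  if (anyDuplicated(ids))
    stop("duplicate annotation id(s) in ", doc$doc_id, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  validate_spans(doc$entities, doc$text, "entity")
  validate_spans(doc$triggers, doc$text, "trigger")
  ev_ids <- vapply(doc$events, `[[`, "", "id")
  fillable <- c(doc$entities$id, doc$triggers$id, ev_ids)
  for (ev in doc$events) {
    if (!ev$trigger_id %in% doc$triggers$id)
      stop("event ", ev$id, " references unknown trigger ", ev$trigger_id)
    ttype <- doc$triggers$type[doc$triggers$id == ev$trigger_id]
    if (!identical(ev$type, ttype))
      stop("event ", ev$id, " type ", ev$type,
           " differs from its trigger's type ", ttype)
    bad <- setdiff(ev$args$filler, fillable)
    if (length(bad))
      stop("event ", ev$id, " references unknown filler(s) ",
           paste(bad, collapse = ", "))
  }
  check_event_acyclic(doc$events)
  invisible(TRUE)
}

# Depth-first check that no event is its own transitive argument.
check_event_acyclic <- function(events) {
  ev_ids <- vapply(events, `[[`, "", "id")
  kids <- lapply(events, function(ev)
    ev$args$filler[grepl("^E", ev$args$filler)])
  names(kids) <- ev_ids
  state <- setNames(rep(0L, length(ev_ids)), ev_ids) # 0 new, 1 open, 2 done
  visit <- function(id) {
    if (state[[id]] == 1L) stop("event reference cycle involving ", id)
    if (state[[id]] == 2L) return(invisible())
    state[[id]] <<- 1L
    for (k in kids[[id]]) if (k %in% ev_ids) visit(k)
    state[[id]] <<- 2L
  }
  for (id in ev_ids) visit(id)
  invisible(TRUE)
}

#' @export
print.annotated_document <- function(x, ...) {
  cat("<annotated_document> ", x$doc_id, ": ", nchar(x$text), " chars, ",
      nrow(x$entities), " entities, ", nrow(x$triggers), " triggers, ",
      length(x$events), " events\n", sep = "")
  invisible(x)
}

parse_t_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) < 3)
    stop("parse error at ", file, ":", lineno,
         ": expected 3 tab-separated fields in T-line, got ", length(parts))
  mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  if (grepl(";", parts[2], fixed = TRUE))
    stop("parse error at ", file, ":", lineno,
         ": discontinuous spans are not supported")
  if (length(mid) != 3)
    stop("parse error at ", file, ":", lineno,
         ": expected 'TYPE START END', got ", dQuote(parts[2]))
  data.frame(id = parts[1], type = mid[1],
             start = as.integer(mid[2]), end = as.integer(mid[3]),
             text = parts[3], stringsAsFactors = FALSE)
}

parse_e_line <- function(line, lineno, file) {
  parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("parse error at ", file, ":", lineno,
         ": expected 2 tab-separated fields in E-line")
  toks <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  kv <- strsplit(toks, ":", fixed = TRUE)
  if (any(lengths(kv) != 2))
    stop("parse error at ", file, ":", lineno,
         ": malformed ROLE:ID pair in ", dQuote(parts[2]))
  head_kv <- kv[[1]]
  args <- if (length(kv) > 1) {
    data.frame(role = vapply(kv[-1], `[`, "", 1),
               filler = vapply(kv[-1], `[`, "", 2),
               stringsAsFactors = FALSE)
  } else data.frame(role = character(), filler = character(),
                    stringsAsFactors = FALSE)
  list(id = parts[1], type = head_kv[1], trigger_id = head_kv[2], args = args)
}

#' Read a standoff-annotated document
#'
#' Reads a BioNLP ST document: the raw text, the given entities (.a1) and,
#' when present, the triggers and events (.a2). All spans are validated
#' against the text; a mismatch, dangling reference or malformed line is an
#' error, never a warning.
#'
#' @param txt_path Path to the `.txt` file.
#' @param a1_path Path to the `.a1` entity file.
#' @param a2_path Optional path to the `.a2` trigger/event file; `NULL` or a
#'   missing file yields a document with no triggers or events.
#' @return An [annotated_document()].
#' @export
read_document <- function(txt_path, a1_path, a2_path = NULL) {
  if (!file.exists(txt_path)) stop("text file not found: ", txt_path)
  text <- paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
                collapse = "\n")
  doc_id <- sub("\\.txt$", "", basename(txt_path))

  read_ann <- function(path) {
    lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
    lines <- sub("\r$", "", lines)
    lines[nzchar(lines)]
  }

  ents <- empty_spans()
  if (!is.null(a1_path) && file.exists(a1_path)) {
    lines <- read_ann(a1_path)
    for (i in seq_along(lines)) {
      if (!grepl("^T", lines[i]))
        stop("parse error at ", a1_path, ":", i,
             ": only T-lines are allowed in .a1")
      ents <- rbind(ents, parse_t_line(lines[i], i, a1_path))
    }
  } else if (is.null(a1_path) || !file.exists(a1_path)) {
    stop("entity file not found: ", a1_path)
  }

  trigs <- empty_spans(); events <- list()
  if (!is.null(a2_path) && file.exists(a2_path)) {
    lines <- read_ann(a2_path)
    for (i in seq_along(lines)) {
      if (grepl("^T", lines[i])) {
        trigs <- rbind(trigs, parse_t_line(lines[i], i, a2_path))
      } else if (grepl("^E", lines[i])) {
        events <- c(events, list(parse_e_line(lines[i], i, a2_path)))
      } else {
        stop("parse error at ", a2_path, ":", i,
             ": unsupported annotation line ", dQuote(lines[i]))
      }
    }
  }
  annotated_document(doc_id, text, ents, trigs, events)
}

format_t_line <- function(s)
  paste0(s$id, "\t", s$type, " ", s$start, " ", s$end, "\t", s$text)

format_e_line <- function(ev) {
  args <- if (nrow(ev$args)) paste(" ",
    paste(paste0(ev$args$role, ":", ev$args$filler), collapse = " "),
    sep = "") else ""
  paste0(ev$id, "\t", ev$type, ":", ev$trigger_id, args)
}

#' Write a document in standoff format
#'
#' Emits `<doc_id>.txt`, `.a1` and `.a2` under `out_dir`. Annotation lines
#' are written in ascending numeric id order so output is byte-stable. The
#' document is validated before anything is written.
#'
#' @param doc An [annotated_document()].
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, the three file paths written.
#' @export
write_document <- function(doc, out_dir) {
  validate_document(doc)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(out_dir, doc$doc_id)
  paths <- paste0(base, c(".txt", ".a1", ".a2"))

  ord <- function(df) df[order(numeric_id(df$id)), , drop = FALSE]
  a1 <- if (nrow(doc$entities))
    vapply(seq_len(nrow(doc$entities)),
           function(i) format_t_line(ord(doc$entities)[i, ]), "") else character()
  trig <- ord(doc$triggers)
  a2_t <- if (nrow(trig))
    vapply(seq_len(nrow(trig)), function(i) format_t_line(trig[i, ]), "")
    else character()
  evs <- doc$events[order(numeric_id(vapply(doc$events, `[[`, "", "id")))]
  a2_e <- vapply(evs, format_e_line, "")

  writeLines(doc$text, paths[1], useBytes = TRUE)
  writeLines(a1, paths[2], useBytes = TRUE)
  writeLines(c(a2_t, a2_e), paths[3], useBytes = TRUE)
  invisible(paths)
}

#' Compare two annotated documents field by field
#'
#' @param a,b Documents to compare.
#' @param canonical_ids If `TRUE`, annotations are renumbered in span order
#'   before comparison so documents differing only by id labels compare
#'   equal; the default is strict id equality.
#' @return `TRUE` or `FALSE`.
#' @export
documents_equal <- function(a, b, canonical_ids = FALSE) {
  if (canonical_ids) { a <- canonicalize_ids(a); b <- canonicalize_ids(b) }
  ev_key <- function(evs) lapply(
    evs[order(vapply(evs, `[[`, "", "id"))],
    function(ev) list(ev$id, ev$type, ev$trigger_id,
                      ev$args[order(ev$args$role, ev$args$filler), ]))
  sp_key <- function(df) {
    df <- df[order(df$id), ]; rownames(df) <- NULL; df
  }
  identical(a$doc_id, b$doc_id) && identical(a$text, b$text) &&
    isTRUE(all.equal(sp_key(a$entities), sp_key(b$entities))) &&
    isTRUE(all.equal(sp_key(a$triggers), sp_key(b$triggers))) &&
    isTRUE(all.equal(ev_key(a$events), ev_key(b$events)))
}

canonicalize_ids <- function(doc) {
  spans <- rbind(doc$entities, doc$triggers)
  spans <- spans[order(spans$start, spans$end, spans$type), ]
  t_map <- setNames(id_seq("T", nrow(spans)), spans$id)
  ev_ids <- vapply(doc$events, `[[`, "", "id")
  e_map <- setNames(id_seq("E", length(ev_ids)),
                    ev_ids[order(numeric_id(ev_ids))])
  remap <- function(x) ifelse(x %in% names(t_map), t_map[x],
                       ifelse(x %in% names(e_map), e_map[x], x))
  doc$entities$id <- unname(remap(doc$entities$id))
  doc$triggers$id <- unname(remap(doc$triggers$id))
  doc$events <- lapply(doc$events, function(ev) {
    ev$id <- unname(remap(ev$id)); ev$trigger_id <- unname(remap(ev$trigger_id))
    ev$args$filler <- unname(remap(ev$args$filler)); ev
  })
  doc
}
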