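# CoNLL-X dependency parse ingestion and annotation-to-token alignment.
#
# Sentence segmentation is taken from the CoNLL-X block structure (one
# blank-line-separated block per sentence); token character offsets are
# recovered by greedy left-to-right alignment of token surfaces against the
# document text.

#' Read a CoNLL-X dependency parse file
#'
#' Parses the 10-column tab-separated CoNLL-X format (ID, FORM, LEMMA,
#' CPOSTAG, POSTAG, FEATS, HEAD, DEPREL, PHEAD, PDEPREL); blank lines
#' separate sentences. Only FORM, POSTAG, HEAD and DEPREL are used
#' downstream.
#'
#' @param path Path to a `.conllx` file.
#' @return A list of data frames, one per sentence, with columns `index`,
#'   `surface`, `pos`, `head`, `deprel`.
#' @export
read_conllx <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- sub("\r$", "", lines)
  blocks <- split(lines, cumsum(!nzchar(lines)))
  blocks <- lapply(blocks, function(b) b[nzchar(b)])
  blocks <- blocks[lengths(blocks) > 0]
  lapply(blocks, function(b) {
    fields <- strsplit(b, "\t", fixed = TRUE)
    if (any(lengths(fields) < 8))
      stop("CoNLL-X parse error in ", path,
           ": a token line has fewer than 8 columns")
    data.frame(
      index = as.integer(vapply(fields, `[`, "", 1)),
      surface = vapply(fields, `[`, "", 2),
      pos = vapply(fields, `[`, "", 5),
      head = as.integer(vapply(fields, `[`, "", 7)),
      deprel = vapply(fields, `[`, "", 8),
      stringsAsFactors = FALSE)
  })
}

validate_tree <- function(tok, where = "") {
  n <- nrow(tok)
  if (any(tok$head == tok$index))
    stop("dependency tree error", where, ": token is its own head")
  if (sum(tok$head == 0L) != 1L)
    stop("dependency tree error", where, ": expected exactly one root, got ",
         sum(tok$head == 0L))
  if (any(tok$head < 0L | tok$head > n))
    stop("dependency tree error", where, ": head index out of range")
  # connectivity: walk up from every token; a cycle never reaches the root
  for (i in seq_len(n)) {
    seen <- logical(n); j <- i
    while (tok$head[j] != 0L) {
      if (seen[j]) stop("dependency tree error", where, ": cyclic heads")
      seen[j] <- TRUE
      j <- tok$head[j]
    }
  }
  invisible(TRUE)
}

#' Attach dependency parses to an annotated document
#'
#' Aligns each CoNLL-X sentence block to the document text left to right:
#' every token surface must occur, in order, in the remaining text. Each
#' resulting sentence records its token table (with recovered character
#' offsets), its own character span, and which entities and triggers fall
#' inside it. Dependency structure is validated as a single-rooted tree.
#'
#' @param doc An [annotated_document()].
#' @param conllx Either a path to a `.conllx` file or the result of
#'   [read_conllx()].
#' @return A list of `sentence` objects.
#' @export
attach_parse <- function(doc, conllx) {
  blocks <- if (is.character(conllx)) read_conllx(conllx) else conllx
  cursor <- 0L
  sentences <- vector("list", length(blocks))
  for (s in seq_along(blocks)) {
    tok <- blocks[[s]]
    validate_tree(tok, paste0(" in sentence ", s))
    starts <- ends <- integer(nrow(tok))
    for (i in seq_len(nrow(tok))) {
      rel <- regexpr(tok$surface[i], substr(doc$text, cursor + 1L,
                                            nchar(doc$text)), fixed = TRUE)
      if (rel < 0)
        stop("alignment error in sentence ", s, ": token ",
             dQuote(tok$surface[i]), " not found after offset ", cursor)
      starts[i] <- cursor + as.integer(rel) - 1L
      ends[i] <- starts[i] + nchar(tok$surface[i])
      cursor <- ends[i]
    }
    tok$start <- starts; tok$end <- ends
    sentences[[s]] <- new_sentence(tok, doc, s)
  }
  sentences
}

new_sentence <- function(tok, doc, s_index) {
  s_start <- min(tok$start); s_end <- max(tok$end)
  inside <- function(df)
    df$id[df$start < s_end & df$end > s_start]
  structure(list(
    doc_id = doc$doc_id, index = s_index,
    tokens = tok, sent_start = s_start, sent_end = s_end,
    entity_ids = inside(doc$entities),
    trigger_ids = inside(doc$triggers)),
    class = "sentence")
}

#' @export
print.sentence <- function(x, ...) {
  cat("<sentence> ", x$doc_id, "#", x$index, ": ",
      paste(x$tokens$surface, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Anchor an annotation span to a token
#'
#' Multi-token spans are reduced to a single anchor token: the last token
#' overlapping the span (English noun phrases are head-final). With
#' `rule = "head"` the anchor is instead the span token whose dependency
#' head lies outside the span (the span's syntactic head).
#'
#' @param sentence A `sentence` from [attach_parse()].
#' @param start,end 0-based half-open character span.
#' @param rule `"last"` (default) or `"head"`.
#' @return The 1-based token index of the anchor.
#' @export
anchor_annotation <- function(sentence, start, end, rule = c("last", "head")) {
  rule <- match.arg(rule)
  tok <- sentence$tokens
  hit <- which(tok$start < end & tok$end > start)
  if (!length(hit))
    stop("anchoring error: span [", start, ",", end,
         ") overlaps no token of sentence ", sentence$index)
  if (rule == "last") return(hit[length(hit)])
  outside <- hit[!(tok$head[hit] %in% tok$index[hit])]
  if (length(outside)) outside[length(outside)] else hit[length(hit)]
}

# Lowercase surfaces and collapse digit strings for dictionary/embedding
# lookup; original case stays on the token table for offsets.
norm_word <- function(w) {
  w <- tolower(w)
  ifelse(grepl("^[0-9][0-9.,]*$", w), "<num>", w)
}

UNK <- "<unk>"
PAD <- "<pad>"

make_index <- function(keys) {
  keys <- sort(unique(keys))
  setNames(seq_along(keys) + 2L, keys) # 1 = <unk>, 2 = <pad>
}

index_size <- function(map) length(map) + 2L

# Look indices up with the unknown fallback.
lookup_index <- function(map, keys) {
  i <- unname(map[keys])
  i[is.na(i)] <- 1L
  i
}

#' Build training-set dictionaries
#'
#' Collects every surface form (lowercased, digit strings collapsed to a
#' `<num>` placeholder), POS tag, and annotation type seen in the training
#' sentences, and fixes the dependency-distance bucket inventory. Each map
#' reserves distinct unknown and padding indices (1 and 2); observed keys
#' are indexed densely from 3. Test-time misses resolve to the unknown
#' index.
#'
#' @param sentences Training sentences from [attach_parse()].
#' @param types Character vector of annotation types (entity and trigger
#'   types) to index.
#' @param max_distance Dependency distances are clipped at this bucket; one
#'   extra bucket marks unreachable pairs.
#' @return A `dictionary` object with named integer maps `word`, `pos`,
#'   `type`, `dist`.
#' @export
build_dictionary <- function(sentences, types = character(),
                             max_distance = 10L) {
  if (!length(sentences)) stop("cannot build a dictionary from no sentences")
  words <- unlist(lapply(sentences, function(s) norm_word(s$tokens$surface)))
  pos <- unlist(lapply(sentences, function(s) s$tokens$pos))
  structure(list(
    word = make_index(words),
    pos = make_index(pos),
    type = make_index(types),
    dist = make_index(as.character(0:(max_distance + 1L))),
    max_distance = as.integer(max_distance)),
    class = "dictionary")
}

#' @export
print.dictionary <- function(x, ...) {
  cat("<dictionary> words:", length(x$word), " pos:", length(x$pos),
      " types:", length(x$type), " distance buckets:", length(x$dist), "\n")
  invisible(x)
}
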