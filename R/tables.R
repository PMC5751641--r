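# Lookup tables of distributed representations: the pretrained/random word
# embedding table W, and the randomly initialized, trainable tables for POS
# (W_pos), dependency distance (W_dis) and annotation type (W_type). Row 1
# of every table is the unknown entry, row 2 the padding entry.

#' Create an embedding table over a dictionary map
#'
#' @param map Named integer map from [build_dictionary()] (keys indexed
#'   from 3; 1 and 2 are the reserved unknown/padding rows).
#' @param dim Embedding width.
#' @param seed RNG seed for the random initialization.
#' @param range Rows are drawn from uniform(-range, range); the default
#'   scales with table size (Glorot-style). Word tables use 0.25.
#' @param trainable Whether supervised training may update the rows.
#' @return An `embedding_table`.
#' @export
embedding_table <- function(map, dim, seed, range = NULL, trainable = TRUE) {
  stopifnot(dim > 0)
  rows <- index_size(map)
  if (is.null(range)) range <- sqrt(6 / (rows + dim))
  mat <- with_seed(seed,
    matrix(stats::runif(rows * dim, -range, range), rows, dim))
  mat[2L, ] <- 0 # padding row starts at zero
  structure(list(map = map, mat = mat, dim = as.integer(dim),
                 trainable = trainable),
            class = "embedding_table")
}

#' @export
print.embedding_table <- function(x, ...) {
  cat("<embedding_table> ", nrow(x$mat), " rows x ", x$dim, " dims",
      if (x$trainable) " (trainable)", "\n", sep = "")
  invisible(x)
}

table_rows <- function(tab, keys) {
  tab$mat[lookup_index(tab$map, keys), , drop = FALSE]
}

#' Load word embeddings in word2vec text format
#'
#' Reads a `word2vec` text table (header line `"count dim"`, then one
#' `"word v1 ... vdim"` line per word). Dictionary words found in the file
#' take their file vectors; misses — along with the unknown row — are
#' initialized from a seeded uniform(-0.25, 0.25) draw, so a run is fully
#' reproducible whether or not pretrained vectors cover the vocabulary.
#'
#' @param path Path to the embeddings file, or `NULL` to random-initialize
#'   the whole table.
#' @param dictionary A [build_dictionary()] result.
#' @param dim Required when `path` is `NULL`; otherwise taken from the file
#'   header (and cross-checked against `dim` when both are given).
#' @param seed RNG seed for rows not covered by the file.
#' @param trainable Whether supervised training may update the table.
#' @return An `embedding_table` over `dictionary$word`.
#' @export
load_word_embeddings <- function(path, dictionary, dim = NULL, seed = 1L,
                                 trainable = TRUE) {
  if (is.null(path)) {
    if (is.null(dim)) stop("dim is required when no embedding file is given")
    return(embedding_table(dictionary$word, dim, seed, range = 0.25,
                           trainable = trainable))
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (!length(lines)) stop("embedding format error: empty file ", path)
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) != 2 || anyNA(suppressWarnings(as.integer(header))))
    stop("embedding format error: header must be 'count dim', got ",
         dQuote(lines[1]))
  n_words <- as.integer(header[1]); file_dim <- as.integer(header[2])
  if (!is.null(dim) && dim != file_dim)
    stop("embedding format error: file dim ", file_dim,
         " does not match requested dim ", dim)
  body <- lines[-1][nzchar(lines[-1])]
  if (length(body) != n_words)
    stop("embedding format error: header promises ", n_words,
         " rows, file has ", length(body))
  tab <- embedding_table(dictionary$word, file_dim, seed, range = 0.25,
                         trainable = trainable)
  for (ln in body) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != file_dim + 1L)
      stop("embedding format error: row for ", dQuote(parts[1]),
           " has ", length(parts) - 1L, " values, expected ", file_dim)
    idx <- tab$map[parts[1]]
    if (!is.na(idx)) tab$mat[idx, ] <- as.numeric(parts[-1])
  }
  tab
}

#' Write an embedding table in word2vec text format
#'
#' @param tab An `embedding_table`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_word_embeddings <- function(tab, path) {
  keys <- names(tab$map)
  rows <- vapply(seq_along(keys), function(i)
    paste(keys[i], paste(format(tab$mat[tab$map[i], ], digits = 17,
                                scientific = TRUE, trim = TRUE),
                         collapse = " ")), "")
  writeLines(c(paste(length(keys), tab$dim), rows), path, useBytes = TRUE)
  invisible(path)
}
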