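# Seeded synthetic standoff corpus with planted, learnable signal.
#
# The generator emulates the structure of an MLEE-style corpus: documents
# of template sentences carrying typed entity mentions, typed triggers
# whose surface form deterministically encodes their type (unless noise is
# injected), and events whose role assignment follows a fixed
# (trigger type, argument type) -> role rule, including nested
# trigger -> trigger events. Dependency trees are built alongside the
# tokens, so parses are consistent with the annotation by construction.
# The signal is lexical and type-structural, not distributional, which
# keeps small models convergent on a CPU in seconds.

SYN_TRIGGER_TYPES <- c(
  "Cell_proliferation", "Development", "Blood_vessel_development",
  "Growth", "Death", "Breakdown", "Remodeling", "Synthesis",
  "Gene_expression", "Transcription", "Catabolism", "Phosphorylation",
  "Dephosphorylation", "Localization", "Binding", "Planned_process",
  "Regulation", "Positive_regulation", "Negative_regulation")

SYN_REG_TYPES <- c("Regulation", "Positive_regulation",
                   "Negative_regulation")

SYN_ENTITY_TYPES <- c("Cell", "Drug", "Gene_or_gene_product", "Organism",
                      "Tissue")

syn_entity_stub <- c(Cell = "cell", Drug = "drug",
                     Gene_or_gene_product = "gene", Organism = "organism",
                     Tissue = "tissue")

# Deterministic surface lexicon: three inflections per trigger type.
syn_trigger_lexicon <- function(types = SYN_TRIGGER_TYPES) {
  stems <- tolower(gsub("_", "", types))
  data.frame(
    type = rep(types, each = 3L),
    surface = as.vector(vapply(stems, function(s)
      paste0(s, c("ates", "ated", "ation")), character(3))),
    pos = rep(c("VBZ", "VBN", "NN"), length(types)),
    stringsAsFactors = FALSE)
}

syn_ambiguous_pool <- paste0("modulat", c("es", "ed", "ion", "ing", "or"))

# Fixed (trigger type, entity type) -> role tables.
syn_role_tables <- function(types = SYN_TRIGGER_TYPES,
                            etypes = SYN_ENTITY_TYPES) {
  k <- seq_along(types)
  theme <- setNames(etypes[(k - 1L) %% length(etypes) + 1L], types)
  cause <- setNames(etypes[(k + 1L) %% length(etypes) + 1L], types)
  cause[!(types %in% SYN_REG_TYPES)] <- NA_character_
  list(theme = theme, cause = cause)
}

#' Deterministic role of a candidate pair under the planted rule
#'
#' @param ttype Source trigger type.
#' @param target_type Target annotation type.
#' @param target_is_trigger Whether the target is a trigger.
#' @param rules [syn_role_tables()] output (the generator's answer key).
#' @return `"Theme"`, `"Cause"`, or `NA` for no relation.
#' @export
syn_role_rule <- function(ttype, target_type, target_is_trigger, rules) {
  if (target_is_trigger)
    return(if (ttype %in% SYN_REG_TYPES) "Theme" else NA_character_)
  if (!is.na(rules$theme[ttype]) && rules$theme[ttype] == target_type)
    return("Theme")
  if (!is.na(rules$cause[ttype]) && rules$cause[ttype] == target_type)
    return("Cause")
  NA_character_
}

#' Synthetic corpus configuration
#'
#' @param n_documents Number of documents.
#' @param sentences_per_doc Sentences per document.
#' @param n_filler_nouns,n_filler_verbs Size of the non-trigger vocabulary.
#' @param entity_types,trigger_types Type inventories (defaults mirror an
#'   MLEE-style corpus: 19 trigger types, 5 entity types).
#' @param p_event Probability that a sentence carries an event.
#' @param nesting_probability Probability that an event sentence is a
#'   nested regulation (trigger-valued Theme).
#' @param noise_rate Probability that a trigger surface is replaced by an
#'   ambiguous word shared across types, destroying the lexical signal.
#' @param seed Mandatory RNG seed; generation is byte-deterministic.
#' @return A `syn_config` list.
#' @export
syn_config <- function(n_documents = 50L, sentences_per_doc = 6L,
                       n_filler_nouns = 30L, n_filler_verbs = 10L,
                       entity_types = SYN_ENTITY_TYPES,
                       trigger_types = SYN_TRIGGER_TYPES,
                       p_event = 0.75, nesting_probability = 0.25,
                       noise_rate = 0, seed) {
  if (missing(seed)) stop("a seed is mandatory for corpus generation")
  stopifnot(p_event >= 0, p_event <= 1, nesting_probability >= 0,
            nesting_probability <= 1, noise_rate >= 0, noise_rate <= 1,
            length(trigger_types) >= 2, length(entity_types) >= 1)
  structure(list(
    n_documents = as.integer(n_documents),
    sentences_per_doc = as.integer(sentences_per_doc),
    n_filler_nouns = as.integer(n_filler_nouns),
    n_filler_verbs = as.integer(n_filler_verbs),
    entity_types = entity_types, trigger_types = trigger_types,
    p_event = p_event, nesting_probability = nesting_probability,
    noise_rate = noise_rate, seed = as.integer(seed)),
    class = "syn_config")
}

# One sentence: a token table (surface, pos, head, deprel), entity
# records, trigger records, and rule-derived relations (local indices).
syn_sentence <- function(cfg, lex, rules) {
  nouns <- paste0("noun", seq_len(cfg$n_filler_nouns))
  verbs <- paste0("verb", seq_len(cfg$n_filler_verbs))
  ent <- function(etype) paste0(syn_entity_stub[[etype]],
                                sample.int(20L, 1L))
  trig_surface <- function(ttype) {
    if (stats::runif(1) < cfg$noise_rate)
      return(c(sample(syn_ambiguous_pool, 1L), "VBZ"))
    row <- lex[lex$type == ttype, , drop = FALSE]
    i <- sample.int(nrow(row), 1L)
    c(row$surface[i], row$pos[i])
  }
  kind <- if (stats::runif(1) >= cfg$p_event) "none"
          else if (stats::runif(1) < cfg$nesting_probability) "nested"
          else "flat"
  tokens <- NULL; ents <- list(); trigs <- list(); rel <- list()
  add <- function(surface, pos, head, deprel)
    tokens <<- rbind(tokens, data.frame(surface = surface, pos = pos,
                                        head = head, deprel = deprel,
                                        stringsAsFactors = FALSE))
  add_ent <- function(tok_i, etype)
    ents[[length(ents) + 1L]] <<- list(tok = tok_i, type = etype)
  add_trig <- function(tok_i, ttype)
    trigs[[length(trigs) + 1L]] <<- list(tok = tok_i, type = ttype)

  if (kind == "none") {
    etype <- sample(cfg$entity_types, 1L)
    add("The", "DT", 2L, "det")
    add(ent(etype), "NN", 3L, "nsubj"); add_ent(2L, etype)
    add(sample(verbs, 1L), "VBZ", 0L, "root")
    add("the", "DT", 5L, "det")
    add(sample(nouns, 1L), "NN", 3L, "dobj")
    add(".", ".", 3L, "punct")
  } else if (kind == "flat") {
    ttype <- sample(cfg$trigger_types, 1L)
    theme <- rules$theme[[ttype]]
    subj <- if (ttype %in% SYN_REG_TYPES) rules$cause[[ttype]]
            else sample(setdiff(cfg$entity_types,
                                c(theme, stats::na.omit(rules$cause[[ttype]]))),
                        1L)
    ts <- trig_surface(ttype)
    add("The", "DT", 2L, "det")
    add(ent(subj), "NN", 3L, "nsubj"); add_ent(2L, subj)
    add(ts[1], ts[2], 0L, "root"); add_trig(3L, ttype)
    add("the", "DT", 5L, "det")
    add(ent(theme), "NN", 3L, "dobj"); add_ent(5L, theme)
    add(".", ".", 3L, "punct")
  } else { # nested regulation
    reg <- sample(SYN_REG_TYPES, 1L)
    ok_inner <- setdiff(cfg$trigger_types, SYN_REG_TYPES)
    ok_inner <- ok_inner[!(rules$theme[ok_inner] %in%
                           c(rules$theme[[reg]], rules$cause[[reg]]))]
    inner <- sample(ok_inner, 1L)
    its <- lex[lex$type == inner & lex$pos == "NN", , drop = FALSE]
    inner_surface <- if (stats::runif(1) < cfg$noise_rate)
      sample(syn_ambiguous_pool, 1L) else its$surface[1]
    rs <- trig_surface(reg)
    add("The", "DT", 2L, "det")
    add(ent(rules$cause[[reg]]), "NN", 3L, "nsubj")
    add_ent(2L, rules$cause[[reg]])
    add(rs[1], rs[2], 0L, "root"); add_trig(3L, reg)
    add("the", "DT", 5L, "det")
    add(inner_surface, "NN", 3L, "dobj"); add_trig(5L, inner)
    add("of", "IN", 5L, "prep")
    add(ent(rules$theme[[inner]]), "NN", 6L, "pobj")
    add_ent(7L, rules$theme[[inner]])
    add(".", ".", 3L, "punct")
  }
  # optional filler prepositional phrase before the period
  if (stats::runif(1) < 0.3) {
    np <- nrow(tokens)
    tokens <- tokens[-np, , drop = FALSE] # drop period, re-append after
    root <- which(tokens$head == 0L)
    add("in", "IN", root, "prep")
    add("the", "DT", nrow(tokens) + 2L, "det")
    add(sample(nouns, 1L), "NN", nrow(tokens) - 1L, "pobj")
    add(".", ".", root, "punct")
  }
  # rule-derived relations over all (trigger, target) pairs
  for (ti in seq_along(trigs)) {
    for (ei in seq_along(ents)) {
      role <- syn_role_rule(trigs[[ti]]$type, ents[[ei]]$type, FALSE, rules)
      if (!is.na(role))
        rel[[length(rel) + 1L]] <- list(src = ti, dst = ei,
                                        dst_kind = "entity", role = role)
    }
    for (tj in seq_along(trigs)) {
      if (tj == ti) next
      role <- syn_role_rule(trigs[[ti]]$type, trigs[[tj]]$type, TRUE, rules)
      if (!is.na(role))
        rel[[length(rel) + 1L]] <- list(src = ti, dst = tj,
                                        dst_kind = "trigger", role = role)
    }
  }
  list(tokens = tokens, ents = ents, trigs = trigs, rel = rel)
}

#' Generate a synthetic annotated corpus
#'
#' Produces standoff documents (entities, triggers, events), matching
#' CoNLL-X parses, and the answer key (lexicon and role tables) that makes
#' the planted signal decodable without a model. The same seed yields a
#' byte-identical corpus.
#'
#' @param config A [syn_config()].
#' @return A `synthetic_corpus`: `documents` (named list of
#'   [annotated_document()]), `parses` (named list of CoNLL-X sentence
#'   tables), `answer_key`.
#' @export
generate_corpus <- function(config) {
  lex <- syn_trigger_lexicon(config$trigger_types)
  rules <- syn_role_tables(config$trigger_types, config$entity_types)
  with_seed(config$seed, {
    docs <- list(); parses <- list()
    for (d in seq_len(config$n_documents)) {
      doc_id <- sprintf("SYN%04d", d)
      sents <- lapply(seq_len(config$sentences_per_doc), function(i)
        syn_sentence(config, lex, rules))
      # lay sentences out in text, assigning character offsets
      text <- ""; offset <- 0L
      ents <- empty_spans(); trig <- empty_spans(); rel_all <- list()
      blocks <- list()
      for (s in sents) {
        tok <- s$tokens
        n <- nrow(tok)
        starts <- integer(n); ends <- integer(n)
        pos_c <- offset
        for (i in seq_len(n)) {
          if (nzchar(text)) { text <- paste0(text, " "); pos_c <- pos_c + 1L }
          starts[i] <- pos_c
          text <- paste0(text, tok$surface[i])
          pos_c <- pos_c + nchar(tok$surface[i])
          ends[i] <- pos_c
        }
        offset <- pos_c
        for (e in s$ents)
          ents <- rbind(ents, data.frame(
            id = NA_character_, type = e$type, start = starts[e$tok],
            end = ends[e$tok], text = tok$surface[e$tok],
            stringsAsFactors = FALSE))
        base_t <- nrow(trig)
        for (t in s$trigs)
          trig <- rbind(trig, data.frame(
            id = NA_character_, type = t$type, start = starts[t$tok],
            end = ends[t$tok], text = tok$surface[t$tok],
            stringsAsFactors = FALSE))
        base_e <- nrow(ents) - length(s$ents)
        for (r in s$rel)
          rel_all[[length(rel_all) + 1L]] <- data.frame(
            src = base_t + r$src,
            dst = if (r$dst_kind == "entity") base_e + r$dst
                  else base_t + r$dst,
            dst_kind = r$dst_kind, role = r$role, stringsAsFactors = FALSE)
        blocks[[length(blocks) + 1L]] <- data.frame(
          index = seq_len(n), surface = tok$surface, pos = tok$pos,
          head = tok$head, deprel = tok$deprel, stringsAsFactors = FALSE)
      }
      ents$id <- id_seq("T", nrow(ents))
      trig$id <- id_seq("T", nrow(trig), offset = nrow(ents))
      relations <- if (length(rel_all)) {
        r <- do.call(rbind, rel_all)
        data.frame(source_id = trig$id[r$src],
                   target_id = ifelse(r$dst_kind == "entity",
                                      ents$id[r$dst], trig$id[r$dst]),
                   target_kind = r$dst_kind, role = r$role,
                   stringsAsFactors = FALSE)
      } else data.frame(source_id = character(), target_id = character(),
                        target_kind = character(), role = character(),
                        stringsAsFactors = FALSE)
      events <- assemble_events(trig, relations, ents)
      docs[[doc_id]] <- annotated_document(doc_id, text, ents, trig, events)
      parses[[doc_id]] <- blocks
    }
    structure(list(
      documents = docs, parses = parses,
      answer_key = list(lexicon = lex, rules = rules,
                        reg_types = SYN_REG_TYPES, config = config)),
      class = "synthetic_corpus")
  })
}

#' @export
print.synthetic_corpus <- function(x, ...) {
  nev <- sum(vapply(x$documents, function(d) length(d$events), 1L))
  cat("<synthetic_corpus> ", length(x$documents), " documents, ",
      nev, " events\n", sep = "")
  invisible(x)
}

format_conllx <- function(blocks) {
  unlist(lapply(blocks, function(b) {
    c(paste(b$index, b$surface, tolower(b$surface),
            substr(b$pos, 1, 1), b$pos, "_", b$head, b$deprel, "_", "_",
            sep = "\t"), "")
  }))
}

#' Write a synthetic corpus in BioNLP ST layout
#'
#' Emits `<split>/<doc>.txt/.a1/.a2/.conllx` per document plus an
#' `answer_key.json`. Documents are assigned to splits in order.
#'
#' @param corpus A [generate_corpus()] result.
#' @param dir Output directory.
#' @param splits Named integer vector of document counts per split (must
#'   sum to the corpus size), e.g. `c(train = 50, test = 20)`.
#' @return Invisibly, `dir`.
#' @export
write_corpus <- function(corpus, dir,
                         splits = c(train = length(corpus$documents))) {
  if (sum(splits) != length(corpus$documents))
    stop("splits must sum to the number of documents")
  assign <- rep(names(splits), splits)
  ids <- names(corpus$documents)
  for (i in seq_along(ids)) {
    sub <- file.path(dir, assign[i])
    doc <- corpus$documents[[ids[i]]]
    write_document(doc, sub)
    writeLines(format_conllx(corpus$parses[[ids[i]]]),
               file.path(sub, paste0(doc$doc_id, ".conllx")),
               useBytes = TRUE)
  }
  key <- corpus$answer_key
  jsonlite::write_json(
    list(lexicon = key$lexicon,
         theme = as.list(key$rules$theme),
         cause = as.list(key$rules$cause),
         reg_types = key$reg_types),
    file.path(dir, "answer_key.json"), auto_unbox = TRUE, na = "null")
  invisible(dir)
}

#' Split a corpus into sub-corpora by document counts
#'
#' @param corpus A `synthetic_corpus`.
#' @param counts Named integer vector, e.g. `c(train = 50, test = 20)`.
#' @return Named list of `synthetic_corpus` objects.
#' @export
split_corpus <- function(corpus, counts) {
  if (sum(counts) > length(corpus$documents))
    stop("split counts exceed corpus size")
  assign <- rep(names(counts), counts)
  ids <- names(corpus$documents)[seq_along(assign)]
  out <- lapply(unique(names(counts)), function(k) {
    keep <- ids[assign == k]
    structure(list(documents = corpus$documents[keep],
                   parses = corpus$parses[keep],
                   answer_key = corpus$answer_key),
              class = "synthetic_corpus")
  })
  names(out) <- unique(names(counts))
  out
}
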