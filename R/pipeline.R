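# End-to-end orchestration: preprocess -> train trigger model -> train
# argument model -> predict -> assemble events -> score. All randomness
# fans out from one run-level seed.

#' Pipeline configuration
#'
#' Bundles the trigger and argument model configurations (whose defaults
#' reproduce the reference parameter tables), the event schema, optional
#' pretrained word embeddings, and the run seed.
#'
#' @param trigger A [trigger_config()].
#' @param argument An [argument_config()].
#' @param schema_path Event schema YAML; `NULL` for the packaged default.
#' @param embeddings_path Optional word2vec-text embeddings for the
#'   trigger model's word table.
#' @param seed Run-level seed; every stage derives its own stream from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(trigger = trigger_config(),
                            argument = argument_config(),
                            schema_path = NULL, embeddings_path = NULL,
                            seed = 1L) {
  structure(list(trigger = trigger, argument = argument,
                 schema_path = schema_path,
                 embeddings_path = embeddings_path,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Attach parses to every document of a corpus
#'
#' @param corpus A `synthetic_corpus`, or a list with `documents` and
#'   `parses` entries (parses as CoNLL-X sentence tables or file paths).
#' @return Named list (by doc id) of sentence lists.
#' @export
preprocess_corpus <- function(corpus) {
  out <- lapply(names(corpus$documents), function(id)
    attach_parse(corpus$documents[[id]], corpus$parses[[id]]))
  names(out) <- names(corpus$documents)
  out
}

annotation_types <- function(docs) {
  sort(unique(unlist(lapply(docs, function(d)
    c(d$entities$type, d$triggers$type)))))
}

#' Run the full extraction pipeline
#'
#' Trains both models on the training corpus (gold triggers for the
#' argument stage), then on the test corpus predicts triggers, classifies
#' candidate pairs, assembles and filters events, and scores triggers and
#' events against gold.
#'
#' @param train,test Corpora as accepted by [preprocess_corpus()]; the
#'   test documents' gold triggers/events are used only for scoring.
#' @param config A [pipeline_config()].
#' @return An `event_pipeline` result: models, predicted documents,
#'   trigger and event `eval_report`s.
#' @export
run_pipeline <- function(train, test, config = pipeline_config()) {
  seed <- config$seed
  train_sent <- preprocess_corpus(train)
  test_sent <- preprocess_corpus(test)
  flat_train <- unlist(train_sent, recursive = FALSE)

  dict <- build_dictionary(flat_train, annotation_types(train$documents),
                           max_distance = config$trigger$max_distance)

  word_tab <- if (!is.null(config$embeddings_path))
    load_word_embeddings(config$embeddings_path, dict,
                         seed = derive_seed(seed, "word"),
                         trainable = config$trigger$train_embeddings)
  else NULL
  trig_tabs <- trigger_tables(dict, config$trigger, seed = seed,
                              word_table = word_tab,
                              sentences = flat_train)
  trig_ex <- make_trigger_examples(flat_train, trig_tabs, config$trigger,
                                   train$documents, dict)
  trig_model <- train_trigger_model(trig_ex, config$trigger, seed = seed)

  arg_tabs <- argument_tables(dict, config$argument, seed = seed)
  arg_ex <- make_argument_examples(flat_train, arg_tabs, config$argument,
                                   train$documents, dict)
  arg_model <- train_argument_model(arg_ex, config$argument, seed = seed)

  schema <- load_schema(config$schema_path)
  pred_docs <- predict_documents(trig_model, arg_model, test, test_sent,
                                 dict, schema)

  trig_report <- score_predictions(test$documents, pred_docs, test_sent,
                                   mode = "trigger")
  event_report <- score_predictions(test$documents, pred_docs, test_sent,
                                    mode = "event")
  structure(list(
    trigger_model = trig_model, argument_model = arg_model,
    dictionary = dict, schema = schema, predicted = pred_docs,
    trigger_report = trig_report, event_report = event_report,
    config = config),
    class = "event_pipeline")
}

#' Predict annotated documents with trained models
#'
#' @param trig_model,arg_model Trained models.
#' @param corpus Corpus whose documents carry gold entities.
#' @param sentences Preprocessed sentences (from [preprocess_corpus()]).
#' @param dictionary The training dictionary.
#' @param schema An [load_schema()] result.
#' @return Named list of predicted [annotated_document()]s.
#' @export
predict_documents <- function(trig_model, arg_model, corpus, sentences,
                              dictionary, schema) {
  # strip gold triggers/events: prediction sees entities only
  bare <- lapply(corpus$documents, function(d)
    annotated_document(d$doc_id, d$text, d$entities))
  bare_sent <- lapply(names(bare), function(id)
    attach_parse(bare[[id]], corpus$parses[[id]]))
  names(bare_sent) <- names(bare)
  flat_bare <- unlist(bare_sent, recursive = FALSE)

  trig <- predict_triggers(trig_model, flat_bare, bare, dictionary)
  arg_ex <- make_argument_examples(flat_bare, arg_model$tables,
                                   arg_model$config, bare, dictionary,
                                   triggers = trig)
  rel <- predict_arguments(arg_model, arg_ex)

  out <- lapply(names(bare), function(id) {
    d <- bare[[id]]
    tr <- trig[trig$doc_id == id, c("id", "type", "start", "end", "text"),
               drop = FALSE]
    rl <- rel[rel$doc_id == id, , drop = FALSE]
    evs <- if (nrow(tr)) assemble_events(tr, rl, d$entities) else list()
    evs <- postprocess_events(evs, schema)
    # drop triggers orphaned by filtering? keep them: trigger scoring is
    # independent of event assembly
    annotated_document(id, d$text, d$entities,
                       if (nrow(tr)) as_span_frame(tr) else empty_spans(),
                       evs)
  })
  names(out) <- names(bare)
  out
}

#' @export
print.event_pipeline <- function(x, ...) {
  cat("<event_pipeline>\n")
  tm <- micro_scores(x$trigger_report)
  em <- micro_scores(x$event_report)
  cat(sprintf("  trigger micro  P %.2f  R %.2f  F %.2f\n",
              tm["precision"], tm["recall"], tm["fscore"]))
  cat(sprintf("  event micro    P %.2f  R %.2f  F %.2f\n",
              em["precision"], em["recall"], em["fscore"]))
  invisible(x)
}

#' @export
summary.event_pipeline <- function(object, ...) {
  print(object$trigger_report)
  cat("\n")
  print(object$event_report)
  invisible(object)
}
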