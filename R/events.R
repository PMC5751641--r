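# Event assembly and rule-based post-processing.
#
# Predicted triggers and positively-labeled relations are composed into
# events (one event per trigger, carrying all of the trigger's arguments)
# and then filtered against a declarative event schema: allowed roles per
# event type, which roles may take event-valued fillers, and which roles
# count as core. The schema is a YAML data file, so corpus-specific rules
# are configuration, not code.

#' Load an event schema
#'
#' @param path YAML schema file; `NULL` loads the packaged default. Keys:
#'   one entry per event type with `roles` (allowed role names),
#'   `event_valued` (roles that may be filled by events) and `core`
#'   (roles at least one of which an event must retain).
#' @return A list of class `event_schema`.
#' @export
load_schema <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "default_schema.yaml",
                        package = "bioevent")
  raw <- yaml::read_yaml(path)
  types <- lapply(raw$types, function(x) list(
    roles = as.character(x$roles %||% "Theme"),
    event_valued = as.character(x$event_valued %||% character()),
    core = as.character(x$core %||% "Theme")))
  structure(list(types = types), class = "event_schema")
}

schema_entry <- function(schema, type) {
  schema$types[[type]] %||%
    list(roles = "Theme", event_valued = character(), core = "Theme")
}

#' @export
print.event_schema <- function(x, ...) {
  cat("<event_schema> ", length(x$types), " event types\n", sep = "")
  invisible(x)
}

#' Assemble events from triggers and labeled relations
#'
#' Each trigger with at least one positive relation yields one event whose
#' type is the trigger's type; trigger-valued relation targets resolve to
#' the target trigger's event (and are silently dropped when the target
#' trigger assembled no event). Triggers with no positive relations yield
#' no event.
#'
#' @param triggers Data frame of triggers (`id`, `type`, `start`, `end`).
#' @param relations Data frame of positive relations (`source_id`,
#'   `target_id`, `target_kind`, `role`).
#' @param entities Data frame of entities, used to validate references.
#' @return A list of events (id, type, trigger_id, args).
#' @export
assemble_events <- function(triggers, relations, entities) {
  if (nrow(relations)) {
    bad <- setdiff(relations$source_id, triggers$id)
    if (length(bad))
      stop("relation references unknown trigger(s): ",
           paste(bad, collapse = ", "))
    bad <- setdiff(relations$target_id, c(triggers$id, entities$id))
    if (length(bad))
      stop("relation references unknown annotation(s): ",
           paste(bad, collapse = ", "))
  }
  with_ev <- intersect(triggers$id[order(numeric_id(triggers$id))],
                       unique(relations$source_id))
  ev_of <- setNames(id_seq("E", length(with_ev)), with_ev)
  events <- list()
  for (tid in with_ev) {
    rel <- relations[relations$source_id == tid, , drop = FALSE]
    filler <- character(nrow(rel)); keep <- logical(nrow(rel))
    for (i in seq_len(nrow(rel))) {
      if (rel$target_kind[i] == "trigger") {
        f <- ev_of[rel$target_id[i]]
        keep[i] <- !is.na(f)
        filler[i] <- if (keep[i]) f else NA_character_
      } else {
        keep[i] <- TRUE
        filler[i] <- rel$target_id[i]
      }
    }
    args <- data.frame(role = rel$role[keep], filler = filler[keep],
                       stringsAsFactors = FALSE)
    args <- unique(args[order(args$role, args$filler), , drop = FALSE])
    rownames(args) <- NULL
    events[[length(events) + 1L]] <- list(
      id = unname(ev_of[tid]),
      type = triggers$type[triggers$id == tid],
      trigger_id = tid, args = args)
  }
  events
}

event_key <- function(ev)
  paste(ev$type, ev$trigger_id,
        paste(ev$args$role, ev$args$filler, sep = ":", collapse = " "))

# Drop any argument of the latest-id event on a reference cycle.
break_cycles <- function(events) {
  repeat {
    ids <- vapply(events, `[[`, "", "id")
    cyc <- find_cycle(events, ids)
    if (is.null(cyc)) return(events)
    victim <- cyc[which.max(numeric_id(cyc))]
    vi <- which(ids == victim)
    nxt <- cyc[(match(victim, cyc) %% length(cyc)) + 1L]
    ev <- events[[vi]]
    ev$args <- ev$args[ev$args$filler != nxt, , drop = FALSE]
    events[[vi]] <- ev
  }
}

find_cycle <- function(events, ids) {
  kids <- lapply(events, function(ev)
    intersect(ev$args$filler[grepl("^E", ev$args$filler)], ids))
  names(kids) <- ids
  state <- setNames(rep(0L, length(ids)), ids)
  stack <- character(0)
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return()
    if (state[[id]] == 1L) {
      found <<- stack[seq(match(id, stack), length(stack))]
      return()
    }
    if (state[[id]] == 2L) return()
    state[[id]] <<- 1L; stack <<- c(stack, id)
    for (k in kids[[id]]) visit(k)
    stack <<- stack[-length(stack)]; state[[id]] <<- 2L
  }
  for (id in ids) { visit(id); if (!is.null(found)) break }
  found
}

#' Post-process assembled events against a schema
#'
#' Applies, iterated to a fixpoint: (1) drop arguments whose role the
#' event type does not allow; (2) drop event-valued arguments on roles the
#' schema does not permit to take events; (3) drop arguments whose filler
#' event no longer exists; (4) drop events lacking a core argument;
#' (5) break reference cycles by dropping the offending argument of the
#' later-id event; (6) de-duplicate identical (type, trigger, args)
#' events. The result always satisfies the schema and is acyclic, and a
#' second application is the identity.
#'
#' @param events Events from [assemble_events()].
#' @param schema An [load_schema()] result.
#' @return The filtered event list.
#' @export
postprocess_events <- function(events, schema) {
  repeat {
    before <- vapply(events, event_key, "")
    ids <- vapply(events, `[[`, "", "id")
    events <- lapply(events, function(ev) {
      sc <- schema_entry(schema, ev$type)
      a <- ev$args
      a <- a[a$role %in% sc$roles, , drop = FALSE]
      is_ev <- grepl("^E", a$filler)
      a <- a[!is_ev | a$role %in% sc$event_valued, , drop = FALSE]
      is_ev <- grepl("^E", a$filler)
      a <- a[!is_ev | a$filler %in% ids, , drop = FALSE]
      ev$args <- a
      ev
    })
    events <- Filter(function(ev) {
      sc <- schema_entry(schema, ev$type)
      any(ev$args$role %in% sc$core)
    }, events)
    events <- break_cycles(events)
    events <- events[!duplicated(vapply(events, event_key, ""))]
    after <- vapply(events, event_key, "")
    if (identical(before, after)) return(events)
  }
}
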