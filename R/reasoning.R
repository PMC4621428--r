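RELATIONS <- c("before", "after", "while", "when", "during")

#' Construct a temporal assertion
#'
#' A relation between two named events. `after` is normalized away:
#' `after(a, b)` becomes `before(b, a)`. Aspect hints may force an
#' operand to be construed as punctate (a single moment) or durational
#' (an interval); unspecified aspects are inferred from the premise set
#' (see [build_models()]).
#'
#' @param subject,object event labels.
#' @param relation one of `before`, `after`, `while`, `when`, `during`.
#' @param subject_aspect,object_aspect `NA`, `"punctate"` or
#'   `"durational"`.
#' @return An object of class `temporal_assertion`.
#' @export
temporal_assertion <- function(subject, relation, object,
                               subject_aspect = NA_character_,
                               object_aspect = NA_character_) {
  stopifnot(relation %in% RELATIONS, nzchar(subject), nzchar(object))
  if (relation == "after") {
    tmp <- subject; subject <- object; object <- tmp
    tmp <- subject_aspect; subject_aspect <- object_aspect
    object_aspect <- tmp
    relation <- "before"
  }
  structure(list(subject = subject, relation = relation, object = object,
                 subject_aspect = subject_aspect,
                 object_aspect = object_aspect),
            class = "temporal_assertion")
}

#' Parse a temporal assertion from text
#'
#' Grammar: `<label> (before|after|while|when|during) <label>`.
#'
#' @param text a single assertion string.
#' @return A [temporal_assertion()].
#' @examples
#' parse_assertion("shower before coffee")
#' @export
parse_assertion <- function(text) {
  m <- regmatches(text, regexec(
    "^\\s*(\\S+)\\s+(before|after|while|when|during)\\s+(\\S+)\\s*$",
    text))[[1]]
  if (length(m) != 4L)
    stop("cannot parse assertion: '", text, "'")
  temporal_assertion(m[2], m[3], m[4])
}

#' Parse premises, one assertion per line
#'
#' @param text character vector of lines, or a single string with
#'   newlines; blank lines and `#` comments are skipped.
#' @return A list of [temporal_assertion()]s.
#' @export
parse_premises <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(lines, parse_assertion)
}

#' @export
print.temporal_assertion <- function(x, ...) {
  cat(sprintf("<%s %s %s>\n", x$subject, x$relation, x$object))
  invisible(x)
}

# ---------------------------------------------------------------------------
# aspect inference: events default to punctate; the object of `during` and
# of `while` is construed durationally; `when` forces both operands
# punctate; explicit hints win. Returns named character vector or NULL on
# an aspect contradiction.
infer_aspects <- function(premises, extra_labels = character()) {
  labels <- unique(c(unlist(lapply(premises, function(p)
    c(p$subject, p$object))), extra_labels))
  want <- stats::setNames(rep(NA_character_, length(labels)), labels)
  claim <- function(lab, asp) {
    cur <- want[[lab]]
    if (is.na(cur)) want[[lab]] <<- asp
    else if (cur != asp) want[[lab]] <<- "conflict"
  }
  for (p in premises) {
    if (!is.na(p$subject_aspect)) claim(p$subject, p$subject_aspect)
    if (!is.na(p$object_aspect)) claim(p$object, p$object_aspect)
  }
  for (p in premises) {
    if (p$relation == "when") {
      for (lab in c(p$subject, p$object))
        if (is.na(want[[lab]])) want[[lab]] <- "punctate"
    }
    if (p$relation %in% c("while", "during")) {
      if (is.na(want[[p$object]])) want[[p$object]] <- "durational"
    }
  }
  if (any(want == "conflict", na.rm = TRUE)) return(NULL)
  for (p in premises) {
    if (p$relation == "when" &&
        any(want[c(p$subject, p$object)] == "durational", na.rm = TRUE))
      return(NULL)    # `when` requires punctate co-position
  }
  want[is.na(want)] <- "punctate"
  want
}

# tokens for one event under an aspect map: punctate "p:<x>", durational
# "s:<x>" and "e:<x>"
start_token <- function(x, aspects)
  if (aspects[[x]] == "punctate") paste0("p:", x) else paste0("s:", x)
end_token <- function(x, aspects)
  if (aspects[[x]] == "punctate") paste0("p:", x) else paste0("e:", x)

# compile a premise to strict-precedence atoms lt(x, y) and coincidence
# atoms eq(x, y) over tokens
compile_premise <- function(p, aspects) {
  a <- p$subject; b <- p$object
  lt <- function(x, y) list(op = "lt", x = x, y = y)
  eq <- function(x, y) list(op = "eq", x = x, y = y)
  switch(p$relation,
    before = list(lt(end_token(a, aspects), start_token(b, aspects))),
    when = list(eq(start_token(a, aspects), start_token(b, aspects))),
    during = list(lt(start_token(b, aspects), start_token(a, aspects)),
                  lt(end_token(a, aspects), end_token(b, aspects))),
    "while" = {
      ap <- aspects[[a]] == "punctate"; bp <- aspects[[b]] == "punctate"
      if (ap && bp) list(eq(paste0("p:", a), paste0("p:", b)))
      else if (ap) list(lt(paste0("s:", b), paste0("p:", a)),
                        lt(paste0("p:", a), paste0("e:", b)))
      else if (bp) list(lt(paste0("s:", a), paste0("p:", b)),
                        lt(paste0("p:", b), paste0("e:", a)))
      else list(lt(paste0("s:", a), paste0("e:", b)),
                lt(paste0("s:", b), paste0("e:", a)))
    },
    stop("unknown relation ", p$relation))
}

# turn one slot arrangement (token -> slot index) into an event model
arrangement_to_model <- function(slot_of, labels, aspects, priority_order,
                                 max_depth) {
  rows <- lapply(labels, function(x) {
    punct <- aspects[[x]] == "punctate"
    s <- slot_of[[start_token(x, aspects)]]
    e <- slot_of[[end_token(x, aspects)]]
    data.frame(label = x, channel = NA_character_, entity = x,
               start_marker = NA_character_, end_marker = NA_character_,
               start_time = as.numeric(s), end_time = as.numeric(e),
               punctate = punct, stringsAsFactors = FALSE)
  })
  finalize_model(do.call(rbind, rows), "veridical", priority_order,
                 max_depth)
}

#' Build event models from premises
#'
#' Constructs the discrete arrangements of events on an ordinal timeline
#' that are consistent with all premises. Events are punctate or
#' durational (aspects inferred per [temporal_assertion()]); two events
#' coincide only where a `when` premise forces it. The first model
#' returned is the deterministic initial model obtained by placing each
#' event at the first position that satisfies the premises in their given
#' order; subsequent models enumerate the remaining distinct arrangements,
#' up to `max_models` (the `truncated` attribute records whether more
#' exist). Contradictory premises yield an empty list with attribute
#' `inconsistent = TRUE`.
#'
#' @param premises list of [temporal_assertion()]s (or a character vector
#'   parsed by [parse_premises()]).
#' @param max_models bound on the number of models returned (default 8).
#' @return A list of `event_model`s with attributes `inconsistent`,
#'   `truncated`, and `model_count` (= number returned).
#' @examples
#' length(build_models(parse_premises(
#'   "shower before coffee\ncoffee before breakfast")))  # 1
#' @export
build_models <- function(premises, max_models = 8) {
  if (is.character(premises)) premises <- parse_premises(premises)
  stopifnot(length(premises) >= 1L)
  aspects <- infer_aspects(premises)
  done <- function(models, inconsistent, truncated) {
    attr(models, "inconsistent") <- inconsistent
    attr(models, "truncated") <- truncated
    attr(models, "model_count") <- length(models)
    models
  }
  if (is.null(aspects)) return(done(list(), TRUE, FALSE))
  labels <- names(aspects)

  atoms <- unlist(lapply(premises, compile_premise, aspects = aspects),
                  recursive = FALSE)
  # merge coincident tokens (from `when`) into units
  tokens <- unique(unlist(lapply(labels, function(x)
    c(start_token(x, aspects), end_token(x, aspects)))))
  unit <- stats::setNames(tokens, tokens)
  find <- function(t) { while (unit[[t]] != t) t <- unit[[t]]; t }
  for (at in atoms) if (at$op == "eq") unit[[find(at$x)]] <- find(at$y)
  rep_of <- vapply(tokens, find, "")

  # strict precedence edges between units, incl. s < e within each event
  edges <- list()
  for (x in labels) if (aspects[[x]] == "durational")
    edges[[length(edges) + 1L]] <- c(rep_of[[paste0("s:", x)]],
                                     rep_of[[paste0("e:", x)]])
  for (at in atoms) if (at$op == "lt")
    edges[[length(edges) + 1L]] <- c(rep_of[[at$x]], rep_of[[at$y]])
  units <- unique(unname(rep_of))
  if (any(vapply(edges, function(e) e[1] == e[2], TRUE)))
    return(done(list(), TRUE, FALSE))
  pred <- stats::setNames(vector("list", length(units)), units)
  for (e in edges) pred[[e[2]]] <- unique(c(pred[[e[2]]], e[1]))

  # units in order of first mention: the greedy (first) linear extension
  # is the first-fit initial model
  mention <- unique(unlist(lapply(premises, function(p) {
    c(start_token(p$subject, aspects), end_token(p$subject, aspects),
      start_token(p$object, aspects), end_token(p$object, aspects))
  })))
  unit_order <- unique(c(vapply(mention, function(t) rep_of[[t]], ""), units))

  arrangements <- list()
  limit <- max_models + 1L
  recurse <- function(placed) {
    if (length(arrangements) >= limit) return()
    if (length(placed) == length(units)) {
      arrangements[[length(arrangements) + 1L]] <<- placed
      return()
    }
    remaining <- setdiff(unit_order, placed)
    for (u in remaining) {
      if (all(pred[[u]] %in% placed)) recurse(c(placed, u))
      if (length(arrangements) >= limit) return()
    }
  }
  recurse(character(0))
  if (!length(arrangements)) return(done(list(), TRUE, FALSE))

  truncated <- length(arrangements) > max_models
  arrangements <- utils::head(arrangements, max_models)
  models <- lapply(arrangements, function(ord) {
    slot_of <- stats::setNames(match(rep_of, ord), tokens)
    arrangement_to_model(as.list(slot_of), labels, aspects, CHANNELS, 4)
  })
  done(models, FALSE, truncated)
}

# ---------------------------------------------------------------------------

event_extent <- function(model, label) {
  i <- match(label, model$events$label)
  if (is.na(i)) stop("unknown event label '", label, "'")
  s <- model$events$start_ord[i]
  e <- if (model$events$punctate[i]) s
       else if (is.na(model$events$end_ord[i])) Inf
       else model$events$end_ord[i]
  list(s = s, e = e, punctate = isTRUE(model$events$punctate[i]))
}

#' Does an assertion hold in one model?
#'
#' Scans the model's ordinal timeline. `before`: the subject's end
#' strictly precedes the object's start. `when`: identical extent
#' (punctate co-position). `while`: a punctate operand strictly inside
#' the durational operand's extent; two durational operands overlap; two
#' punctate operands coincide. `during`: proper containment. Open events
#' are right-unbounded.
#'
#' @param model an `event_model`.
#' @param assertion a [temporal_assertion()] or string.
#' @return Logical.
#' @export
holds_in <- function(model, assertion) {
  if (is.character(assertion)) assertion <- parse_assertion(assertion)
  a <- event_extent(model, assertion$subject)
  b <- event_extent(model, assertion$object)
  switch(assertion$relation,
    before = a$e < b$s,
    when = a$s == b$s && a$e == b$e && is.finite(a$e),
    during = b$s < a$s && a$e < b$e,
    "while" = {
      if (a$punctate && !b$punctate) b$s < a$s && a$s < b$e
      else if (!a$punctate && b$punctate) a$s < b$s && b$s < a$e
      else if (a$punctate && b$punctate) a$s == b$s
      else a$s < b$e && b$s < a$e
    },
    stop("unknown relation ", assertion$relation))
}

new_verdict <- function(status, model_count, holds_count = NA_integer_,
                        bounded = FALSE, witness = list()) {
  structure(list(status = status, model_count = model_count,
                 holds_count = holds_count, bounded = bounded,
                 witness = witness),
            class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  lab <- x$status
  if (x$status == "necessary" && x$bounded) lab <- "necessary-up-to-bound"
  cat(sprintf("<verdict: %s (%d/%d models)>\n", lab,
              ifelse(is.na(x$holds_count), 0L, x$holds_count),
              x$model_count))
  invisible(x)
}

#' Query models for the modal status of an assertion
#'
#' Scans each model: the relation is `necessary` if it holds in every
#' model, `impossible` if it holds in none, and `possible` otherwise. An
#' inconsistent (zero-model) premise set yields status
#' `inconsistent-premises`. If the model list was truncated at its bound,
#' a `necessary` verdict is flagged `bounded` (necessary up to the bound).
#'
#' @param models list of `event_model`s from [build_models()], or a
#'   single `event_model`.
#' @param assertion a [temporal_assertion()] or string.
#' @return An object of class `verdict`.
#' @examples
#' query(build_models("shower before coffee\ncoffee before breakfast"),
#'       "shower before breakfast")
#' @export
query <- function(models, assertion) {
  if (inherits(models, "event_model")) models <- list(models)
  if (is.character(assertion)) assertion <- parse_assertion(assertion)
  if (!length(models))
    return(new_verdict("inconsistent-premises", 0L))
  hold <- vapply(models, holds_in, TRUE, assertion = assertion)
  status <- if (all(hold)) "necessary"
            else if (!any(hold)) "impossible"
            else "possible"
  new_verdict(status, length(models), sum(hold),
              bounded = isTRUE(attr(models, "truncated")),
              witness = models[hold])
}

#' Counterfactually revise an event model
#'
#' Returns a new model in which one event is repositioned while every
#' other event keeps its position; ordinals, nesting, and depths are
#' recomputed. The original model is unchanged. Either give the new
#' boundary values directly (on the model's time axis; values between or
#' beyond existing boundaries are allowed) or name an event to move
#' `after`.
#'
#' @param model an `event_model`.
#' @param label event to move.
#' @param new_start,new_end new boundary values (`new_end` ignored for
#'   punctate events; `NA` end keeps an open event open).
#' @param after alternative placement: move the event to just after the
#'   named event's end, preserving its width.
#' @return A new `event_model`.
#' @examples
#' m <- construct_model(segment_stream(two_location_goal_fixture()))
#' query(revise(m, "location-1", after = "location-2"),
#'       "location-1 during goal")  # impossible
#' @export
revise <- function(model, label, new_start = NULL, new_end = NULL,
                   after = NULL) {
  stopifnot(inherits(model, "event_model"))
  ev <- model$events
  i <- match(label, ev$label)
  if (is.na(i)) stop("unknown event label '", label, "'")
  if (!is.null(after)) {
    j <- match(after, ev$label)
    if (is.na(j)) stop("unknown event label '", after, "'")
    ref_end <- ev$end_time[j]
    if (is.na(ref_end)) ref_end <- max(model$positions$time)
    width <- if (ev$punctate[i] || is.na(ev$end_time[i])) 0
             else ev$end_time[i] - ev$start_time[i]
    new_start <- ref_end + 1
    new_end <- if (is.na(ev$end_time[i])) NA_real_ else new_start + width
  }
  if (is.null(new_start) || !is.finite(new_start))
    stop("revise needs a finite new_start (or an 'after' event)")
  if (ev$punctate[i]) new_end <- new_start
  if (is.null(new_end)) new_end <- ev$end_time[i]
  if (!is.na(new_end) && new_end < new_start)
    stop("placement collides with interval invariants: end before start")
  ev$start_time[i] <- new_start
  ev$end_time[i] <- new_end
  finalize_model(ev, model$mode, model$priority_order, model$max_depth)
}

#' Infer the modal status of an assertion from premises
#'
#' Convenience wrapper: `query(build_models(premises, max_models),
#' assertion)`.
#'
#' @inheritParams build_models
#' @param assertion a [temporal_assertion()] or string.
#' @return A `verdict`; its `model_count` field exposes how many models
#'   the premises admit (one-model problems are decidable from the
#'   initial model alone).
#' @export
infer <- function(premises, assertion, max_models = 8) {
  query(build_models(premises, max_models), assertion)
}
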