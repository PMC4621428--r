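#' @keywords internal
new_event_model <- function(events, positions, mode, priority_order,
                            max_depth) {
  structure(list(events = events, positions = positions, mode = mode,
                 priority_order = priority_order, max_depth = max_depth),
            class = "event_model")
}

empty_events_df <- function() {
  data.frame(label = character(), channel = character(),
             entity = character(), start_marker = character(),
             end_marker = character(), start_time = numeric(),
             end_time = numeric(), start_ord = numeric(),
             end_ord = numeric(), punctate = logical(),
             parent = character(), depth = numeric(),
             stringsAsFactors = FALSE)
}

channel_rank <- function(channel, priority_order) {
  r <- match(channel, priority_order)
  ifelse(is.na(r), length(priority_order) + 1L, r)
}

# assign ordinals, nesting parents, and bounded depths to an events table
finalize_model <- function(events, mode, priority_order, max_depth) {
  if (!nrow(events)) {
    return(new_event_model(empty_events_df(),
                           data.frame(time = numeric(), ordinal = integer()),
                           mode, priority_order, max_depth))
  }
  bounds <- sort(unique(c(events$start_time,
                          events$end_time[!is.na(events$end_time)])))
  positions <- data.frame(time = bounds, ordinal = seq_along(bounds))
  events$start_ord <- match(events$start_time, bounds)
  events$end_ord <- ifelse(is.na(events$end_time), NA_integer_,
                           match(events$end_time, bounds))

  # nesting by interval containment; a container must be of priority >=
  # the child's channel; deepest (smallest-span) container wins, ties go
  # to the earliest-starting container
  n <- nrow(events)
  s <- events$start_time
  e <- ifelse(is.na(events$end_time), Inf, events$end_time)
  rank <- channel_rank(events$channel, priority_order)
  events$parent <- NA_character_
  for (i in seq_len(n)) {
    cand <- which(seq_len(n) != i & s <= s[i] & e >= e[i] &
                    (s < s[i] | e > e[i]) & rank <= rank[i])
    if (!length(cand)) next
    span <- e[cand] - s[cand]
    cand <- cand[order(span, s[cand])]
    events$parent[i] <- events$label[cand[1]]
  }

  depth_of <- function(i, seen = character()) {
    p <- events$parent[i]
    if (is.na(p) || p %in% seen) return(1L)
    1L + depth_of(match(p, events$label), c(seen, events$label[i]))
  }
  events$depth <- vapply(seq_len(n), depth_of, 1L)

  # flatten nesting beyond max_depth: reparent to the ancestor sitting at
  # depth max_depth - 1 so the event lands at depth max_depth
  if (any(events$depth > max_depth)) {
    for (i in order(events$depth)) {
      if (events$depth[i] <= max_depth) next
      p <- match(events$parent[i], events$label)
      while (events$depth[p] > max_depth - 1L)
        p <- match(events$parent[p], events$label)
      events$parent[i] <- events$label[p]
      events$depth[i] <- max_depth
    }
  }
  rownames(events) <- NULL
  new_event_model(events, positions, mode, priority_order, max_depth)
}

#' Construct an event model from episodic markers
#'
#' Retrospective reconstruction: markers are swept earliest to latest;
#' each onset change opens a provisional event and each offset change
#' closes the compatible provisional event (same channel and entity). A
#' single marker may close one event and open another (location
#' transitions carry the previous location as `prior`). When a goal
#' offsets, the lower-priority provisional events that were opened within
#' that goal's context are closed by the goal's end marker (a goal's
#' satisfaction bounds its subevents). Provisional events still open when
#' the markers run out are committed as open (`end_time = NA`), which
#' behave as right-unbounded intervals.
#'
#' In `veridical` mode every committed event is kept (a one-to-one mapping
#' of marker pairs to events). In `prioritized` mode only the events of
#' the highest-priority channel present are kept — the superordinate
#' events; pass `flesh_out = TRUE` to additionally keep lower-priority
#' events that fall within the bounds of a kept event of strictly higher
#' priority.
#'
#' Events are then placed on an ordinal timeline (no metric information:
#' boundary timestamps map to consecutive ordinals 1..k, simultaneous
#' boundaries sharing one ordinal) and nested into a partonomy by interval
#' containment, bounded at `max_depth`.
#'
#' @param markers an `episodic_markers` list, time-ordered.
#' @param mode `"veridical"` or `"prioritized"`.
#' @param priority_order channel ranking, highest priority first.
#' @param max_depth partonomy depth bound (default 4).
#' @param flesh_out logical; see above (prioritized mode only).
#' @return An object of class `event_model`.
#' @examples
#' construct_model(segment_stream(two_location_goal_fixture()))
#' @export
construct_model <- function(markers, mode = c("veridical", "prioritized"),
                            priority_order = CHANNELS, max_depth = 4,
                            flesh_out = FALSE) {
  mode <- match.arg(mode)
  if (!length(markers))
    return(finalize_model(empty_events_df(), mode, priority_order, max_depth))
  times <- vapply(markers, `[[`, 0, "time")
  if (is.unsorted(times)) stop("markers must be time-ordered")

  goal_stack <- character(0)
  provisional <- list()   # each: channel, entity, start_id, start_time, goals
  committed <- list()

  close_prov <- function(k, m) {
    p <- provisional[[k]]
    committed[[length(committed) + 1L]] <<- data.frame(
      label = p$entity, channel = p$channel, entity = p$entity,
      start_marker = p$start_id, end_marker = m$id,
      start_time = p$start_time, end_time = m$time,
      punctate = p$start_time == m$time, stringsAsFactors = FALSE)
    provisional[[k]] <<- NULL
  }
  find_prov <- function(channel, entity) {
    hits <- which(vapply(provisional, function(p)
      p$channel == channel && p$entity == entity, TRUE))
    if (length(hits)) hits[length(hits)] else 0L
  }

  for (m in markers) {
    for (i in seq_len(nrow(m$changes))) {
      ch <- m$changes$channel[i]; en <- m$changes$entity[i]
      pol <- m$changes$polarity[i]; prior <- m$changes$prior[i]
      if (pol == "onset") {
        if (!is.na(prior)) {
          k <- find_prov(ch, prior)
          if (k) close_prov(k, m)
        }
        provisional[[length(provisional) + 1L]] <-
          list(channel = ch, entity = en, start_id = m$id,
               start_time = m$time, goals = goal_stack)
        if (ch == "goal") goal_stack <- c(goal_stack, en)
      } else {
        k <- find_prov(ch, en)
        if (k) close_prov(k, m)
        if (ch == "goal") {
          pos <- which(goal_stack == en)
          if (length(pos))
            goal_stack <- goal_stack[seq_len(max(pos) - 1L)]
          # goal satisfaction bounds the subevents opened in its context
          in_ctx <- which(vapply(provisional, function(p)
            en %in% p$goals, TRUE))
          for (k2 in rev(in_ctx)) close_prov(k2, m)
        }
      }
    }
  }
  last <- markers[[length(markers)]]
  for (p in provisional) {
    committed[[length(committed) + 1L]] <- data.frame(
      label = p$entity, channel = p$channel, entity = p$entity,
      start_marker = p$start_id, end_marker = NA_character_,
      start_time = p$start_time, end_time = NA_real_,
      punctate = FALSE, stringsAsFactors = FALSE)
  }
  events <- do.call(rbind, committed)
  if (is.null(events)) events <- empty_events_df()
  events <- number_duplicate_labels(events, start = "start_time")

  if (mode == "prioritized" && nrow(events)) {
    rank <- channel_rank(events$channel, priority_order)
    keep <- rank == min(rank)
    if (flesh_out) {
      s <- events$start_time
      e <- ifelse(is.na(events$end_time), Inf, events$end_time)
      for (r in sort(unique(rank[!keep]))) {
        cand <- which(rank == r & !keep)
        for (i in cand) {
          holders <- which(keep & rank < r & s <= s[i] & e >= e[i])
          if (length(holders)) keep[i] <- TRUE
        }
      }
    }
    events <- events[keep, , drop = FALSE]
  }
  finalize_model(events, mode, priority_order, max_depth)
}

#' @export
print.event_model <- function(x, ...) {
  cat(sprintf("<event model (%s): %d events, %d ordinal positions>\n",
              x$mode, nrow(x$events), nrow(x$positions)))
  if (nrow(x$events)) cat(render(x), sep = "\n")
  invisible(x)
}

#' Events of a model
#'
#' @param model an `event_model`.
#' @return The events `data.frame` (one row per event, with marker ids,
#'   timestamps, ordinals, punctate flag, parent and depth).
#' @export
events <- function(model) {
  stopifnot(inherits(model, "event_model"))
  model$events
}

#' Boundary positions of a model
#'
#' Maps each distinct boundary timestamp to its ordinal (1..k, in time
#' order, no metric spacing). Punctate events occupy a single ordinal.
#'
#' @param model a non-empty `event_model`.
#' @return A `data.frame` with columns `time` and `ordinal`.
#' @export
positions_of <- function(model) {
  stopifnot(inherits(model, "event_model"))
  if (!nrow(model$events)) stop("model has no events")
  model$positions
}

#' Ordinal of an event boundary
#'
#' @param model an `event_model`.
#' @param label event label.
#' @param boundary `"start"` or `"end"`.
#' @return The ordinal position (integer), or `NA` for the end of an open
#'   event.
#' @examples
#' m <- construct_model(segment_stream(office_day_fixture()))
#' boundary_ordinal(m, "meeting", "end")  # 3
#' @export
boundary_ordinal <- function(model, label, boundary = c("start", "end")) {
  boundary <- match.arg(boundary)
  i <- match(label, model$events$label)
  if (is.na(i)) stop("unknown event label '", label, "'")
  model$events[[paste0(boundary, "_ord")]][i]
}
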