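#' Create an empty world state
#'
#' The world state tracks, per channel, which entities are currently
#' active. The location channel is single-valued (an onset of a new
#' location implicitly ends the previous one); goal, person, and object
#' channels are multi-valued. Goals additionally form a stack: the most
#' recently onset goal is the current goal context.
#'
#' @return An environment of class `world_state`.
#' @export
new_world_state <- function() {
  st <- new.env(parent = emptyenv())
  st$location <- NA_character_
  st$goal <- character(0)     # stack, last = innermost/current
  st$person <- character(0)
  st$object <- character(0)
  class(st) <- "world_state"
  st
}

#' Detect the changes implied by one observation
#'
#' Compares an observation with the current world state, returns the
#' implied change set (possibly empty, e.g. when re-observing an already
#' active entity), and updates the state in place. A location onset
#' carries the previous location as `prior`.
#'
#' Offsets of entities that are not currently active are "dangling": in
#' tolerant mode (default) they are recorded with `prior = NA` and a
#' warning; in strict mode they are an error.
#'
#' @param state a [new_world_state()] environment (modified in place).
#' @param obs a single-row observation table.
#' @param strict logical; error on dangling offsets instead of warning.
#' @return A `data.frame` of changes with columns `channel`, `entity`,
#'   `polarity`, `prior` (zero rows if the observation changes nothing).
#' @export
detect_changes <- function(state, obs, strict = FALSE) {
  stopifnot(inherits(state, "world_state"), nrow(obs) == 1L)
  ch <- obs$channel; en <- obs$entity; pol <- obs$polarity
  change <- function(prior = NA_character_)
    data.frame(channel = ch, entity = en, polarity = pol, prior = prior,
               stringsAsFactors = FALSE)
  none <- change()[0, , drop = FALSE]

  if (ch == "location") {
    if (pol == "onset") {
      if (!is.na(state$location) && state$location == en) return(none)
      out <- change(prior = state$location)
      state$location <- en
      return(out)
    }
    # location offset: leaving the current location
    if (is.na(state$location) || state$location != en) {
      if (strict) stop("offset of inactive entity '", en, "' on channel ", ch)
      warning("dangling offset of '", en, "' on channel ", ch)
      return(change())
    }
    state$location <- NA_character_
    return(change())
  }

  active <- get(ch, envir = state)
  if (pol == "onset") {
    if (en %in% active) return(none)
    assign(ch, c(active, en), envir = state)
    return(change())
  }
  if (!en %in% active) {
    if (strict) stop("offset of inactive entity '", en, "' on channel ", ch)
    warning("dangling offset of '", en, "' on channel ", ch)
    return(change())
  }
  assign(ch, if (ch == "goal") active[seq_len(max(which(active == en)) - 1L)]
             else setdiff(active, en),
         envir = state)
  change()
}

new_marker <- function(id, time, changes, prior_marker, goal_context,
                       encoding_strength) {
  structure(list(id = id, time = time, changes = changes,
                 prior_marker = prior_marker, goal_context = goal_context,
                 encoding_strength = encoding_strength),
            class = "episodic_marker")
}

#' Encode an episodic marker
#'
#' A marker is a punctate chunk in episodic memory recording every change
#' detected at one instant, linked to its predecessor and tagged with the
#' goal active at encoding time. Its initial encoding strength grows with
#' the number of changes it encodes: `base + beta * nrow(changes)`.
#'
#' @param changes non-empty change table from [detect_changes()] (rows
#'   from several observations at the same timestamp may be combined).
#' @param time encoding timestamp.
#' @param prior_marker id of the preceding marker, or `NA` for the first.
#' @param active_goal goal entity providing context, or `NA`.
#' @param id marker id (`"Ep-<n>"`).
#' @param base,beta encoding-strength parameters.
#' @return An object of class `episodic_marker`.
#' @export
encode_marker <- function(changes, time, prior_marker = NA_character_,
                          active_goal = NA_character_, id = "Ep-1",
                          base = 0, beta = 1) {
  if (is.null(changes) || nrow(changes) == 0L)
    stop("cannot encode a marker with an empty change set")
  new_marker(id = id, time = time, changes = changes,
             prior_marker = prior_marker, goal_context = active_goal,
             encoding_strength = base + beta * nrow(changes))
}

#' @export
print.episodic_marker <- function(x, ...) {
  cat(sprintf("<%s t=%g goal=%s changes=%s>\n", x$id, x$time,
              ifelse(is.na(x$goal_context), "-", x$goal_context),
              paste(sprintf("%s:%s/%s", x$changes$channel, x$changes$entity,
                            substr(x$changes$polarity, 1, 3)),
                    collapse = ",")))
  invisible(x)
}

#' @export
print.episodic_markers <- function(x, ...) {
  cat(sprintf("<%d episodic markers>\n", length(x)))
  for (m in x) print(m)
  invisible(x)
}

#' Segment an observation stream into episodic markers
#'
#' Online, single-pass encoding: all changes detected at one timestamp
#' collapse into one marker; timestamps at which nothing changes yield no
#' marker. Each marker is linked to its predecessor and tagged with the
#' goal context active at that instant (a marker that offsets a goal
#' carries the ending goal as its context; with nested goals the most
#' recent onset wins). The process never revises earlier markers, so
#' segmenting a prefix of a stream gives a prefix of the markers.
#'
#' @param scen a [scenario()] or an observation table.
#' @param strict logical, passed to [detect_changes()].
#' @param base,beta encoding-strength parameters (see [encode_marker()]).
#' @return An ordered list of markers, class `episodic_markers`.
#' @examples
#' length(segment_stream(two_location_goal_fixture()))  # 4
#' @export
segment_stream <- function(scen, strict = FALSE, base = 0, beta = 1) {
  obs <- if (inherits(scen, "scenario")) scen$observations else scen
  if (nrow(obs) == 0L)
    return(structure(list(), class = "episodic_markers"))
  if (is.unsorted(obs$time)) stop("observations must be time-ordered")

  state <- new_world_state()
  markers <- list()
  prior_id <- NA_character_
  for (tm in unique(obs$time)) {
    group <- obs[obs$time == tm, , drop = FALSE]
    chg <- list()
    for (i in seq_len(nrow(group))) {
      one <- detect_changes(state, group[i, , drop = FALSE], strict = strict)
      if (nrow(one)) chg[[length(chg) + 1L]] <- one
    }
    if (!length(chg)) next
    changes <- do.call(rbind, chg)
    # goal context: a marker that offsets a goal carries the ending goal
    # (the innermost one if several end here); otherwise the innermost
    # goal active at this instant
    goal_offs <- changes$entity[changes$channel == "goal" &
                                  changes$polarity == "offset"]
    ctx <- if (length(goal_offs)) goal_offs[1]
           else if (length(state$goal)) state$goal[length(state$goal)]
           else NA_character_
    id <- sprintf("Ep-%d", length(markers) + 1L)
    markers[[length(markers) + 1L]] <- encode_marker(
      changes, time = tm, prior_marker = prior_id,
      active_goal = ctx, id = id, base = base, beta = beta)
    prior_id <- id
  }
  structure(markers, class = "episodic_markers")
}

#' Markers as a data frame
#'
#' @param markers an `episodic_markers` list.
#' @return One row per marker: `id`, `time`, `prior_marker`,
#'   `goal_context`, `n_changes`, `encoding_strength`.
#' @export
markers_to_df <- function(markers) {
  if (!length(markers))
    return(data.frame(id = character(), time = numeric(),
                      prior_marker = character(), goal_context = character(),
                      n_changes = integer(), encoding_strength = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(markers, function(m)
    data.frame(id = m$id, time = m$time, prior_marker = m$prior_marker,
               goal_context = m$goal_context, n_changes = nrow(m$changes),
               encoding_strength = m$encoding_strength,
               stringsAsFactors = FALSE)))
}
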