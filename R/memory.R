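#' Create an episodic store
#'
#' Holds episodic markers together with their activation state. Activation
#' follows a base-level learning curve: a marker accessed (created,
#' retrieved, or reached by spreading) at times `t_j` with weights `w_j`
#' has, at time `now`,
#'
#' `A(now) = offset + log( sum_j w_j * max(now - t_j, epsilon)^(-decay) )`
#'
#' where `offset` is the marker's encoding strength (which grows with the
#' number of changes the marker encodes), so markers that encode many
#' changes start more active, all markers fade between accesses, and each
#' retrieval produces a spike. A retrieval also spreads a fractional
#' pseudo-access (`spread_fraction` of a full access) to the marker's
#' one-step associates: markers sharing its goal context or any change
#' channel.
#'
#' @param markers an `episodic_markers` list from [segment_stream()].
#' @param decay positive decay exponent `d` (default 0.5).
#' @param spread_fraction fraction in `[0, 1]` of a retrieval spike passed
#'   to associates (default 0.5).
#' @param epsilon floor on `now - t_j` to avoid the singularity at the
#'   instant of access (default 1e-3).
#' @param retrieval_threshold default activation cutoff for [retrieve()]
#'   (default `-Inf`: nothing is forgotten).
#' @param temporal_limit default lookback horizon for [retrieve()]
#'   (default `Inf`).
#' @return An environment of class `episodic_store`.
#' @export
episodic_store <- function(markers, decay = 0.5, spread_fraction = 0.5,
                           epsilon = 1e-3, retrieval_threshold = -Inf,
                           temporal_limit = Inf) {
  stopifnot(decay > 0, spread_fraction >= 0, spread_fraction <= 1,
            epsilon > 0)
  st <- new.env(parent = emptyenv())
  st$markers <- stats::setNames(as.list(markers),
                                vapply(markers, `[[`, "", "id"))
  st$access <- lapply(st$markers, function(m)
    data.frame(time = m$time, weight = 1))
  st$params <- list(decay = decay, spread_fraction = spread_fraction,
                    epsilon = epsilon,
                    retrieval_threshold = retrieval_threshold,
                    temporal_limit = temporal_limit)
  class(st) <- "episodic_store"
  st
}

#' @export
print.episodic_store <- function(x, ...) {
  cat(sprintf("<episodic store: %d markers, d=%g, spread=%g>\n",
              length(x$markers), x$params$decay, x$params$spread_fraction))
  invisible(x)
}

#' Activation of a marker
#'
#' @param store an [episodic_store()].
#' @param id marker id (e.g. `"Ep-3"`).
#' @param now evaluation time; must not precede the marker's creation.
#' @return The activation (a real number).
#' @examples
#' m <- segment_stream(patrol_fixture())
#' st <- episodic_store(m)
#' activation(st, "Ep-1", now = 10)
#' @export
activation <- function(store, id, now) {
  stopifnot(inherits(store, "episodic_store"))
  m <- store$markers[[id]]
  if (is.null(m)) stop("unknown marker id '", id, "'")
  if (now < m$time)
    stop("activation queried before creation of ", id)
  acc <- store$access[[id]]
  p <- store$params
  dt <- pmax(now - acc$time, p$epsilon)
  m$encoding_strength + log(sum(acc$weight * dt^(-p$decay)))
}

marker_matches_cue <- function(m, cue) {
  if (!is.null(cue$goal_context) &&
      (is.na(m$goal_context) || m$goal_context != cue$goal_context))
    return(FALSE)
  if (!is.null(cue$channel) && !cue$channel %in% m$changes$channel)
    return(FALSE)
  if (!is.null(cue$window) &&
      (m$time < cue$window[1] || m$time > cue$window[2]))
    return(FALSE)
  TRUE
}

associates_of <- function(store, m) {
  Filter(function(x) {
    if (identical(x$id, m$id)) return(FALSE)
    same_goal <- !is.na(x$goal_context) && !is.na(m$goal_context) &&
      x$goal_context == m$goal_context
    same_goal || length(intersect(x$changes$channel, m$changes$channel)) > 0
  }, store$markers)
}

#' Retrieve markers from the store
#'
#' Returns, in time order, the markers matching the cue whose activation
#' at `now` reaches the threshold and whose time lies within
#' `temporal_limit` of `now`. Each retrieved marker receives a full access
#' (spike) at `now`, and each of its one-step associates receives a
#' fractional access of weight `spread_fraction`. Retrieval never changes
#' marker content, only activation state. With the default threshold
#' (`-Inf`) and limit (`Inf`) retrieval is lossless.
#'
#' @param store an [episodic_store()].
#' @param cue a list with any of `goal_context` (exact match), `channel`
#'   (matches markers encoding a change on that channel), `window`
#'   (`c(from, to)` on marker time); `NULL`/empty cue matches everything.
#' @param now retrieval time (defaults to just after the newest marker).
#' @param threshold activation cutoff; default from the store.
#' @param temporal_limit lookback horizon; default from the store.
#' @return An `episodic_markers` list (possibly empty).
#' @export
retrieve <- function(store, cue = list(), now = NULL, threshold = NULL,
                     temporal_limit = NULL) {
  stopifnot(inherits(store, "episodic_store"))
  if (!length(store$markers))
    return(structure(list(), class = "episodic_markers"))
  if (is.null(now))
    now <- max(vapply(store$markers, `[[`, 0, "time"))
  if (is.null(threshold)) threshold <- store$params$retrieval_threshold
  if (is.null(temporal_limit)) temporal_limit <- store$params$temporal_limit

  hit <- Filter(function(m) {
    marker_matches_cue(m, cue) &&
      abs(now - m$time) <= temporal_limit &&
      m$time <= now &&
      activation(store, m$id, now) >= threshold
  }, store$markers)
  hit <- hit[order(vapply(hit, `[[`, 0, "time"))]

  sf <- store$params$spread_fraction
  for (m in hit) {
    store$access[[m$id]] <- rbind(store$access[[m$id]],
                                  data.frame(time = now, weight = 1))
    if (sf > 0) {
      for (a in associates_of(store, m))
        store$access[[a$id]] <- rbind(store$access[[a$id]],
                                      data.frame(time = now, weight = sf))
    }
  }
  structure(unname(hit), class = "episodic_markers")
}
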