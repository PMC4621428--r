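#' Observation channels
#'
#' The four channels an agent monitors, in the default priority order used
#' throughout the package: goal changes outrank location changes, which
#' outrank person changes, which outrank object changes.
#' @export
CHANNELS <- c("goal", "location", "person", "object")

#' Construct an observation table
#'
#' An observation is one timestamped symbolic change report: an entity on a
#' channel either appears/begins (`onset`) or disappears/completes
#' (`offset`). Streams of observations are the input to [segment_stream()].
#'
#' @param time numeric vector of finite, non-negative timestamps
#'   (arbitrary units).
#' @param channel character vector; each element one of
#'   `"goal"`, `"location"`, `"person"`, `"object"`.
#' @param entity character vector of non-empty symbolic labels.
#' @param polarity character vector; `"onset"` or `"offset"`.
#' @return A `data.frame` with columns `time`, `channel`, `entity`,
#'   `polarity`, sorted stably by time.
#' @examples
#' observations(c(1, 2), c("goal", "location"),
#'              c("patrol", "location-a"), c("onset", "onset"))
#' @export
observations <- function(time = numeric(), channel = character(),
                         entity = character(), polarity = character()) {
  stopifnot(length(time) == length(channel),
            length(time) == length(entity),
            length(time) == length(polarity))
  if (length(time)) {
    if (any(!is.finite(time)) || any(time < 0))
      stop("observation times must be finite and non-negative")
    if (any(!channel %in% CHANNELS))
      stop("unknown channel: ", paste(setdiff(channel, CHANNELS), collapse = ", "))
    if (any(!nzchar(entity))) stop("entity labels must be non-empty")
    if (any(!polarity %in% c("onset", "offset")))
      stop("polarity must be 'onset' or 'offset'")
  }
  obs <- data.frame(time = as.numeric(time), channel = as.character(channel),
                    entity = as.character(entity),
                    polarity = as.character(polarity),
                    stringsAsFactors = FALSE)
  # stable sort: ties keep insertion order
  obs[order(obs$time), , drop = FALSE]
}

#' Construct a scenario
#'
#' A scenario bundles a time-ordered observation stream with (optionally)
#' the ground-truth events it encodes, so that reconstruction can be
#' checked against a known answer.
#'
#' @param name scenario label.
#' @param obs observation table from [observations()].
#' @param ground_truth optional `data.frame` with columns `label`,
#'   `channel`, `entity`, `start`, `end` (`NA` end = ongoing/open event).
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, obs, ground_truth = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (is.unsorted(obs$time)) stop("observations must be time-ordered")
  if (!is.null(ground_truth)) {
    stopifnot(all(c("label", "channel", "entity", "start", "end") %in%
                    names(ground_truth)))
    closed <- !is.na(ground_truth$end)
    if (any(ground_truth$start[closed] > ground_truth$end[closed]))
      stop("ground-truth events must have start <= end")
  }
  structure(list(name = name, observations = obs,
                 ground_truth = ground_truth),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s': %d observations, %s ground-truth events>\n",
              x$name, nrow(x$observations),
              if (is.null(x$ground_truth)) "no" else nrow(x$ground_truth)))
  invisible(x)
}

gt_row <- function(label, channel, entity, start, end) {
  data.frame(label = label, channel = channel, entity = entity,
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Patrol fixture
#'
#' The worked patrol trace: an agent is given the goal of patrolling an
#' area, moves through three locations, encounters a person (Bob) who then
#' leaves, satisfies the goal, and afterwards moves to a fourth location.
#' Eight change points at unit spacing. Ground truth reflects that a
#' goal's satisfaction bounds the subevents opened within it: location-c,
#' entered during the patrol, ends with the goal at t = 7; the post-goal
#' location-d event is open-ended.
#'
#' @return A [scenario()].
#' @examples
#' patrol_fixture()
#' @export
patrol_fixture <- function() {
  obs <- observations(
    time     = 1:8,
    channel  = c("goal", "location", "location", "location",
                 "person", "person", "goal", "location"),
    entity   = c("patrol", "location-a", "location-b", "location-c",
                 "Bob", "Bob", "patrol", "location-d"),
    polarity = c("onset", "onset", "onset", "onset",
                 "onset", "offset", "offset", "onset"))
  gt <- rbind(
    gt_row("patrol",     "goal",     "patrol",     1, 7),
    gt_row("location-a", "location", "location-a", 2, 3),
    gt_row("location-b", "location", "location-b", 3, 4),
    gt_row("location-c", "location", "location-c", 4, 7),
    gt_row("Bob",        "person",   "Bob",        5, 6),
    gt_row("location-d", "location", "location-d", 8, NA))
  scenario("patrol", obs, gt)
}

#' Two-location goal fixture
#'
#' The minimal retrospective-construction example: a goal begins, the
#' agent visits two locations in turn, and the goal is satisfied. Four
#' change points yield four episodic markers; the satisfaction of the goal
#' bounds the visit to location-2, giving the three-row model (goal
#' containing location-1 then location-2).
#'
#' @return A [scenario()].
#' @export
two_location_goal_fixture <- function() {
  obs <- observations(
    time     = 1:4,
    channel  = c("goal", "location", "location", "goal"),
    entity   = c("goal", "location-1", "location-2", "goal"),
    polarity = c("onset", "onset", "onset", "offset"))
  gt <- rbind(
    gt_row("goal",       "goal",     "goal",       1, 4),
    gt_row("location-1", "location", "location-1", 2, 3),
    gt_row("location-2", "location", "location-2", 3, 4))
  scenario("two-location-goal", obs, gt)
}

#' Office-day fixture
#'
#' The day/meeting/evening/dinner partonomy: a durational day contains a
#' durational meeting followed by a durational evening; a punctate dinner
#' (onset and offset at the same instant) falls inside the evening. Seven
#' distinct change-point timestamps, matching the seven ordinal positions
#' of the classic event-model table.
#'
#' @return A [scenario()].
#' @export
office_day_fixture <- function() {
  obs <- observations(
    time     = c(1, 2, 3, 4, 5, 5, 6, 7),
    channel  = rep("goal", 8),
    entity   = c("day", "meeting", "meeting", "evening",
                 "dinner", "dinner", "evening", "day"),
    polarity = c("onset", "onset", "offset", "onset",
                 "onset", "offset", "offset", "offset"))
  gt <- rbind(
    gt_row("day",     "goal", "day",     1, 7),
    gt_row("meeting", "goal", "meeting", 2, 3),
    gt_row("evening", "goal", "evening", 4, 6),
    gt_row("dinner",  "goal", "dinner",  5, 5))
  scenario("office-day", obs, gt)
}

#' Seeded random scenario with ground truth
#'
#' Places Poisson-like change points independently on each active channel
#' and records the event intervals a veridical reconstruction should
#' recover. The goal channel (when active) carries a single recurring goal
#' entity with alternating onset/offset; the location channel switches
#' between location labels (each onset implicitly ends the previous
#' location); person and object channels hold two entities each with
#' alternating onset/offset. Ground-truth intervals account for goal
#' closure: a non-goal event opened while the goal is active ends no later
#' than that goal's offset.
#'
#' @param seed integer seed; identical seeds give identical scenarios.
#' @param n_channels_active number of channels used, 1-4, taken in the
#'   order goal, location, person, object.
#' @param duration positive real extent of the stream.
#' @param change_rate_per_channel positive expected change points per unit
#'   time and channel; `change_rate_per_channel * duration` must be >= 1.
#' @return A [scenario()].
#' @examples
#' random_scenario(7, n_channels_active = 2, duration = 50,
#'                 change_rate_per_channel = 0.1)
#' @export
random_scenario <- function(seed, n_channels_active = 2, duration = 100,
                            change_rate_per_channel = 0.1) {
  if (!is.finite(duration) || duration <= 0)
    stop("invalid parameter: duration must be positive")
  if (!is.finite(change_rate_per_channel) || change_rate_per_channel <= 0)
    stop("invalid parameter: change_rate_per_channel must be positive")
  if (change_rate_per_channel * duration < 1)
    stop("invalid parameter: change_rate_per_channel * duration must be >= 1")
  n_channels_active <- as.integer(n_channels_active)
  stopifnot(n_channels_active >= 1L, n_channels_active <= 4L)
  chans <- CHANNELS[seq_len(n_channels_active)]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))

  poisson_times <- function(rate) {
    # at least one change point per channel (precondition floor);
    # 1e-6 rounding keeps cross-channel time collisions negligible while
    # making JSONL round-trips exact
    n <- max(1L, stats::rpois(1L, rate * duration))
    round(sort(stats::runif(n, 0, duration)), 6)
  }

  rows <- list()
  add <- function(t, ch, en, pol)
    rows[[length(rows) + 1L]] <<- data.frame(
      time = t, channel = ch, entity = en, polarity = pol,
      stringsAsFactors = FALSE)

  # --- goal channel: one entity, alternating onset/offset ---------------
  goal_on <- numeric(0); goal_off <- numeric(0)
  if ("goal" %in% chans) {
    ts <- poisson_times(change_rate_per_channel)
    pol <- rep(c("onset", "offset"), length.out = length(ts))
    for (i in seq_along(ts)) add(ts[i], "goal", "goal-1", pol[i])
    goal_on <- ts[pol == "onset"]; goal_off <- ts[pol == "offset"]
  }
  # end imposed by goal closure on a non-goal event opened at time t0:
  # finite goal offset of the goal interval containing t0, or NA
  goal_bound <- function(t0) {
    if (!length(goal_on)) return(NA_real_)
    k <- findInterval(t0, goal_on)
    if (k == 0L) return(NA_real_)
    off <- goal_off[goal_off > goal_on[k]]
    if (!length(off)) return(NA_real_)       # goal never satisfied
    if (t0 < off[1]) off[1] else NA_real_    # t0 inside [onset, offset)
  }

  gt <- list()
  push_gt <- function(ch, en, s, e) {
    if (ch != "goal") {
      b <- goal_bound(s)
      if (!is.na(b)) e <- if (is.na(e)) b else min(e, b)
    }
    gt[[length(gt) + 1L]] <<- gt_row(en, ch, en, s, e)
  }
  if (length(goal_on)) {
    for (i in seq_along(goal_on)) {
      off <- goal_off[goal_off > goal_on[i]]
      push_gt("goal", "goal-1", goal_on[i],
              if (length(off)) off[1] else NA_real_)
    }
  }

  # --- location channel: switching labels -------------------------------
  if ("location" %in% chans) {
    ts <- poisson_times(change_rate_per_channel)
    labs <- paste0("location-", ((seq_along(ts) - 1L) %% 5L) + 1L)
    for (i in seq_along(ts)) add(ts[i], "location", labs[i], "onset")
    for (i in seq_along(ts)) {
      nxt <- if (i < length(ts)) ts[i + 1L] else NA_real_
      push_gt("location", labs[i], ts[i], nxt)
    }
  }

  # --- person / object channels: two alternating entities each ----------
  for (ch in intersect(c("person", "object"), chans)) {
    for (k in 1:2) {
      en <- paste0(ch, "-", k)
      ts <- poisson_times(change_rate_per_channel / 2)
      pol <- rep(c("onset", "offset"), length.out = length(ts))
      for (i in seq_along(ts)) add(ts[i], ch, en, pol[i])
      ons <- ts[pol == "onset"]
      for (i in seq_along(ons)) {
        off <- ts[pol == "offset" & ts > ons[i]]
        push_gt(ch, en, ons[i], if (length(off)) off[1] else NA_real_)
      }
    }
  }

  obs <- do.call(rbind, rows)
  obs <- obs[order(obs$time), , drop = FALSE]
  rownames(obs) <- NULL
  gtd <- number_duplicate_labels(do.call(rbind, gt))
  scenario(sprintf("random-%d", as.integer(seed)), obs, gtd)
}

# append "#k" to the label of repeated (channel, entity) events, numbered
# by start time, so labels are unique within a scenario/model
number_duplicate_labels <- function(df, start = "start") {
  if (!nrow(df)) return(df)
  df <- df[order(df[[start]], df$channel, df$entity), , drop = FALSE]
  key <- paste(df$channel, df$entity)
  idx <- stats::ave(seq_along(key), key, FUN = seq_along)
  rep_key <- key %in% key[duplicated(key)]
  df$label <- ifelse(rep_key, paste0(df$entity, "#", idx), df$entity)
  rownames(df) <- NULL
  df
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
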