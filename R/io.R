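#' Write an observation stream as JSONL
#'
#' One observation per line:
#' `{"t": <number>, "ch": "goal|location|person|object",
#'   "entity": "<label>", "pol": "onset|offset"}`.
#'
#' @param obs observation table from [observations()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(obs, path) {
  lines <- vapply(seq_len(nrow(obs)), function(i) {
    jsonlite::toJSON(list(t = obs$time[i], ch = obs$channel[i],
                          entity = obs$entity[i], pol = obs$polarity[i]),
                     auto_unbox = TRUE, digits = NA)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an observation stream from JSONL
#'
#' @param path file written by [write_observations()] (or by hand, same
#'   dialect).
#' @return An observation table; parse failures report the line number.
#' @export
read_observations <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(observations())
  rows <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i]),
                    error = function(e)
                      stop(sprintf("line %d: cannot parse JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    need <- c("t", "ch", "entity", "pol")
    if (!all(need %in% names(rec)))
      stop(sprintf("line %d: missing field(s) %s", i,
                   paste(setdiff(need, names(rec)), collapse = ", ")),
           call. = FALSE)
    data.frame(time = as.numeric(rec$t), channel = as.character(rec$ch),
               entity = as.character(rec$entity),
               polarity = as.character(rec$pol), stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  observations(df$time, df$channel, df$entity, df$polarity)
}

#' Write episodic markers as JSONL
#'
#' One marker per line with its change set inlined:
#' `{"id":"Ep-1","t":1,"prior":null,"goal":"patrol","strength":2,
#'   "changes":[{"ch":"goal","entity":"patrol","pol":"onset","prior":null}]}`.
#'
#' @param markers an `episodic_markers` list from [segment_stream()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(markers, path) {
  lines <- vapply(markers, function(m) {
    ch <- lapply(seq_len(nrow(m$changes)), function(i)
      list(ch = m$changes$channel[i], entity = m$changes$entity[i],
           pol = m$changes$polarity[i],
           prior = if (is.na(m$changes$prior[i])) NULL else m$changes$prior[i]))
    jsonlite::toJSON(list(
      id = m$id, t = m$time,
      prior = if (is.na(m$prior_marker)) NULL else m$prior_marker,
      goal = if (is.na(m$goal_context)) NULL else m$goal_context,
      strength = m$encoding_strength, changes = ch),
      auto_unbox = TRUE, digits = NA, null = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read episodic markers from JSONL
#'
#' @param path file written by [write_markers()].
#' @return An `episodic_markers` list.
#' @export
read_markers <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                    error = function(e)
                      stop(sprintf("line %d: cannot parse JSON (%s)",
                                   i, conditionMessage(e)), call. = FALSE))
    changes <- do.call(rbind, lapply(rec$changes, function(cg)
      data.frame(channel = cg$ch, entity = cg$entity, pol = cg$pol,
                 prior = if (is.null(cg$prior)) NA_character_ else cg$prior,
                 stringsAsFactors = FALSE)))
    names(changes) <- c("channel", "entity", "polarity", "prior")
    new_marker(id = rec$id, time = as.numeric(rec$t), changes = changes,
               prior_marker = if (is.null(rec$prior)) NA_character_ else rec$prior,
               goal_context = if (is.null(rec$goal)) NA_character_ else rec$goal,
               encoding_strength = as.numeric(rec$strength))
  })
  structure(out, class = "episodic_markers")
}

#' Write an event model as JSON
#'
#' Serializes the events (with ordinal and, when known, timestamp
#' boundaries), the boundary-position table, and the construction
#' parameters.
#'
#' @param model an `event_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  payload <- list(mode = model$mode, priority_order = model$priority_order,
                  max_depth = model$max_depth,
                  events = model$events, positions = model$positions)
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows", null = "null", na = "null"),
             path)
  invisible(path)
}

#' Read an event model from JSON
#'
#' @param path file written by [write_model()].
#' @return An `event_model`.
#' @export
read_model <- function(path) {
  rec <- jsonlite::fromJSON(paste(readLines(path), collapse = "\n"),
                            simplifyDataFrame = TRUE)
  ev <- as.data.frame(rec$events, stringsAsFactors = FALSE)
  for (col in c("start_time", "end_time", "start_ord", "end_ord", "depth"))
    if (col %in% names(ev)) ev[[col]] <- as.numeric(ev[[col]])
  if (!"parent" %in% names(ev)) ev$parent <- NA_character_
  pos <- as.data.frame(rec$positions, stringsAsFactors = FALSE)
  new_event_model(events = ev, positions = pos, mode = rec$mode,
                  priority_order = rec$priority_order,
                  max_depth = rec$max_depth)
}

#' Read random-scenario parameters from a YAML config
#'
#' Recognized keys: `seed`, `n_channels_active`, `duration`,
#' `change_rate_per_channel`. Unknown keys are rejected by name.
#'
#' @param path YAML file path.
#' @return A named list of parameters suitable for
#'   `do.call(random_scenario, ...)`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("seed", "n_channels_active", "duration",
             "change_rate_per_channel")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown scenario config key(s): ", paste(extra, collapse = ", "))
  if (is.null(cfg$seed)) stop("scenario config requires a 'seed' key")
  cfg
}
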