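#' Render an event model as a text diagram
#'
#' One line per event. Ordinal positions map to fixed-width columns;
#' punctate events print their label at the column of their single
#' ordinal, durational events print `[` at the start column, `]` at the
#' end column and the label centred between them, and open events end
#' with `...`. Vertical alignment of tokens therefore means "same
#' ordinal". The diagram is parseable: `parse_model(render(m))`
#' reproduces the ordinal structure of `m`.
#'
#' @param model an `event_model`.
#' @return A character vector of lines.
#' @examples
#' cat(render(construct_model(segment_stream(office_day_fixture()))),
#'     sep = "\n")
#' @export
render <- function(model) {
  stopifnot(inherits(model, "event_model"))
  ev <- model$events
  if (!nrow(ev)) return(character(0))
  width <- max(nchar(ev$label)) + 4L
  lines <- character(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    s_col <- (ev$start_ord[i] - 1L) * width + 1L
    if (ev$punctate[i]) {
      lines[i] <- paste0(strrep(" ", s_col - 1L), ev$label[i])
    } else if (is.na(ev$end_ord[i])) {
      lines[i] <- paste0(strrep(" ", s_col - 1L), "[ ", ev$label[i], " ...")
    } else {
      e_col <- (ev$end_ord[i] - 1L) * width + 1L
      span <- e_col - s_col - 1L
      lab <- ev$label[i]
      pad <- span - nchar(lab)
      left <- pad %/% 2L
      lines[i] <- paste0(strrep(" ", s_col - 1L), "[",
                         strrep(" ", left), lab,
                         strrep(" ", pad - left), "]")
    }
  }
  lines
}

#' Parse a rendered event-model diagram
#'
#' Inverse of [render()] up to ordinal structure: recovers each line's
#' label, start/end ordinal and punctate/open status. Timestamps, marker
#' ids and channels are not represented in a diagram and come back as
#' unknown (times equal ordinals).
#'
#' @param lines character vector produced by [render()].
#' @param width the column width used; inferred from the widest label if
#'   omitted.
#' @return An `event_model` whose events carry labels and ordinals.
#' @export
parse_model <- function(lines, width = NULL) {
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(finalize_model(empty_events_df(), "veridical", CHANNELS, 4))
  if (is.null(width)) {
    labs <- vapply(lines, function(l)
      trimws(gsub("\\[|\\]|\\.\\.\\.", "", l)), "")
    width <- max(nchar(labs)) + 4L
  }
  rows <- lapply(lines, function(l) {
    open <- grepl("\\.\\.\\.\\s*$", l)
    br_s <- regexpr("[", l, fixed = TRUE)
    lab <- trimws(gsub("\\[|\\]|\\.\\.\\.", "", l))
    if (br_s > 0) {
      s_ord <- (br_s - 1L) %/% width + 1L
      if (open) {
        e_ord <- NA_real_
      } else {
        br_e <- regexpr("]", l, fixed = TRUE)
        e_ord <- (br_e - 1L) %/% width + 1L
      }
      punct <- FALSE
    } else {
      tok <- regexpr("\\S", l)
      s_ord <- (tok - 1L) %/% width + 1L
      e_ord <- s_ord
      punct <- TRUE
    }
    data.frame(label = lab, channel = NA_character_, entity = lab,
               start_marker = NA_character_, end_marker = NA_character_,
               start_time = as.numeric(s_ord), end_time = as.numeric(e_ord),
               punctate = punct, stringsAsFactors = FALSE)
  })
  finalize_model(do.call(rbind, rows), "veridical", CHANNELS, 4)
}
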