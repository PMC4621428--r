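#' Exhaustive-enumeration verdict (reference oracle)
#'
#' An independent reference implementation of the modal verdict for small
#' problems: it enumerates every distinct arrangement of the events'
#' boundary tokens over an ordinal grid by a direct permutation recursion
#' (coincidence only where a `when` premise forces it, starts before ends
#' within a durational event), evaluates every premise directly from the
#' token positions in each leaf arrangement, and aggregates the assertion
#' over the surviving arrangements. It shares no search machinery with
#' [build_models()]/[query()], and is used to validate them.
#'
#' @param premises list of [temporal_assertion()]s (or character vector;
#'   may be empty).
#' @param assertion a [temporal_assertion()] or string; its labels are
#'   added to the event set.
#' @param max_events combinatorial guard; more events is an error
#'   (default 6).
#' @return A `verdict` whose `model_count` is the exact number of
#'   premise-consistent arrangements.
#' @examples
#' brute_force_verdict(parse_premises("shower before coffee
#' coffee before breakfast"), "shower before breakfast")
#' @export
brute_force_verdict <- function(premises, assertion, max_events = 6) {
  if (is.character(premises)) premises <- parse_premises(premises)
  if (is.character(assertion)) assertion <- parse_assertion(assertion)
  aspects <- infer_aspects(premises,
                           extra_labels = c(assertion$subject,
                                            assertion$object))
  if (is.null(aspects))
    return(new_verdict("inconsistent-premises", 0L))
  labels <- names(aspects)
  if (length(labels) > max_events)
    stop("brute_force_verdict refuses more than ", max_events, " events")

  # coincidence classes forced by `when` premises: naive repeated merge
  group <- stats::setNames(seq_along(labels), labels)
  for (rep_pass in seq_along(premises)) {
    for (p in premises) {
      if (p$relation == "when" ||
          (p$relation == "while" &&
           aspects[[p$subject]] == "punctate" &&
           aspects[[p$object]] == "punctate")) {
        g <- group[c(p$subject, p$object)]
        group[group == max(g)] <- min(g)
      }
    }
  }

  # one "unit" per coincidence class of punctate events, two per
  # durational event (which never coincides with anything)
  units <- list()
  for (x in labels) {
    if (aspects[[x]] == "durational") {
      units[[length(units) + 1L]] <- list(kind = "s", members = x)
      units[[length(units) + 1L]] <- list(kind = "e", members = x)
    }
  }
  punct <- labels[vapply(labels, function(x)
    aspects[[x]] == "punctate", TRUE)]
  for (g in unique(group[punct]))
    units[[length(units) + 1L]] <- list(kind = "p",
                                        members = punct[group[punct] == g])

  n <- length(units)

  # position lookup tables built per leaf
  eval_leaf <- function(order_idx) {
    s_of <- numeric(0); e_of <- numeric(0)
    for (slot in seq_len(n)) {
      u <- units[[order_idx[slot]]]
      for (m in u$members) {
        if (u$kind != "e") s_of[[m]] <- slot
        if (u$kind != "s") e_of[[m]] <- slot
      }
    }
    holds <- function(p) {
      a <- p$subject; b <- p$object
      ap <- aspects[[a]] == "punctate"; bp <- aspects[[b]] == "punctate"
      switch(p$relation,
        before = e_of[[a]] < s_of[[b]],
        when = s_of[[a]] == s_of[[b]] && e_of[[a]] == e_of[[b]],
        during = s_of[[b]] < s_of[[a]] && e_of[[a]] < e_of[[b]],
        "while" = {
          if (ap && bp) s_of[[a]] == s_of[[b]]
          else if (ap) s_of[[b]] < s_of[[a]] && s_of[[a]] < e_of[[b]]
          else if (bp) s_of[[a]] < s_of[[b]] && s_of[[b]] < e_of[[a]]
          else s_of[[a]] < e_of[[b]] && s_of[[b]] < e_of[[a]]
        },
        stop("unknown relation"))
    }
    for (p in premises) if (!holds(p)) return(NA)
    holds(assertion)
  }

  n_models <- 0L; n_holds <- 0L
  # recursive permutation of units; the only structural constraint is
  # that a durational start is placed before its end
  recurse <- function(placed, used) {
    if (length(placed) == n) {
      r <- eval_leaf(placed)
      if (!is.na(r)) {
        n_models <<- n_models + 1L
        if (r) n_holds <<- n_holds + 1L
      }
      return()
    }
    for (k in seq_len(n)) {
      if (used[k]) next
      u <- units[[k]]
      if (u$kind == "e") {
        s_idx <- which(vapply(units, function(v)
          v$kind == "s" && v$members == u$members, TRUE))
        if (!used[s_idx]) next
      }
      used[k] <- TRUE
      recurse(c(placed, k), used)
      used[k] <- FALSE
    }
  }
  recurse(integer(0), logical(n))

  status <- if (n_models == 0L) "inconsistent-premises"
            else if (n_holds == n_models) "necessary"
            else if (n_holds == 0L) "impossible"
            else "possible"
  new_verdict(status, n_models, n_holds)
}
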