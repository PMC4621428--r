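# shared test helpers: normalized event tables and random premise sets

# events of a model as a ground-truth-shaped table, sorted for comparison
model_as_gt <- function(model) {
  ev <- events(model)
  norm_gt(data.frame(label = ev$label, channel = ev$channel,
                     entity = ev$entity, start = ev$start_time,
                     end = ev$end_time, stringsAsFactors = FALSE))
}

norm_gt <- function(df) {
  df <- df[order(df$start, df$channel, df$entity),
           c("label", "channel", "entity", "start", "end")]
  rownames(df) <- NULL
  df
}

# seeded random premise set over up to `n_events` punctate/durational
# events; the assertion refers only to events mentioned in the premises
random_premise_set <- function(seed, n_events = 5, n_premises = 5) {
  set.seed(seed)
  evs <- LETTERS[seq_len(n_events)]
  rels <- c("before", "after", "while", "during", "when")
  prem <- lapply(seq_len(n_premises), function(i) {
    ab <- sample(evs, 2)
    temporal_assertion(ab[1],
                       sample(rels, 1, prob = c(.3, .2, .2, .2, .1)),
                       ab[2])
  })
  labs <- unique(unlist(lapply(prem, function(p) c(p$subject, p$object))))
  ab <- sample(labs, min(2L, length(labs)))
  if (length(ab) == 1L) ab <- c(ab, ab)
  list(premises = prem,
       assertion = temporal_assertion(ab[1], sample(rels, 1), ab[2]))
}

expect_verdict <- function(v, status) {
  expect_s3_class(v, "verdict")
  expect_identical(v$status, status)
}
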