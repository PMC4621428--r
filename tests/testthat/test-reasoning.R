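test_that("assertion parsing and normalization", {
  a <- parse_assertion("shower before coffee")
  expect_identical(a$relation, "before")
  # after(a, b) normalizes to before(b, a)
  b <- parse_assertion("coffee after shower")
  expect_identical(b$subject, "shower")
  expect_identical(b$object, "coffee")
  expect_identical(b$relation, "before")
  expect_error(parse_assertion("shower sometime coffee"), "cannot parse")
  prem <- parse_premises("a before b\n# comment\n\nb while c")
  expect_length(prem, 2)
})

test_that("one-model chain: shower before coffee before breakfast", {
  ms <- build_models("shower before coffee\ncoffee before breakfast")
  expect_length(ms, 1)
  expect_equal(attr(ms, "model_count"), 1)
  ev <- events(ms[[1]])
  expect_true(all(ev$punctate))
  ords <- ev$start_ord[match(c("shower", "coffee", "breakfast"), ev$label)]
  expect_identical(order(ords), 1:3)
  expect_verdict(query(ms, "shower before breakfast"), "necessary")
  expect_verdict(query(ms, "breakfast before shower"), "impossible")
})

test_that("multi-model indeterminacy: two orders, nothing necessary", {
  ms <- build_models("shower before coffee\nshower before breakfast")
  expect_length(ms, 2)
  expect_verdict(query(ms, "coffee before breakfast"), "possible")
  expect_verdict(query(ms, "breakfast before coffee"), "possible")
  expect_verdict(query(ms, "shower before coffee"), "necessary")
  # the initial model is deterministic and follows premise order
  ev <- events(ms[[1]])
  expect_lt(ev$start_ord[ev$label == "coffee"],
            ev$start_ord[ev$label == "breakfast"])
})

test_that("'when' aligns punctate events; 'while' places one inside", {
  ms <- build_models("exploded when arrived")
  expect_length(ms, 1)
  ev <- events(ms[[1]])
  expect_equal(ev$start_ord[1], ev$start_ord[2])
  expect_verdict(query(ms, "exploded when arrived"), "necessary")

  ms <- build_models("exploded while arrived")
  expect_length(ms, 1)
  ev <- events(ms[[1]])
  expect_false(ev$punctate[ev$label == "arrived"])
  expect_verdict(query(ms, "exploded while arrived"), "necessary")
  expect_verdict(query(ms, "exploded during arrived"), "necessary")
})

test_that("contradictory premises yield zero models, flagged", {
  ms <- build_models("A before B\nB before A")
  expect_length(ms, 0)
  expect_true(attr(ms, "inconsistent"))
  expect_verdict(query(ms, "A before B"), "inconsistent-premises")
})

test_that("unknown labels in queries are named in the error", {
  ms <- build_models("a before b")
  expect_error(query(ms, "a before zebra"), "zebra")
})

test_that("model enumeration truncates at max_models with a bound flag", {
  # 4 unrelated punctate events: 4! = 24 arrangements
  prem <- parse_premises("a before b\nc before d")
  full <- build_models(prem, max_models = 100)
  expect_length(full, 6)      # 4!/(2!2!) interleavings
  expect_false(attr(full, "truncated"))
  cut <- build_models(prem, max_models = 3)
  expect_length(cut, 3)
  expect_true(attr(cut, "truncated"))
  v <- query(cut, "a before b")
  expect_identical(v$status, "necessary")
  expect_true(v$bounded)      # necessary only up to the bound
})

test_that("counterfactual revision moves one event, persistently", {
  m <- construct_model(segment_stream(two_location_goal_fixture()))
  expect_verdict(query(m, "location-1 during goal"), "necessary")
  r <- revise(m, "location-1", after = "location-2")
  expect_verdict(query(r, "location-1 during goal"), "impossible")
  expect_verdict(query(r, "location-2 before location-1"), "necessary")
  # original unchanged; identity move is a no-op
  expect_verdict(query(m, "location-1 during goal"), "necessary")
  ev <- events(m)
  same <- revise(m, "location-1",
                 new_start = ev$start_time[ev$label == "location-1"],
                 new_end = ev$end_time[ev$label == "location-1"])
  expect_equal(events(same), ev)
  expect_error(revise(m, "nowhere", new_start = 1), "nowhere")
  expect_error(revise(m, "location-1", new_start = 5, new_end = 2),
               "collides")
})

test_that("brute-force oracle reproduces the worked examples", {
  chain <- parse_premises("shower before coffee\ncoffee before breakfast")
  v <- brute_force_verdict(chain, "shower before breakfast")
  expect_identical(v$status, "necessary")
  expect_equal(v$model_count, 1)
  v <- brute_force_verdict(
    parse_premises("shower before coffee\nshower before breakfast"),
    "coffee before breakfast")
  expect_identical(v$status, "possible")
  expect_equal(v$model_count, 2)
  expect_verdict(brute_force_verdict(list(), "A before A"), "impossible")
  expect_error(brute_force_verdict(
    parse_premises(paste(LETTERS[1:7], "before", LETTERS[2:8],
                         collapse = "\n")), "A before H"),
    "refuses")
})

test_that("query/build_models agree with the oracle on exhaustive pairs", {
  rels <- c("before", "while", "during", "when")
  shapes <- list(c("A", "B", "B", "C"), c("A", "B", "A", "C"),
                 c("A", "B", "C", "A"))
  for (sh in shapes) {
    for (r1 in rels) for (r2 in rels) {
      prem <- list(temporal_assertion(sh[1], r1, sh[2]),
                   temporal_assertion(sh[3], r2, sh[4]))
      for (target in list(c("A", "C"), c("C", "B"))) {
        assertion <- temporal_assertion(target[1], "before", target[2])
        bf <- brute_force_verdict(prem, assertion)
        ms <- build_models(prem, max_models = 500)
        qv <- query(ms, assertion)
        expect_identical(qv$status, bf$status,
                         label = sprintf("%s(%s,%s)+%s(%s,%s)", r1, sh[1],
                                         sh[2], r2, sh[3], sh[4]))
        if (bf$status != "inconsistent-premises")
          expect_equal(length(ms), bf$model_count)
      }
    }
  }
})

test_that("query/build_models agree with the oracle on random 5-event sets", {
  for (seed in 1:60) {
    gs <- random_premise_set(seed)
    bf <- brute_force_verdict(gs$premises, gs$assertion)
    if (bf$model_count > 300) next  # keep the check desk-scale
    ms <- build_models(gs$premises, max_models = 400)
    qv <- query(ms, gs$assertion)
    expect_identical(qv$status, bf$status, label = paste("seed", seed))
    if (bf$status != "inconsistent-premises")
      expect_equal(length(ms), bf$model_count,
                   label = paste("count seed", seed))
  }
})

test_that("necessity of 'before' is transitive across random sets", {
  for (seed in 1:40) {
    gs <- random_premise_set(seed, n_events = 4, n_premises = 4)
    ms <- build_models(gs$premises, max_models = 500)
    if (!length(ms) || attr(ms, "truncated")) next
    labs <- events(ms[[1]])$label
    if (length(labs) < 3) next
    for (a in labs) for (b in labs) for (c in labs) {
      if (a == b || b == c || a == c) next
      if (query(ms, paste(a, "before", b))$status == "necessary" &&
          query(ms, paste(b, "before", c))$status == "necessary")
        expect_identical(query(ms, paste(a, "before", c))$status,
                         "necessary")
    }
  }
})
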