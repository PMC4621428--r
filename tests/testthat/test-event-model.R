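test_that("veridical reconstruction of the patrol trace", {
  m <- construct_model(segment_stream(patrol_fixture()))
  ev <- events(m)
  expect_setequal(ev$label, c("patrol", "location-a", "location-b",
                              "location-c", "Bob", "location-d"))
  # every closed event is a marker pair
  closed <- ev[!is.na(ev$end_marker), ]
  expect_true(all(nzchar(closed$start_marker)))
  expect_identical(ev$start_marker[ev$label == "patrol"], "Ep-1")
  expect_identical(ev$end_marker[ev$label == "patrol"], "Ep-7")
  # Bob's visit nests inside the location where it happened
  expect_identical(ev$parent[ev$label == "Bob"], "location-c")
  # the post-goal location event is open
  expect_true(is.na(ev$end_time[ev$label == "location-d"]))
})

test_that("two-location goal reconstruction matches the three-row model", {
  m <- construct_model(segment_stream(two_location_goal_fixture()))
  ev <- events(m)
  expect_identical(ev$label, c("goal", "location-1", "location-2"))
  expect_identical(ev$parent, c(NA, "goal", "goal"))
  # location-1 precedes location-2, sharing its end boundary with
  # location-2's start; location-2 ends with the goal's satisfaction
  expect_equal(ev$end_ord[ev$label == "location-1"],
               ev$start_ord[ev$label == "location-2"])
  expect_equal(ev$end_ord[ev$label == "location-2"],
               ev$end_ord[ev$label == "goal"])
  expect_verdict(query(m, "location-1 during goal"), "necessary")
  expect_verdict(query(m, "location-1 before location-2"), "impossible")
})

test_that("prioritized mode keeps the superordinate goal event only", {
  mk <- segment_stream(patrol_fixture())
  pm <- construct_model(mk, mode = "prioritized")
  expect_identical(events(pm)$label, "patrol")
  # swapping the priority order surfaces location events at top level
  pl <- construct_model(mk, mode = "prioritized",
                        priority_order = c("location", "goal", "person",
                                           "object"))
  expect_setequal(events(pl)$label,
                  c("location-a", "location-b", "location-c", "location-d"))
  expect_true(all(is.na(events(pl)$parent)))
  # fleshing out admits lower-priority events inside committed bounds
  pf <- construct_model(mk, mode = "prioritized", flesh_out = TRUE)
  expect_true(all(c("patrol", "location-a", "Bob") %in% events(pf)$label))
  expect_false("location-d" %in% events(pf)$label)  # outside goal bounds
})

test_that("prioritized events are a subset of veridical events", {
  for (seed in c(1, 8, 23)) {
    s <- random_scenario(seed, 4, 80, 0.15)
    mk <- segment_stream(s)
    v <- model_as_gt(construct_model(mk))
    for (fo in c(FALSE, TRUE)) {
      p <- model_as_gt(construct_model(mk, mode = "prioritized",
                                       flesh_out = fo))
      expect_true(nrow(merge(p, v)) == nrow(p))
    }
  }
})

test_that("office-day model has 7 ordinals with meeting end at 3", {
  m <- construct_model(segment_stream(office_day_fixture()))
  expect_equal(nrow(positions_of(m)), 7)
  expect_equal(boundary_ordinal(m, "meeting", "end"), 3)
  ev <- events(m)
  expect_true(ev$punctate[ev$label == "dinner"])
  expect_equal(ev$start_ord[ev$label == "dinner"],
               ev$end_ord[ev$label == "dinner"])
  expect_identical(ev$parent[ev$label == "dinner"], "evening")
  expect_error(boundary_ordinal(m, "breakfast"), "breakfast")
})

test_that("empty marker list gives an empty model", {
  m <- construct_model(structure(list(), class = "episodic_markers"))
  expect_equal(nrow(events(m)), 0)
  expect_error(positions_of(m), "no events")
})

test_that("veridical reconstruction recovers ground truth", {
  fixtures <- list(patrol_fixture(), two_location_goal_fixture(),
                   office_day_fixture())
  for (s in fixtures) {
    m <- construct_model(segment_stream(s))
    expect_equal(model_as_gt(m), norm_gt(s$ground_truth))
  }
  for (seed in 1:30) {
    s <- random_scenario(seed, n_channels_active = (seed %% 4) + 1,
                         duration = 80, change_rate_per_channel = 0.15)
    m <- construct_model(segment_stream(s))
    expect_equal(model_as_gt(m), norm_gt(s$ground_truth),
                 tolerance = 1e-12)
  }
})

test_that("ordinal iconicity: ordinals order exactly as timestamps", {
  for (seed in c(5, 12)) {
    s <- random_scenario(seed, 3, 80, 0.2)
    m <- construct_model(segment_stream(s))
    pos <- positions_of(m)
    expect_identical(pos$ordinal, seq_len(nrow(pos)))
    expect_true(all(diff(pos$time) > 0))
    ev <- events(m)
    expect_identical(order(ev$start_ord), order(ev$start_time))
  }
})

test_that("partonomy depth is bounded and flattened beyond max_depth", {
  # six nested goals
  obs <- observations(c(1:6, 7:12), rep("goal", 12),
                      c(paste0("g", 1:6), paste0("g", 6:1)),
                      rep(c("onset", "offset"), each = 6))
  m <- construct_model(segment_stream(obs), max_depth = 4)
  ev <- events(m)
  expect_equal(max(ev$depth), 4)
  expect_identical(ev$parent[ev$label == "g5"], "g3")
  expect_identical(ev$parent[ev$label == "g6"], "g3")
  deep <- construct_model(segment_stream(obs), max_depth = 10)
  expect_equal(max(events(deep)$depth), 6)
})

test_that("repeated entities get distinct, numbered labels", {
  obs <- observations(c(1, 2, 3, 4), rep("person", 4),
                      rep("Bob", 4), rep(c("onset", "offset"), 2))
  ev <- events(construct_model(segment_stream(obs)))
  expect_identical(ev$label, c("Bob#1", "Bob#2"))
})

test_that("render/parse round-trips the ordinal structure", {
  models <- list(
    construct_model(segment_stream(patrol_fixture())),
    construct_model(segment_stream(office_day_fixture())),
    build_models("shower before coffee\ncoffee before breakfast")[[1]])
  for (m in models) {
    p <- parse_model(render(m))
    cols <- c("label", "start_ord", "end_ord", "punctate")
    expect_identical(events(p)[, cols], events(m)[, cols])
  }
  expect_identical(render(parse_model(character(0))), character(0))
})

test_that("punctate-within-durational renders vertically aligned", {
  m <- build_models("exploded while arrived")[[1]]
  lines <- render(m)
  expect_length(lines, 2)
  i_p <- which(events(m)$punctate)
  tok_col <- regexpr("\\S", lines[i_p])
  br_open <- regexpr("[", lines[-i_p], fixed = TRUE)
  br_close <- regexpr("]", lines[-i_p], fixed = TRUE)
  expect_true(br_open < tok_col && tok_col < br_close)
})

test_that("event model JSON round-trips through the reader", {
  m <- construct_model(segment_stream(patrol_fixture()))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_model(path)
  expect_equal(events(m2), events(m))
  expect_equal(positions_of(m2)$ordinal, positions_of(m)$ordinal)
})

test_that("construct_model rejects unordered markers", {
  mk <- segment_stream(patrol_fixture())
  expect_error(construct_model(rev(unclass(mk))), "time-ordered")
})
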