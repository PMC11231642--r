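tagged_toy <- function() {
  ts <- toy_scene()
  bank <- load_instruction("go to all objects and go back",
                           module_bank(ts$map, B = 4))
  pg <- parse_goto(bank)
  list(map = copy_map(pg$map, strip_action_words = TRUE),
       dt = ts$distances)
}

test_that("destination lists sort by distance with rank bookkeeping", {
  dl <- destination_list(c("p", "q", "r"), c(30, 10, 20))
  expect_identical(dl$id, c("q", "r", "p"))
  expect_identical(dl$position, 1:3)
  expect_identical(dl$inverse_position, 3:1)
  expect_identical(dl$inverse_position[1], nrow(dl))
  # ties break toward the lower location index
  dl2 <- destination_list(c("a", "b", "c"), c(5, 5, 1))
  expect_identical(dl2$id, c("c", "a", "b"))
  expect_error(destination_list(character(), numeric()), "empty")
})

test_that("position-weighted probabilities match the closed form", {
  dl5 <- destination_list(letters[1:5], 1:5)
  expect_equal(position_weighted_probabilities(dl5, 4),
               c(625, 256, 81, 16, 1) / 979)
  dl3 <- destination_list(letters[1:3], 1:3)
  expect_equal(position_weighted_probabilities(dl3, 4),
               c(81, 16, 1) / 98)
  expect_equal(position_weighted_probabilities(dl5, 30),
               c(1, 0, 0, 0, 0))
  expect_equal(position_weighted_probabilities(
    destination_list("a", 7), 4), 1)
  expect_error(position_weighted_probabilities(dl5, 0), "positive")
})

test_that("value-weighted probabilities use excess-over-minimum reciprocals", {
  p1 <- value_weighted_probabilities(destination_list(1:3, c(12, 13, 44)))
  expect_equal(p1, c(1, 1, 1 / 32) / (2 + 1 / 32))
  p2 <- value_weighted_probabilities(destination_list(1:3, c(12, 42, 44)))
  expect_equal(p2, c(1, 1 / 30, 1 / 32) / (1 + 1 / 30 + 1 / 32))
  # all distances equal: uniform
  expect_equal(value_weighted_probabilities(
    destination_list(1:4, rep(9, 4))), rep(0.25, 4))
})

test_that("probability vectors sum to one and ignore distance scale", {
  set.seed(11)
  for (len in c(1:6, 12, 20)) {
    d <- sort(sample.int(500, len))
    dl <- destination_list(seq_len(len), d)
    for (w in c(1:5, 9, 10, 30)) {
      p <- position_weighted_probabilities(dl, w)
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(p >= 0))
      # rank-based: scaling distances leaves p unchanged
      expect_equal(position_weighted_probabilities(
        destination_list(seq_len(len), d * 7), w), p)
    }
    pv <- value_weighted_probabilities(dl)
    expect_equal(sum(pv), 1, tolerance = 1e-12)
    if (len > 1 && length(unique(diff(d))) > 1) {
      expect_false(isTRUE(all.equal(value_weighted_probabilities(
        destination_list(seq_len(len), d * 7)), pv)))
    }
  }
})

test_that("roulette selection picks the first rank exceeding the draw", {
  expect_identical(select_next(c(0.83, 0.16, 0.01), 0.55), 1L)
  expect_identical(select_next(c(0.94, 0.06), 0.95), 2L)
  expect_identical(select_next(1, 0.999), 1L)
  expect_error(select_next(c(0.5, 0.5), 1), "\\[0, 1\\)")
  expect_error(select_next(c(0.5, 0.5), -0.1), "\\[0, 1\\)")
})

test_that("small_plan reproduces the worked toy routes and tags", {
  tt <- tagged_toy()
  det <- small_plan(tt$map, tt$dt, plan_config("deterministic-nn"))
  expect_identical(det$visit_order, c("2,2,0", "3,0,0", "4,2,0", "0,0,0"))
  expect_equal(det$total_distance, 109)
  expect_equal(det$leg_distances, c(25, 22, 20, 42))

  alt <- small_plan(tt$map, tt$dt, plan_config("position-weighted"),
                    draws = toy_forced_draws)
  expect_identical(alt$visit_order, c("2,2,0", "4,2,0", "3,0,0", "0,0,0"))
  expect_equal(alt$total_distance, 100)
  expect_equal(alt$leg_distances, c(25, 24, 20, 31))
  expect_identical(unname(alt$tag_assignment[c("2,2,0", "4,2,0", "3,0,0",
                                               "0,0,0")]), c(1L, 2L, 3L, 0L))
  ms <- move_sequence(alt)
  expect_identical(ms$id, c("2,2,0", "4,2,0", "3,0,0", "0,0,0"))
  expect_identical(ms$tag, c(1L, 2L, 3L, 0L))

  # single destination: out-and-back doubles the leg
  ts <- toy_scene()
  bank <- load_instruction("go to the black sphere and go back",
                           module_bank(ts$map, B = 4))
  one <- small_plan(parse_goto(bank)$map, ts$distances,
                    plan_config("deterministic-nn"))
  expect_equal(one$total_distance, 2 * 31)
  expect_identical(move_sequence(one)$tag, c(1L, 0L))

  # missing coverage is a hard error
  sub <- distance_table(ts$distances$d[1:3, 1:3],
                        labels = ts$distances$labels[1:3])
  expect_error(small_plan(tt$map, sub, plan_config()), "cover")
})

test_that("deterministic replication on the 13-city table", {
  dt <- cities13()
  for (i in 1:5) {
    expect_equal(tour_totals(dt, 1, 1, "deterministic-nn")$best_total,
                 8131)
  }
  pr <- navbank:::construct_tour(dt, "city0", "deterministic-nn")
  expect_equal(pr$total, 8131)
})

test_that("weight >= 10 collapses to deterministic nearest-neighbour", {
  dt <- cities13()
  det <- tour_totals(dt, 1, 1, "deterministic-nn")$best_total
  for (seed in 1:10) {
    set.seed(seed)
    draws <- matrix(runif(60), 5)
    for (w in c(10, 17, 30)) {
      res <- tour_totals(dt, 1, 5, "position-weighted", w, draws)
      expect_true(all(res$totals == det))
    }
  }
})

test_that("compiled kernel agrees exactly with the pure-R constructor", {
  set.seed(21)
  for (i in 1:12) {
    n <- sample(4:9, 1)
    dt <- random_distance_table(n, c(5, 99))
    draws <- runif(n - 1)
    for (mode in c("deterministic-nn", "position-weighted",
                   "value-weighted")) {
      w <- sample(1:9, 1)
      ref <- navbank:::construct_tour(dt, dt$labels[1], mode, w, draws)
      fast <- tour_totals(dt, 1, 1, mode, w, matrix(draws, 1))
      expect_equal(fast$best_total, ref$total)
      expect_identical(dt$labels[fast$best_order], ref$order)
    }
  }
})

test_that("every plan is a valid tour with total equal to leg sum", {
  set.seed(31)
  for (i in 1:10) {
    sc <- random_scene((i %% 4) + 2L, seed = 100 + i)
    bank <- load_instruction("go to all objects and go back",
                             module_bank(sc$map, B = 4))
    pg <- parse_goto(bank)
    pr <- small_plan(copy_map(pg$map, TRUE), sc$distances,
                     plan_config("position-weighted"))
    dests <- navbank:::keys_with_tag(pg$map, "all-marker")
    expect_setequal(pr$visit_order[-length(pr$visit_order)], dests)
    expect_identical(anyDuplicated(pr$visit_order[-length(pr$visit_order)]),
                     0L)
    expect_identical(pr$visit_order[length(pr$visit_order)],
                     navbank:::keys_with_tag(pg$map, "back-marker"))
    expect_equal(pr$total_distance, sum(pr$leg_distances))
  }
})

test_that("bank planning finds the 100 cm toy route and beats slot 1", {
  ts <- toy_scene()
  bank <- load_instruction("go to all objects and go back",
                           module_bank(ts$map, B = 1024))
  bank <- broadcast(parse_goto(bank)$bank)
  set.seed(41)
  br <- run_bank(bank, ts$distances)
  expect_equal(br$best_plan$total_distance, 100)
  expect_setequal(unique(br$per_module_totals), c(109, 100, 119))
  # the 100 cm route, in either direction (the table is symmetric)
  ids <- move_sequence(br$best_plan)$id
  expect_true(identical(ids, c("2,2,0", "4,2,0", "3,0,0", "0,0,0")) ||
                identical(ids, c("3,0,0", "4,2,0", "2,2,0", "0,0,0")))
  # slot n = 1 is deterministic, so the bank can never do worse
  expect_lte(br$best_plan$total_distance, br$per_module_totals[["1"]])
  expect_error(run_bank(load_instruction("go to all objects and go back",
                                         module_bank(ts$map, B = 4)),
                        ts$distances), "broadcast")
})

test_that("bank best equals the brute-force optimum on 2-destination scenes", {
  for (seed in 1:5) {
    sc <- random_scene(2L, seed = 200 + seed)
    bank <- load_instruction("go to all objects and go back",
                             module_bank(sc$map, B = 16))
    bank <- broadcast(parse_goto(bank)$bank)
    set.seed(seed)
    br <- run_bank(bank, sc$distances)
    keys <- c(navbank:::keys_with_tag(bank$module_a, "back-marker"),
              navbank:::keys_with_tag(bank$module_a, "all-marker"))
    keys <- keys[order(match(keys, sc$distances$labels))]
    sub <- distance_table(sc$distances$d[keys, keys], labels = keys)
    expect_equal(br$best_plan$total_distance,
                 exhaustive_shortest(sub,
                   match(navbank:::keys_with_tag(bank$module_a,
                                                 "back-marker"), keys)))
  }
})
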