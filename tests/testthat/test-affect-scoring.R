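test_that("episode affect means follow the two-positive / five-negative split", {
  r <- ratings_row(calm_relaxed = 3, enjoyment = 3)
  expect_equal(episode_positive_affect(r), 3)
  expect_equal(episode_positive_affect(ratings_row(calm_relaxed = 1,
                                                   enjoyment = 3)), 2)
  expect_equal(episode_positive_affect(ratings_row(calm_relaxed = 2,
                                                   enjoyment = 2)), 2)

  expect_equal(episode_negative_affect(ratings_row()), 1)
  expect_equal(episode_negative_affect(
    ratings_row(worried = 3, rushed = 3, irritated_angry = 3, depressed = 3,
                tense_stressed = 3)), 3)
  expect_equal(episode_negative_affect(ratings_row(tense_stressed = 3)), 1.4)

  expect_equal(episode_net_affect(ratings_row(calm_relaxed = 3,
                                              enjoyment = 3)), 2)
  expect_equal(episode_net_affect(
    ratings_row(worried = 3, rushed = 3, irritated_angry = 3, depressed = 3,
                tense_stressed = 3)), -2)
  all2 <- ratings_row(2, 2, 2, 2, 2, 2, 2)
  expect_equal(episode_net_affect(all2), 0)
})

test_that("ratings outside the 1-3 grid are rejected with the item named", {
  bad <- ratings_row(); bad$enjoyment <- 4
  expect_error(episode_positive_affect(bad), "enjoyment")
  bad2 <- ratings_row(); bad2$worried <- 0
  expect_error(episode_negative_affect(bad2), "worried")
  expect_error(episode_net_affect(ratings_row()[-1]), "worried")
})

test_that("unpleasant episodes need a strictly dominant negative feeling", {
  expect_true(episode_is_unpleasant(ratings_row(worried = 3)))
  # tie between top negative and top positive: not unpleasant
  expect_false(episode_is_unpleasant(ratings_row(worried = 3,
                                                 calm_relaxed = 3)))
  expect_false(episode_is_unpleasant(ratings_row()))  # tie at the floor
  expect_true(episode_is_unpleasant(ratings_row(), ties_unpleasant = TRUE))
})

test_that("net affect spans exactly [-2, 2] over the full rating grid", {
  grid <- expand.grid(rep(list(1:3), 7))
  names(grid) <- c(drm_affect_items()$negative, drm_affect_items()$positive)
  net <- episode_net_affect(grid)
  expect_equal(nrow(grid), 3^7)
  expect_true(all(net >= -2 & net <= 2))
  expect_equal(max(net), 2)
  expect_equal(min(net), -2)
})

test_that("score_wave duration-weights episodes and computes the U-index", {
  one <- cbind(data.frame(start_min = 0, end_min = 60),
               ratings_row(calm_relaxed = 3, enjoyment = 3))
  s <- score_wave(one)
  expect_equal(s$net, 2)
  expect_equal(s$u_index, 0)

  two <- cbind(data.frame(start_min = c(0, 60), end_min = c(60, 180)),
               ratings_row(calm_relaxed = c(3, 2), enjoyment = c(3, 3),
                           worried = c(1, 2), rushed = c(1, 2),
                           irritated_angry = c(1, 2), depressed = c(1, 2),
                           tense_stressed = c(1, 2)))
  # nets are 2 and 0.5; (60*2 + 120*0.5) / 180 = 1
  expect_equal(episode_net_affect(two), c(2, 0.5))
  expect_equal(score_wave(two)$net, 1)

  ui <- cbind(data.frame(start_min = c(0, 30), end_min = c(30, 120)),
              ratings_row(worried = c(3, 1), calm_relaxed = c(1, 3),
                          enjoyment = c(1, 3), rushed = c(1, 1),
                          irritated_angry = c(1, 1), depressed = c(1, 1),
                          tense_stressed = c(1, 1)))
  expect_equal(score_wave(ui)$u_index, 0.25)
})

test_that("score_wave is invariant to episode order and contiguous splits", {
  set.seed(42)
  ep <- cbind(
    data.frame(start_min = c(0, 90, 200), end_min = c(90, 200, 330)),
    ratings_row(worried = c(2, 1, 3), rushed = c(1, 2, 1),
                irritated_angry = c(1, 1, 2), depressed = c(1, 1, 1),
                tense_stressed = c(2, 1, 1), calm_relaxed = c(3, 2, 1),
                enjoyment = c(2, 3, 1))
  )
  base <- score_wave(ep)
  shuffled <- ep[c(3, 1, 2), ]
  expect_equal(score_wave(shuffled), base, ignore_attr = TRUE)
  # split the middle episode at minute 150, ratings unchanged
  split <- ep[c(1, 2, 2, 3), ]
  split$start_min <- c(0, 90, 150, 200)
  split$end_min <- c(90, 150, 200, 330)
  expect_equal(score_wave(split)[c("pa", "na", "net", "u_index")],
               base[c("pa", "na", "net", "u_index")], ignore_attr = TRUE)
})

test_that("segment (set D) raw scoring equals equal-weight episode scoring", {
  seg <- ratings_row(worried = c(1, 2), calm_relaxed = c(3, 1),
                     enjoyment = c(2, 2))
  raw <- score_wave(seg, duration_weighted = FALSE)
  as_ep <- cbind(data.frame(start_min = c(0, 60), end_min = c(60, 120)), seg)
  eq <- score_wave(as_ep)
  expect_equal(raw$net, eq$net)
  expect_true(is.na(raw$u_index))
  expect_true(is.na(raw$total_minutes))
})

test_that("score_wave flags incomplete and degenerate input", {
  expect_error(score_wave(ratings_row()[0, ]), "no episodes")
  ep <- cbind(data.frame(start_min = c(0, 60), end_min = c(60, 120)),
              ratings_row(worried = c(1, NA), calm_relaxed = c(2, 2),
                          enjoyment = c(2, 2)))
  expect_warning(s <- score_wave(ep), "incomplete")
  expect_equal(s$n_used, 1)
  expect_equal(attr(s, "n_dropped"), 1)
  allna <- ep; allna$worried <- NA
  expect_warning(expect_error(score_wave(allna), "complete"), "incomplete")
  badint <- cbind(data.frame(start_min = 60, end_min = 60), ratings_row())
  expect_error(score_wave(badint), "interval")
})

test_that("slice_full_wave clips, prorates, and guards its domain", {
  ep <- cbind(
    data.frame(set = "FULL", period = c("morning", "morning", "evening"),
               start_min = c(400, 700, 1080), end_min = c(700, 760, 1300)),
    ratings_row(calm_relaxed = c(2, 3, 1), enjoyment = c(2, 3, 1))
  )
  morn <- slice_full_wave(ep, "morning")
  expect_equal(morn$end_min, c(700, 720))  # straddler cut at noon
  aft <- slice_full_wave(ep, "afternoon")
  expect_equal(aft$start_min, 720)
  expect_equal(aft$end_min, 760)
  expect_equal(aft$period, "afternoon")
  # all episodes before noon: morning slice is the identity
  before_noon <- ep[1:2, ]; before_noon$end_min <- c(700, 710)
  expect_equal(slice_full_wave(before_noon, "morning")[, -2],
               before_noon[, -2], ignore_attr = TRUE)
  # empty slice comes back with zero rows, and proration conserves time
  expect_equal(nrow(slice_full_wave(ep[1:2, ], "evening")), 0)
  tot <- sum(ep$end_min - ep$start_min)
  parts <- sum(vapply(drm_periods(), function(p) {
    s <- slice_full_wave(ep, p); sum(s$end_min - s$start_min)
  }, numeric(1)))
  expect_equal(parts, tot)
  shortset <- ep; shortset$set <- "A"
  expect_error(slice_full_wave(shortset, "morning"), "FULL")
})
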