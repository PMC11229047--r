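test_that("transition entropy handles degenerate and analytic cases", {
  # deterministic cycle: every conditional is a point mass
  expect_equal(transition_entropy(rep(c("1", "2", "3"), 5)), 0)
  # uniform conditionals over the other 11 of 12 AOIs
  expect_equal(transition_entropy(matrix(1, 12, 12) - diag(12)), log2(11),
               tolerance = 1e-12)
  # worked example: counts {(A->B):2, (A->C):2, (B->A):4}
  counts <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"),
                                            c("A", "B", "C")))
  counts["A", "B"] <- 2; counts["A", "C"] <- 2; counts["B", "A"] <- 4
  # p(A)=1/2 with 1 bit of conditional entropy; p(B)=1/2 with 0
  expect_equal(transition_entropy(counts), 0.5)
  # fewer than 2 transitions
  expect_equal(transition_entropy(c("1", "2")), 0)
  expect_equal(transition_entropy(character(0)), 0)
})

test_that("transition entropy matches the brute-force oracle exhaustively", {
  # all 3-AOI sequences up to length 7, plus random longer ones
  for (L in 1:7) {
    grid <- as.matrix(expand.grid(rep(list(c("a", "b", "c")), L)))
    for (r in seq_len(nrow(grid))) {
      s <- as.character(grid[r, ])
      expect_equal(transition_entropy(s), entropy_oracle(s),
                   tolerance = 1e-12)
    }
  }
  set.seed(4)
  for (r in 1:300) {
    s <- sample(c("a", "b", "c"), sample(8:12, 1), replace = TRUE)
    expect_equal(transition_entropy(s), entropy_oracle(s), tolerance = 1e-12)
  }
})

test_that("entropy is bounded and collapsing never adds transitions", {
  set.seed(11)
  for (r in 1:50) {
    n_aoi <- sample(2:12, 1)
    s <- as.character(sample(n_aoi, sample(2:40, 1), replace = TRUE))
    h <- transition_entropy(s)
    expect_gte(h, 0)
    expect_lte(h, log2(max(2, n_aoi - 1)) + 1e-12)
    expect_lte(length(collapse_aoi_runs(s)), length(s))
  }
})

test_that("saccadic angle follows atan2 conventions on (-180, 180]", {
  expect_equal(saccadic_angle(1, 0), 0)
  expect_equal(saccadic_angle(-1, 0), 180)
  expect_equal(saccadic_angle(0, 1), 90)
  expect_equal(saccadic_angle(0, -1), -90)
  expect_equal(saccadic_angle(1, 1), 45)
  expect_error(saccadic_angle(0, 0), "undefined")
})

test_that("intersaccadic angles wrap to the shorter arc", {
  expect_equal(intersaccadic_angles(c(0, 0, 0)), c(0, 0))
  expect_equal(intersaccadic_angles(c(170, -170)), 20)
  expect_equal(intersaccadic_angles(c(0, 180)), 180)
  expect_equal(intersaccadic_angles(c(10, -80)), -90)
  expect_equal(length(intersaccadic_angles(5)), 0)
})

test_that("antipersistent fraction uses an inclusive 90-degree boundary", {
  expect_equal(antipersistent_fraction(c(0, 10, -30)), 0)
  expect_equal(antipersistent_fraction(c(180, 179, -120)), 100)
  expect_equal(antipersistent_fraction(90), 0)   # inclusive-persistent
  expect_equal(antipersistent_fraction(-90), 0)
  expect_equal(antipersistent_fraction(90.5), 100)
  expect_true(is.na(antipersistent_fraction(numeric(0))))
})

test_that("persistence classification is rotation and wrap invariant", {
  set.seed(3)
  for (r in 1:20) {
    theta <- runif(sample(3:15, 1), -180, 180)
    d0 <- intersaccadic_angles(theta)
    # global rotation of all saccade directions
    rot <- runif(1, -360, 360)
    d1 <- intersaccadic_angles(theta + rot)
    expect_equal(antipersistent_fraction(d1), antipersistent_fraction(d0),
                 tolerance = 1e-9)
    # adding full turns to any single angle
    k <- sample(length(theta), 1)
    theta2 <- theta; theta2[k] <- theta2[k] + 360
    expect_equal(intersaccadic_angles(theta2), d0, tolerance = 1e-9)
  }
})

test_that("AOI assignment uses containment with ordered tie-breaks", {
  lay <- test_layout()
  fx <- tibble::tibble(az_deg = c(-95, 500, -150, 15),
                       el_deg = c(0, 0, 25, 0),
                       onset_s = 1:4, offset_s = 2:5, duration_s = 1)
  out <- assign_aois(fx, lay)
  expect_equal(out$aoi_id[1], "3")   # -95 lies inside segment 3
  expect_true(is.na(out$aoi_id[2])) # outside all polygons
  # shared boundary between segments 1 and 2 at az = -150: lower id wins
  expect_equal(out$aoi_id[3], "1")
  expect_equal(out$aoi_id[4], "7")   # targets ignored by default
  # prefer_targets labels fixations inside target boxes with the target
  out2 <- assign_aois(fx, lay, prefer_targets = TRUE)
  expect_equal(out2$aoi_id[4], "T2")  # target box centred in segment 7
})

test_that("time to first target measures latency from entry", {
  lay <- test_layout()
  n <- 360
  t <- (0:(n - 1)) / 120
  az <- rep(-170, n); el <- rep(0, n)
  az[t >= 2.4] <- -105   # centre of segment 3's target box
  rec <- gaze_recording(t, az, el)
  expect_equal(time_to_first_target(rec, lay, entry_time = 0), 2.4)
  # gaze already inside a target at entry
  expect_equal(time_to_first_target(rec, lay, entry_time = 2.5), 0)
  # never intersects
  rec2 <- gaze_recording(t, rep(-170, n), rep(0, n))
  expect_true(is.na(time_to_first_target(rec2, lay, 0)))
  expect_error(time_to_first_target(rec, lay, entry_time = 99), "span")
})

test_that("search order compliance follows the trained near-corner rule", {
  lay <- test_layout()  # near corners: 1, 12; back wall: 6, 7
  expect_true(search_order_met(c("1", "2", "6"), lay))
  expect_false(search_order_met(c("6", "1", "2"), lay))
  expect_true(search_order_met(c("3", "12", "4"), lay))  # corner, no back wall
  expect_false(search_order_met(c("3", "4", "5"), lay))  # neither tagged
  expect_true(search_order_met(c("6", "1"), lay, invert = TRUE))
  bad <- aoi_layout(lay$vertices)  # no role tags
  expect_error(search_order_met(c("1"), bad), "role")
})

test_that("trial metrics assemble the battery with the printed definitions", {
  lay <- test_layout()
  fx <- tibble::tibble(
    onset_s = seq(0, 4.5, by = 0.5), offset_s = seq(0.25, 4.75, by = 0.5),
    duration_s = 0.25, az_deg = 0, el_deg = 0
  )
  fx <- assign_aois(fx, lay)
  ev <- list(fixations = fx,
             saccades = tibble::tibble(onset_s = numeric(),
                                       offset_s = numeric(),
                                       duration_s = numeric(),
                                       r_x = numeric(), r_y = numeric(),
                                       theta_deg = numeric()))
  m <- compute_trial_metrics(ev, lay, meta = list(time_to_shoot_all = 6.5))
  expect_equal(m$n_fixations, 10)
  expect_equal(m$mean_fixation_duration, 0.25)
  expect_equal(m$search_rate, 40)  # 10 fixations / 0.25 s mean duration
  expect_equal(m$time_to_shoot_all, 6.5)
  # zero fixations: undefined duration-derived fields
  ev0 <- list(fixations = fx[0, ], saccades = ev$saccades)
  m0 <- compute_trial_metrics(ev0, lay)
  expect_true(is.na(m0$mean_fixation_duration))
  expect_true(is.na(m0$search_rate))
  expect_equal(m0$n_fixations, 0)
})

test_that("participant aggregation averages trials and scores compliance", {
  trials <- tibble::tibble(
    participant = "P01", group = "FFEMT", pool = "Army",
    phase = rep(c("pre", "post"), each = 20),
    mean_fixation_duration = rep(c(0.2, 0.3, 0.4, 0.3), 10),
    search_order_met = c(rep(TRUE, 15), rep(FALSE, 5), rep(TRUE, 20))
  )
  agg <- aggregate_participant(trials)
  expect_equal(nrow(agg), 2)
  expect_equal(agg$pct_search_order_met[agg$phase == "pre"], 75)
  expect_equal(agg$pct_search_order_met[agg$phase == "post"], 100)
  expect_equal(agg$mean_fixation_duration,
               rep(mean(c(0.2, 0.3, 0.4, 0.3)), 2))
  # single-trial aggregate is the trial itself
  agg1 <- aggregate_participant(trials[1, ])
  expect_equal(agg1$mean_fixation_duration, 0.2)
  # all-missing metric propagates NA
  trials$entropy <- NA_real_
  expect_true(all(is.na(aggregate_participant(trials)$entropy)))
})
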