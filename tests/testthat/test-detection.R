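test_that("acceleration is the central-difference second derivative", {
  rate <- 120
  t <- (0:119) / rate
  # linear ramp: zero interior acceleration
  a_lin <- compute_acceleration(5 * t, rep(0, 120), rate)
  expect_lt(max(a_lin[2:119]), 1e-8)
  # quadratic t^2 -> 2 deg/s^2
  a_quad <- compute_acceleration(t^2, rep(0, 120), rate)
  expect_equal(a_quad[2:119], rep(2, 118), tolerance = 1e-6)
  # channel symmetry
  a_el <- compute_acceleration(rep(0, 120), t^2, rate)
  expect_equal(a_el, a_quad)
  expect_error(compute_acceleration(1:4, 1:4, rate), "at least 5")
})

test_that("I-DT finds stationary clusters and honours the duration floor", {
  rec <- step_recording(rbind(c(5, 5), c(10, 5)), c(0.3, 0.3))
  fx <- detect_fixations(raw_streams(rec))
  expect_equal(nrow(fx), 2)
  expect_equal(fx$az_deg, c(5, 10), tolerance = 1e-9)
  expect_equal(fx$el_deg, c(5, 5), tolerance = 1e-9)
  # an 80 ms cluster is never a fixation
  rec2 <- step_recording(rbind(c(0, 0), c(30, 0), c(0, 0)),
                         c(0.3, 0.08, 0.3))
  fx2 <- detect_fixations(raw_streams(rec2))
  expect_equal(nrow(fx2), 2)
  expect_true(all(abs(fx2$az_deg) < 0.5))
  # empty input
  expect_equal(nrow(detect_fixations(raw_streams(
    step_recording(rbind(c(0, 0)), 0.3))[0, ])), 0)
})

test_that("I-DT matches the brute-force maximal-window oracle", {
  set.seed(101)
  for (rep in 1:20) {
    n_fix <- sample(2:5, 1)
    centres <- cbind(runif(n_fix, -150, 150), runif(n_fix, -20, 20))
    durs <- runif(n_fix, 0.08, 0.5)
    rec <- step_recording(centres, durs, noise = runif(1, 0, 0.15))
    st <- raw_streams(rec)
    expect_lte(nrow(st), 500)
    got <- detect_fixations(st, merge_gap_s = 0)
    want <- idt_oracle(st$t_s, st$az_fix, st$el_fix, 1.0, 0.1)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(nrow(got), nrow(want))
      expect_equal(got$onset_s, want$onset_s, tolerance = 1e-12)
      expect_equal(got$offset_s, want$offset_s, tolerance = 1e-12)
      expect_equal(got$az_deg, want$az_deg, tolerance = 1e-12)
    }
  }
})

test_that("saccade onset/offset land on the acceleration extrema", {
  # one raised-cosine saccade: the acceleration extrema of the analytic
  # profile sit exactly at the movement's start and end; the detector is
  # run on the rendered positions directly so the comparison is against
  # the analytic kinematics, not the smoothing filter's spread
  lay <- test_layout()
  prof <- scan_profile(noise_sd = 0, blink_rate = 0, trial_duration = 1.2,
                       fixation_duration_mean = 0.5,
                       fixation_duration_sd = 0)
  sp <- generate_scanpath(prof, lay, seed = 5)
  sp$fixations <- sp$fixations[1:2, ]
  sp$saccades <- sp$saccades[1, ]
  rec <- render_recording(sp, rate = 120, noise_sd = 0)
  sac <- detect_saccades(raw_streams(rec), rate = 120)
  expect_equal(nrow(sac), 1)
  expect_lt(abs(sac$onset_s - sp$saccades$onset_s), 2 / 120 + 1e-9)
  expect_lt(abs(sac$offset_s - sp$saccades$offset_s), 2 / 120 + 1e-9)
  # displacement direction matches ground truth
  expect_equal(sign(sac$r_x), sign(sp$saccades$r_x))
})

test_that("sub-threshold traces yield no saccades", {
  rate <- 120
  t <- (0:(rate * 3 - 1)) / rate
  # amplitude-modulated sinusoid: peak acceleration ~4x its median
  env <- 1 + 2 * exp(-((t - 1.5) / 0.15)^2)
  x <- 0.3 * env * sin(2 * pi * 4 * t)
  st <- tibble::tibble(t_s = t, segment = 1L, az_fix = x, el_fix = 0 * t,
                       az_sac = x, el_sac = 0 * t)
  a <- compute_acceleration(x, 0 * t, rate)
  ratio <- max(a) / median(a)
  expect_gt(ratio, 3); expect_lt(ratio, 5)
  expect_equal(nrow(detect_saccades(st, rate = rate)), 0)
})

test_that("stationary jitter rarely produces false saccades", {
  set.seed(77)
  fp <- 0
  for (s in 1:100) {
    rec <- step_recording(rbind(c(0, 0)), 2, noise = 0.1)
    st <- preprocess_gaze(rec)
    sac <- detect_saccades(st, rate = 120)
    fp <- fp + (nrow(sac) > 0)
  }
  expect_lt(fp / 100, 0.05)
})

test_that("raising the threshold multiplier never adds saccades", {
  lay <- test_layout()
  sp <- generate_scanpath(scan_profile(blink_rate = 0), lay, seed = 9)
  rec <- render_recording(sp, seed = 10)
  st <- preprocess_gaze(rec)
  counts <- vapply(c(5, 8, 12, 20), function(k) {
    nrow(detect_saccades(st, rate = 120, k = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("events are non-overlapping and inside the recording span", {
  lay <- test_layout()
  for (s in 1:5) {
    sp <- generate_scanpath(scan_profile(), lay, seed = s)
    rec <- render_recording(sp, seed = s + 100)
    ev <- detect_events(rec, layout = lay)
    for (tab in ev) {
      if (nrow(tab) >= 2) {
        expect_true(all(tab$onset_s[-1] >= tab$offset_s[-nrow(tab)] - 1e-9))
      }
      if (nrow(tab) >= 1) {
        expect_gte(min(tab$onset_s), min(rec$t_s) - 1e-9)
        expect_lte(max(tab$offset_s), max(rec$t_s) + 1e-9)
        expect_true(all(tab$offset_s > tab$onset_s))
      }
    }
  }
})

test_that("reconciliation truncates fixations at saccade boundaries", {
  fx <- tibble::tibble(onset_s = 0, offset_s = 0.5, duration_s = 0.5,
                       az_deg = 1, el_deg = 1)
  sac <- tibble::tibble(onset_s = 0.2, offset_s = 0.25, duration_s = 0.05,
                        r_x = 3, r_y = 0, theta_deg = 0)
  out <- reconcile_events(fx, sac)
  expect_equal(nrow(out$fixations), 2)
  expect_equal(out$fixations$offset_s[1], 0.2)
  expect_equal(out$fixations$onset_s[2], 0.25)
  # a truncation fragment below 100 ms is dropped
  sac2 <- tibble::tibble(onset_s = 0.42, offset_s = 0.47, duration_s = 0.05,
                         r_x = 3, r_y = 0, theta_deg = 0)
  out2 <- reconcile_events(fx, sac2)
  expect_equal(nrow(out2$fixations), 1)
  expect_equal(out2$fixations$offset_s, 0.42)
  # disjoint events pass through unchanged
  sac3 <- tibble::tibble(onset_s = 0.6, offset_s = 0.65, duration_s = 0.05,
                         r_x = 3, r_y = 0, theta_deg = 0)
  out3 <- reconcile_events(fx, sac3)
  expect_equal(out3$fixations$onset_s, fx$onset_s)
  expect_equal(out3$fixations$offset_s, fx$offset_s)
})

test_that("detection recovers ground truth on noisy synthetic recordings", {
  lay <- test_layout()
  f1s <- c(); cnt <- c(); dur <- c()
  for (s in 1:15) {
    sp <- generate_scanpath(scan_profile(blink_rate = 0), lay, seed = s)
    rec <- render_recording(sp, rate = 120, seed = s + 500)
    ev <- detect_events(rec, layout = lay)
    f1s <- c(f1s, event_f1(ev$fixations, sp$fixations))
    cnt <- c(cnt, abs(nrow(ev$fixations) - nrow(sp$fixations)))
    dur <- c(dur, abs(mean(ev$fixations$duration_s) -
                        mean(sp$fixations$duration_s)))
  }
  expect_true(all(f1s >= 0.9))
  expect_true(all(cnt <= 1))
  expect_lt(mean(dur), 0.010)
})

test_that("noiseless rendering is recovered exactly", {
  lay <- test_layout()
  frac2 <- numeric(5)
  for (s in 1:5) {
    sp <- generate_scanpath(scan_profile(noise_sd = 0, blink_rate = 0),
                            lay, seed = s)
    rec <- render_recording(sp, rate = 120, noise_sd = 0)
    ev <- detect_events(rec, layout = lay)
    expect_equal(nrow(ev$fixations), nrow(sp$fixations))
    err <- abs(ev$fixations$duration_s - sp$fixations$duration_s)
    # the slow tails of small-amplitude raised-cosine saccades sit inside
    # the dispersion budget, so a couple of boundary samples can migrate
    expect_true(all(err <= 5 / 120 + 1e-9))
    frac2[s] <- mean(err <= 2 / 120 + 1e-9)
  }
  expect_gte(mean(frac2), 0.75)
})
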