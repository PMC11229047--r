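test_that("Holm adjustment matches the hand-computed step-down values", {
  expect_equal(holm_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(holm_adjust(0.2), 0.2)
  expect_equal(holm_adjust(c(0.5, 0.5)), c(1, 1))
  # order-preserving and monotone
  p <- c(0.04, 0.001, 0.3, 0.012)
  adj <- holm_adjust(p)
  expect_equal(order(adj), order(p))
  expect_true(all(adj >= p))
  expect_error(holm_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("balanced no-covariate fits equal the split-plot oracle", {
  for (seed in 1:5) {
    df <- make_balanced(n = 8, seed = seed, time_shift = 0.3,
                        int_shift = 0.2)
    fit <- mixed_anova(df, "value")
    want <- splitplot_oracle(df)
    eff <- fit$effects
    expect_equal(eff$F[eff$effect == "time"], want$F_time,
                 tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "group"], want$F_group,
                 tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "group:time"], want$F_int,
                 tolerance = 1e-8)
  }
})

test_that("a pure time shift loads on the time effect, not the interaction", {
  df <- make_balanced(n = 20, seed = 3, time_shift = 1.0)
  fit <- mixed_anova(df, "value")
  eff <- fit$effects
  expect_lt(eff$p[eff$effect == "time"], 1e-6)
  expect_gt(eff$p[eff$effect == "group:time"], 0.01)
  expect_gt(eff$F[eff$effect == "time"], 10 * eff$F[eff$effect == "group:time"])
})

test_that("covariate retention follows the significance rule exactly", {
  # unrelated covariate: removed, and the refit equals a plain mixed ANOVA
  df <- make_balanced(n = 10, seed = 5)
  fit_cov <- mixed_anova(df, "value", covariate = "pool")
  fit_plain <- mixed_anova(df, "value")
  expect_false(fit_cov$covariate_retained)
  expect_gte(fit_cov$covariate_test[["p"]], 0.05)
  expect_equal(fit_cov$effects, fit_plain$effects)
  # strongly related covariate: retained, with dfs reduced by one
  df2 <- df
  df2$value <- df2$value + ifelse(df2$pool == "RM", 2, 0)
  fit2 <- mixed_anova(df2, "value", covariate = "pool")
  expect_true(fit2$covariate_retained)
  expect_lt(fit2$covariate_test[["p"]], 0.05)
  n <- length(unique(df2$participant))
  eff2 <- fit2$effects
  expect_equal(eff2$df_den[eff2$effect == "group"], n - 3 - 1)
  expect_equal(eff2$df_den[eff2$effect == "time"], n - 3 - 1)
  expect_equal(fit_plain$effects$df_den[1], n - 3)
})

test_that("the reference design reproduces the study's error dfs", {
  d <- study_design(seed = 42)
  ds <- simulate_metric_dataset(d, metric = "entropy")
  fit <- mixed_anova(ds, "entropy", covariate = "pool")
  eff <- fit$effects
  want_den <- if (fit$covariate_retained) 34 else 35
  expect_true(all(eff$df_den == want_den))
  expect_equal(eff$df_num[eff$effect == "group"], 2)
  expect_equal(eff$df_num[eff$effect == "time"], 1)
})

test_that("interaction type-I error is calibrated at alpha", {
  n_sim <- 400
  rej <- 0
  for (s in seq_len(n_sim)) {
    ds <- simulate_metric_dataset(study_design(seed = s), metric = "entropy")
    fit <- mixed_anova(ds, "entropy", posthoc_band = -1)
    rej <- rej + (fit$effects$p[fit$effects$effect == "group:time"] < 0.05)
  }
  rate <- rej / n_sim
  # three Monte-Carlo standard errors around 0.05
  se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lt(abs(rate - 0.05), 3 * se)
})

test_that("power rises monotonically with the interaction effect size", {
  n_rep <- 150
  power <- vapply(c(0, 0.25, 0.5), function(shift) {
    rej <- 0
    for (s in seq_len(n_rep)) {
      d <- study_design(
        seed = s + 7000,
        effect_spec = if (shift > 0) {
          data.frame(metric = "entropy", group = "FBEMT", phase = "post",
                     shift = shift)
        } else {
          NULL
        }
      )
      ds <- simulate_metric_dataset(d, metric = "entropy")
      fit <- mixed_anova(ds, "entropy", posthoc_band = -1)
      rej <- rej + (fit$effects$p[fit$effects$effect == "group:time"] < 0.05)
    }
    rej / n_rep
  }, numeric(1))
  expect_true(all(diff(power) > 0))
  expect_gt(power[3], 0.5)
})

test_that("injected cell shifts are recovered by the marginal means", {
  diffs <- numeric(80)
  for (s in seq_len(80)) {
    d <- study_design(seed = s + 2000,
                      effect_spec = data.frame(metric = "entropy",
                                               group = "FFEMT",
                                               phase = "post", shift = 0.4))
    ds <- simulate_metric_dataset(d, metric = "entropy")
    ff <- ds[ds$group == "FFEMT", ]
    ctl <- ds[ds$group == "Control", ]
    diffs[s] <- (mean(ff$entropy[ff$phase == "post"]) -
                   mean(ff$entropy[ff$phase == "pre"])) -
      (mean(ctl$entropy[ctl$phase == "post"]) -
         mean(ctl$entropy[ctl$phase == "pre"]))
  }
  se <- sd(diffs) / sqrt(length(diffs))
  expect_lt(abs(mean(diffs) - 0.4), 3 * se)
})

test_that("post-hoc battery has the pre/post/paired structure", {
  df <- make_balanced(n = 12, seed = 11, int_shift = 1.2)
  fit <- mixed_anova(df, "value")
  expect_false(is.null(fit$posthoc))
  ph <- fit$posthoc
  expect_equal(nrow(ph), 9)
  expect_equal(as.integer(table(ph$family)[c("pre", "post", "pre-post change")]),
               c(3L, 3L, 3L))
  expect_true(all(ph$p_adj >= ph$p))
  # identical groups: adjusted p-values near 1
  df0 <- make_balanced(n = 20, seed = 12)
  ph0 <- posthoc_battery(fit0 <- mixed_anova(df0, "value")$data)
  expect_gt(min(ph0$p_adj), 0.05)
})

test_that("an FBEMT-only post shift yields the smallest paired p for FBEMT", {
  hits <- 0
  n_rep <- 200
  for (s in seq_len(n_rep)) {
    d <- study_design(seed = s + 5000,
                      effect_spec = data.frame(metric = "entropy",
                                               group = "FBEMT",
                                               phase = "post", shift = 0.6))
    ds <- simulate_metric_dataset(d, metric = "entropy")
    wide <- tidyr::pivot_wider(ds, names_from = "phase",
                               values_from = "entropy")
    ph <- posthoc_battery(wide)
    paired <- ph[ph$family == "pre-post change", ]
    hits <- hits + (paired$comparison[which.min(paired$p_adj)] == "FBEMT")
  }
  expect_gt(hits / n_rep, 0.9)
})

test_that("degenerate inputs raise informative errors", {
  df <- make_balanced(n = 10, seed = 20)
  expect_error(mixed_anova(df[df$group != "FFEMT", ][1:4, ], "value"),
               "pre")
  dfc <- df; dfc$value <- 1
  expect_error(mixed_anova(dfc, "value"), "degenerate")
  df1 <- df[df$participant %in% c("p01", "p02", "p11", "p21"), ]
  expect_error(mixed_anova(df1, "value"), "insufficient|2 complete")
})

test_that("reports are deterministic, ordered and serialisable", {
  d <- study_design(seed = 77)
  ds1 <- simulate_metric_dataset(d, metric = "entropy")
  ds2 <- simulate_metric_dataset(d, metric = "search_rate", baseline = 100,
                                 participant_sd = 10, resid_sd = 8)
  ds <- dplyr::left_join(ds1, ds2,
                         by = c("participant", "group", "pool", "phase"))
  rep1 <- analyse_study(ds, dvs = c("search_rate", "entropy"))
  expect_equal(names(rep1), c("entropy", "search_rate"))  # alphabetical
  s1 <- report_summary(rep1)
  s2 <- report_summary(analyse_study(ds, dvs = c("entropy", "search_rate")))
  expect_identical(s1, s2)
  j1 <- jsonlite::toJSON(s1, auto_unbox = TRUE, digits = NA)
  j2 <- jsonlite::toJSON(s2, auto_unbox = TRUE, digits = NA)
  expect_identical(j1, j2)
  expect_match(as.character(j1), "covariate_retained")
  # tidy/glance accessors
  expect_s3_class(tidy(rep1$entropy), "tbl_df")
  expect_equal(nrow(glance(rep1$entropy)), 1)
})
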