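metric_names <- c("n_fixations", "mean_fixation_duration", "search_rate",
                  "entropy", "pct_antipersistent", "time_to_first_target",
                  "pct_search_order_met", "failures_to_inhibit",
                  "time_to_shoot_all", "prop_hostiles_cleared")

#' Pre/post training study design
#'
#' Describes a participants x group(3) x time(2) independent-groups design
#' with a two-level participant-pool covariate, matching the structure of a
#' VR room-clearance training study: three training arms (feed-forward eye
#' movement training, feed-back eye movement training, control) measured
#' before and after training, each phase comprising repeated search trials.
#'
#' @param n_per_group Named integer vector of analysed participants per
#'   group. The default `c(FFEMT = 12, FBEMT = 13, Control = 13)` gives the
#'   38 complete datasets of the reference design.
#' @param trials_per_phase Search trials per participant per phase
#'   (default 20).
#' @param effect_spec A data frame with columns `metric`, `group`, `phase`,
#'   `shift`: additive shifts injected into the named metric in the given
#'   group x phase cell. May be `NULL` (no effects).
#' @param pool_levels Two labels for the participant-pool covariate.
#' @param pool_prob Probability that a participant belongs to the second
#'   pool level (default 26/40, the reference cohort's Royal Marines
#'   share).
#' @param pool_effects Named numeric: additive shift on each named metric
#'   for participants in the second pool level.
#' @param seed Integer seed; identical seeds give bit-identical datasets.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_per_group = c(FFEMT = 12, FBEMT = 13,
                                         Control = 13),
                         trials_per_phase = 20,
                         effect_spec = NULL,
                         pool_levels = c("Army", "RM"),
                         pool_prob = 26 / 40,
                         pool_effects = NULL,
                         seed = 1L) {
  stopifnot(all(n_per_group >= 2), trials_per_phase >= 1,
            length(pool_levels) == 2)
  if (is.null(names(n_per_group))) {
    names(n_per_group) <- c("FFEMT", "FBEMT", "Control")[seq_along(n_per_group)]
  }
  if (!is.null(effect_spec)) {
    effect_spec <- tibble::as_tibble(effect_spec)
    stopifnot(all(c("metric", "group", "phase", "shift") %in%
                    names(effect_spec)))
    bad <- setdiff(effect_spec$metric, metric_names)
    if (length(bad) > 0) {
      stop("effect_spec names unknown metric(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    bad_g <- setdiff(effect_spec$group, names(n_per_group))
    if (length(bad_g) > 0) {
      stop("effect_spec names unknown group(s): ",
           paste(bad_g, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(pool_effects)) {
    bad <- setdiff(names(pool_effects), metric_names)
    if (length(bad) > 0) {
      stop("pool_effects names unknown metric(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(n_per_group = n_per_group, trials_per_phase = trials_per_phase,
         effect_spec = effect_spec, pool_levels = pool_levels,
         pool_prob = pool_prob, pool_effects = pool_effects,
         seed = as.integer(seed)),
    class = "study_design"
  )
}

# participant roster for a design: id, group, pool, skill
draw_roster <- function(design) {
  groups <- rep(names(design$n_per_group), design$n_per_group)
  n <- length(groups)
  tibble::tibble(
    participant = sprintf("P%02d", seq_len(n)),
    group = groups,
    pool = design$pool_levels[1 + stats::rbinom(n, 1, design$pool_prob)],
    skill = stats::runif(n, 0.25, 0.75)
  )
}

# linear interpolation between novice (s = 0) and expert (s = 1) profiles
blend_profiles <- function(novice, expert, s) {
  num <- c("sweep_persistence", "fixation_duration_mean",
           "fixation_duration_sd", "noise_sd")
  args <- unclass(novice)
  for (f in num) args[[f]] <- novice[[f]] + s * (expert[[f]] - novice[[f]])
  do.call(scan_profile, args)
}

apply_shifts <- function(metrics, design, group, phase, pool) {
  es <- design$effect_spec
  if (!is.null(es)) {
    hit <- es[es$group == group & es$phase == phase, , drop = FALSE]
    for (k in seq_len(nrow(hit))) {
      m <- hit$metric[k]
      if (m %in% names(metrics)) metrics[[m]] <- metrics[[m]] + hit$shift[k]
    }
  }
  pe <- design$pool_effects
  if (!is.null(pe) && pool == design$pool_levels[2]) {
    for (m in intersect(names(pe), names(metrics))) {
      metrics[[m]] <- metrics[[m]] + pe[[m]]
    }
  }
  metrics
}

#' Generate a full synthetic study dataset
#'
#' Simulates every trial of a pre/post training study by generating
#' ground-truth scanpaths (no signal rendering) and computing the metric
#' battery on them, then aggregating to participant x phase cells. Each
#' participant draws a latent skill that blends the novice and expert
#' profiles and persists across phases (inducing the within-participant
#' correlation a mixed design relies on); group x phase effects are
#' injected as the additive shifts named in the design's `effect_spec`.
#' Per-trial performance outcomes (failures to inhibit, time to shoot all
#' hostiles, proportion cleared) are drawn from simple parametric models
#' and passed through the same aggregation.
#'
#' @param design A [study_design()].
#' @param expert,novice [scan_profile()]s bounding the skill blend.
#' @param layout An [aoi_layout()].
#' @param return_trials If `TRUE`, also return the per-trial metric table.
#' @return A tibble with one row per participant x phase and one column
#'   per metric (class `study_dataset`), or a list
#'   `(participants, trials)` when `return_trials = TRUE`.
#' @export
generate_study <- function(design,
                           expert = expert_profile(),
                           novice = novice_profile(),
                           layout = room_layout(),
                           return_trials = FALSE) {
  withr::with_seed(design$seed, {
    roster <- draw_roster(design)
    trials <- purrr::pmap_dfr(roster, function(participant, group, pool,
                                               skill) {
      prof <- blend_profiles(novice, expert, skill)
      purrr::map_dfr(c("pre", "post"), function(phase) {
        purrr::map_dfr(seq_len(design$trials_per_phase), function(tr) {
          sp <- scanpath_impl(prof, layout)
          m <- ground_truth_metrics(sp, layout)
          m$failures_to_inhibit <- stats::rpois(1, 0.5)
          m$time_to_shoot_all <- stats::rnorm(1, 6, 1.5)
          m$prop_hostiles_cleared <- stats::rbinom(1, 4, 0.85) / 4
          m <- apply_shifts(m, design, group, phase, pool)
          dplyr::bind_cols(
            tibble::tibble(participant = participant, group = group,
                           pool = pool, phase = phase, trial = tr), m)
        })
      })
    })
    agg <- aggregate_participant(trials)
    # percent-scale shifts on the compliance metric apply after aggregation
    es <- design$effect_spec
    if (!is.null(es) && "pct_search_order_met" %in% es$metric) {
      hit <- es[es$metric == "pct_search_order_met", , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        sel <- agg$group == hit$group[k] & agg$phase == hit$phase[k]
        agg$pct_search_order_met[sel] <-
          agg$pct_search_order_met[sel] + hit$shift[k]
      }
    }
    agg$phase <- factor(agg$phase, levels = c("pre", "post"))
    agg <- dplyr::select(agg, -dplyr::any_of(c("trial", "skill")))
    class(agg) <- c("study_dataset", class(agg))
    if (return_trials) list(participants = agg, trials = trials) else agg
  })
}

#' Fast parametric study simulator
#'
#' Draws a participant x phase dataset for a single metric directly from a
#' Gaussian mixed model: metric = baseline + participant random intercept +
#' pool effect + injected cell shift + residual. Useful for calibration
#' studies of the statistics stage (type-I error, power), where thousands
#' of replicate datasets are needed and scanpath simulation would be
#' needless.
#'
#' @param design A [study_design()]; its `effect_spec` rows for `metric`
#'   are honoured, as are `pool_effects[[metric]]`.
#' @param metric Metric name (column name of the output).
#' @param baseline Grand mean.
#' @param participant_sd SD of the participant random intercept.
#' @param resid_sd Residual SD per cell observation.
#' @param seed Seed; defaults to the design's.
#' @return A `study_dataset` tibble: `participant`, `group`, `pool`,
#'   `phase`, `<metric>`.
#' @export
simulate_metric_dataset <- function(design, metric = "entropy",
                                    baseline = 2.5, participant_sd = 0.4,
                                    resid_sd = 0.3, seed = design$seed) {
  stopifnot(metric %in% metric_names)
  withr::with_seed(seed, {
    roster <- draw_roster(design)
    n <- nrow(roster)
    b_i <- stats::rnorm(n, 0, participant_sd)
    out <- purrr::map_dfr(c("pre", "post"), function(phase) {
      val <- baseline + b_i + stats::rnorm(n, 0, resid_sd)
      df <- tibble::tibble(participant = roster$participant,
                           group = roster$group, pool = roster$pool,
                           phase = phase, value = val)
      df
    })
    es <- design$effect_spec
    if (!is.null(es)) {
      hit <- es[es$metric == metric, , drop = FALSE]
      for (k in seq_len(nrow(hit))) {
        sel <- out$group == hit$group[k] & out$phase == hit$phase[k]
        out$value[sel] <- out$value[sel] + hit$shift[k]
      }
    }
    pe <- design$pool_effects
    if (!is.null(pe) && metric %in% names(pe)) {
      sel <- out$pool == design$pool_levels[2]
      out$value[sel] <- out$value[sel] + pe[[metric]]
    }
    names(out)[names(out) == "value"] <- metric
    out$phase <- factor(out$phase, levels = c("pre", "post"))
    class(out) <- c("study_dataset", class(out))
    out
  })
}
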