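#' Scanning-behaviour profile
#'
#' Parameterises the synthetic gaze generator. The central parameter is
#' `sweep_persistence`: the probability that the next fixation continues
#' the current sweep to the adjacent wall segment. At 1 the scanpath is a
#' single ordered sweep around the room (the trained, expert-like search);
#' at 0 every transition reverses the sweep direction and jumps to a random
#' segment on the other side (a disorganised, antipersistent search).
#'
#' @param sweep_persistence Probability in `[0, 1]` of continuing the
#'   current sweep direction at each transition.
#' @param fixation_duration_mean,fixation_duration_sd Fixation duration
#'   distribution, seconds (normal, truncated at the 0.1 s minimum).
#' @param saccade_peak_velocity_scale Peak saccadic velocity per degree of
#'   amplitude (deg/s per deg). With the raised-cosine kinematics used for
#'   rendering this fixes the saccade duration at `pi / (2 * scale)`
#'   seconds.
#' @param noise_sd Fixational jitter, degrees (per-sample Gaussian noise
#'   added at render time).
#' @param blink_rate Blink events per minute (rendered as invalid gaps).
#' @param blink_duration Mean blink duration, seconds.
#' @param trial_duration Trial length, seconds (t = 0 is room entry).
#' @return A list of class `scan_profile`.
#' @seealso [expert_profile()], [novice_profile()]
#' @export
scan_profile <- function(sweep_persistence = 0.5,
                         fixation_duration_mean = 0.32,
                         fixation_duration_sd = 0.08,
                         saccade_peak_velocity_scale = 30,
                         noise_sd = 0.1,
                         blink_rate = 2,
                         blink_duration = 0.15,
                         trial_duration = 15) {
  stopifnot(sweep_persistence >= 0, sweep_persistence <= 1,
            fixation_duration_mean >= 0.1, fixation_duration_sd >= 0,
            saccade_peak_velocity_scale > 0, noise_sd >= 0,
            blink_rate >= 0, trial_duration > 0)
  structure(
    list(sweep_persistence = sweep_persistence,
         fixation_duration_mean = fixation_duration_mean,
         fixation_duration_sd = fixation_duration_sd,
         saccade_peak_velocity_scale = saccade_peak_velocity_scale,
         noise_sd = noise_sd, blink_rate = blink_rate,
         blink_duration = blink_duration, trial_duration = trial_duration),
    class = "scan_profile"
  )
}

#' Expert-like scanning profile
#'
#' A persistent, systematic sweep with longer fixations: the search pattern
#' room-clearance training aims to instil.
#' @param ... Overrides passed to [scan_profile()].
#' @export
expert_profile <- function(...) {
  defaults <- list(sweep_persistence = 1, fixation_duration_mean = 0.40,
                   fixation_duration_sd = 0.08)
  do.call(scan_profile, utils::modifyList(defaults, list(...)))
}

#' Novice-like scanning profile
#'
#' An antipersistent, disorganised search with shorter fixations: gaze
#' keeps doubling back to re-check already-searched areas.
#' @param ... Overrides passed to [scan_profile()].
#' @export
novice_profile <- function(...) {
  defaults <- list(sweep_persistence = 0, fixation_duration_mean = 0.28,
                   fixation_duration_sd = 0.08)
  do.call(scan_profile, utils::modifyList(defaults, list(...)))
}

# truncated-normal fixation duration (>= 0.1 s)
rfixdur <- function(n, mean, sd) {
  pmax(0.1, stats::rnorm(n, mean, sd))
}

# random point inside a segment polygon's bounding box, shrunk by a margin
# so rendered jitter stays inside the polygon (segments are rectangles).
# Azimuth is uniform; elevation concentrates near eye level (search is
# mostly horizontal), truncated to the polygon.
point_in_aoi <- function(layout, aoi_id, margin = 1, el_sd = 6) {
  v <- layout$vertices[layout$vertices$aoi_id == aoi_id, , drop = FALSE]
  rx <- range(v$az_deg); ry <- range(v$el_deg)
  m <- min(margin, (rx[2] - rx[1]) / 4, (ry[2] - ry[1]) / 4)
  el <- min(max(stats::rnorm(1, 0, el_sd), ry[1] + m), ry[2] - m)
  c(stats::runif(1, rx[1] + m, rx[2] - m), el)
}

#' Generate a ground-truth scanpath
#'
#' Simulates one trial's fixation/saccade sequence over the segment AOIs of
#' a layout. The walk keeps a sweep direction along the ordered segments:
#' with probability `sweep_persistence` it advances to the adjacent segment
#' in the current direction (wrapping to the far end after completing a
#' full pass, like a carriage return); otherwise it reverses direction and
#' jumps to a uniformly chosen segment on the new side. Fixation centroids
#' are placed uniformly inside the chosen segment; saccades between
#' successive fixations get raised-cosine kinematics with duration
#' `pi / (2 * saccade_peak_velocity_scale)` seconds. Blinks are drawn as a
#' Poisson process and stored as gap windows.
#'
#' @param profile A [scan_profile()].
#' @param layout An [aoi_layout()] with at least 2 segment AOIs.
#' @param seed Integer seed; the call is deterministic given
#'   `(profile, layout, seed)`. `NULL` uses the current RNG state.
#' @return A list of class `scanpath` with elements `aoi_sequence`
#'   (character), `fixations` (tibble: `onset_s`, `offset_s`, `duration_s`,
#'   `az_deg`, `el_deg`, `aoi_id`), `saccades` (tibble: `onset_s`,
#'   `offset_s`, `duration_s`, `r_x`, `r_y`, `theta_deg`), `blinks`
#'   (tibble: `onset_s`, `offset_s`), and `profile`.
#' @export
generate_scanpath <- function(profile, layout, seed = NULL) {
  if (length(layout$aoi_ids) < 2) {
    stop("invalid layout: need at least 2 segment AOIs", call. = FALSE)
  }
  run <- function() scanpath_impl(profile, layout)
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

scanpath_impl <- function(profile, layout) {
  ids <- layout$aoi_ids
  n_aoi <- length(ids)
  sac_dur <- pi / (2 * profile$saccade_peak_velocity_scale)
  # disciplined searchers enter at a near corner and sweep away from it;
  # undisciplined ones start anywhere (they may check the back wall first)
  if (stats::runif(1) <= profile$sweep_persistence) {
    pos <- sample(c(1L, n_aoi), 1)
  } else {
    pos <- sample(seq_len(n_aoi), 1)
  }
  dir <- if (pos == 1L) 1L else if (pos == n_aoi) -1L else
    sample(c(-1L, 1L), 1)
  t <- 0
  fx <- list(); idx_seq <- integer(0)
  # stop once the remaining trial time cannot hold a minimum fixation
  while (profile$trial_duration - t >= 0.1 - 1e-9) {
    dur <- rfixdur(1, profile$fixation_duration_mean,
                   profile$fixation_duration_sd)
    offset <- min(t + dur, profile$trial_duration)
    cen <- point_in_aoi(layout, ids[pos])
    fx[[length(fx) + 1]] <- c(onset = t, offset = offset,
                              az = cen[1], el = cen[2], pos = pos)
    idx_seq <- c(idx_seq, pos)
    t <- offset + sac_dur
    # next AOI: continue the sweep or reverse and jump
    if (stats::runif(1) <= profile$sweep_persistence) {
      nxt <- pos + dir
      if (nxt > n_aoi) nxt <- 1L else if (nxt < 1L) nxt <- n_aoi
    } else {
      dir <- -dir
      side <- if (dir > 0) setdiff(seq_len(n_aoi), seq_len(pos)) else
        setdiff(seq_len(n_aoi), pos:n_aoi)
      if (length(side) == 0) side <- setdiff(seq_len(n_aoi), pos)
      nxt <- if (length(side) == 1) side else sample(side, 1)
    }
    pos <- as.integer(nxt)
  }
  fm <- do.call(rbind, fx)
  # gaze rests on the final fixation until the trial ends
  fm[nrow(fm), "offset"] <- profile$trial_duration
  fixations <- tibble::tibble(
    onset_s = fm[, "onset"], offset_s = fm[, "offset"],
    duration_s = fm[, "offset"] - fm[, "onset"],
    az_deg = fm[, "az"], el_deg = fm[, "el"],
    aoi_id = ids[fm[, "pos"]]
  )
  nf <- nrow(fixations)
  saccades <- if (nf >= 2) {
    rx <- fixations$az_deg[-1] - fixations$az_deg[-nf]
    ry <- fixations$el_deg[-1] - fixations$el_deg[-nf]
    tibble::tibble(
      onset_s = fixations$offset_s[-nf],
      offset_s = fixations$onset_s[-1],
      duration_s = fixations$onset_s[-1] - fixations$offset_s[-nf],
      r_x = rx, r_y = ry, theta_deg = saccadic_angle(rx, ry)
    )
  } else {
    tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                   duration_s = numeric(), r_x = numeric(), r_y = numeric(),
                   theta_deg = numeric())
  }
  n_blink <- stats::rpois(1, profile$blink_rate *
                            profile$trial_duration / 60)
  blinks <- if (n_blink > 0) {
    on <- sort(stats::runif(n_blink, 0, profile$trial_duration -
                              profile$blink_duration))
    b <- tibble::tibble(onset_s = on,
                        offset_s = on + profile$blink_duration)
    b[c(TRUE, diff(b$onset_s) > 2 * profile$blink_duration), , drop = FALSE]
  } else {
    tibble::tibble(onset_s = numeric(), offset_s = numeric())
  }
  structure(list(aoi_sequence = fixations$aoi_id, fixations = fixations,
                 saccades = saccades, blinks = blinks, profile = profile),
            class = "scanpath")
}

#' Render a scanpath into a sampled gaze recording
#'
#' Turns ground-truth events into a uniformly sampled angular gaze trace.
#' Within fixations the position is the fixation centroid plus isotropic
#' Gaussian jitter of `noise_sd` degrees; within saccades the position
#' follows a raised-cosine profile between the flanking centroids, whose
#' acceleration has exactly one maximum (at onset) and one minimum (at
#' offset); blink windows are marked invalid.
#'
#' @param scanpath A `scanpath` from [generate_scanpath()] (its events must
#'   be time-ordered and non-overlapping).
#' @param rate Sampling rate, Hz.
#' @param noise_sd Fixational jitter sd in degrees; defaults to the
#'   profile's value.
#' @param seed Integer seed for the jitter; `NULL` uses the current RNG.
#' @param meta Trial metadata list stored on the recording.
#' @return A [gaze_recording()] spanning the profile's trial duration with
#'   `floor(duration * rate)` samples.
#' @export
render_recording <- function(scanpath, rate = 120, noise_sd = NULL,
                             seed = NULL, meta = list()) {
  stopifnot(rate > 0)
  if (is.null(noise_sd)) noise_sd <- scanpath$profile$noise_sd
  fx <- scanpath$fixations
  if (nrow(fx) == 0) stop("scanpath has no fixations", call. = FALSE)
  if (any(fx$onset_s[-1] < fx$offset_s[-nrow(fx)])) {
    stop("inconsistent ground truth: overlapping events", call. = FALSE)
  }
  run <- function() {
    dur <- scanpath$profile$trial_duration
    n <- floor(dur * rate)
    t <- (seq_len(n) - 1) / rate
    az <- numeric(n); el <- numeric(n)
    # fixation intervals: index of the fixation whose span contains t
    fi <- findInterval(t, fx$onset_s)
    for (i in seq_len(n)) {
      k <- fi[i]
      if (k >= 1 && t[i] <= fx$offset_s[k]) {
        az[i] <- fx$az_deg[k]; el[i] <- fx$el_deg[k]
      } else if (k >= 1 && k < nrow(fx)) {
        # raised-cosine transition between fixation k and k+1
        t0 <- fx$offset_s[k]; t1 <- fx$onset_s[k + 1]
        u <- (1 - cos(pi * (t[i] - t0) / (t1 - t0))) / 2
        az[i] <- fx$az_deg[k] + u * (fx$az_deg[k + 1] - fx$az_deg[k])
        el[i] <- fx$el_deg[k] + u * (fx$el_deg[k + 1] - fx$el_deg[k])
      } else if (k < 1) {
        az[i] <- fx$az_deg[1]; el[i] <- fx$el_deg[1]
      } else {
        az[i] <- fx$az_deg[nrow(fx)]; el[i] <- fx$el_deg[nrow(fx)]
      }
    }
    if (noise_sd > 0) {
      az <- az + stats::rnorm(n, 0, noise_sd)
      el <- el + stats::rnorm(n, 0, noise_sd)
    }
    valid <- rep(TRUE, n)
    for (b in seq_len(nrow(scanpath$blinks))) {
      valid[t >= scanpath$blinks$onset_s[b] &
              t < scanpath$blinks$offset_s[b]] <- FALSE
    }
    gaze_recording(t, az, el, valid, rate = rate, meta = meta)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Per-trial metrics straight from ground truth
#'
#' Computes the trial metric battery directly on a scanpath's ground-truth
#' events, bypassing rendering and detection. Used by [generate_study()]
#' to build study-scale datasets quickly.
#'
#' @param scanpath A `scanpath`.
#' @param layout The [aoi_layout()] it was generated on.
#' @return A one-row tibble of trial metrics (as [compute_trial_metrics()],
#'   with `time_to_first_target` taken from the first fixation centroid
#'   inside a target polygon).
#' @export
ground_truth_metrics <- function(scanpath, layout) {
  fx <- scanpath$fixations
  tgt <- match_aoi(fx$az_deg, fx$el_deg, layout, kind = "target")
  first <- which(!is.na(tgt))
  ttft <- if (length(first)) fx$onset_s[first[1]] else NA_real_
  m <- compute_trial_metrics(list(fixations = fx, saccades = scanpath$saccades),
                             layout)
  m$time_to_first_target <- ttft
  m
}
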