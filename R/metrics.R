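#' Collapse consecutive repeats in an AOI sequence
#'
#' Transition-based measures exclude self-transitions, so runs of
#' consecutive fixations on the same AOI count as a single visit.
#' Unlabelled fixations (`NA`) are dropped before collapsing.
#'
#' @param aoi Character vector of AOI labels, in fixation order.
#' @return Character vector with consecutive duplicates collapsed.
#' @export
collapse_aoi_runs <- function(aoi) {
  aoi <- aoi[!is.na(aoi)]
  if (length(aoi) == 0) return(character(0))
  aoi[c(TRUE, aoi[-1] != aoi[-length(aoi)])]
}

#' AOI transition matrix
#'
#' Counts first-order transitions between distinct AOIs in a fixation
#' sequence (consecutive repeats collapsed first, so the diagonal is zero)
#' and derives the marginal source distribution `p_i` (row totals over
#' total transitions) and the conditional distribution `p_cond` (`p(j|i)`,
#' rows summing to 1 where defined).
#'
#' @param aoi Character vector of AOI labels in fixation order; `NA`s are
#'   dropped.
#' @param alphabet Optional character vector fixing the AOI alphabet (e.g.
#'   a layout's segment ids); labels outside it are dropped.
#' @return A list with `counts` (n x n matrix, zero diagonal), `p_i`
#'   (named numeric), `p_cond` (n x n matrix), `n_transitions`.
#' @export
transition_matrix <- function(aoi, alphabet = NULL) {
  seq <- collapse_aoi_runs(aoi)
  if (!is.null(alphabet)) seq <- seq[seq %in% alphabet]
  ids <- if (is.null(alphabet)) sort(unique(seq)) else alphabet
  n <- length(ids)
  counts <- matrix(0, n, n, dimnames = list(from = ids, to = ids))
  if (length(seq) >= 2) {
    from <- seq[-length(seq)]
    to <- seq[-1]
    keep <- from != to  # guaranteed by collapsing, kept as a guard
    for (k in which(keep)) counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
  }
  total <- sum(counts)
  row_tot <- rowSums(counts)
  p_i <- if (total > 0) row_tot / total else rep(0, n)
  p_cond <- counts
  nz <- row_tot > 0
  p_cond[nz, ] <- counts[nz, , drop = FALSE] / row_tot[nz]
  list(counts = counts, p_i = stats::setNames(as.numeric(p_i), ids),
       p_cond = p_cond, n_transitions = total)
}

#' Gaze transition entropy
#'
#' Shannon conditional entropy of AOI-to-AOI fixation transitions, in
#' bits:
#' \deqn{H = -\sum_i p(i) \sum_{j \ne i} p(j\mid i)\, \log_2 p(j\mid i)}
#' with `p(i)` the marginal source distribution of observed transitions
#' and the convention `0 log 0 = 0`. Low entropy indicates a structured,
#' predictable scan (each AOI has few likely successors); the maximum for
#' an alphabet of `n` AOIs with self-transitions excluded is
#' `log2(n - 1)`. Returns 0 when there are fewer than 2 transitions.
#'
#' @param aoi Character vector of AOI labels in fixation order (consecutive
#'   repeats are collapsed internally; `NA`s dropped), or a square
#'   transition-count matrix with zero diagonal.
#' @param alphabet Optional fixed AOI alphabet (see [transition_matrix()]).
#' @return Entropy in bits (scalar, >= 0).
#' @examples
#' transition_entropy(rep(c("1", "2", "3"), 5))  # deterministic cycle: 0 bits
#' @export
transition_entropy <- function(aoi, alphabet = NULL) {
  if (is.matrix(aoi)) {
    counts <- aoi
    stopifnot(nrow(counts) == ncol(counts), all(diag(counts) == 0),
              all(counts >= 0))
    total <- sum(counts)
    if (total < 2) return(0)
    row_tot <- rowSums(counts)
    p_i <- row_tot / total
    p_cond <- counts
    nz <- row_tot > 0
    p_cond[nz, ] <- counts[nz, , drop = FALSE] / row_tot[nz]
    tm <- list(p_i = p_i, p_cond = p_cond, n_transitions = total)
  } else {
    tm <- transition_matrix(aoi, alphabet = alphabet)
  }
  if (tm$n_transitions < 2) return(0)
  plogp <- tm$p_cond * log2(tm$p_cond)
  plogp[!is.finite(plogp)] <- 0
  -sum(tm$p_i * rowSums(plogp))
}

#' Saccadic angle
#'
#' Direction of a saccade from its horizontal and vertical displacement
#' components, as a full-quadrant angle (atan2 semantics) wrapped to
#' `(-180, 180]` degrees: 0 is rightward, +90 upward, 180 leftward.
#'
#' @param r_x,r_y Displacement components in degrees (vectorised).
#' @return Angle(s) in degrees in `(-180, 180]`.
#' @examples
#' saccadic_angle(1, 0)   # 0: rightward
#' saccadic_angle(-1, 0)  # 180: leftward
#' @export
saccadic_angle <- function(r_x, r_y) {
  if (any(r_x == 0 & r_y == 0)) {
    stop("saccadic angle undefined for zero displacement", call. = FALSE)
  }
  wrap_angle(atan2(r_y, r_x) * 180 / pi)
}

# wrap any angle in degrees to (-180, 180]
wrap_angle <- function(theta) {
  w <- theta - 360 * floor(theta / 360)  # [0, 360)
  ifelse(w > 180, w - 360, w)
}

#' Intersaccadic angles
#'
#' The change in direction between successive saccades: element `i` is
#' `theta[i+1] - theta[i]` wrapped to `(-180, 180]` degrees, so a pair of
#' saccades at 170 and -170 degrees yields a 20-degree turn, not 340.
#'
#' @param theta_deg Numeric vector of saccadic angles in degrees (any
#'   representation; wrapping is applied), or a saccade tibble with a
#'   `theta_deg` column.
#' @return Numeric vector of length `length(theta_deg) - 1` (empty when
#'   fewer than 2 saccades).
#' @export
intersaccadic_angles <- function(theta_deg) {
  if (is.data.frame(theta_deg)) theta_deg <- theta_deg$theta_deg
  if (length(theta_deg) < 2) return(numeric(0))
  wrap_angle(diff(theta_deg))
}

#' Fraction of antipersistent saccades
#'
#' Classifies each intersaccadic angle as persistent (the saccade continues
#' within 90 degrees of the previous direction, boundary inclusive) or
#' antipersistent (it doubles back by more than 90 degrees), and returns
#' the antipersistent percentage. High values indicate a search that keeps
#' reversing on itself; trained, systematic sweeps produce low values.
#'
#' @param theta_d Numeric vector of intersaccadic angles, degrees.
#' @return Percentage in `[0, 100]`, or `NA` for an empty input.
#' @export
antipersistent_fraction <- function(theta_d) {
  if (length(theta_d) == 0) return(NA_real_)
  100 * mean(abs(wrap_angle(theta_d)) > 90)
}

#' Time to fixate the first target
#'
#' Latency from room entry to the first gaze sample inside any target
#' polygon. Operates on the raw sample stream (the gaze vector, not
#' detected fixations), matching how a VR environment logs target
#' acquisition.
#'
#' @param recording A [gaze_recording()] (valid samples are used).
#' @param layout An [aoi_layout()] with at least one target AOI.
#' @param entry_time Trial start reference, seconds; must lie within the
#'   recording span.
#' @return Latency in seconds, or `NA` if gaze never enters a target.
#' @export
time_to_first_target <- function(recording, layout, entry_time = 0) {
  recording <- tibble::as_tibble(recording)
  if (nrow(recording) == 0) stop("empty recording", call. = FALSE)
  span <- range(recording$t_s)
  if (entry_time < span[1] || entry_time > span[2]) {
    stop("entry_time outside the recording span", call. = FALSE)
  }
  sub <- recording[recording$t_s >= entry_time & recording$valid, ,
                   drop = FALSE]
  if (nrow(sub) == 0) return(NA_real_)
  hit <- match_aoi(sub$az_deg, sub$el_deg, layout, kind = "target")
  first <- which(!is.na(hit))
  if (length(first) == 0) return(NA_real_)
  sub$t_s[first[1]] - entry_time
}

#' Search-order compliance
#'
#' Room-clearance doctrine trains a search that starts at the near corners
#' (the wall segments just inside the door) and proceeds systematically
#' around the room, reaching the back wall later. A trial is compliant
#' when the earliest fixation on any `near_corner` AOI precedes the
#' earliest fixation on any `back_wall` AOI; a trial that fixates the back
#' wall first is non-compliant. Trials with near-corner fixations but no
#' back-wall fixation count as compliant; trials fixating neither count as
#' non-compliant. Set `invert = TRUE` to score the opposite reading
#' (back wall first = criterion met).
#'
#' @param aoi Character vector of fixation AOI labels in time order.
#' @param layout An [aoi_layout()] with `near_corner` and `back_wall` role
#'   tags.
#' @param invert Flip the compliance direction.
#' @return Logical scalar.
#' @export
search_order_met <- function(aoi, layout, invert = FALSE) {
  nc <- role_ids(layout, "near_corner")
  bw <- role_ids(layout, "back_wall")
  if (length(nc) == 0 || length(bw) == 0) {
    stop("layout must tag near_corner and back_wall roles", call. = FALSE)
  }
  first_nc <- match(TRUE, aoi %in% nc)
  first_bw <- match(TRUE, aoi %in% bw)
  met <- if (is.na(first_nc)) {
    FALSE
  } else if (is.na(first_bw)) {
    TRUE
  } else {
    first_nc < first_bw
  }
  if (invert) !met else met
}

#' Per-trial scanpath metric battery
#'
#' Assembles all eye-movement measures for one trial from its detected
#' events: mean fixation duration, fixation count, search rate (fixations
#' divided by their average duration), gaze transition entropy over the
#' segment alphabet, percentage of antipersistent saccades, time to fixate
#' the first target, and search-order compliance. Pre-computed per-trial
#' performance outcomes supplied in `meta` (e.g. `failures_to_inhibit`,
#' `time_to_shoot_all`, `prop_hostiles_cleared`) pass through unchanged.
#'
#' @param events A list with `fixations` and `saccades` tibbles, as from
#'   [detect_events()]. Fixations must carry `aoi_id` (see
#'   [assign_aois()]).
#' @param layout An [aoi_layout()].
#' @param recording Optional [gaze_recording()] for [time_to_first_target()].
#' @param meta Named list of trial metadata; entries named in
#'   `passthrough` are copied to the output.
#' @param entry_time Room-entry reference time, seconds.
#' @param entropy_alphabet `"segments"` (default) restricts the entropy
#'   alphabet to the ordered wall segments; `"all"` includes target AOIs.
#' @param passthrough Names of `meta` fields copied into the result.
#' @return A one-row tibble of trial metrics.
#' @export
compute_trial_metrics <- function(events, layout, recording = NULL,
                                  meta = list(), entry_time = 0,
                                  entropy_alphabet = c("segments", "all"),
                                  passthrough = c("failures_to_inhibit",
                                                  "time_to_shoot_all",
                                                  "prop_hostiles_cleared")) {
  entropy_alphabet <- match.arg(entropy_alphabet)
  fix <- events$fixations
  sac <- events$saccades
  n_fix <- nrow(fix)
  mean_dur <- if (n_fix > 0) mean(fix$duration_s) else NA_real_
  search_rate <- if (n_fix > 0) n_fix / mean_dur else NA_real_
  alphabet <- if (entropy_alphabet == "segments") layout$aoi_ids else NULL
  theta_d <- intersaccadic_angles(sac)
  ttft <- if (!is.null(recording)) {
    time_to_first_target(recording, layout, entry_time)
  } else {
    NA_real_
  }
  out <- tibble::tibble(
    n_fixations = n_fix,
    mean_fixation_duration = mean_dur,
    search_rate = search_rate,
    entropy = transition_entropy(fix$aoi_id, alphabet = alphabet),
    pct_antipersistent = antipersistent_fraction(theta_d),
    time_to_first_target = ttft,
    search_order_met = search_order_met(fix$aoi_id, layout)
  )
  for (nm in intersect(passthrough, names(meta))) out[[nm]] <- meta[[nm]]
  out
}

#' Aggregate trial metrics to participant-phase cells
#'
#' Averages the per-trial metric battery within each participant and
#' phase, producing the table the group-level statistics consume. Numeric
#' metrics are aggregated as arithmetic means over non-missing trials;
#' `search_order_met` becomes the percentage of trials in which the
#' criterion was met.
#'
#' @param trials A tibble of per-trial metrics carrying grouping columns
#'   (by default `participant`, `group`, `pool`, `phase`) plus metric
#'   columns.
#' @param by Character vector of grouping columns present in `trials`.
#' @return A tibble with one row per grouping cell and one column per
#'   metric (`search_order_met` renamed `pct_search_order_met`).
#' @export
aggregate_participant <- function(trials,
                                  by = c("participant", "group", "pool",
                                         "phase")) {
  trials <- tibble::as_tibble(trials)
  by <- intersect(by, names(trials))
  if (length(by) == 0) stop("no grouping columns found", call. = FALSE)
  if ("search_order_met" %in% names(trials)) {
    trials$pct_search_order_met <- 100 * as.numeric(trials$search_order_met)
    trials$search_order_met <- NULL
  }
  metric_cols <- setdiff(names(trials)[vapply(trials, is.numeric, logical(1))],
                         by)
  trials |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(metric_cols),
                                   ~ mean(.x[!is.na(.x)])),
                     .groups = "drop") |>
    dplyr::mutate(dplyr::across(dplyr::all_of(metric_cols),
                                ~ ifelse(is.nan(.x), NA_real_, .x)))
}
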