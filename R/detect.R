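#' Gaze acceleration magnitude
#'
#' Second derivative of the 2D gaze position via central differences,
#' returned as the Euclidean magnitude over the two angular channels, in
#' deg/s^2. End samples are copied from their nearest interior neighbour.
#'
#' @param az,el Numeric position vectors, degrees (normally the 50 Hz
#'   saccade stream).
#' @param rate Sampling rate, Hz.
#' @return Numeric vector of acceleration magnitudes, same length.
#' @export
compute_acceleration <- function(az, el, rate) {
  n <- length(az)
  if (n < 5) stop("need at least 5 samples to compute acceleration",
                  call. = FALSE)
  d2 <- function(x) {
    a <- rep(NA_real_, n)
    a[2:(n - 1)] <- (x[3:n] - 2 * x[2:(n - 1)] + x[1:(n - 2)]) * rate^2
    a[1] <- a[2]; a[n] <- a[n - 1]
    a
  }
  sqrt(d2(az)^2 + d2(el)^2)
}

# indices of local maxima of a series (boundaries count when they dominate
# their single neighbour); plateaus yield their first index
local_maxima <- function(a) {
  n <- length(a)
  if (n < 2) return(seq_len(n))
  left <- c(-Inf, a[-n])
  right <- c(a[-1], -Inf)
  which(a >= left & a >= right & (a > left | a > right))
}

#' Detect fixations by spatial dispersion (I-DT)
#'
#' Groups successive gaze samples into fixation clusters: maximal
#' contiguous runs whose spatial dispersion stays within
#' `dispersion_deg` and whose duration reaches `min_dur_s`. Dispersion is
#' measured as the spatial extent `(max - min azimuth) + (max - min
#' elevation)` over the window, the convention of dispersion-threshold
#' (I-DT) identification. The window grows greedily from the earliest
#' admissible start until dispersion would be exceeded.
#'
#' @param streams A preprocessed stream tibble from [preprocess_gaze()]
#'   (the 30 Hz `az_fix`/`el_fix` channels are used), or any tibble with
#'   columns `t_s`, `az_fix`, `el_fix` and optionally `segment`.
#' @param dispersion_deg Maximum spatial dispersion of a fixation, degrees.
#' @param min_dur_s Minimum fixation duration, seconds.
#' @param merge_gap_s Post-pass cluster merging: consecutive fixations
#'   separated by no more than this gap *and* whose centroids lie within
#'   `dispersion_deg` of each other are rejoined (a noise spike can
#'   transiently break the dispersion budget of one true fixation). The
#'   default is below the minimum fixation duration, so merging can never
#'   bridge a genuine intervening fixation; a genuine saccade moves the
#'   centroid beyond the dispersion threshold and is never merged across.
#'   Set 0 to disable.
#' @return A tibble of fixation events: `onset_s`, `offset_s`,
#'   `duration_s`, `az_deg`, `el_deg` (centroid), ordered and
#'   non-overlapping. Empty input gives an empty tibble.
#' @export
detect_fixations <- function(streams, dispersion_deg = 1.0, min_dur_s = 0.1,
                             merge_gap_s = 0.075) {
  stopifnot(dispersion_deg > 0, min_dur_s > 0)
  streams <- tibble::as_tibble(streams)
  empty <- tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          duration_s = numeric(), az_deg = numeric(),
                          el_deg = numeric())
  if (nrow(streams) == 0) return(empty)
  seg <- if ("segment" %in% names(streams)) streams$segment else
    rep(1L, nrow(streams))
  out <- purrr::map_dfr(unique(stats::na.omit(seg)), function(s) {
    idx <- which(!is.na(seg) & seg == s)
    fx <- idt_fixations(streams$t_s[idx], streams$az_fix[idx],
                        streams$el_fix[idx], dispersion_deg, min_dur_s)
    merge_close_fixations(fx, merge_gap_s, dispersion_deg)
  })
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$onset_s)
}

# rejoin fixation fragments separated by a short gap and a small centroid
# displacement (duration-weighted centroid for the merged event)
merge_close_fixations <- function(fx, merge_gap_s, max_dist_deg) {
  if (is.null(fx) || nrow(fx) < 2 || merge_gap_s <= 0) return(fx)
  out <- list()
  cur <- fx[1, ]
  for (i in 2:nrow(fx)) {
    nxt <- fx[i, ]
    gap <- nxt$onset_s - cur$offset_s
    dist <- sqrt((nxt$az_deg - cur$az_deg)^2 + (nxt$el_deg - cur$el_deg)^2)
    if (gap <= merge_gap_s && dist <= max_dist_deg) {
      w <- c(cur$duration_s, nxt$duration_s)
      cur$az_deg <- stats::weighted.mean(c(cur$az_deg, nxt$az_deg), w)
      cur$el_deg <- stats::weighted.mean(c(cur$el_deg, nxt$el_deg), w)
      cur$offset_s <- nxt$offset_s
      cur$duration_s <- cur$offset_s - cur$onset_s
    } else {
      out[[length(out) + 1]] <- cur
      cur <- nxt
    }
  }
  out[[length(out) + 1]] <- cur
  dplyr::bind_rows(out)
}

# Greedy dispersion-threshold pass over one contiguous segment.
# Event boundaries sit at the midpoints between samples (each sample
# represents one sample period of dwell), so a run of m samples has
# duration m / rate; this is the unbiased estimate of the underlying
# interval given uniform sampling phase. Boundaries are clamped to the
# segment span.
idt_fixations <- function(t, az, el, dispersion_deg, min_dur_s) {
  n <- length(t)
  if (n < 2) return(NULL)
  eps <- 1e-9  # guard against t-grid floating-point error in span checks
  dt <- stats::median(diff(t))
  # first index whose run from each start reaches min_dur_s of dwell
  j_min <- findInterval(t + (min_dur_s - dt - eps), t, left.open = TRUE) + 1L
  res <- list()
  i <- 1L
  while (i <= n) {
    j <- j_min[i]
    if (j > n) break
    win_az <- range(az[i:j]); win_el <- range(el[i:j])
    disp <- (win_az[2] - win_az[1]) + (win_el[2] - win_el[1])
    if (disp <= dispersion_deg) {
      while (j < n) {
        na <- c(min(win_az[1], az[j + 1]), max(win_az[2], az[j + 1]))
        ne <- c(min(win_el[1], el[j + 1]), max(win_el[2], el[j + 1]))
        if ((na[2] - na[1]) + (ne[2] - ne[1]) > dispersion_deg) break
        j <- j + 1L; win_az <- na; win_el <- ne
      }
      on <- max(t[1], t[i] - dt / 2)
      off <- min(t[n], t[j] + dt / 2)
      res[[length(res) + 1]] <- tibble::tibble(
        onset_s = on, offset_s = off, duration_s = off - on,
        az_deg = mean(az[i:j]), el_deg = mean(el[i:j])
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  dplyr::bind_rows(res)
}

#' Detect saccades by adaptive acceleration threshold
#'
#' Flags candidate saccades wherever the gaze acceleration magnitude
#' exceeds `k` times the trial's median absolute acceleration, then refines
#' each candidate's onset to the last acceleration maximum at or before the
#' threshold crossing and its offset to the first acceleration maximum at
#' or after the recrossing. Refined intervals that overlap (e.g. the two
#' suprathreshold lobes flanking a saccade's mid-flight acceleration zero)
#' are merged into one event. Displacement components and the saccadic
#' angle are computed between the refined boundary samples.
#'
#' @param streams A preprocessed stream tibble from [preprocess_gaze()]
#'   (the 50 Hz `az_sac`/`el_sac` channels are used).
#' @param rate Sampling rate, Hz; taken from the stream attribute when
#'   `NULL`.
#' @param k Threshold multiplier on the median absolute acceleration.
#' @param min_displacement_deg Events with total displacement below this
#'   are dropped as numerically degenerate (the angle is unstable at zero
#'   displacement).
#' @param min_gap_s Refined events separated by less than this are merged:
#'   two genuine saccades must be separated by at least a minimum-duration
#'   fixation, so shorter gaps can only be fragments of one movement
#'   (e.g. the two suprathreshold lobes flanking a saccade's mid-flight
#'   acceleration zero when noise breaks the run).
#' @param min_threshold Absolute floor on the acceleration threshold, in
#'   deg/s^2. The adaptive rule scales with the trial's noise level; on a
#'   nearly noiseless signal the median absolute acceleration collapses to
#'   numerical precision and would flag filter ripple. Any genuine saccade
#'   peaks orders of magnitude above this floor.
#' @return A tibble of saccade events: `onset_s`, `offset_s`,
#'   `duration_s`, `r_x`, `r_y` (displacement, degrees), `theta_deg`
#'   (direction in (-180, 180]).
#' @export
detect_saccades <- function(streams, rate = NULL, k = 5.0,
                            min_displacement_deg = 0.1, min_gap_s = 0.05,
                            min_threshold = 50) {
  stopifnot(k > 0)
  streams <- tibble::as_tibble(streams)
  if (is.null(rate)) rate <- gaze_rate(streams)
  if (nrow(streams) < 5) stop("trial too short for saccade detection",
                              call. = FALSE)
  seg <- if ("segment" %in% names(streams)) streams$segment else
    rep(1L, nrow(streams))
  segs <- unique(stats::na.omit(seg))
  acc <- rep(NA_real_, nrow(streams))
  for (s in segs) {
    idx <- which(!is.na(seg) & seg == s)
    if (length(idx) >= 5) {
      acc[idx] <- compute_acceleration(streams$az_sac[idx],
                                       streams$el_sac[idx], rate)
    }
  }
  threshold <- max(k * stats::median(acc, na.rm = TRUE), min_threshold)
  empty <- tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                          duration_s = numeric(), r_x = numeric(),
                          r_y = numeric(), theta_deg = numeric())
  if (!is.finite(threshold)) return(empty)
  out <- purrr::map_dfr(segs, function(s) {
    idx <- which(!is.na(seg) & seg == s)
    if (length(idx) < 5) return(NULL)
    saccades_one_segment(streams$t_s[idx], streams$az_sac[idx],
                         streams$el_sac[idx], acc[idx], threshold,
                         min_displacement_deg, min_gap_s)
  })
  if (nrow(out) == 0) empty else dplyr::arrange(out, .data$onset_s)
}

saccades_one_segment <- function(t, az, el, a, threshold,
                                 min_displacement_deg, min_gap_s = 0.05) {
  above <- a > threshold
  if (!any(above)) return(NULL)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  r0 <- starts[runs$values]
  r1 <- ends[runs$values]
  # refinement extrema must themselves reach the threshold (sub-threshold
  # ripple maxima are not movement boundaries) and must lie within a few
  # samples of the crossing: the boundary extremum of a saccade's
  # acceleration profile sits at the edge of the suprathreshold run, never
  # beyond the adjacent fixation
  dt <- stats::median(diff(t))
  w <- max(1L, as.integer(round(0.05 / dt)))
  peaks <- local_maxima(a)
  peaks <- peaks[a[peaks] >= threshold]
  onset <- vapply(r0, function(i) {
    p <- peaks[peaks <= i & peaks >= i - w]
    as.integer(if (length(p)) max(p) else i)
  }, integer(1))
  offset <- vapply(r1, function(i) {
    p <- peaks[peaks >= i & peaks <= i + w]
    as.integer(if (length(p)) min(p) else i)
  }, integer(1))
  # merge refined intervals that overlap or sit closer than the shortest
  # possible intervening fixation
  merged <- list()
  cur_on <- onset[1]; cur_off <- offset[1]
  if (length(onset) > 1) {
    for (q in 2:length(onset)) {
      if (onset[q] <= cur_off || t[onset[q]] - t[cur_off] < min_gap_s) {
        cur_off <- max(cur_off, offset[q])
      } else {
        merged[[length(merged) + 1]] <- c(cur_on, cur_off)
        cur_on <- onset[q]; cur_off <- offset[q]
      }
    }
  }
  merged[[length(merged) + 1]] <- c(cur_on, cur_off)
  purrr::map_dfr(merged, function(m) {
    i0 <- m[1]; i1 <- m[2]
    if (i1 <= i0) return(NULL)
    rx <- az[i1] - az[i0]
    ry <- el[i1] - el[i0]
    if (sqrt(rx^2 + ry^2) < min_displacement_deg) return(NULL)
    tibble::tibble(onset_s = t[i0], offset_s = t[i1],
                   duration_s = t[i1] - t[i0], r_x = rx, r_y = ry,
                   theta_deg = saccadic_angle(rx, ry))
  })
}

#' Reconcile fixation and saccade streams
#'
#' The fixation and saccade detectors run on differently filtered streams
#' and can disagree at the margins. This optional step truncates fixations
#' at the boundaries of detected saccades (splitting a fixation that spans
#' a saccade) and re-applies the minimum-duration criterion to the
#' fragments; sub-threshold fragments are dropped.
#'
#' @param fixations,saccades Event tibbles from [detect_fixations()] and
#'   [detect_saccades()], each time-ordered.
#' @param min_dur_s Minimum fixation duration re-applied after truncation.
#' @return A list with elements `fixations` and `saccades` (saccades pass
#'   through unchanged).
#' @export
reconcile_events <- function(fixations, saccades, min_dur_s = 0.1) {
  fixations <- tibble::as_tibble(fixations)
  saccades <- tibble::as_tibble(saccades)
  if (nrow(fixations) == 0 || nrow(saccades) == 0) {
    return(list(fixations = fixations, saccades = saccades))
  }
  pieces <- purrr::pmap_dfr(fixations, function(onset_s, offset_s, ...) {
    extra <- list(...)
    cuts <- saccades[saccades$offset_s > onset_s &
                       saccades$onset_s < offset_s, , drop = FALSE]
    if (nrow(cuts) == 0) {
      return(tibble::tibble(onset_s = onset_s, offset_s = offset_s, !!!extra))
    }
    bounds_lo <- c(onset_s, pmin(cuts$offset_s, offset_s))
    bounds_hi <- c(pmax(cuts$onset_s, onset_s), offset_s)
    keep <- bounds_hi > bounds_lo
    tibble::tibble(onset_s = bounds_lo[keep], offset_s = bounds_hi[keep],
                   !!!extra)
  })
  pieces$duration_s <- pieces$offset_s - pieces$onset_s
  pieces <- pieces[pieces$duration_s >= min_dur_s, , drop = FALSE]
  list(fixations = dplyr::arrange(pieces, .data$onset_s),
       saccades = saccades)
}

#' Detect all oculomotor events in a recording
#'
#' Convenience wrapper running the full chain: [preprocess_gaze()],
#' [detect_fixations()] on the 30 Hz stream, [detect_saccades()] on the
#' 50 Hz stream, optional [reconcile_events()], and AOI labelling of
#' fixation centroids when a layout is supplied.
#'
#' @param recording A [gaze_recording()].
#' @param layout Optional [aoi_layout()] for fixation labelling.
#' @param config A [pipeline_config()]; individual parameters can also be
#'   overridden directly.
#' @param reconcile Truncate fixations at saccade boundaries (off by
#'   default: the detectors run on separate streams, as is conventional).
#' @return A list with tibbles `fixations` and `saccades`.
#' @export
detect_events <- function(recording, layout = NULL,
                          config = pipeline_config(), reconcile = FALSE) {
  streams <- preprocess_gaze(recording,
                             cutoff_fix_hz = config$cutoff_fix_hz,
                             cutoff_sac_hz = config$cutoff_sac_hz,
                             max_interp = config$max_interp_s)
  fix <- detect_fixations(streams, dispersion_deg = config$dispersion_deg,
                          min_dur_s = config$min_fix_dur_s)
  sac <- if (nrow(streams) >= 5) {
    detect_saccades(streams, rate = gaze_rate(recording), k = config$accel_k)
  } else {
    tibble::tibble(onset_s = numeric(), offset_s = numeric(),
                   duration_s = numeric(), r_x = numeric(), r_y = numeric(),
                   theta_deg = numeric())
  }
  if (reconcile) {
    rec <- reconcile_events(fix, sac, min_dur_s = config$min_fix_dur_s)
    fix <- rec$fixations; sac <- rec$saccades
  }
  if (!is.null(layout)) fix <- assign_aois(fix, layout)
  list(fixations = fix, saccades = sac)
}
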