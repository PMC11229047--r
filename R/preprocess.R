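#' Three-frame median filter
#'
#' Replaces each interior sample by the median of itself and its two
#' neighbours; the first and last samples pass through unchanged. This is
#' the standard despiking step applied to gaze direction signals before
#' low-pass smoothing: it removes single-sample tracker glitches while
#' leaving monotone ramps untouched.
#'
#' @param x Numeric vector (degrees), length >= 3. `NA`s propagate locally.
#' @return Numeric vector of the same length.
#' @examples
#' median_filter3(c(1, 100, 1))  # spike removed
#' @export
median_filter3 <- function(x) {
  n <- length(x)
  if (n < 3) stop("median_filter3 needs at least 3 samples", call. = FALSE)
  out <- x
  trip <- cbind(x[1:(n - 2)], x[2:(n - 1)], x[3:n])
  out[2:(n - 1)] <- apply(trip, 1, stats::median)
  out
}

#' Zero-phase second-order Butterworth low-pass filter
#'
#' Applies a second-order Butterworth low-pass design forward and backward
#' (filtfilt), giving zero phase shift and an effective magnitude response
#' equal to the squared magnitude of the one-pass filter. The signal is
#' extended by reflection (odd-symmetric about the end points) before
#' filtering to suppress edge transients; the extension is at least three
#' filter time-constants long.
#'
#' @param x Numeric vector, the signal (degrees).
#' @param rate Sampling rate in Hz.
#' @param cutoff Low-pass cut-off frequency in Hz; must be below the
#'   Nyquist frequency `rate / 2`.
#' @return Filtered numeric vector, same length as `x`.
#' @seealso [butterworth_response()] for the analytic magnitude response.
#' @export
butterworth_zero_lag <- function(x, rate, cutoff) {
  if (!(cutoff > 0 && cutoff < rate / 2)) {
    stop("invalid cutoff: must satisfy 0 < cutoff < rate/2 (Nyquist)",
         call. = FALSE)
  }
  n <- length(x)
  if (n < 2) return(x)
  bf <- signal::butter(2, cutoff / (rate / 2), type = "low")
  # remove the DC level so the filter's zero initial state sees a near-zero
  # signal (the start-up transient scales with the absolute level), then pad
  # by odd reflection over >= 3 time-constants of the cut-off
  dc <- x[1]
  xc <- x - dc
  pad <- min(n - 1, max(24L, ceiling(3 * rate / cutoff)))
  head_ext <- 2 * xc[1] - xc[(pad + 1):2]
  tail_ext <- 2 * xc[n] - xc[(n - 1):(n - pad)]
  xp <- c(head_ext, xc, tail_ext)
  yp <- signal::filter(bf, xp)
  yp <- rev(as.numeric(signal::filter(bf, rev(as.numeric(yp)))))
  yp[(pad + 1):(pad + n)] + dc
}

#' Analytic magnitude response of the zero-phase Butterworth filter
#'
#' Returns the theoretical amplitude gain of [butterworth_zero_lag()] at
#' given frequencies: the squared magnitude (two passes) of the discrete
#' second-order Butterworth low-pass obtained by bilinear transform with
#' frequency prewarping at the cut-off,
#' \deqn{|H(f)|^2 = \left[1 + \left(\frac{\tan(\pi f / r)}{\tan(\pi f_c / r)}\right)^4\right]^{-1}.}
#'
#' @param f Frequencies (Hz) at which to evaluate the response.
#' @param rate Sampling rate, Hz.
#' @param cutoff Cut-off frequency, Hz.
#' @return Numeric vector of amplitude gains in `[0, 1]`.
#' @export
butterworth_response <- function(f, rate, cutoff) {
  v <- tan(pi * f / rate) / tan(pi * cutoff / rate)
  1 / (1 + v^4)
}

#' Interpolate short gaps and segment a recording at long ones
#'
#' Invalid runs (blinks, tracking loss) no longer than `max_interp` seconds
#' are filled by linear interpolation of azimuth and elevation; longer runs
#' split the trace into independent segments so that filtering and event
#' detection never fabricate data across a blink. The default limit of
#' 0.075 s is deliberately shorter than the 0.1 s minimum fixation
#' duration, so interpolation alone can never create a fixation.
#'
#' @param recording A gaze recording tibble (see [gaze_recording()]).
#' @param max_interp Longest invalid run to interpolate, seconds.
#' @return The recording with columns `az_deg`/`el_deg` interpolated where
#'   possible, a logical `interpolated` column, and an integer `segment`
#'   column numbering the contiguous valid stretches (gap samples that were
#'   not interpolated keep `segment = NA`).
#' @export
handle_gaps <- function(recording, max_interp = 0.075) {
  recording <- tibble::as_tibble(recording)
  n <- nrow(recording)
  if (n == 0) {
    recording$interpolated <- logical(0)
    recording$segment <- integer(0)
    return(recording)
  }
  valid <- recording$valid
  interpolated <- rep(FALSE, n)
  runs <- rle(!valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  for (k in seq_along(runs$lengths)) {
    if (!runs$values[k]) next
    i0 <- starts[k]; i1 <- ends[k]
    dur <- recording$t_s[min(i1 + 1, n)] - recording$t_s[max(i0 - 1, 1)]
    # only interior gaps bounded by valid samples can be interpolated
    if (i0 > 1 && i1 < n && dur <= max_interp) {
      idx <- i0:i1
      for (col in c("az_deg", "el_deg")) {
        recording[[col]][idx] <- stats::approx(
          x = recording$t_s[c(i0 - 1, i1 + 1)],
          y = recording[[col]][c(i0 - 1, i1 + 1)],
          xout = recording$t_s[idx]
        )$y
      }
      interpolated[idx] <- TRUE
    }
  }
  usable <- valid | interpolated
  seg <- cumsum(usable & !dplyr::lag(usable, default = FALSE))
  recording$interpolated <- interpolated
  recording$segment <- ifelse(usable, seg, NA_integer_)
  recording
}

#' Build the filtered streams for event detection
#'
#' Runs the full preprocessing chain on a gaze recording: short gaps are
#' interpolated and long gaps split the trace ([handle_gaps()]); each
#' usable segment is despiked with a three-frame median filter and then
#' smoothed with a zero-phase second-order Butterworth low-pass, once with
#' a 30 Hz cut-off (the fixation stream) and once with a 50 Hz cut-off
#' (the saccade stream). Both streams come from the same median-filtered
#' input and stay sample-aligned with it.
#'
#' @param recording A gaze recording tibble (see [gaze_recording()]).
#' @param cutoff_fix_hz Cut-off for the fixation-detection stream, Hz.
#' @param cutoff_sac_hz Cut-off for the saccade-detection stream, Hz.
#' @param max_interp Gap-interpolation limit, seconds.
#' @return A tibble sample-aligned with the input, columns `t_s`,
#'   `segment`, `az_fix`, `el_fix`, `az_sac`, `el_sac`. Samples inside
#'   non-interpolable gaps carry `NA` streams.
#' @export
preprocess_gaze <- function(recording,
                            cutoff_fix_hz = 30,
                            cutoff_sac_hz = 50,
                            max_interp = 0.075) {
  rate <- gaze_rate(recording)
  rec <- handle_gaps(recording, max_interp = max_interp)
  n <- nrow(rec)
  out <- tibble::tibble(
    t_s = rec$t_s,
    segment = rec$segment,
    az_fix = NA_real_, el_fix = NA_real_,
    az_sac = NA_real_, el_sac = NA_real_
  )
  if (n == 0) return(out)
  for (s in unique(stats::na.omit(rec$segment))) {
    idx <- which(!is.na(rec$segment) & rec$segment == s)
    az <- rec$az_deg[idx]
    el <- rec$el_deg[idx]
    if (length(idx) >= 3) {
      az <- median_filter3(az)
      el <- median_filter3(el)
    }
    if (length(idx) >= 2) {
      out$az_fix[idx] <- butterworth_zero_lag(az, rate, cutoff_fix_hz)
      out$el_fix[idx] <- butterworth_zero_lag(el, rate, cutoff_fix_hz)
      out$az_sac[idx] <- butterworth_zero_lag(az, rate, cutoff_sac_hz)
      out$el_sac[idx] <- butterworth_zero_lag(el, rate, cutoff_sac_hz)
    } else {
      out$az_fix[idx] <- az; out$el_fix[idx] <- el
      out$az_sac[idx] <- az; out$el_sac[idx] <- el
    }
  }
  attr(out, "rate") <- rate
  out
}
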