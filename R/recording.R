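#' Construct a gaze recording
#'
#' A gaze recording is a tibble of time-stamped angular gaze samples from a
#' head-mounted eye tracker, one trial per recording. Positions are 2D
#' angular coordinates on the unwrapped room-wall surface (azimuth,
#' elevation, degrees); time is seconds with t = 0 at room entry. The
#' nominal sampling rate (120 Hz for the target hardware) and trial
#' metadata travel as attributes.
#'
#' @param t_s Numeric, strictly increasing sample times in seconds.
#' @param az_deg,el_deg Numeric, gaze azimuth / elevation in degrees. Must
#'   be finite wherever `valid` is `TRUE`.
#' @param valid Logical, per-sample tracking validity (blinks and dropouts
#'   are `FALSE`).
#' @param rate Nominal sampling rate, Hz.
#' @param meta A named list of trial metadata (e.g. `participant`, `group`,
#'   `pool`, `phase`, `trial_id`, `room_config`, `entry_time`).
#' @return A tibble of class `gaze_recording` with columns `t_s`, `az_deg`,
#'   `el_deg`, `valid`.
#' @export
gaze_recording <- function(t_s, az_deg, el_deg,
                           valid = rep(TRUE, length(t_s)),
                           rate = 120, meta = list()) {
  stopifnot(length(az_deg) == length(t_s), length(el_deg) == length(t_s),
            length(valid) == length(t_s))
  if (length(t_s) > 1 && any(diff(t_s) <= 0)) {
    stop("sample times must be strictly increasing", call. = FALSE)
  }
  if (!(is.numeric(rate) && rate > 0)) {
    stop("sampling rate must be positive", call. = FALSE)
  }
  if (any(valid & !(is.finite(az_deg) & is.finite(el_deg)))) {
    stop("valid samples must have finite az/el", call. = FALSE)
  }
  out <- tibble::tibble(t_s = as.numeric(t_s), az_deg = as.numeric(az_deg),
                        el_deg = as.numeric(el_deg), valid = as.logical(valid))
  class(out) <- c("gaze_recording", class(out))
  attr(out, "rate") <- rate
  attr(out, "meta") <- meta
  out
}

#' Sampling rate of a recording or stream
#'
#' Returns the `rate` attribute if present, otherwise infers the rate from
#' the median sample interval.
#'
#' @param x A gaze recording or preprocessed stream tibble with a `t_s`
#'   column.
#' @return Sampling rate in Hz.
#' @export
gaze_rate <- function(x) {
  r <- attr(x, "rate")
  if (!is.null(r)) return(r)
  if (nrow(x) < 2) stop("cannot infer rate from < 2 samples", call. = FALSE)
  1 / stats::median(diff(x$t_s))
}

#' Trial metadata of a recording
#' @param x A gaze recording.
#' @return The named metadata list (possibly empty).
#' @export
gaze_meta <- function(x) {
  m <- attr(x, "meta")
  if (is.null(m)) list() else m
}
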