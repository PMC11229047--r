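#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis chain in one validated
#' object. The defaults are the standard values for 120 Hz head-mounted
#' eye tracking of room-clearance search: 30/50 Hz zero-phase Butterworth
#' cut-offs for the fixation/saccade streams, a 1 degree dispersion and
#' 100 ms minimum-duration fixation criterion, a 5x median-absolute
#' acceleration saccade threshold, an inclusive 90 degree persistence
#' boundary, and alpha = .05.
#'
#' @param sampling_rate Hz.
#' @param cutoff_fix_hz,cutoff_sac_hz Butterworth cut-offs, Hz (must be
#'   below Nyquist).
#' @param dispersion_deg Fixation dispersion threshold, degrees.
#' @param min_fix_dur_s Minimum fixation duration, seconds.
#' @param accel_k Saccade threshold multiplier.
#' @param persistence_boundary_deg Persistent/antipersistent boundary
#'   (inclusive), degrees.
#' @param max_interp_s Longest blink/dropout gap to interpolate, seconds.
#' @param alpha Significance level for the statistics stage.
#' @param seed Integer seed for any simulation steps.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sampling_rate = 120,
                            cutoff_fix_hz = 30,
                            cutoff_sac_hz = 50,
                            dispersion_deg = 1.0,
                            min_fix_dur_s = 0.1,
                            accel_k = 5.0,
                            persistence_boundary_deg = 90,
                            max_interp_s = 0.075,
                            alpha = 0.05,
                            seed = 1L) {
  vals <- c(sampling_rate, cutoff_fix_hz, cutoff_sac_hz, dispersion_deg,
            min_fix_dur_s, accel_k, persistence_boundary_deg, max_interp_s,
            alpha)
  if (any(vals <= 0)) stop("all thresholds must be positive", call. = FALSE)
  if (cutoff_fix_hz >= sampling_rate / 2 ||
      cutoff_sac_hz >= sampling_rate / 2) {
    stop("filter cut-offs must be below the Nyquist frequency ",
         sampling_rate / 2, " Hz", call. = FALSE)
  }
  structure(
    list(sampling_rate = sampling_rate, cutoff_fix_hz = cutoff_fix_hz,
         cutoff_sac_hz = cutoff_sac_hz, dispersion_deg = dispersion_deg,
         min_fix_dur_s = min_fix_dur_s, accel_k = accel_k,
         persistence_boundary_deg = persistence_boundary_deg,
         max_interp_s = max_interp_s, alpha = alpha, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

gaze_csv_columns <- c("t_s", "az_deg", "el_deg", "valid", "trial_id")

#' Read a gaze CSV file
#'
#' Reads the package's gaze CSV dialect (columns `t_s`, `az_deg`,
#' `el_deg`, `valid`, `trial_id`). Rows with non-finite positions are
#' flagged invalid rather than dropped, so the row count is preserved.
#'
#' @param path File path.
#' @param rate Nominal sampling rate stored on the recording, Hz.
#' @return A [gaze_recording()] (single trial), or a named list of
#'   recordings when the file holds several `trial_id`s.
#' @export
read_gaze_csv <- function(path, rate = 120) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(gaze_csv_columns, names(df))
  if (length(missing_cols) > 0) {
    stop("gaze CSV schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  make_rec <- function(sub, trial) {
    if (any(diff(sub$t_s) <= 0)) {
      stop("data error: non-monotone time stamps in trial ", trial,
           call. = FALSE)
    }
    bad <- !is.finite(sub$az_deg) | !is.finite(sub$el_deg)
    valid <- as.logical(sub$valid) & !bad
    az <- ifelse(is.finite(sub$az_deg), sub$az_deg, 0)
    el <- ifelse(is.finite(sub$el_deg), sub$el_deg, 0)
    gaze_recording(sub$t_s, az, el, valid, rate = rate,
                   meta = list(trial_id = trial))
  }
  trials <- unique(df$trial_id)
  recs <- purrr::map(rlang::set_names(as.character(trials)), function(tr) {
    make_rec(df[df$trial_id == tr, , drop = FALSE], tr)
  })
  if (length(recs) == 1) recs[[1]] else recs
}

#' Write a gaze recording to CSV
#'
#' @param recording A [gaze_recording()] (or named list of recordings, in
#'   which case trials are concatenated).
#' @param path Output file path.
#' @param trial_id Trial label; defaults to the recording's metadata.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(recording, path, trial_id = NULL) {
  as_rows <- function(rec, id) {
    tibble::tibble(t_s = rec$t_s, az_deg = rec$az_deg, el_deg = rec$el_deg,
                   valid = rec$valid, trial_id = id)
  }
  df <- if (inherits(recording, "gaze_recording")) {
    id <- trial_id %||% gaze_meta(recording)$trial_id %||% "trial1"
    as_rows(recording, id)
  } else {
    purrr::imap_dfr(recording, as_rows)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an AOI layout as JSON
#'
#' @param layout An [aoi_layout()].
#' @param path File path.
#' @return `path` (write) or an [aoi_layout()] (read).
#' @export
write_layout_json <- function(layout, path) {
  jsonlite::write_json(
    list(vertices = layout$vertices, roles = layout$roles,
         entry_point = layout$entry_point),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_layout_json
#' @export
read_layout_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  roles <- obj$roles
  if (length(roles) == 0) roles <- NULL
  aoi_layout(obj$vertices, roles = roles,
             entry_point = as.numeric(obj$entry_point))
}

#' Run the full analysis pipeline
#'
#' Executes the whole chain on a set of trial recordings: preprocessing,
#' event detection, AOI labelling, the per-trial metric battery,
#' participant-phase aggregation, and the group-by-time ANCOVA stage.
#' Each recording's metadata must identify `participant`, `group`, `pool`
#' and `phase`. Stage progress is logged with counts.
#'
#' @param recordings A list of [gaze_recording()]s (one per trial).
#' @param layout An [aoi_layout()].
#' @param config A [pipeline_config()].
#' @param dvs Metrics to analyse statistically; defaults to the core
#'   eye-movement battery.
#' @param covariate Covariate column for [mixed_anova()] (`NULL` to omit).
#' @param quiet Suppress stage logs.
#' @return A list: `trial_metrics` (tibble), `participants` (aggregated
#'   tibble), `report` (a `gaze_report`).
#' @export
run_pipeline <- function(recordings, layout, config = pipeline_config(),
                         dvs = c("mean_fixation_duration", "search_rate",
                                 "entropy", "pct_antipersistent"),
                         covariate = "pool", quiet = FALSE) {
  say <- function(...) if (!quiet) message(sprintf(...))
  say("pipeline: %d trial recordings", length(recordings))
  trial_metrics <- purrr::imap_dfr(recordings, function(rec, nm) {
    meta <- gaze_meta(rec)
    ev <- detect_events(rec, layout = layout, config = config)
    m <- compute_trial_metrics(ev, layout, recording = rec, meta = meta)
    dplyr::bind_cols(
      tibble::tibble(participant = meta$participant %||% nm,
                     group = meta$group %||% NA_character_,
                     pool = meta$pool %||% NA_character_,
                     phase = meta$phase %||% NA_character_,
                     trial = meta$trial_id %||% nm),
      m
    )
  })
  say("detected events: %d fixations, metrics for %d trials",
      sum(trial_metrics$n_fixations), nrow(trial_metrics))
  participants <- aggregate_participant(trial_metrics)
  participants$phase <- factor(participants$phase, levels = c("pre", "post"))
  say("aggregated: %d participant-phase cells", nrow(participants))
  report <- analyse_study(participants, dvs = intersect(dvs,
                                                        names(participants)),
                          covariate = covariate, alpha = config$alpha)
  say("statistics: %d metrics analysed", length(report))
  list(trial_metrics = trial_metrics, participants = participants,
       report = report)
}

#' Write a tidy long metrics CSV
#'
#' @param participants Aggregated participant-phase metric tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(participants, path) {
  long <- tidyr::pivot_longer(
    participants,
    cols = -dplyr::any_of(c("participant", "group", "pool", "phase")),
    names_to = "metric", values_to = "value"
  )
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a tidy long metrics CSV back into wide participant form
#'
#' @param path File path written by [write_metrics_csv()].
#' @return A `study_dataset` tibble.
#' @export
read_metrics_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  wide <- tidyr::pivot_wider(tibble::as_tibble(long),
                             names_from = "metric", values_from = "value")
  wide$phase <- factor(wide$phase, levels = c("pre", "post"))
  class(wide) <- c("study_dataset", class(wide))
  wide
}

`%||%` <- function(a, b) if (is.null(a)) b else a
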