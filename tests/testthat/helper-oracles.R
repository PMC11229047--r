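# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately naive (direct formula evaluation, O(n^2)
# scans) and never call the code paths they check.

test_layout <- function() room_layout()

# --- entropy oracle: explicit count table -> probabilities -> formula -----
entropy_oracle <- function(seq) {
  seq <- seq[!is.na(seq)]
  if (length(seq) == 0) return(0)
  s <- seq[c(TRUE, seq[-1] != seq[-length(seq)])]
  if (length(s) < 3) return(0)           # fewer than 2 transitions
  from <- s[-length(s)]; to <- s[-1]
  tab <- table(from, to)
  tot <- sum(tab)
  if (tot < 2) return(0)
  p_i <- rowSums(tab) / tot
  h <- 0
  for (i in rownames(tab)) {
    for (j in colnames(tab)) {
      pji <- tab[i, j] / rowSums(tab)[i]
      if (is.finite(pji) && pji > 0) h <- h - p_i[i] * pji * log2(pji)
    }
  }
  unname(h)
}

# --- I-DT oracle: brute-force maximal dispersion-satisfying windows ------
idt_oracle <- function(t, az, el, dispersion_deg, min_dur_s) {
  n <- length(t)
  dt <- stats::median(diff(t))
  disp <- function(i, j) {
    (max(az[i:j]) - min(az[i:j])) + (max(el[i:j]) - min(el[i:j]))
  }
  res <- list()
  i <- 1L
  while (i <= n) {
    j0 <- NA
    for (j in i:n) {
      if ((t[j] + dt / 2) - (t[i] - dt / 2) >= min_dur_s - 1e-9) {
        j0 <- j; break
      }
    }
    if (is.na(j0)) break
    if (disp(i, j0) <= dispersion_deg) {
      j <- j0
      while (j < n && disp(i, j + 1) <= dispersion_deg) j <- j + 1
      on <- max(t[1], t[i] - dt / 2); off <- min(t[n], t[j] + dt / 2)
      res[[length(res) + 1]] <- data.frame(
        onset_s = on, offset_s = off, duration_s = off - on,
        az_deg = mean(az[i:j]), el_deg = mean(el[i:j])
      )
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  do.call(rbind, res)
}

# --- split-plot ANOVA oracle: textbook cell-means sums of squares --------
# balanced 2-phase, g-group design; returns F for time, group, interaction
splitplot_oracle <- function(df) {
  # df: participant, group, phase, value; balanced
  wide <- reshape(as.data.frame(df[, c("participant", "group", "phase",
                                       "value")]),
                  idvar = c("participant", "group"), timevar = "phase",
                  direction = "wide")
  y <- as.matrix(wide[, c("value.pre", "value.post")])
  g <- factor(wide$group)
  N <- nrow(y); a <- nlevels(g); q <- 2
  grand <- mean(y)
  subj_mean <- rowMeans(y)
  grp_mean <- tapply(subj_mean, g, mean)
  phase_mean <- colMeans(y)
  cell_mean <- apply(y, 2, function(col) tapply(col, g, mean))
  n_per <- as.vector(table(g))
  ss_group <- q * sum(n_per * (grp_mean - grand)^2)
  ss_subj_within <- q * sum((subj_mean - grp_mean[g])^2)
  ss_time <- N * sum((phase_mean - grand)^2)
  ss_int <- 0
  for (k in seq_len(a)) {
    for (p in 1:q) {
      ss_int <- ss_int + n_per[k] *
        (cell_mean[k, p] - grp_mean[k] - phase_mean[p] + grand)^2
    }
  }
  ss_err_within <- 0
  for (r in seq_len(N)) {
    for (p in 1:q) {
      ss_err_within <- ss_err_within +
        (y[r, p] - subj_mean[r] - cell_mean[as.integer(g[r]), p] +
           grp_mean[g[r]])^2
    }
  }
  df_b <- N - a; df_w <- N - a
  list(
    F_group = unname((ss_group / (a - 1)) / (ss_subj_within / df_b)),
    F_time = unname((ss_time / 1) / (ss_err_within / df_w)),
    F_int = unname((ss_int / (a - 1)) / (ss_err_within / df_w))
  )
}

# --- event matching: F1 against ground truth (onset tolerance) -----------
event_f1 <- function(detected, truth, onset_tol = 0.025) {
  used <- rep(FALSE, nrow(detected))
  tp <- 0
  for (i in seq_len(nrow(truth))) {
    j <- which(!used & abs(detected$onset_s - truth$onset_s[i]) <= onset_tol)
    if (length(j)) {
      tp <- tp + 1
      used[j[1]] <- TRUE
    }
  }
  prec <- tp / max(1, nrow(detected))
  rec <- tp / max(1, nrow(truth))
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

# piecewise-stationary recording: fixations at given centres/durations with
# instantaneous jumps (for detector unit tests, not via the renderer)
step_recording <- function(centres, durations, rate = 120, noise = 0) {
  t <- c(); az <- c(); el <- c()
  t0 <- 0
  for (k in seq_len(nrow(centres))) {
    nk <- round(durations[k] * rate)
    tk <- t0 + (seq_len(nk) - 1) / rate
    t <- c(t, tk)
    az <- c(az, rep(centres[k, 1], nk))
    el <- c(el, rep(centres[k, 2], nk))
    t0 <- t0 + nk / rate
  }
  if (noise > 0) {
    az <- az + stats::rnorm(length(az), 0, noise)
    el <- el + stats::rnorm(length(el), 0, noise)
  }
  gaze_recording(t, az, el, rate = rate)
}

# streams tibble straight from positions (identity "filtering") for unit
# tests that target the detectors in isolation
raw_streams <- function(rec) {
  tibble::tibble(t_s = rec$t_s, segment = 1L,
                 az_fix = rec$az_deg, el_fix = rec$el_deg,
                 az_sac = rec$az_deg, el_sac = rec$el_deg)
}

# balanced three-group pre/post dataset with optional time and
# FBEMT-only interaction shifts
make_balanced <- function(n = 10, seed = 1, time_shift = 0, int_shift = 0) {
  set.seed(seed)
  g <- rep(c("FFEMT", "FBEMT", "Control"), each = n)
  id <- sprintf("p%02d", seq_along(g))
  b <- rnorm(length(g), 0, 0.8)
  df <- rbind(
    data.frame(participant = id, group = g, phase = "pre",
               value = 2 + b + rnorm(length(g), 0, 0.5)),
    data.frame(participant = id, group = g, phase = "post",
               value = 2 + b + time_shift +
                 ifelse(g == "FBEMT", int_shift, 0) +
                 rnorm(length(g), 0, 0.5))
  )
  df$pool <- rep(rep(c("Army", "RM"), length.out = length(g)), 2)
  df
}
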