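#' Holm (step-down Bonferroni) adjustment
#'
#' Step-down multiplicity correction: the smallest of `m` p-values is
#' multiplied by `m`, the next by `m - 1`, and so on, with monotonicity
#' enforced and results capped at 1. Order-preserving with the input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same order and length.
#' @examples
#' holm_adjust(c(0.01, 0.02, 0.03))
#' @export
holm_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "holm")
}

# sum-coded within-stratum fit: returns the type-III style intercept test
# (time main effect) and the group partial F (group-by-time interaction)
# computed on participant pre-to-post differences.
fit_within <- function(d, group, cov = NULL) {
  g <- factor(group)
  X <- stats::model.matrix(~ g, contrasts.arg = list(g = "contr.sum"))
  if (!is.null(cov)) X <- cbind(X, cov = cov - mean(cov))
  fit <- stats::lm.fit(X, d)
  n <- length(d)
  p_full <- ncol(X)
  rss <- sum(fit$residuals^2)
  df_err <- n - p_full
  mse <- rss / df_err
  XtXinv <- chol2inv(chol(crossprod(X)))
  se_int <- sqrt(mse * XtXinv[1, 1])
  t_int <- fit$coefficients[1] / se_int
  F_time <- unname(t_int^2)
  ss_time <- F_time * mse
  # interaction: partial F for the group columns
  keep <- !grepl("^g", colnames(X))
  fit0 <- stats::lm.fit(X[, keep, drop = FALSE], d)
  ss_int <- sum(fit0$residuals^2) - rss
  df_int <- sum(grepl("^g", colnames(X)))
  F_int <- (ss_int / df_int) / mse
  list(
    time = c(F = F_time, df_num = 1, df_den = df_err,
             p = stats::pf(F_time, 1, df_err, lower.tail = FALSE),
             eta_sq = ss_time / (ss_time + rss)),
    interaction = c(F = F_int, df_num = df_int, df_den = df_err,
                    p = stats::pf(F_int, df_int, df_err, lower.tail = FALSE),
                    eta_sq = ss_int / (ss_int + rss))
  )
}

# between-stratum fit on participant means: group partial F and (when a
# covariate is present) the covariate partial F.
fit_between <- function(pm, group, cov = NULL) {
  g <- factor(group)
  base <- data.frame(pm = pm, g = g)
  if (is.null(cov)) {
    full <- stats::lm(pm ~ g, data = base)
    a <- stats::anova(stats::lm(pm ~ 1, data = base), full)
    rss <- sum(stats::residuals(full)^2)
    df_err <- full$df.residual
    ss_g <- a$`Sum of Sq`[2]
    list(group = c(F = a$F[2], df_num = a$Df[2], df_den = df_err,
                   p = a$`Pr(>F)`[2], eta_sq = ss_g / (ss_g + rss)),
         covariate = NULL)
  } else {
    base$cov <- cov - mean(cov)
    full <- stats::lm(pm ~ cov + g, data = base)
    rss <- sum(stats::residuals(full)^2)
    df_err <- full$df.residual
    ag <- stats::anova(stats::lm(pm ~ cov, data = base), full)
    ac <- stats::anova(stats::lm(pm ~ g, data = base), full)
    ss_g <- ag$`Sum of Sq`[2]; ss_c <- ac$`Sum of Sq`[2]
    list(group = c(F = ag$F[2], df_num = ag$Df[2], df_den = df_err,
                   p = ag$`Pr(>F)`[2], eta_sq = ss_g / (ss_g + rss)),
         covariate = c(F = ac$F[2], df_num = ac$Df[2], df_den = df_err,
                       p = ac$`Pr(>F)`[2], eta_sq = ss_c / (ss_c + rss)))
  }
}

#' Group-by-time mixed ANCOVA
#'
#' Fits the 3 (group, between) x 2 (time, within) analysis used for each
#' metric of a pre/post training study, as a split-plot decomposition:
#' participant means carry the between-participant stratum (group and,
#' optionally, a participant-level covariate) and pre-to-post differences
#' carry the within stratum (time and the group-by-time interaction; when
#' the covariate is retained it also enters this stratum, i.e. a
#' covariate-by-time term, mirroring standard repeated-measures ANCOVA).
#' Effects use unweighted (type III) marginal means; effect sizes are
#' partial eta squared, `SS_effect / (SS_effect + SS_error)`.
#'
#' The covariate follows a retention rule: it is kept in the model only
#' when its relationship with the dependent variable is significant
#' (`p < alpha` in the between stratum); otherwise the model is refit
#' without it. Participants missing either phase are removed listwise.
#'
#' @param data A `study_dataset` tibble: one row per participant x phase
#'   with columns `participant`, `group`, `phase` (`pre`/`post`), the
#'   metric columns, and any covariate column.
#' @param dv Name of the dependent-variable column (string).
#' @param covariate Optional name of a participant-level covariate column
#'   (two-level factor/character or numeric).
#' @param alpha Significance level for covariate retention and for
#'   triggering post-hoc comparisons.
#' @param posthoc_band Post-hocs are computed when the interaction p-value
#'   does not exceed `alpha + posthoc_band` (interactions just beyond the
#'   threshold are conventionally still explored; set 0 to require strict
#'   significance).
#' @return An object of class `gaze_anova`: effects table, covariate
#'   decision, post-hoc table (or `NULL`), and the cleaned wide data.
#' @seealso [posthoc_battery()], [tidy.gaze_anova()], [glance.gaze_anova()]
#' @export
mixed_anova <- function(data, dv, covariate = NULL, alpha = 0.05,
                        posthoc_band = 0.01) {
  data <- tibble::as_tibble(data)
  stopifnot(dv %in% names(data))
  if (!is.null(covariate)) stopifnot(covariate %in% names(data))
  wide <- data |>
    dplyr::select(dplyr::all_of(c("participant", "group", covariate,
                                  "phase", dv))) |>
    tidyr::pivot_wider(names_from = "phase", values_from = dplyr::all_of(dv))
  if (!all(c("pre", "post") %in% names(wide))) {
    stop("data must contain both 'pre' and 'post' phases", call. = FALSE)
  }
  wide <- wide[stats::complete.cases(wide), , drop = FALSE]
  counts <- table(wide$group)
  if (length(counts) < 2 || any(counts < 2)) {
    stop("insufficient data: need >= 2 complete participants per group",
         call. = FALSE)
  }
  pm <- (wide$pre + wide$post) / 2
  d <- wide$post - wide$pre
  if (stats::var(d) == 0 || stats::var(pm) == 0) {
    stop("degenerate data: zero error variance", call. = FALSE)
  }
  cov_num <- NULL
  if (!is.null(covariate)) {
    cv <- wide[[covariate]]
    cov_num <- if (is.numeric(cv)) cv else as.numeric(factor(cv)) - 1
  }
  cov_test <- NULL
  retained <- FALSE
  if (!is.null(cov_num)) {
    with_cov <- fit_between(pm, wide$group, cov_num)
    cov_test <- with_cov$covariate
    retained <- cov_test[["p"]] < alpha
  }
  if (retained) {
    bet <- fit_between(pm, wide$group, cov_num)
    wit <- fit_within(d, wide$group, cov_num)
  } else {
    bet <- fit_between(pm, wide$group, NULL)
    wit <- fit_within(d, wide$group, NULL)
  }
  rows <- list(time = wit$time, group = bet$group,
               `group:time` = wit$interaction)
  if (retained) rows$covariate <- bet$covariate
  effects <- purrr::imap_dfr(rows, function(v, nm) {
    tibble::tibble(effect = nm, F = v[["F"]], df_num = v[["df_num"]],
                   df_den = v[["df_den"]], p = v[["p"]],
                   eta_sq = v[["eta_sq"]])
  })
  res <- structure(
    list(dv = dv, covariate = covariate, covariate_retained = retained,
         covariate_test = cov_test, effects = effects,
         n = nrow(wide), n_per_group = as.list(counts),
         alpha = alpha, data = wide),
    class = "gaze_anova"
  )
  p_int <- effects$p[effects$effect == "group:time"]
  if (p_int <= alpha + posthoc_band) {
    res$posthoc <- posthoc_battery(wide)
  }
  res
}

#' Post-hoc comparison battery
#'
#' The pairwise comparisons used to decompose a group-by-time interaction:
#' between-group comparisons at pre and at post (pooled-variance two-sample
#' t-tests) and within-group pre-vs-post paired t-tests, Holm-adjusted
#' within each of the three families.
#'
#' @param wide A wide participant table with columns `group`, `pre`,
#'   `post` (as held in a `gaze_anova` object's `data`).
#' @return A tibble: `family`, `comparison`, `estimate`, `t`, `df`, `p`,
#'   `p_adj`.
#' @export
posthoc_battery <- function(wide) {
  groups <- sort(unique(as.character(wide$group)))
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  between <- purrr::map_dfr(c("pre", "post"), function(ph) {
    purrr::map_dfr(pairs, function(pr) {
      x <- wide[[ph]][wide$group == pr[1]]
      y <- wide[[ph]][wide$group == pr[2]]
      tt <- stats::t.test(x, y, var.equal = TRUE)
      tibble::tibble(family = ph,
                     comparison = paste(pr[1], "v", pr[2]),
                     estimate = unname(diff(rev(tt$estimate))),
                     t = unname(tt$statistic), df = unname(tt$parameter),
                     p = tt$p.value)
    })
  })
  within <- purrr::map_dfr(groups, function(g) {
    x <- wide[wide$group == g, , drop = FALSE]
    tt <- stats::t.test(x$post, x$pre, paired = TRUE)
    tibble::tibble(family = "pre-post change", comparison = g,
                   estimate = unname(tt$estimate), t = unname(tt$statistic),
                   df = unname(tt$parameter), p = tt$p.value)
  })
  dplyr::bind_rows(between, within) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(p_adj = holm_adjust(.data$p)) |>
    dplyr::ungroup()
}

#' @export
print.gaze_anova <- function(x, ...) {
  cat("Mixed group-by-time ANCOVA on '", x$dv, "' (n = ", x$n, ")\n",
      sep = "")
  if (!is.null(x$covariate)) {
    ct <- x$covariate_test
    cat(sprintf("covariate '%s': F(%d,%d) = %.2f, p = %.3f -> %s\n",
                x$covariate, ct[["df_num"]], ct[["df_den"]], ct[["F"]],
                ct[["p"]],
                if (x$covariate_retained) "retained" else "removed"))
  }
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-11s F(%d,%d) = %6.2f, p = %.4f, eta_sq = %.3f\n",
                eff$effect[i], eff$df_num[i], eff$df_den[i], eff$F[i],
                eff$p[i], eff$eta_sq[i]))
  }
  if (is.null(x$posthoc)) {
    cat("  interaction not significant: no post-hoc comparisons\n")
  } else {
    cat("  post-hoc comparisons (Holm-adjusted within family):\n")
    ph <- x$posthoc
    for (i in seq_len(nrow(ph))) {
      cat(sprintf("    [%s] %-18s p = %.4f (adj %.4f)\n", ph$family[i],
                  ph$comparison[i], ph$p[i], ph$p_adj[i]))
    }
  }
  invisible(x)
}

#' Tidy a mixed-ANCOVA fit
#'
#' @param x A `gaze_anova` object.
#' @param ... Unused.
#' @return The effects table as a tibble: `effect`, `F`, `df_num`,
#'   `df_den`, `p`, `eta_sq`.
#' @export
tidy.gaze_anova <- function(x, ...) x$effects

#' One-row summary of a mixed-ANCOVA fit
#'
#' @param x A `gaze_anova` object.
#' @param ... Unused.
#' @return A one-row tibble: dv, n, covariate retention, and the
#'   interaction test.
#' @export
glance.gaze_anova <- function(x, ...) {
  int <- x$effects[x$effects$effect == "group:time", ]
  tibble::tibble(dv = x$dv, n = x$n,
                 covariate_retained = x$covariate_retained,
                 F_interaction = int$F, p_interaction = int$p,
                 eta_sq_interaction = int$eta_sq,
                 n_posthoc = if (is.null(x$posthoc)) 0L else nrow(x$posthoc))
}

#' Run the statistics stage over several metrics
#'
#' Applies [mixed_anova()] to each named metric of a study dataset and
#' assembles a deterministic, alphabetically ordered report.
#'
#' @param data A `study_dataset` tibble.
#' @param dvs Character vector of metric columns to analyse.
#' @param covariate Optional covariate column name (see [mixed_anova()]).
#' @param alpha Significance level.
#' @return A named list of `gaze_anova` objects (class `gaze_report`),
#'   ordered alphabetically by metric.
#' @export
analyse_study <- function(data, dvs, covariate = "pool", alpha = 0.05) {
  dvs <- sort(dvs)
  out <- purrr::map(rlang::set_names(dvs), function(dv) {
    mixed_anova(data, dv, covariate = covariate, alpha = alpha)
  })
  class(out) <- "gaze_report"
  out
}

#' @export
print.gaze_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("==", nm, "==\n")
    print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}

#' Machine-readable summary of an analysis report
#'
#' Flattens a `gaze_report` (or single `gaze_anova`) into plain lists ready
#' for `jsonlite::write_json()`; regenerating from the same inputs is
#' byte-identical.
#'
#' @param report A `gaze_report` or `gaze_anova`.
#' @return A named list (one element per metric, alphabetical).
#' @export
report_summary <- function(report) {
  if (inherits(report, "gaze_anova")) {
    report <- structure(stats::setNames(list(report), report$dv),
                        class = "gaze_report")
  }
  purrr::map(report[sort(names(report))], function(a) {
    list(
      dv = a$dv, n = a$n,
      covariate = if (is.null(a$covariate)) NULL else a$covariate,
      covariate_retained = a$covariate_retained,
      covariate_p = if (is.null(a$covariate_test)) NULL else
        unname(a$covariate_test[["p"]]),
      effects = as.data.frame(a$effects),
      posthoc = if (is.null(a$posthoc)) "interaction not significant" else
        as.data.frame(a$posthoc)
    )
  })
}
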