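#' Correlation between consecutive change scores
#'
#' Pearson correlation between consecutive non-overlapping change scores
#' (y2 - y1 vs y3 - y2) pooled over patients, using observations spaced
#' exactly `interval` months apart on the annual visit grid.  Under the
#' progression model this correlation has the closed form
#' `-sigma_e2 / (sigma_dt2 + 2 * sigma_e2)`: measurement error induces
#' regression toward the mean, so an apparent improvement tends to be
#' followed by an apparent worsening.  The within-subject reliability is
#' tied to it by `r = 1 + 2 * rho`.
#'
#' @param cohort A [cohort_table()].
#' @param scale_id Scale to analyse.
#' @param interval Spacing of the change scores in months (default 12;
#'   consecutive annual visits).
#' @param off_threshold Washout threshold applied for `"part3_off"`.
#' @return The pooled Pearson correlation (scalar).  Errors when fewer
#'   than 10 change-score pairs are available.
#' @export
change_score_correlation <- function(cohort, scale_id, interval = 12,
                                     off_threshold = 6) {
  thr <- if (identical(scale_id, "part3_off")) off_threshold else NULL
  series <- to_monthly_series(cohort, scale_id, off_threshold = thr)
  d1 <- d2 <- numeric(0)
  for (y in series) {
    mo <- as.integer(names(y))[!is.na(y)]
    yv <- y[!is.na(y)]
    if (length(mo) < 3) next
    # every available consecutive triple at exact `interval` spacing
    for (i in seq_len(length(mo) - 2)) {
      if (mo[i + 1] - mo[i] == interval && mo[i + 2] - mo[i + 1] == interval) {
        d1 <- c(d1, yv[i + 1] - yv[i])
        d2 <- c(d2, yv[i + 2] - yv[i + 1])
      }
    }
  }
  if (length(d1) < 10)
    stop("fewer than 10 change-score pairs; estimate would be unstable")
  stats::cor(d1, d2)
}

#' Model-adequacy diagnostics report
#'
#' Collects the residual diagnostics for a fitted progression model:
#' standardized one-step (innovation) residuals and smoothed residuals
#' for every observed point, normal QQ pairs for the innovations, a
#' Shapiro-Wilk normality check (diagnostic only; no data are rejected),
#' the lag-1 correlation of consecutive annual change scores, and
#' per-visit group summaries.
#'
#' @param cohort The [cohort_table()] the model was fitted to.
#' @param fit A converged [fit_mle()] result.
#' @param off_threshold Washout threshold applied for `"part3_off"`.
#' @return An object of class `diagnostics_report`: `innovations`,
#'   `smoothed` (data frames from [residuals.progression_fit()]),
#'   `qq_points` (theoretical vs empirical quantiles),
#'   `shapiro_p`, `lag1_change_correlation` (`NA` when too few pairs),
#'   `group_summary`.
#' @export
residual_report <- function(cohort, fit, off_threshold = 6) {
  stopifnot(inherits(fit, "progression_fit"))
  if (!fit$converged) stop("diagnostics require a converged fit")
  innov <- residuals(fit, type = "innovation")
  smoothed <- residuals(fit, type = "smoothed")
  z <- sort(innov$residual)
  qq <- data.frame(theoretical = stats::qnorm(stats::ppoints(length(z))),
                   empirical = z)
  sw <- stats::shapiro.test(if (length(z) > 5000) sample(z, 5000) else z)
  lag1 <- tryCatch(
    change_score_correlation(cohort, fit$scale_id,
                             off_threshold = off_threshold),
    error = function(e) NA_real_)
  gs <- tryCatch(group_trajectories(cohort, fit$scale_id),
                 error = function(e) NULL)
  structure(list(innovations = innov, smoothed = smoothed,
                 qq_points = qq, shapiro_p = sw$p.value,
                 lag1_change_correlation = lag1, group_summary = gs),
            class = "diagnostics_report")
}

#' @export
print.diagnostics_report <- function(x, ...) {
  cat("Progression model diagnostics\n")
  cat(sprintf("  %d standardized innovations; Shapiro-Wilk p = %.3g\n",
              nrow(x$innovations), x$shapiro_p))
  cat(sprintf("  max |QQ deviation| = %.3f\n",
              max(abs(x$qq_points$empirical - x$qq_points$theoretical))))
  if (!is.na(x$lag1_change_correlation))
    cat(sprintf("  lag-1 correlation of annual change scores: %.3f\n",
                x$lag1_change_correlation))
  invisible(x)
}

#' Per-visit group trajectory summaries
#'
#' For each scheduled visit month with data: the number of non-missing
#' scores, their median, and the 10% and 25% bands around the median
#' (i.e. the 40%/60% and 25%/75% quantiles).  Missing values are
#' excluded from every summary.
#'
#' @param cohort A [cohort_table()].
#' @param scale_id Scale to summarise.
#' @return Data frame with columns `month`, `n`, `median`, `lo10`,
#'   `hi10`, `lo25`, `hi25`.
#' @export
group_trajectories <- function(cohort, scale_id) {
  sub <- cohort[cohort$scale_id == scale_id, , drop = FALSE]
  if (nrow(sub) == 0) stop("scale '", scale_id, "' not present in cohort")
  out <- lapply(split(sub$subtotal, sub$month), function(v) {
    v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0.25, 0.4, 0.5, 0.6, 0.75), names = FALSE)
    data.frame(n = length(v), median = q[3], lo10 = q[2], hi10 = q[4],
               lo25 = q[1], hi25 = q[5])
  })
  res <- do.call(rbind, out)
  res <- cbind(month = as.integer(names(out)), res)
  res <- res[order(res$month), ]
  rownames(res) <- NULL
  res
}
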