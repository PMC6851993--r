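#' Within-subject reliability of 1-year change scores
#'
#' The fraction of 1-year change-score variance attributable to true
#' long-term change:
#' `r = sigma_dt2 / (sigma_dt2 + 2 * sigma_e2)`,
#' where `sigma_dt2` is the annual true-change variance and `sigma_e2`
#' the measurement-error variance (which enters twice because a change
#' score is a difference of two noisy measurements).  Values near 1 mean
#' observed change scores track true progression; values near 0 mean they
#' are mostly noise.
#'
#' @param sigma_dt2_annual Annual true-change variance (score^2), >= 0;
#'   or a [fit_mle()] result, from which both components are taken.
#' @param sigma_e2 Measurement-error variance (score^2), >= 0.
#' @return A number in `[0, 1]`; vectorized over its arguments.
#' @export
#' @examples
#' within_subject_reliability(7.22, 3.66)  # ~0.50
within_subject_reliability <- function(sigma_dt2_annual, sigma_e2) {
  if (inherits(sigma_dt2_annual, "progression_fit")) {
    a <- annualize(sigma_dt2_annual$params)
    sigma_e2 <- a$sigma_e2
    sigma_dt2_annual <- a$sigma_dt2
  }
  if (any(sigma_dt2_annual < 0) || any(sigma_e2 < 0))
    stop("variance components must be >= 0")
  tot <- sigma_dt2_annual + 2 * sigma_e2
  if (any(tot == 0))
    stop("reliability is undefined when both variance components are 0")
  sigma_dt2_annual / tot
}

# Annual-scale summary vector reported for each (re)fit.
.reliability_stats <- function(fit) {
  a <- annualize(fit$params)
  c(sigma_e2 = a$sigma_e2, sigma_dt2_annual = a$sigma_dt2,
    trend_annual = a$trend,
    r_dd = within_subject_reliability(a$sigma_dt2, a$sigma_e2))
}

#' Percentile-bootstrap confidence intervals by patient resampling
#'
#' Resamples whole patients with replacement, refits the progression
#' model on each bootstrap cohort (warm-started at the full-sample
#' estimate) and reports empirical `alpha/2` and `1 - alpha/2`
#' percentiles — the simple percentile bootstrap — for the four reported
#' quantities: `sigma_e2`, annual `sigma_dt2`, annual trend, and the
#' within-subject reliability.  Percentiles use linear interpolation
#' between order statistics (`quantile` type 7).  The result is a
#' deterministic function of `(cohort, seed)`.  Replicates whose refit
#' does not converge are dropped and counted; more than 10% dropped
#' raises a warning recorded in the result.
#'
#' @param cohort A [cohort_table()].
#' @param scale_id Scale to analyse.
#' @param n_boot Number of bootstrap replicates (default 1000).
#' @param alpha Two-sided miscoverage level (default 0.05 for 95% CIs).
#' @param seed Integer seed (mandatory).
#' @param off_threshold Washout threshold (hours) for `"part3_off"`.
#' @return An object of class `reliability_estimate`: `point` (named
#'   vector of the four quantities), `ci` (2 x 4 matrix), the replicate
#'   draws, the full-sample fit, `n_boot`, `n_dropped`, `alpha`, `seed`.
#' @seealso [within_subject_reliability()], [compare_washout()]
#' @export
bootstrap_ci <- function(cohort, scale_id, n_boot = 1000, alpha = 0.05,
                         seed = NULL, off_threshold = 6) {
  if (is.null(seed)) stop("an explicit integer seed is required")
  stopifnot(n_boot >= 1, alpha > 0, alpha < 1)
  dat <- .as_fit_matrix(cohort, scale_id, off_threshold)
  Y0 <- dat$Y
  dimnames(Y0) <- list(dat$months, dat$patients)
  fit0 <- fit_mle(Y0, scale_id = scale_id)
  reps <- .with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 4)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(ncol(dat$Y), replace = TRUE)
      Yb <- dat$Y[, idx, drop = FALSE]
      rownames(Yb) <- dat$months
      fb <- tryCatch(fit_mle(Yb, start = fit0$params, restarts = 0),
                     error = function(e) NULL)
      if (!is.null(fb) && fb$converged) out[b, ] <- .reliability_stats(fb)
    }
    out
  })
  ok <- stats::complete.cases(reps)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.1 * n_boot)
    warning(sprintf("%d of %d bootstrap refits failed to converge",
                    n_dropped, n_boot))
  reps <- reps[ok, , drop = FALSE]
  colnames(reps) <- names(.reliability_stats(fit0))
  ci <- apply(reps, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), type = 7)
  structure(list(point = .reliability_stats(fit0), ci = ci,
                 replicates = reps, fit = fit0, n_boot = n_boot,
                 n_dropped = n_dropped, alpha = alpha, seed = seed,
                 scale_id = scale_id),
            class = "reliability_estimate")
}

#' @export
print.reliability_estimate <- function(x, ...) {
  cat(sprintf(
    "Within-subject reliability analysis [%s], %d bootstrap replicates\n",
    x$scale_id, x$n_boot))
  tab <- rbind(estimate = x$point, x$ci)
  print(round(tab, 3))
  if (x$n_dropped)
    cat(sprintf("(%d non-converged replicates dropped)\n", x$n_dropped))
  invisible(x)
}

#' Report table of reliability analyses
#'
#' Formats one or more [bootstrap_ci()] results as a single table with
#' one row per scale and the columns `sigma_e2`, `sigma_dt2_annual`
#' (per year), `trend_annual` (per year) and `r_dd`, each with its
#' bootstrap CI.
#'
#' @param ... [bootstrap_ci()] results (optionally named).
#' @param path Optional CSV path to write the table to.
#' @return The table, invisibly if written.
#' @export
reliability_report <- function(..., path = NULL) {
  ests <- list(...)
  rows <- lapply(ests, function(e) {
    stopifnot(inherits(e, "reliability_estimate"))
    p <- x <- e$point; ci <- e$ci
    data.frame(scale_id = e$scale_id,
               sigma_e2 = p["sigma_e2"],
               sigma_e2_ci = sprintf("%.2f-%.2f", ci[1, 1], ci[2, 1]),
               sigma_dt2_annual = p["sigma_dt2_annual"],
               sigma_dt2_ci = sprintf("%.2f-%.2f", ci[1, 2], ci[2, 2]),
               trend_annual = p["trend_annual"],
               trend_ci = sprintf("%.2f-%.2f", ci[1, 3], ci[2, 3]),
               r_dd = p["r_dd"],
               r_dd_ci = sprintf("%.2f-%.2f", ci[1, 4], ci[2, 4]),
               row.names = NULL)
  })
  tab <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Paired bootstrap comparison of two washout thresholds
#'
#' Quantifies how the length of the medication washout before an OFF
#' motor exam affects the error variance and reliability: for each
#' bootstrap replicate the SAME resampled patients are filtered under
#' both OFF thresholds (an assessment qualifies when taken strictly more
#' than the threshold hours postdose, or the patient is untreated), both
#' models are refitted, and the paired differences (threshold_b minus
#' threshold_a) in `sigma_e2` and in the reliability are recorded.
#' Resampling before thresholding maximizes the power of the paired
#' comparison.  The one-sided empirical p-value is the fraction of
#' replicates with difference >= 0; double it for a two-sided test.
#'
#' @param cohort A [cohort_table()] whose part III OFF records carry
#'   `hours_postdose`.
#' @param threshold_a,threshold_b Washout thresholds in hours (distinct;
#'   equality is only meaningful in degenerate checks).
#' @param n_boot,alpha,seed As in [bootstrap_ci()].
#' @return An object of class `washout_comparison`: point differences,
#'   percentile CIs of the paired differences, one-sided p-values, the
#'   two full-sample fits and the replicate differences.
#' @export
compare_washout <- function(cohort, threshold_a = 6, threshold_b = 14,
                            n_boot = 1000, alpha = 0.05, seed = NULL) {
  if (is.null(seed)) stop("an explicit integer seed is required")
  da <- .cohort_matrix(cohort, "part3_off", off_threshold = threshold_a)
  db <- .cohort_matrix(cohort, "part3_off", off_threshold = threshold_b)
  # align patient columns of the two filtered matrices
  pats <- sort(unique(c(da$patients, db$patients)))
  months <- sort(unique(c(da$months, db$months)))
  expand <- function(d) {
    Y <- matrix(NA_real_, length(months), length(pats),
                dimnames = list(months, pats))
    Y[match(d$months, months), match(d$patients, pats)] <- d$Y
    Y
  }
  Ya <- expand(da); Yb <- expand(db)
  if (mean(colSums(!is.na(Ya))) < 2 || mean(colSums(!is.na(Yb))) < 2)
    stop("a threshold leaves fewer than 2 observations per patient ",
         "on average")
  fa <- fit_mle(Ya); fb <- fit_mle(Yb)
  point <- c(d_sigma_e2 = unname(.reliability_stats(fb)["sigma_e2"] -
                                   .reliability_stats(fa)["sigma_e2"]),
             d_r_dd = unname(.reliability_stats(fb)["r_dd"] -
                               .reliability_stats(fa)["r_dd"]))
  reps <- .with_seed(seed, {
    out <- matrix(NA_real_, n_boot, 2,
                  dimnames = list(NULL, c("d_sigma_e2", "d_r_dd")))
    for (b in seq_len(n_boot)) {
      idx <- sample.int(length(pats), replace = TRUE)
      ra <- tryCatch(fit_mle(`rownames<-`(Ya[, idx, drop = FALSE], months),
                             start = fa$params, restarts = 0),
                     error = function(e) NULL)
      rb <- tryCatch(fit_mle(`rownames<-`(Yb[, idx, drop = FALSE], months),
                             start = fb$params, restarts = 0),
                     error = function(e) NULL)
      if (!is.null(ra) && !is.null(rb) && ra$converged && rb$converged) {
        sa <- .reliability_stats(ra); sb <- .reliability_stats(rb)
        out[b, ] <- c(sb["sigma_e2"] - sa["sigma_e2"],
                      sb["r_dd"] - sa["r_dd"])
      }
    }
    out
  })
  ok <- stats::complete.cases(reps)
  reps <- reps[ok, , drop = FALSE]
  ci <- apply(reps, 2, stats::quantile,
              probs = c(alpha / 2, 1 - alpha / 2), type = 7)
  p_one <- colMeans(reps >= 0)
  structure(list(thresholds = c(threshold_a, threshold_b), point = point,
                 ci = ci, p_one_sided = p_one, replicates = reps,
                 fit_a = fa, fit_b = fb, n_boot = n_boot,
                 n_dropped = sum(!ok), alpha = alpha, seed = seed),
            class = "washout_comparison")
}

#' @export
print.washout_comparison <- function(x, ...) {
  cat(sprintf(
    "Washout comparison: >%g h vs >%g h postdose (%d paired replicates)\n",
    x$thresholds[1], x$thresholds[2], nrow(x$replicates)))
  tab <- rbind(difference = x$point, x$ci,
               `one-sided p (diff >= 0)` = x$p_one_sided)
  print(round(tab, 4))
  invisible(x)
}
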