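# Canonicalize fit_mle() input to a months x patients matrix.
.as_fit_matrix <- function(x, scale_id = NULL, off_threshold = 6) {
  if (inherits(x, "cohort_table")) {
    if (is.null(scale_id))
      stop("scale_id is required when fitting a cohort_table")
    thr <- if (identical(scale_id, "part3_off")) off_threshold else NULL
    return(.cohort_matrix(x, scale_id, off_threshold = thr))
  }
  if (is.matrix(x)) {
    months <- if (!is.null(rownames(x))) as.integer(rownames(x))
              else seq_len(nrow(x)) - 1L
    pats <- if (!is.null(colnames(x))) colnames(x)
            else sprintf("P%04d", seq_len(ncol(x)))
    return(list(Y = unname(x), months = months, patients = pats))
  }
  if (is.list(x)) {  # per-patient monthly series, as from to_monthly_series()
    ms <- lapply(x, function(y) {
      mo <- if (!is.null(names(y))) as.integer(names(y)) else seq_along(y) - 1L
      mo[!is.na(y)]
    })
    months <- sort(unique(unlist(ms)))
    Y <- matrix(NA_real_, length(months), length(x))
    for (j in seq_along(x)) {
      y <- x[[j]]
      mo <- if (!is.null(names(y))) as.integer(names(y)) else seq_along(y) - 1L
      ok <- !is.na(y)
      Y[match(mo[ok], months), j] <- y[ok]
    }
    pats <- names(x)
    if (is.null(pats)) pats <- sprintf("P%04d", seq_along(x))
    return(list(Y = Y, months = months, patients = pats))
  }
  stop("unsupported input type for fitting")
}

# Moment-based starting values: split the variance of first differences
# at adjacent annual visits evenly between measurement error and annual
# true-change variance; trend from the mean monthly change; m0/c0 from
# the distribution of each patient's earliest score.
.moment_start <- function(Y, months) {
  diffs <- gaps <- numeric(0)
  for (j in seq_len(ncol(Y))) {
    obs <- which(!is.na(Y[, j]))
    if (length(obs) >= 2) {
      g <- diff(months[obs]); d <- diff(Y[obs, j])
      ann <- g >= 11 & g <= 13
      if (any(ann)) { diffs <- c(diffs, d[ann]); gaps <- c(gaps, g[ann]) }
    }
  }
  if (length(diffs) < 5) {  # no annual spacing available: use all diffs
    for (j in seq_len(ncol(Y))) {
      obs <- which(!is.na(Y[, j]))
      if (length(obs) >= 2) {
        diffs <- c(diffs, diff(Y[obs, j]))
        gaps <- c(gaps, diff(months[obs]))
      }
    }
  }
  vd <- if (length(diffs) >= 2) stats::var(diffs) else 1
  trend <- if (length(diffs)) mean(diffs / gaps) else 0
  first <- apply(Y, 2, function(y) y[which(!is.na(y))[1]])
  first <- first[!is.na(first)]
  m0 <- if (length(first)) mean(first) else 0
  c0 <- if (length(first) >= 2) stats::var(first) else 1
  model_params(sigma_e2 = max(vd / 2, 1e-3),
               sigma_dt2 = max(vd / 2 / 12, 1e-4),
               trend = trend, m0 = m0, c0 = max(c0, 1e-3))
}

.par_to_theta <- function(p)
  c(log(max(p$sigma_e2, 1e-10)), log(max(p$sigma_dt2, 1e-10)),
    p$trend, p$m0, log(max(p$c0, 1e-10)))

.theta_to_par <- function(th) {
  th[c(1, 2, 5)] <- pmin(th[c(1, 2, 5)], 50)  # cap exp() overflow
  model_params(exp(th[1]), exp(th[2]), th[3], th[4], exp(th[5]))
}

#' Fit the progression model by pooled maximum likelihood
#'
#' Maximizes the summed Kalman-filter log-likelihood of all patients'
#' series over the five parameters (`sigma_e2`, `sigma_dt2`, `trend`,
#' `m0`, `c0`): one shared parameter set describes the whole study
#' population, so the average progression is linear in time while
#' individual paths vary through the random-walk innovations.  Variances
#' are optimized on the log scale by quasi-Newton (BFGS) from
#' moment-based starting values with additional restarts; each series is
#' used up to its last observation.
#'
#' @param x A [cohort_table()] (with `scale_id`), a list of per-patient
#'   monthly series as returned by [to_monthly_series()], or a months x
#'   patients matrix with `NA` for missing.
#' @param scale_id Scale to fit when `x` is a cohort table.  The two part
#'   III conditions are fitted as separate independent models.
#' @param off_threshold Washout threshold (hours) applied when fitting
#'   `"part3_off"`; default 6.
#' @param start Optional [model_params()] used as the only starting value
#'   (e.g. warm starts during bootstrapping).
#' @param restarts Number of additional deterministic restarts around the
#'   moment-based start (default 3); ignored when `start` is given.
#' @return An object of class `progression_fit`: monthly-grid parameter
#'   estimates (`$params`), total log-likelihood, convergence flag,
#'   boundary flag (a variance estimate indistinguishable from 0 is
#'   reported as 0), counts, and optimizer metadata.  Non-convergence is
#'   flagged, not thrown.
#' @seealso [annualize()], [within_subject_reliability()],
#'   [bootstrap_ci()], [residuals.progression_fit()]
#' @export
#' @examples
#' sim <- simulate_cohort(generator_config(n_patients = 60, seed = 1,
#'                                         scales = "part2"))
#' fit <- fit_mle(sim$cohort, "part2")
#' coef(fit, time_unit = "year")
fit_mle <- function(x, scale_id = NULL, off_threshold = 6, start = NULL,
                    restarts = 3) {
  dat <- .as_fit_matrix(x, scale_id, off_threshold)
  Y <- dat$Y; months <- dat$months
  nobs_per <- colSums(!is.na(Y))
  if (sum(nobs_per >= 2) < 2)
    stop("need at least 2 patients with at least 2 observations each")

  negll <- function(th) {
    if (any(!is.finite(th))) return(1e12)
    p <- .theta_to_par(th)
    v <- -.kf_loglik_mat(Y, months, p)
    if (!is.finite(v)) 1e12 else v
  }

  if (is.null(start)) {
    base <- .moment_start(Y, months)
    starts <- list(base)
    scal <- c(4, 1 / 4, 16)[seq_len(max(restarts, 0))]
    for (s in scal)
      starts <- c(starts, list(model_params(base$sigma_e2 * s,
                                            base$sigma_dt2 / s, base$trend,
                                            base$m0, base$c0)))
  } else {
    stopifnot(inherits(start, "model_params"))
    starts <- list(if (start$time_unit == "year") deannualize(start) else start)
  }

  best <- NULL; trace <- list()
  for (st in starts) {
    opt <- tryCatch(
      stats::optim(.par_to_theta(st), negll, method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-10)),
      error = function(e) NULL)
    if (is.null(opt)) next
    trace[[length(trace) + 1]] <- c(value = opt$value,
                                    convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("optimization failed from every starting value")

  p <- .theta_to_par(best$par)
  boundary <- FALSE
  for (nm in c("sigma_e2", "sigma_dt2", "c0"))
    if (p[[nm]] < 1e-6) { p[[nm]] <- 0; boundary <- TRUE }
  params <- model_params(p$sigma_e2, p$sigma_dt2, p$trend, p$m0, p$c0)

  structure(list(
    params = params,
    loglik = -best$value,
    converged = best$convergence == 0 && is.finite(best$value),
    boundary = boundary,
    n_patients = ncol(Y),
    n_observations = sum(!is.na(Y)),
    optimizer_trace = trace,
    scale_id = scale_id,
    data = dat,
    call = match.call()),
    class = "progression_fit")
}

#' @export
coef.progression_fit <- function(object, time_unit = c("month", "year"),
                                 ...) {
  time_unit <- match.arg(time_unit)
  p <- object$params
  if (time_unit == "year") p <- annualize(p)
  c(sigma_e2 = p$sigma_e2, sigma_dt2 = p$sigma_dt2, trend = p$trend,
    m0 = p$m0, c0 = p$c0)
}

#' @export
logLik.progression_fit <- function(object, ...)
  structure(object$loglik, df = 5L, nobs = object$n_observations,
            class = "logLik")

#' @export
print.progression_fit <- function(x, ...) {
  a <- annualize(x$params)
  cat("Latent progression model fit",
      if (!is.null(x$scale_id)) paste0(" [", x$scale_id, "]"), "\n", sep = "")
  cat(sprintf("  %d patients, %d observations; log-likelihood %.2f%s\n",
              x$n_patients, x$n_observations, x$loglik,
              if (!x$converged) "  (NOT converged)" else ""))
  cat(sprintf("  sigma_e2 = %.3f   sigma_dt2 = %.3f /yr   trend = %.3f /yr\n",
              a$sigma_e2, a$sigma_dt2, a$trend))
  cat(sprintf("  m0 = %.2f   c0 = %.2f\n", a$m0, a$c0))
  cat(sprintf("  within-subject reliability of 1-year changes: %.3f\n",
              within_subject_reliability(a$sigma_dt2, a$sigma_e2)))
  if (x$boundary)
    cat("  note: a variance was estimated at the boundary (reported as 0)\n")
  invisible(x)
}

#' @export
summary.progression_fit <- function(object, ...) {
  m <- object$params; a <- annualize(m)
  tab <- rbind(month = unlist(m[c("sigma_e2", "sigma_dt2", "trend",
                                  "m0", "c0")]),
               year = unlist(a[c("sigma_e2", "sigma_dt2", "trend",
                                 "m0", "c0")]))
  structure(list(fit = object, table = tab,
                 r_dd = within_subject_reliability(a$sigma_dt2, a$sigma_e2)),
            class = "summary.progression_fit")
}

#' @export
print.summary.progression_fit <- function(x, ...) {
  print(x$fit)
  cat("\nParameter estimates by time unit:\n")
  print(round(x$table, 4))
  invisible(x)
}

#' Smoothed latent progression paths
#'
#' Runs the fixed-interval smoother at the fitted parameters for each
#' patient, returning the posterior mean and variance of the latent
#' severity at every month from 0 to the patient's last observation.
#'
#' @param object A [fit_mle()] result.
#' @param patients Optional character vector restricting the patients.
#' @param ... Unused.
#' @return Named list of `latent_path` data frames (see
#'   [kalman_smooth()]).
#' @export
predict.progression_fit <- function(object, patients = NULL, ...) {
  dat <- object$data
  idx <- seq_along(dat$patients)
  if (!is.null(patients)) idx <- match(patients, dat$patients)
  out <- lapply(idx, function(j) {
    obs <- !is.na(dat$Y[, j])
    kalman_smooth(dat$Y[obs, j], object$params,
                  months = dat$months[obs])
  })
  names(out) <- dat$patients[idx]
  out
}

#' Residuals of a progression-model fit
#'
#' Two residual families: `"innovation"` residuals (difference between
#' the one-step predicted state and its measurement, standardized by the
#' prediction variance so they are iid standard normal under the model)
#' and `"smoothed"` residuals (difference between the estimated true
#' progression state and the observed value; standardized by their sample
#' standard deviation).
#'
#' @param object A [fit_mle()] result.
#' @param type `"innovation"` or `"smoothed"`.
#' @param standardize Return standardized residuals (default `TRUE`).
#' @param ... Unused.
#' @return Data frame with `patient_id`, `month`, `residual`.
#' @export
residuals.progression_fit <- function(object,
                                      type = c("innovation", "smoothed"),
                                      standardize = TRUE, ...) {
  type <- match.arg(type)
  dat <- object$data
  out <- vector("list", length(dat$patients))
  for (j in seq_along(dat$patients)) {
    obs <- which(!is.na(dat$Y[, j]))
    if (!length(obs)) next
    mo <- dat$months[obs]; yv <- dat$Y[obs, j]
    dense <- rep(NA_real_, max(mo) + 1); dense[mo + 1] <- yv
    if (type == "innovation") {
      f <- .kf_forward(dense, object$params)
      r <- f$innov[mo + 1]
      if (standardize) r <- r / sqrt(f$innov_var[mo + 1])
    } else {
      sm <- kalman_smooth(dense, object$params)
      r <- yv - sm$state_mean[mo + 1]
    }
    out[[j]] <- data.frame(patient_id = dat$patients[j], month = mo,
                           residual = r)
  }
  res <- do.call(rbind, out)
  if (type == "smoothed" && standardize)
    res$residual <- res$residual / stats::sd(res$residual)
  rownames(res) <- NULL
  res
}

#' Simulate new data from a fitted progression model
#'
#' Draws new cohorts from the fitted parameters on the same month grid
#' and missingness pattern as the data the model was fitted to
#' (a parametric-bootstrap style check of model adequacy).
#'
#' @param object A [fit_mle()] result.
#' @param nsim Number of replicate cohorts.
#' @param seed Integer seed (required for reproducibility).
#' @param ... Unused.
#' @return A list of `nsim` matrices shaped like the fitted data.
#' @export
simulate.progression_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(seed)) stop("an explicit integer seed is required")
  dat <- object$data; p <- object$params
  months <- dat$months; n <- ncol(dat$Y)
  .with_seed(seed, {
    lapply(seq_len(nsim), function(k) {
      theta <- matrix(NA_real_, length(months), n)
      prev <- matrix(stats::rnorm(n, p$m0, sqrt(p$c0)), 1)
      last <- 0L
      for (r in seq_along(months)) {
        gap <- months[r] - last
        if (gap > 0)
          prev <- prev + stats::rnorm(n, gap * p$trend,
                                      sqrt(gap * p$sigma_dt2))
        theta[r, ] <- prev
        last <- months[r]
      }
      Y <- theta + stats::rnorm(length(theta), 0, sqrt(p$sigma_e2))
      Y[is.na(dat$Y)] <- NA
      dimnames(Y) <- list(months, dat$patients)
      Y
    })
  })
}

#' @export
plot.progression_fit <- function(x, which = c("qq", "trajectories"), ...) {
  which <- match.arg(which)
  if (which == "qq") {
    r <- residuals(x, type = "innovation")$residual
    stats::qqnorm(r, main = "Standardized innovation residuals")
    stats::qqline(r)
  } else {
    dat <- x$data
    graphics::matplot(dat$months, dat$Y, type = "l", lty = 1,
                      col = grDevices::adjustcolor("grey40", 0.3),
                      xlab = "month", ylab = "score", ...)
    med <- apply(dat$Y, 1, stats::median, na.rm = TRUE)
    graphics::lines(dat$months, med, lwd = 2)
  }
  invisible(x)
}

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring
# the caller's RNG stream afterwards.
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
  })
  expr
}
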