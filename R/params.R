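#' Model parameters for the latent progression model
#'
#' Bundles the five estimable quantities of the local level model with
#' drift: observation-noise variance `sigma_e2`, true-progression variance
#' `sigma_dt2` per time unit, mean progression `trend` per time unit, and
#' the initial-state mean `m0` and variance `c0`.  The time unit is tagged
#' explicitly so that monthly-grid estimates and annualized summaries
#' cannot be confused.
#'
#' @param sigma_e2 Observation noise variance (score^2), >= 0.
#' @param sigma_dt2 True-change variance per `time_unit` (score^2/unit), >= 0.
#' @param trend Mean progression per `time_unit` (score/unit).
#' @param m0 Initial latent-state mean (score).
#' @param c0 Initial latent-state variance (score^2), >= 0.
#' @param time_unit `"month"` or `"year"`.
#'
#' @return An object of class `model_params` (a named list).
#' @seealso [annualize()], [deannualize()], [fit_mle()]
#' @export
#' @examples
#' p <- model_params(sigma_e2 = 3.66, sigma_dt2 = 7.22 / 12,
#'                   trend = 1.03 / 12, m0 = 5.7, c0 = 17.6)
#' annualize(p)
model_params <- function(sigma_e2, sigma_dt2, trend, m0, c0,
                         time_unit = c("month", "year")) {
  time_unit <- match.arg(time_unit)
  vals <- c(sigma_e2 = sigma_e2, sigma_dt2 = sigma_dt2, trend = trend,
            m0 = m0, c0 = c0)
  if (any(!is.finite(vals)))
    stop("model parameters must be finite numbers")
  if (sigma_e2 < 0 || sigma_dt2 < 0 || c0 < 0)
    stop("variances sigma_e2, sigma_dt2 and c0 must be non-negative")
  structure(list(sigma_e2 = sigma_e2, sigma_dt2 = sigma_dt2, trend = trend,
                 m0 = m0, c0 = c0, time_unit = time_unit),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(
    "Latent progression parameters (per %s):\n", x$time_unit))
  cat(sprintf("  sigma_e2  (measurement error variance) : %.4g\n", x$sigma_e2))
  cat(sprintf("  sigma_dt2 (true change variance)       : %.4g\n", x$sigma_dt2))
  cat(sprintf("  trend     (mean progression)           : %.4g\n", x$trend))
  cat(sprintf("  m0, c0    (initial state mean, var)    : %.4g, %.4g\n",
              x$m0, x$c0))
  invisible(x)
}

#' Convert parameters between the monthly grid and annual units
#'
#' The latent state evolves on a monthly grid; results are conventionally
#' reported per year of follow-up.  Both the true-change variance and the
#' trend accumulate linearly in time, so the conversion multiplies (or
#' divides) them by 12; `sigma_e2`, `m0` and `c0` are per-assessment
#' quantities and are unchanged.  `deannualize()` is the exact inverse of
#' `annualize()`.
#'
#' @param params A [model_params()] object tagged `"month"` (for
#'   `annualize`) or `"year"` (for `deannualize`).
#' @return A [model_params()] object in the other time unit.
#' @export
annualize <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$time_unit != "month")
    stop("annualize() expects parameters on the monthly grid")
  model_params(params$sigma_e2, params$sigma_dt2 * 12, params$trend * 12,
               params$m0, params$c0, time_unit = "year")
}

#' @rdname annualize
#' @export
deannualize <- function(params) {
  stopifnot(inherits(params, "model_params"))
  if (params$time_unit != "year")
    stop("deannualize() expects annualized parameters")
  model_params(params$sigma_e2, params$sigma_dt2 / 12, params$trend / 12,
               params$m0, params$c0, time_unit = "month")
}

#' Reference parameter estimates from the PPMI de novo cohort
#'
#' Published state-space parameter estimates (with 95% bootstrap
#' confidence intervals) for the MDS-UPDRS subscales and factor scores in
#' the PPMI de novo Parkinson's disease cohort, annualized.  They serve two
#' purposes here: as the default ground-truth parameters of the synthetic
#' cohort generator (see [generator_config()]), and as the reference point
#' for the reliability algebra, since
#' `within_subject_reliability(sigma_dt2, sigma_e2)` applied to each row
#' reproduces the reported within-subject reliability `r_dd`.
#'
#' `m0` and `c0` are baseline score means and variances for the subscales
#' (part III ON is a generator default: the OFF baseline mean minus a
#' symptomatic-benefit offset of 6 points); factor rows carry `NA` because
#' factor subscores are not simulated by default.
#'
#' @return A data frame with one row per scale: `scale_id`, `label`,
#'   `sigma_e2` (+ `_lo`/`_hi` CI bounds), `sigma_dt2` (annual, +
#'   CI bounds), `trend` (annual, + CI bounds), `r_dd` (+ CI bounds),
#'   `m0`, `c0`.
#' @export
#' @examples
#' ref <- ppmi_reference_params()
#' with(ref[ref$scale_id == "part2", ],
#'      within_subject_reliability(sigma_dt2, sigma_e2))
ppmi_reference_params <- function() {
  tab <- read.csv(text = "
scale_id,label,sigma_e2,sigma_e2_lo,sigma_e2_hi,sigma_dt2,sigma_dt2_lo,sigma_dt2_hi,trend,trend_lo,trend_hi,r_dd,r_dd_lo,r_dd_hi
part1,Part I,4.87,4.41,5.42,4.22,3.35,5.17,0.92,0.82,1.02,0.30,0.25,0.36
part2,Part II,3.66,3.15,4.19,7.22,5.96,8.52,1.03,0.91,1.16,0.50,0.43,0.56
part3_off,Part III (OFF),15.52,12.16,19.24,31.13,24.14,38.73,2.63,2.34,2.94,0.50,0.40,0.60
part3_on,Part III (ON),27.07,17.22,35.66,16.15,7.44,36.14,1.04,0.55,1.48,0.23,0.10,0.43
factor:F1.1,F1.1 other nonmotor,0.29,0.26,0.32,0.15,0.12,0.17,0.15,0.13,0.17,0.20,0.17,0.24
factor:F1.2,F1.2 affective,0.41,0.35,0.47,0.16,0.11,0.21,0.03,0.01,0.05,0.16,0.11,0.22
factor:F1.3,F1.3 cognitive,0.30,0.25,0.35,0.26,0.16,0.39,0.13,0.10,0.16,0.30,0.20,0.43
factor:F2.1,F2.1 mobility,0.16,0.14,0.19,0.27,0.22,0.34,0.17,0.15,0.20,0.45,0.38,0.53
factor:F2.2,F2.2 swallowing speech,0.23,0.20,0.25,0.15,0.12,0.19,0.09,0.07,0.11,0.25,0.21,0.31
factor:F2.3,F2.3 tremor,0.28,0.26,0.31,0.21,0.17,0.26,0.02,0.00,0.04,0.27,0.22,0.32
factor:F3.1,F3.1 bradykinesia left,0.14,0.11,0.16,0.10,0.08,0.13,0.11,0.09,0.14,0.27,0.20,0.35
factor:F3.2,F3.2 bradykinesia right,0.22,0.17,0.27,0.13,0.08,0.18,0.11,0.08,0.13,0.23,0.14,0.33
factor:F3.3,F3.3 gait and posture,0.11,0.08,0.14,0.35,0.19,0.51,0.10,0.07,0.14,0.62,0.44,0.75
factor:F3.4,F3.4 rest tremor,0.19,0.15,0.23,0.28,0.20,0.37,0.10,0.08,0.13,0.43,0.33,0.54
factor:F3.5,F3.5 rigidity,0.26,0.21,0.30,0.17,0.12,0.23,0.08,0.05,0.11,0.25,0.18,0.34
factor:F3.6,F3.6 other bradykinesia,0.29,0.25,0.34,0.10,0.07,0.14,0.05,0.03,0.08,0.15,0.09,0.21
factor:F3.7,F3.7 postural kinetic tremor,0.43,0.36,0.49,0.13,0.08,0.19,-0.01,-0.04,0.01,0.13,0.08,0.19
", stringsAsFactors = FALSE)
  base <- c(part1 = 5.8, part2 = 5.7, part3_off = 20.3, part3_on = 20.3 - 6)
  bsd <- c(part1 = 4.2, part2 = 4.2, part3_off = 8.9, part3_on = 8.9)
  tab$m0 <- unname(base[tab$scale_id])
  tab$c0 <- unname(bsd[tab$scale_id]^2)
  tab
}
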