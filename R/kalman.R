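#' Kalman filter log-likelihood of a monthly series
#'
#' Exact Gaussian log marginal likelihood of the observed entries of one
#' patient's series under the local level model with drift: the latent
#' severity follows a random walk, theta_t = theta_{t-1} + w_t with
#' w_t ~ N(trend, sigma_dt2) per month, starting from
#' theta_0 ~ N(m0, c0), and each observation is y_t = theta_t + v_t with
#' v_t ~ N(0, sigma_e2).  Months without measurements are handled exactly:
#' the state prediction propagates (mean += trend, variance += sigma_dt2)
#' with no measurement update.  The first observation receives no
#' transition step before it: y at month 0 is distributed N(m0, c0 +
#' sigma_e2).  A series with no observations has log-likelihood 0.
#'
#' @param y Numeric vector with `NA` for missing months, indexed from
#'   month 0 (i.e. `y[1]` is month 0), or a sparse series if `months` is
#'   given.
#' @param params [model_params()] on the monthly grid.
#' @param months Optional integer months corresponding to the entries of
#'   `y`; defaults to `seq_along(y) - 1`.
#' @return The log-likelihood (a scalar).
#' @seealso [kalman_smooth()], [fit_mle()]
#' @export
#' @examples
#' p <- model_params(1, 0.5, 0.1, 5, 0)
#' kalman_loglik(c(5, NA, 5.2), p)
kalman_loglik <- function(y, params, months = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (params$time_unit != "month")
    stop("kalman_loglik() expects monthly-grid parameters")
  if (is.null(months)) months <- seq_along(y) - 1L
  if (length(months) != length(y)) stop("months and y lengths differ")
  .kf_loglik_mat(matrix(y, ncol = 1), as.integer(months), params)
}

# Vectorized-across-patients Kalman filter on an arbitrary increasing
# month grid.  Y: length(months) x n matrix with NA for missing; between
# consecutive rows the prediction step is applied in closed form over the
# month gap.  Patients' series effectively end at their last observation
# (trailing NAs contribute nothing).  Returns the total log-likelihood.
.kf_loglik_mat <- function(Y, months, params) {
  if (is.unsorted(months, strictly = TRUE))
    stop("months must be strictly increasing")
  if (any(months < 0)) stop("months must be >= 0")
  n <- ncol(Y)
  se2 <- params$sigma_e2; sd2 <- params$sigma_dt2
  m <- rep(params$m0, n); C <- rep(params$c0, n)
  ll <- 0; prev <- 0L
  for (r in seq_along(months)) {
    gap <- months[r] - prev
    if (gap > 0) {
      m <- m + gap * params$trend
      C <- C + gap * sd2
    }
    prev <- months[r]
    obs <- which(!is.na(Y[r, ]))
    if (length(obs)) {
      Fv <- pmax(C[obs] + se2, 1e-300)
      v <- Y[r, obs] - m[obs]
      ll <- ll - 0.5 * sum(log(2 * pi * Fv) + v * v / Fv)
      K <- C[obs] / Fv
      m[obs] <- m[obs] + K * v
      C[obs] <- C[obs] * (1 - K)
    }
  }
  ll
}

# Forward filter on the dense monthly grid for a single series; returns
# predicted/filtered moments per month plus innovations at observed months.
.kf_forward <- function(y, params) {
  Tn <- length(y)
  a <- Rv <- m <- C <- numeric(Tn)      # predicted and filtered moments
  innov <- innov_var <- rep(NA_real_, Tn)
  se2 <- params$sigma_e2
  for (t in seq_len(Tn)) {
    if (t == 1) {
      a[t] <- params$m0; Rv[t] <- params$c0
    } else {
      a[t] <- m[t - 1] + params$trend
      Rv[t] <- C[t - 1] + params$sigma_dt2
    }
    if (!is.na(y[t])) {
      Fv <- max(Rv[t] + se2, 1e-300)
      v <- y[t] - a[t]
      innov[t] <- v; innov_var[t] <- Fv
      K <- Rv[t] / Fv
      m[t] <- a[t] + K * v
      C[t] <- Rv[t] * (1 - K)
    } else {
      m[t] <- a[t]; C[t] <- Rv[t]
    }
  }
  list(a = a, R = Rv, m = m, C = C, innov = innov, innov_var = innov_var)
}

#' Fixed-interval smoother for the latent progression path
#'
#' Rauch-Tung-Striebel smoothing under the same model as
#' [kalman_loglik()]: posterior mean and variance of the latent state
#' theta_t given the whole series, for every month from 0 to the last
#' month, including missing months.  The smoothed variance never exceeds
#' the filtered variance.
#'
#' @inheritParams kalman_loglik
#' @return A data frame of class `latent_path` with columns `month`,
#'   `state_mean`, `state_var` (smoothed), `filtered_mean`, `filtered_var`
#'   and `observed`.
#' @export
kalman_smooth <- function(y, params, months = NULL) {
  stopifnot(inherits(params, "model_params"))
  if (params$time_unit != "month")
    stop("kalman_smooth() expects monthly-grid parameters")
  if (!is.null(months)) {
    dense <- rep(NA_real_, max(months) + 1)
    dense[months + 1] <- y
    y <- dense
  }
  f <- .kf_forward(y, params)
  Tn <- length(y)
  s <- Sv <- numeric(Tn)
  s[Tn] <- f$m[Tn]; Sv[Tn] <- f$C[Tn]
  if (Tn > 1) {
    for (t in (Tn - 1):1) {
      B <- if (f$R[t + 1] > 0) f$C[t] / f$R[t + 1] else 0
      s[t] <- f$m[t] + B * (s[t + 1] - f$a[t + 1])
      Sv[t] <- f$C[t] + B^2 * (Sv[t + 1] - f$R[t + 1])
    }
  }
  structure(data.frame(month = 0:(Tn - 1), state_mean = s,
                       state_var = pmax(Sv, 0),
                       filtered_mean = f$m, filtered_var = f$C,
                       observed = !is.na(y)),
            class = c("latent_path", "data.frame"))
}
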