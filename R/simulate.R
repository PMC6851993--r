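#' Configuration for the synthetic PPMI-like cohort generator
#'
#' Collects everything the generator needs to emulate a de novo
#' Parkinson's disease cohort with the PPMI visit structure: population
#' size, per-scale ground-truth parameters, visit schedules, monotone
#' dropout, the timing of dopaminergic therapy start and of the last dose
#' before annual motor exams, and an optional extra noise term for
#' assessments performed shortly after a dose.
#'
#' Defaults: 423 patients; per-scale parameters from
#' [ppmi_reference_params()] (annual values, deannualized onto the monthly
#' grid; baseline means/SDs as `m0`/`c0`); the 14-visit schedule of
#' [default_schedule()] for parts I/II and [annual_schedule()] for the
#' part III conditions; a per-visit dropout hazard of 0.0125 (about 85%
#' of patients still in follow-up at month 61); therapy start uniform
#' over months 2-24 (no patient is treated at inclusion); hours since
#' last dose at annual OFF exams log-normal with median 14 h; ON exams
#' about 1 hour postdose.
#'
#' @param n_patients Number of patients.
#' @param scales Character vector of scales to generate (subset of
#'   `part1`, `part2`, `part3_off`, `part3_on`).
#' @param params Named list of annual-unit [model_params()] overriding the
#'   reference defaults per scale.
#' @param schedule,part3_schedule Visit months for parts I/II and for the
#'   part III conditions.
#' @param dropout_hazard Per-visit probability of permanent loss to
#'   follow-up after baseline.
#' @param dt_start_range Months between which therapy starts (uniform).
#' @param postdose_meanlog,postdose_sdlog Log-normal parameters of hours
#'   since last dose at OFF exams for treated patients.
#' @param dose_noise_extra Extra observation noise s.d. added to part III
#'   OFF scores observed at most `dose_window` hours postdose (default 0:
#'   faithful to the measurement model).
#' @param dose_window Hours defining "shortly after a dose".
#' @param seed Integer seed; mandatory for every stochastic call.
#' @return A list of class `generator_config`.
#' @seealso [simulate_cohort()]
#' @export
generator_config <- function(n_patients = 423,
                             scales = c("part1", "part2", "part3_off",
                                        "part3_on"),
                             params = list(),
                             schedule = default_schedule(),
                             part3_schedule = annual_schedule(),
                             dropout_hazard = 0.0125,
                             dt_start_range = c(2, 24),
                             postdose_meanlog = log(14),
                             postdose_sdlog = 0.5,
                             dose_noise_extra = 0,
                             dose_window = 14,
                             seed = NULL) {
  scales <- match.arg(scales, several.ok = TRUE)
  if (is.null(seed)) stop("an explicit integer seed is required")
  if (dropout_hazard < 0 || dropout_hazard > 1)
    stop("dropout_hazard must be a probability")
  if (is.unsorted(schedule, strictly = TRUE) ||
      is.unsorted(part3_schedule, strictly = TRUE))
    stop("schedules must be strictly increasing")
  if (dose_noise_extra < 0) stop("dose_noise_extra must be >= 0")
  ref <- ppmi_reference_params()
  full <- list()
  for (sc in scales) {
    if (!is.null(params[[sc]])) {
      p <- params[[sc]]
      stopifnot(inherits(p, "model_params"))
      if (p$time_unit != "year")
        stop("generator parameters must be annual-unit model_params")
      full[[sc]] <- p
    } else {
      row <- ref[ref$scale_id == sc, ]
      full[[sc]] <- model_params(row$sigma_e2, row$sigma_dt2, row$trend,
                                 row$m0, row$c0, time_unit = "year")
    }
  }
  structure(list(n_patients = as.integer(n_patients), scales = scales,
                 params = full, schedule = as.integer(schedule),
                 part3_schedule = as.integer(part3_schedule),
                 dropout_hazard = dropout_hazard,
                 dt_start_range = dt_start_range,
                 postdose_meanlog = postdose_meanlog,
                 postdose_sdlog = postdose_sdlog,
                 dose_noise_extra = dose_noise_extra,
                 dose_window = dose_window,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Simulate a PPMI-like longitudinal cohort with known ground truth
#'
#' Draws, for each scale and patient, a latent monthly severity path
#' theta (random walk with drift: theta_0 ~ N(m0, c0), monthly increments
#' N(trend/12, sigma_dt2/12) from the annual parameters) and observes it
#' with N(0, sigma_e2) noise at the scheduled, non-dropped-out visits.
#' Dropout is monotone (a lost patient has no later visits on any scale).
#' Part III OFF rows exist at screening and annual visits and carry hours
#' since last dose (untreated patients: `NA`); rows failing the washout
#' criterion are still emitted — selection happens at fitting time.  Part
#' III ON rows exist at annual visits for treated patients only, about 1
#' hour postdose, and are generated from their own independent latent
#' path whose parameters default to the ON reference row (baseline mean
#' lowered by a symptomatic-benefit offset).  Scores are kept continuous
#' and unclipped, as the measurement model is Gaussian.
#'
#' The output is a deterministic function of `(config, seed)`.
#'
#' @param config A [generator_config()].
#' @return A list: `cohort` (a [cohort_table()]) and `truth` (per-scale
#'   true latent paths as months x patients matrices, the true annual
#'   parameters, therapy start months, dropout months).
#' @export
#' @examples
#' sim <- simulate_cohort(generator_config(n_patients = 25, seed = 7,
#'                                         scales = "part2"))
#' table(sim$cohort$month)
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_patients
  .with_seed(config$seed, {
    pats <- sprintf("P%04d", seq_len(n))
    sched <- config$schedule
    # monotone dropout: first lost visit index (beyond the last = retained)
    if (config$dropout_hazard > 0) {
      ndrops <- stats::rgeom(n, config$dropout_hazard)  # visits survived after baseline
      drop_after <- ifelse(ndrops >= length(sched) - 2, Inf,
                           sched[2 + ndrops])  # month of last attended visit
    } else {
      drop_after <- rep(Inf, n)
    }
    dt_start <- sample(seq(config$dt_start_range[1],
                           config$dt_start_range[2]), n, replace = TRUE)

    horizon <- max(sched, config$part3_schedule)
    rows <- list(); truth_paths <- list()
    for (sc in config$scales) {
      pa <- deannualize(config$params[[sc]])
      theta <- matrix(0, horizon + 1, n)
      theta[1, ] <- stats::rnorm(n, pa$m0, sqrt(pa$c0))
      for (t in seq_len(horizon))
        theta[t + 1, ] <- theta[t, ] +
          stats::rnorm(n, pa$trend, sqrt(pa$sigma_dt2))
      truth_paths[[sc]] <- theta

      vis <- if (sc %in% c("part3_off", "part3_on"))
        config$part3_schedule else sched
      for (m in vis) {
        alive <- drop_after >= m | m == 0
        treated <- dt_start <= m
        if (sc == "part3_on") {
          use <- alive & treated & m > 0
          if (!any(use)) next
          hours <- stats::runif(sum(use), 0.5, 2)
          ont <- TRUE
        } else if (sc == "part3_off") {
          use <- alive
          hours <- rep(NA_real_, sum(use))
          trt <- treated[use]
          hours[trt] <- stats::rlnorm(sum(trt), config$postdose_meanlog,
                                      config$postdose_sdlog)
          ont <- trt
        } else {
          use <- alive
          hours <- rep(NA_real_, sum(use))
          ont <- treated[use]
        }
        y <- theta[m + 1, use] + stats::rnorm(sum(use), 0, sqrt(pa$sigma_e2))
        if (sc == "part3_off" && config$dose_noise_extra > 0) {
          short <- !is.na(hours) & hours <= config$dose_window
          y[short] <- y[short] +
            stats::rnorm(sum(short), 0, config$dose_noise_extra)
        }
        rows[[length(rows) + 1]] <- data.frame(
          patient_id = pats[use], month = m, scale_id = sc, subtotal = y,
          hours_postdose = hours, on_therapy = ont)
      }
    }
    records <- do.call(rbind, rows)
    cohort <- cohort_table(records,
                           sort(unique(c(sched, config$part3_schedule))))
    list(cohort = cohort,
         truth = list(paths = truth_paths, params = config$params,
                      dt_start = stats::setNames(dt_start, pats),
                      drop_after = stats::setNames(drop_after, pats)))
  })
}

#' Simulate item-level scores from a planted factor structure
#'
#' Generates pooled visit rows of discrete 0-4 item scores from a planted
#' simple-structure loading matrix: continuous scores
#' `loadings %*% factors + unique noise` are shifted to a mean of 2,
#' rounded to integers and clipped into 0..4, emulating rating-scale
#' items.  The planted loadings and latent factor draws are returned for
#' recovery tests.
#'
#' @param n_rows Number of pooled visit rows.
#' @param loadings Items x factors matrix; each item should load mostly
#'   on one factor (simple structure).  Default: 11 items on 3 factors
#'   (blocks of 4/4/3) with loading 0.8.
#' @param unique_sd Unique-noise standard deviation per item; default
#'   completes unit variance given the planted loadings.
#' @param seed Integer seed (mandatory).
#' @return List with `items` (n_rows x n_items integer matrix),
#'   `loadings` (planted), `factors` (n_rows x k latent draws).
#' @export
simulate_items <- function(n_rows, loadings = NULL, unique_sd = NULL,
                           seed = NULL) {
  if (is.null(seed)) stop("an explicit integer seed is required")
  if (is.null(loadings)) {
    loadings <- matrix(0, 11, 3)
    loadings[1:4, 1] <- 0.8; loadings[5:8, 2] <- 0.8; loadings[9:11, 3] <- 0.8
  }
  loadings <- as.matrix(loadings)
  if (ncol(loadings) > nrow(loadings))
    stop("loading matrix cannot be wider than the number of items")
  comm <- rowSums(loadings^2)
  if (is.null(unique_sd)) unique_sd <- sqrt(pmax(1 - comm, 0.05))
  unique_sd <- rep_len(unique_sd, nrow(loadings))
  .with_seed(seed, {
    k <- ncol(loadings); p <- nrow(loadings)
    f <- matrix(stats::rnorm(n_rows * k), n_rows, k)
    x <- f %*% t(loadings) +
      matrix(stats::rnorm(n_rows * p), n_rows, p) %*% diag(unique_sd, p)
    items <- pmin(pmax(round(x + 2), 0), 4)
    colnames(items) <- sprintf("item_%d", seq_len(p))
    list(items = items, loadings = loadings, factors = f)
  })
}

#' Plant an extra postdose noise effect into a cohort
#'
#' Adds independent `N(0, extra_sd^2)` noise to part III OFF observations
#' taken at most `window` hours after the last dose, leaving every other
#' record untouched.  Used to create a known ground-truth effect for the
#' washout-threshold comparison machinery.
#'
#' @param cohort A [cohort_table()].
#' @param extra_sd Extra noise standard deviation (score units), >= 0.
#' @param window Hours defining the affected postdose interval.
#' @param seed Integer seed (mandatory when `extra_sd > 0`).
#' @return The modified [cohort_table()]; unchanged when `extra_sd = 0`.
#' @export
inject_dose_effect <- function(cohort, extra_sd, window = 14, seed = NULL) {
  stopifnot(inherits(cohort, "cohort_table"), extra_sd >= 0)
  if (extra_sd == 0) return(cohort)
  if (is.null(seed)) stop("an explicit integer seed is required")
  sel <- cohort$scale_id == "part3_off" &
    !is.na(cohort$hours_postdose) & cohort$hours_postdose <= window
  .with_seed(seed, {
    cohort$subtotal[sel] <- cohort$subtotal[sel] +
      stats::rnorm(sum(sel), 0, extra_sd)
  })
  cohort
}
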