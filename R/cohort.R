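#' Default visit schedules
#'
#' The full visit schedule used for parts I and II: a screening visit at
#' month 0, baseline at month 1, 3-month intervals during the first year
#' and 6-month intervals thereafter up to 5 years after baseline.  The
#' motor exam in the practically defined OFF state is scripted only at
#' screening and at annual visits, giving the reduced annual schedule; the
#' ON assessment (about 1 hour postdose) exists only at annual visits
#' after baseline.
#'
#' @return Integer vector of visit months since screening.
#' @export
default_schedule <- function() {
  as.integer(c(0, 1, 4, 7, 10, 13, 19, 25, 31, 37, 43, 49, 55, 61))
}

#' @rdname default_schedule
#' @param include_screening Include month 0 (OFF exists there because no
#'   patient is on therapy at inclusion; ON does not).
#' @export
annual_schedule <- function(include_screening = TRUE) {
  m <- as.integer(c(13, 25, 37, 49, 61))
  if (include_screening) c(0L, m) else m
}

.known_scales <- function() c("part1", "part2", "part3_off", "part3_on")

#' Construct a cohort table of longitudinal visit records
#'
#' A cohort table is a long-format data frame of visit records: one row
#' per (patient, month, scale) with the observed subtotal, optional
#' item-level scores (columns `item_1 ... item_k`, integers 0-4), hours
#' since the last dopaminergic dose (`NA` for untreated patients) and the
#' therapy flag.  Months are integers since screening (screening = 0,
#' baseline = 1); every month must belong to the visit schedule —
#' unscheduled months between visits are represented as missing, not as
#' rows.
#'
#' @param records Data frame with columns `patient_id`, `month`,
#'   `scale_id`, `subtotal`, optionally `item_1...item_k`,
#'   `hours_postdose`, `on_therapy`.
#' @param schedule Integer vector of scheduled visit months.
#' @return The validated records with class `cohort_table` and a
#'   `schedule` attribute.
#' @seealso [read_cohort()], [to_monthly_series()]
#' @export
cohort_table <- function(records, schedule) {
  if (length(schedule) == 0) stop("schedule must be nonempty")
  schedule <- sort(unique(as.integer(schedule)))
  records <- as.data.frame(records)
  req <- c("patient_id", "month", "scale_id", "subtotal")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "))
  if (!"hours_postdose" %in% names(records))
    records$hours_postdose <- NA_real_
  if (!"on_therapy" %in% names(records))
    records$on_therapy <- FALSE
  records$patient_id <- as.character(records$patient_id)
  records$month <- as.integer(records$month)
  records$on_therapy <- as.logical(records$on_therapy)
  records$subtotal <- as.numeric(records$subtotal)
  if (is.character(records$hours_postdose)) {
    records$hours_postdose[records$hours_postdose == "untreated"] <- NA
  }
  records$hours_postdose <- as.numeric(records$hours_postdose)

  if (nrow(records)) {
    bad <- which(!(records$month %in% schedule) | records$month < 0)
    if (length(bad))
      stop("rows with months outside the visit schedule: ",
           paste(utils::head(bad, 5), collapse = ", "))
    key <- paste(records$patient_id, records$month, records$scale_id)
    if (anyDuplicated(key))
      stop("duplicate (patient, month, scale) records: row ",
           which(duplicated(key))[1])
    itemcols <- grep("^item_[0-9]+$", names(records), value = TRUE)
    if (length(itemcols)) {
      items <- as.matrix(records[itemcols])
      vals <- items[!is.na(items)]
      if (length(vals) && (any(vals != round(vals)) ||
                           any(vals < 0) || any(vals > 4)))
        stop("item scores must be integers in 0..4")
      # subtotal must equal the item sum on rows carrying a full item set
      full <- rowSums(is.na(items)) == 0
      if (any(full)) {
        dd <- abs(rowSums(items[full, , drop = FALSE]) -
                    records$subtotal[full])
        if (any(dd > 1e-8))
          stop("subtotal disagrees with the item sum at row ",
               which(full)[which(dd > 1e-8)[1]])
      }
    }
    hp <- records$hours_postdose
    if (any(!is.na(hp) & hp < 0)) stop("hours_postdose must be >= 0")
  }
  structure(records, schedule = schedule,
            class = c("cohort_table", "data.frame"))
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf(
    "Cohort table: %d records, %d patients, scales: %s\n",
    nrow(x), n_patients(x),
    paste(sort(unique(x$scale_id)), collapse = ", ")))
  cat("Visit schedule (months):",
      paste(attr(x, "schedule"), collapse = " "), "\n")
  NextMethod()
}

#' Number of distinct patients in a cohort table
#' @param cohort A [cohort_table()].
#' @return Integer count.
#' @export
n_patients <- function(cohort) length(unique(cohort$patient_id))

#' Read / write a long-format cohort CSV
#'
#' The interchange format is comma-delimited UTF-8 with a header and the
#' `cohort_table` columns; missing values are empty fields.  All
#' validation of [cohort_table()] is applied on read, naming the offending
#' row.  `write_cohort()` followed by `read_cohort()` round-trips the
#' table.
#'
#' @param path File path.
#' @param schedule Integer vector of scheduled visit months.
#' @return `read_cohort()`: a [cohort_table()]; `write_cohort()`: the path,
#'   invisibly.
#' @export
read_cohort <- function(path, schedule) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    df <- data.frame(patient_id = character(), month = integer(),
                     scale_id = character(), subtotal = numeric(),
                     hours_postdose = numeric(), on_therapy = logical())
  }
  cohort_table(df, schedule)
}

#' @rdname read_cohort
#' @param cohort A [cohort_table()].
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Scale definitions and weighted subtotals
#'
#' A scale definition names the items of a (sub)scale and the weight each
#' item carries in the subtotal: 1 for plain sums, factor loadings for
#' factor subscores.
#'
#' @param scale_id Scale identifier.
#' @param item_ids Character vector of item names (nonempty).
#' @param weights Per-item weights, finite; defaults to unit weights.
#' @return An object of class `scale_definition`.
#' @export
scale_definition <- function(scale_id, item_ids,
                             weights = rep(1, length(item_ids))) {
  if (length(item_ids) == 0) stop("item_ids must be nonempty")
  if (length(weights) != length(item_ids))
    stop("weights and item_ids lengths differ")
  if (any(!is.finite(weights))) stop("weights must be finite")
  structure(list(scale_id = scale_id, item_ids = as.character(item_ids),
                 max_item_score = 4L, weights = as.numeric(weights)),
            class = "scale_definition")
}

#' Weighted subtotal of item scores
#'
#' Computes `sum(weights * item_scores)`; with unit weights this is the
#' plain subscale subtotal obtained by summing all items.
#'
#' @param item_scores Integer scores, each in 0..4, one per item.
#' @param definition A [scale_definition()].
#' @return Numeric subtotal.
#' @export
#' @examples
#' compute_subtotal(c(1, 2, 3), scale_definition("x", c("a", "b", "c")))
compute_subtotal <- function(item_scores, definition) {
  stopifnot(inherits(definition, "scale_definition"))
  if (length(item_scores) != length(definition$item_ids))
    stop("expected ", length(definition$item_ids), " item scores, got ",
         length(item_scores))
  sum(definition$weights * item_scores)
}

#' Classify the medication state of a motor assessment
#'
#' An assessment counts as OFF when the patient receives no dopaminergic
#' therapy at all, or was assessed strictly more than `threshold` hours
#' after the last dose.  An assessment counts as ON when the patient is on
#' therapy and was assessed strictly less than 6 hours postdose.
#' Comparisons are strict, so equality at the boundary satisfies neither
#' definition.  Untreated patients are encoded as `hours_postdose = NA`
#' with `on_therapy = FALSE` (the string `"untreated"` is also accepted).
#'
#' @param hours_postdose Hours since last dose (numeric), `NA` or
#'   `"untreated"` for patients without dopaminergic therapy.
#' @param threshold Washout threshold in hours (> 0); default 6.
#' @return Logical, vectorized over `hours_postdose`.
#' @export
#' @examples
#' classify_off_state(c(NA, 5.9, 14.5), threshold = 6)
classify_off_state <- function(hours_postdose, threshold = 6) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be a positive number of hours")
  if (is.character(hours_postdose)) {
    untreated <- hours_postdose == "untreated"
    hours_postdose[untreated] <- NA
    hours_postdose <- as.numeric(hours_postdose)
  }
  if (any(hours_postdose < 0, na.rm = TRUE))
    stop("hours_postdose must be >= 0")
  is.na(hours_postdose) | hours_postdose > threshold
}

#' @rdname classify_off_state
#' @param on_therapy Logical: patient receiving dopaminergic therapy.
#' @export
classify_on_state <- function(hours_postdose, on_therapy) {
  if (any(hours_postdose < 0, na.rm = TRUE))
    stop("hours_postdose must be >= 0")
  !is.na(on_therapy) & on_therapy &
    !is.na(hours_postdose) & hours_postdose < 6
}

#' Per-patient monthly series with explicit missing values
#'
#' Expands the sparse visit records of one scale onto the dense monthly
#' grid: for each patient, a numeric vector indexed month 0 .. last
#' observed month, with `NA` at every unobserved month and the observed
#' subtotals preserved exactly.
#'
#' @param cohort A [cohort_table()].
#' @param scale_id Scale to extract; must be present in the cohort.
#' @param off_threshold For `scale_id = "part3_off"`: washout threshold in
#'   hours; assessments failing [classify_off_state()] are treated as
#'   missing.  `NULL` disables the filter.
#' @return Named list, one numeric vector per patient; names of each
#'   vector are the months.
#' @export
to_monthly_series <- function(cohort, scale_id, off_threshold = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  sub <- cohort[cohort$scale_id == scale_id, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("scale '", scale_id, "' not present in cohort")
  if (!is.null(off_threshold)) {
    keep <- classify_off_state(sub$hours_postdose, off_threshold)
    sub <- sub[keep, , drop = FALSE]
  }
  out <- lapply(split(sub, sub$patient_id), function(d) {
    last <- max(d$month)
    y <- rep(NA_real_, last + 1)
    names(y) <- 0:last
    y[as.character(d$month)] <- d$subtotal
    y
  })
  out[order(names(out))]
}

# Dense months x patients observation matrix for one scale, on the union
# of observed months.  The workhorse representation behind fit_mle():
# a column per patient, NA where that patient has no usable observation.
.cohort_matrix <- function(cohort, scale_id, off_threshold = NULL) {
  stopifnot(inherits(cohort, "cohort_table"))
  sub <- cohort[cohort$scale_id == scale_id, , drop = FALSE]
  if (nrow(sub) == 0)
    stop("scale '", scale_id, "' not present in cohort")
  if (!is.null(off_threshold) && scale_id == "part3_off") {
    keep <- classify_off_state(sub$hours_postdose, off_threshold)
    sub <- sub[keep, , drop = FALSE]
  }
  months <- sort(unique(sub$month))
  pats <- sort(unique(sub$patient_id))
  Y <- matrix(NA_real_, length(months), length(pats),
              dimnames = list(months, pats))
  Y[cbind(match(sub$month, months), match(sub$patient_id, pats))] <-
    sub$subtotal
  list(Y = Y, months = months, patients = pats)
}
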