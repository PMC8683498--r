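## Cohort-level statistics: Kaplan-Meier estimation and medians (via the
## survival package), co-occurrence proportions, PET metabolic response,
## xenograft tumor volume and in vitro growth rate.

#' Kaplan-Meier survival curve from survival records
#'
#' Product-limit estimator over records of time (days) and event status
#' (TRUE = event observed, FALSE = censored). Ties of censored and event
#' times are processed events-first, the standard product-limit convention.
#' Confidence intervals are Greenwood-based on the log-log scale.
#'
#' @param records Data frame with columns \code{time} and \code{event}
#'   (logical or 0/1), e.g. \code{\link{packaged_survival_table}}.
#' @return A \code{km_curve}: list with \code{table} (data frame: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{n_censor}, \code{surv},
#'   \code{lower}, \code{upper}) and the underlying
#'   \code{\link[survival]{survfit}} object as \code{fit}.
#' @examples
#' km <- km_estimate(packaged_survival_table())
#' km$table
#' @export
km_estimate <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1,
            all(c("time", "event") %in% names(records)))
  if (any(records$time < 0)) stop("negative survival times")
  if (any(!records$event %in% c(0, 1, TRUE, FALSE)))
    stop("malformed event flags (need TRUE/FALSE or 0/1)")
  fit <- survival::survfit(
    survival::Surv(records$time, as.integer(records$event)) ~ 1,
    conf.type = "log-log")
  s <- summary(fit, censored = TRUE)
  tab <- data.frame(time = s$time, n_risk = s$n.risk, n_event = s$n.event,
                    n_censor = s$n.censor, surv = s$surv,
                    lower = s$lower, upper = s$upper)
  structure(list(table = tab, fit = fit), class = "km_curve")
}

#' Median survival time from a Kaplan-Meier curve
#'
#' The smallest event time at which the survival function drops to 0.5 or
#' below. When the curve never reaches 0.5 the median is undefined and
#' \code{NA} is returned (a typed outcome, not an error).
#'
#' @param curve A \code{km_curve} from \code{\link{km_estimate}}.
#' @return Median in days, or \code{NA} if undefined.
#' @examples
#' km_median(km_estimate(packaged_survival_table()))  # 239
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  tab <- curve$table
  hit <- tab$n_event > 0 & tab$surv <= 0.5 + 1e-12
  if (!any(hit)) return(NA_real_)
  min(tab$time[hit])
}

#' Convert days to months
#'
#' Uses the mean Gregorian month of 365.25/12 days.
#'
#' @param days Numeric days.
#' @return Months.
#' @export
days_to_months <- function(days) days * 12 / 365.25

#' Co-occurrence rate as a percentage with one decimal
#'
#' \code{100 k / n}, rounded half-up to one decimal place.
#'
#' @param k Number of co-occurrences (0 <= k <= n).
#' @param n Cohort size (>= 1).
#' @return Percentage rounded to one decimal.
#' @examples
#' cooccurrence_rate(26, 1951)  # 1.3
#' cooccurrence_rate(4, 184)    # 2.2
#' @export
cooccurrence_rate <- function(k, n) {
  if (any(n < 1)) stop("n must be >= 1")
  if (any(k < 0 | k > n)) stop("k must be in [0, n]")
  floor(1000 * k / n + 0.5) / 10
}

#' Classify PET metabolic response from SUVmax values
#'
#' Metabolic response is an SUVmax reduction of at least 30 percent in the
#' hottest lesion relative to baseline; the 30 percent boundary is inclusive.
#'
#' @param suv_baseline Baseline SUVmax (> 0).
#' @param suv_followup Follow-up SUVmax (>= 0).
#' @return \code{"response"} or \code{"non_response"} (vectorized).
#' @examples
#' classify_metabolic_response(10, 7)    # exactly 30% reduction -> response
#' classify_metabolic_response(10, 7.5)  # 25% -> non_response
#' @export
classify_metabolic_response <- function(suv_baseline, suv_followup) {
  if (any(suv_baseline <= 0)) stop("baseline SUVmax must be > 0")
  if (any(suv_followup < 0)) stop("follow-up SUVmax must be >= 0")
  reduction <- (suv_baseline - suv_followup) / suv_baseline
  ifelse(reduction >= 0.30 - 1e-12, "response", "non_response")
}

#' Xenograft tumor volume from caliper measurements
#'
#' \eqn{V = 0.5 \times length \times width^2}, with length the longest tumor
#' dimension and width the longest dimension perpendicular to it. Swapped
#' inputs (width > length) are auto-corrected with a warning.
#'
#' @param length_mm,width_mm Caliper measurements in mm.
#' @return Volume in cubic mm.
#' @examples
#' tumor_volume(10, 5)  # 125
#' @export
tumor_volume <- function(length_mm, width_mm) {
  if (any(length_mm < 0) || any(width_mm < 0))
    stop("dimensions must be >= 0")
  swap <- width_mm > length_mm
  if (any(swap)) {
    warning("width > length for ", sum(swap),
            " measurement(s); dimensions swapped")
    tmp <- length_mm[swap]
    length_mm[swap] <- width_mm[swap]
    width_mm[swap] <- tmp
  }
  0.5 * length_mm * width_mm^2
}

#' Growth rate from a daily cell-count series
#'
#' Counts are normalized to day 1 and the growth rate is the ordinary
#' least-squares slope of the normalized counts against the day index.
#'
#' @param counts Cell counts at consecutive daily time points (>= 3).
#' @param days Day indices (default \code{seq_along(counts)}).
#' @return Slope in normalized counts per day.
#' @examples
#' growth_rate(c(1, 2, 3, 4, 5) * 1e5)  # 1
#' @export
growth_rate <- function(counts, days = seq_along(counts)) {
  if (length(counts) < 3) stop("need at least 3 time points")
  if (counts[1] == 0) stop("day-1 count is zero; cannot normalize")
  y <- counts / counts[1]
  unname(stats::coef(stats::lm(y ~ days))[2])
}

#' @export
print.km_curve <- function(x, ...) {
  med <- km_median(x)
  cat("Kaplan-Meier curve,", sum(x$table$n_event), "events /",
      x$fit$n, "subjects\n")
  cat("median:", if (is.na(med)) "undefined"
      else paste0(med, " days (", round(days_to_months(med), 2), " months)"),
      "\n")
  invisible(x)
}
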