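#' Kaplan-Meier estimate of a survival curve
#'
#' Product-limit estimator with right censoring (via [survival::survfit()]),
#' returned as a tidy step curve with at-risk counts and optional Greenwood
#' pointwise confidence intervals on the log scale.
#'
#' @param time Event/censoring times (months, non-negative).
#' @param event Event indicators (1 = event, 0 = censored); default all events.
#' @param conf_level Confidence level for the pointwise CIs.
#' @return Object of class `km_curve`: data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper` (one row per
#'   distinct observed time).
#' @export
km_estimate <- function(time, event = rep(1, length(time)),
                        conf_level = 0.95) {
  if (length(time) == 0L) stop("empty input", call. = FALSE)
  if (any(time < 0)) stop("times must be non-negative", call. = FALSE)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1,
                          conf.int = conf_level, conf.type = "log")
  out <- data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                    n_censor = sf$n.censor, surv = sf$surv,
                    lower = sf$lower, upper = sf$upper)
  out$lower[is.na(out$lower)] <- 0
  out$upper[is.na(out$upper)] <- 1
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' Right-continuous step interpolation: S(t) is the estimate at the last
#' event time not exceeding `t` (1 before the first observed time).
#'
#' @param curve A `km_curve` (or data frame with `time` and `surv`).
#' @param times Evaluation times.
#' @return Vector of survival probabilities.
#' @export
km_eval <- function(curve, times) {
  idx <- findInterval(times, curve$time)
  c(1, curve$surv)[idx + 1L]
}

#' Median and restricted mean of a survival curve
#'
#' The median is the first time at which the curve reaches 0.5 or below;
#' when the curve never crosses 0.5 the median is not reached and `NA` is
#' returned. The restricted mean is the area under the step curve up to
#' `horizon` (exact for the step function).
#'
#' @param curve A `km_curve`.
#' @return `km_median`: months, or `NA` (not reached).
#' @export
km_median <- function(curve) {
  i <- which(curve$surv <= 0.5)
  if (length(i) == 0L) return(NA_real_)
  curve$time[min(i)]
}

#' @rdname km_median
#' @param horizon Upper integration limit in months (> 0).
#' @return `restricted_mean`: months.
#' @export
restricted_mean <- function(curve, horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon <= 0)
    stop("horizon must be a single positive number", call. = FALSE)
  tt <- c(0, curve$time[curve$time < horizon], horizon)
  ss <- c(1, curve$surv[curve$time < horizon])
  sum(ss * diff(tt))
}

#' Sample a Kaplan-Meier curve on a grid, as if digitized from a figure
#'
#' Computes the full product-limit curve of a cohort, then records the
#' survival probabilities at the requested grid times and the numbers at risk
#' at the grid times — mimicking the information available from a published
#' survival figure with an at-risk table, which is the input format of
#' [reconstruct_ipd()].
#'
#' @param time,event Observed times and event indicators of the cohort.
#' @param grid Increasing vector of grid times (months); must be non-empty.
#' @return List with `curve` (data frame `time_months,survival`) and
#'   `at_risk` (data frame `time_months,n_at_risk`).
#' @export
generate_digitized_curve <- function(time, event = rep(1, length(time)),
                                     grid) {
  if (length(grid) == 0L) stop("empty grid", call. = FALSE)
  grid <- sort(unique(grid))
  km <- km_estimate(time, event)
  surv <- km_eval(km, grid)
  n_at_risk <- vapply(grid, function(g) sum(time >= g), numeric(1))
  list(curve = data.frame(time_months = grid, survival = surv),
       at_risk = data.frame(time_months = grid, n_at_risk = n_at_risk))
}
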