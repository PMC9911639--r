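#' Competing-event sampling by event-specific distributions
#'
#' Draws one event time per cause from its cause-specific model and selects
#' the cause that occurs first (the "event-specific distribution" device for
#' competing risks in discrete-event simulation: rather than jointly modelling
#' the event type, each competing transition keeps its own time-to-event law
#' and the minimum wins).
#'
#' Exact ties (a probability-zero event in continuous time, but possible in
#' floating point) are broken deterministically by `priority`: the earlier a
#' cause appears in `priority`, the higher its precedence. The default
#' priority is the order of `models`; pathway simulation places death before
#' next-line start.
#'
#' @param models Named list of samplers (`parametric_model` or
#'   `composite_hazard` objects), one per competing cause.
#' @param n Number of patients (independent draws per cause).
#' @param newdata Optional covariate data frame with 1 or `n` rows.
#' @param priority Character vector of cause names, highest precedence first.
#' @return A data frame with columns `event` (the winning cause name, or
#'   `"none"` when every draw is infinite) and `time` (months, possibly `Inf`).
#' @examples
#' m1 <- parametric_model("exponential", c(rate = 1))
#' m2 <- parametric_model("exponential", c(rate = 3))
#' set.seed(1)
#' table(sample_competing(list(a = m1, b = m2), 1000)$event) / 1000  # ~ 1:3
#' @export
sample_competing <- function(models, n, newdata = NULL,
                             priority = names(models)) {
  if (length(models) == 0L) stop("at least one competing model is required",
                                 call. = FALSE)
  if (is.null(names(models)) || any(!nzchar(names(models))))
    stop("models must be a named list", call. = FALSE)
  if (!setequal(priority, names(models)))
    stop("priority must be a permutation of the model names", call. = FALSE)
  draws <- vapply(models[priority], function(m)
    sample_event_time(m, n, newdata), numeric(n))
  if (n == 1L) draws <- matrix(draws, nrow = 1L,
                               dimnames = list(NULL, priority))
  tmin <- do.call(pmin, c(as.data.frame(draws), list(na.rm = FALSE)))
  # first cause (in priority order) attaining the minimum
  win <- priority[apply(draws <= tmin, 1L, which.max)]
  win[is.infinite(tmin)] <- "none"
  data.frame(event = win, time = tmin, stringsAsFactors = FALSE)
}

#' Compose a treatment benefit that wears out at a switch time
#'
#' Builds a piecewise hazard: the `pre` model's hazard applies before
#' `switch_time` (months on the line-specific clock) and the `post` model's
#' hazard — evaluated at the same line-local time — applies from `switch_time`
#' onwards. This encodes a limited treatment benefit: up to the switch the
#' patient progresses under the treatment-modified law, after it the
#' time-to-event function reverts to the unmodified baseline fit. Survival is
#' continuous at the switch because the cumulative hazard is
#' \deqn{H(t) = H_{pre}(\min(t,\tau)) + [H_{post}(t) - H_{post}(\tau)]_+ .}
#'
#' @param pre Model in force before the switch (typically the baseline model
#'   with a treatment hazard ratio applied).
#' @param post Model in force after the switch (typically the baseline model).
#' @param switch_time Non-negative switch time in months; `Inf` means the
#'   benefit is durable and `pre` applies forever.
#' @return An object of class `composite_hazard` supporting [hazard_rate()],
#'   [surv_prob()], [cum_hazard()] and [sample_event_time()].
#' @export
compose_wearout <- function(pre, post, switch_time) {
  stopifnot(inherits(pre, "parametric_model"), inherits(post, "parametric_model"))
  if (!is.numeric(switch_time) || length(switch_time) != 1L || switch_time < 0)
    stop("switch_time must be a single non-negative number (or Inf)",
         call. = FALSE)
  if (!identical(sort(names(pre$coefs)), sort(names(post$coefs))))
    stop("pre and post models must share the same covariate names",
         call. = FALSE)
  structure(list(pre = pre, post = post, switch_time = switch_time),
            class = "composite_hazard")
}

#' @export
print.composite_hazard <- function(x, ...) {
  cat(sprintf("Composite hazard: switch at %s months\n", format(x$switch_time)))
  cat("pre:  "); print(x$pre)
  cat("post: "); print(x$post)
  invisible(x)
}

composite_cumhaz_one <- function(object, t, newdata) {
  tau <- object$switch_time
  Hpre <- cum_hazard(object$pre, pmin(t, tau), newdata)
  extra <- numeric(length(t))
  over <- t > tau
  if (any(over)) {
    Hpost_tau <- cum_hazard(object$post, tau, newdata)
    extra[over] <- cum_hazard(object$post, t[over], newdata) - Hpost_tau
  }
  Hpre + extra
}

#' @export
cum_hazard.composite_hazard <- function(object, t, newdata = NULL, ...) {
  check_times(t)
  if (is.infinite(object$switch_time))
    return(cum_hazard(object$pre, t, newdata))
  composite_cumhaz_one(object, t, newdata)
}

#' @export
surv_prob.composite_hazard <- function(object, t, newdata = NULL, ...) {
  exp(-cum_hazard(object, t, newdata))
}

#' @export
hazard_rate.composite_hazard <- function(object, t, newdata = NULL, ...) {
  check_times(t)
  ifelse(t < object$switch_time,
         hazard_rate(object$pre, t, newdata),
         hazard_rate(object$post, t, newdata))
}

#' @export
sample_event_time.composite_hazard <- function(object, n, newdata = NULL, ...) {
  if (n == 0) return(numeric(0))
  tau <- object$switch_time
  if (is.infinite(tau)) return(sample_event_time(object$pre, n, newdata))
  if (tau == 0) return(sample_event_time(object$post, n, newdata))
  lp_pre <- linear_predictor(object$pre, newdata, n = n)
  lp_post <- linear_predictor(object$post, newdata, n = n)
  E <- stats::rexp(n)
  Hpre_tau <- base_ch_with_lp(object$pre, tau, lp_pre)
  out <- numeric(n)
  before <- E <= Hpre_tau
  out[before] <- invert_cumhaz(object$pre, E[before], lp_pre[before])
  if (any(!before)) {
    Hpost_tau <- base_ch_with_lp(object$post, tau, lp_post[!before])
    out[!before] <- invert_cumhaz(object$post,
                                  Hpost_tau + (E[!before] - Hpre_tau[!before]),
                                  lp_post[!before])
  }
  out
}

# cumulative hazard at scalar time t for vector lp (per-patient)
base_ch_with_lp <- function(model, t, lp) {
  if (is_ph(model)) {
    base_cumhaz(model, t) * exp(lp) * model$hr
  } else {
    -log(aft_base_surv(model, t * exp(-lp)))
  }
}
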