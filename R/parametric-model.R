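#' Parametric time-to-event model for one transition
#'
#' Constructs a parametric survival model describing the time (in months) to a
#' single transition of the disease pathway, optionally adjusted for baseline
#' covariates and an external hazard ratio.
#'
#' Five families are supported. The proportional-hazards (PH) families are
#' parameterized through their baseline cumulative hazard \eqn{H_0(t)}:
#' \describe{
#'   \item{exponential}{\eqn{H_0(t) = \lambda t}; parameter `rate` \eqn{\lambda > 0}.}
#'   \item{weibull}{PH form \eqn{H_0(t) = \lambda t^{\gamma}}; parameters
#'     `shape` \eqn{\gamma > 0} and `rate` \eqn{\lambda > 0} (this is the
#'     "weibullPH" parameterization, not the accelerated-failure-time form of
#'     [stats::rweibull]).}
#'   \item{gompertz}{\eqn{h_0(t) = \lambda e^{\gamma t}}; parameters `rate`
#'     \eqn{\lambda > 0} and `shape` \eqn{\gamma} (any sign). For
#'     \eqn{\gamma < 0} the distribution is improper: a mass
#'     \eqn{S(\infty) = \exp(\lambda/\gamma)} of patients never experience the
#'     event, which the sampler returns as `Inf`.}
#' }
#' For PH families, covariates act multiplicatively on the hazard:
#' \eqn{h(t \mid x) = h_0(t)\, e^{x'\beta}\, \mathrm{HR}}, where `hr` is an
#' external hazard-ratio multiplier (e.g. a treatment effect from a trial).
#'
#' The accelerated-failure-time (AFT) families act on the time scale,
#' \eqn{S(t \mid x) = S_0(t e^{-x'\beta})}:
#' \describe{
#'   \item{loglogistic}{\eqn{S_0(t) = 1/(1 + (t/s)^{\gamma})}; parameters
#'     `shape` \eqn{\gamma > 0} and `scale` \eqn{s > 0}.}
#'   \item{lognormal}{parameters `meanlog` and `sdlog` \eqn{> 0}.}
#' }
#' An external hazard ratio is not defined for AFT families; `hr` must be 1.
#'
#' @param family One of `"exponential"`, `"weibull"`, `"gompertz"`,
#'   `"loglogistic"`, `"lognormal"`.
#' @param params Named numeric vector/list of family parameters (see Details).
#' @param coefs Optional named numeric vector of covariate coefficients
#'   (log hazard ratios for PH families; log time ratios for AFT families).
#'   Names must match numeric columns of the `newdata` passed to the
#'   evaluation functions.
#' @param hr Positive external hazard-ratio multiplier (PH families only).
#' @return An object of class `parametric_model`.
#' @seealso [hazard_rate()], [surv_prob()], [sample_event_time()],
#'   [sample_competing()], [compose_wearout()]
#' @examples
#' m <- parametric_model("gompertz", c(rate = 0.08, shape = -0.05),
#'                       coefs = c(sex_female = -0.3))
#' surv_prob(m, 12, newdata = data.frame(sex_female = 1))
#' @export
parametric_model <- function(family, params, coefs = NULL, hr = 1) {
  family <- match.arg(family, ph_families_and_aft())
  params <- unlist(params)
  need <- family_param_names(family)
  if (!all(need %in% names(params)))
    stop("family '", family, "' needs parameters: ", paste(need, collapse = ", "),
         call. = FALSE)
  params <- params[need]
  if (anyNA(params) || !all(is.finite(params)))
    stop("non-finite parameter for family '", family, "'", call. = FALSE)
  pos <- switch(family,
                exponential = "rate",
                weibull = c("shape", "rate"),
                gompertz = "rate",          # shape may be negative (improper)
                loglogistic = c("shape", "scale"),
                lognormal = "sdlog")        # meanlog unrestricted
  if (any(params[pos] <= 0))
    stop("parameter(s) ", paste(pos[params[pos] <= 0], collapse = ", "),
         " must be positive for family '", family, "'", call. = FALSE)
  if (family %in% c("loglogistic", "lognormal") && hr != 1)
    stop("external hazard ratio is undefined for AFT family '", family,
         "'; hr must be 1", call. = FALSE)
  if (!is.numeric(hr) || length(hr) != 1L || hr <= 0)
    stop("hr must be a single positive number", call. = FALSE)
  if (!is.null(coefs)) {
    coefs <- unlist(coefs)
    if (is.null(names(coefs)) || any(!nzchar(names(coefs))))
      stop("coefs must be named", call. = FALSE)
  }
  structure(
    list(family = family, params = params,
         coefs = coefs, hr = hr),
    class = "parametric_model"
  )
}

ph_families <- function() c("exponential", "weibull", "gompertz")
aft_families <- function() c("loglogistic", "lognormal")
ph_families_and_aft <- function() c(ph_families(), aft_families())

family_param_names <- function(family) {
  switch(family,
         exponential = "rate",
         weibull = c("shape", "rate"),
         gompertz = c("shape", "rate"),
         loglogistic = c("shape", "scale"),
         lognormal = c("meanlog", "sdlog"))
}

is_ph <- function(model) model$family %in% ph_families()

#' @export
print.parametric_model <- function(x, ...) {
  cat(sprintf("Parametric %s model (%s)\n", x$family,
              if (is_ph(x)) "proportional hazards" else "accelerated failure time"))
  cat("  parameters:", paste(sprintf("%s = %.6g", names(x$params), x$params),
                             collapse = ", "), "\n")
  if (!is.null(x$coefs))
    cat("  covariates:", paste(sprintf("%s = %.4g", names(x$coefs), x$coefs),
                               collapse = ", "), "\n")
  if (x$hr != 1) cat("  external hazard ratio:", format(x$hr), "\n")
  invisible(x)
}

# Linear predictor x'beta for each of n rows of newdata (0 when no covariates).
linear_predictor <- function(model, newdata = NULL, n = NULL) {
  if (is.null(model$coefs)) {
    if (is.null(n)) n <- if (is.null(newdata)) 1L else nrow(newdata)
    return(rep(0, n))
  }
  if (is.null(newdata))
    stop("model uses covariates (", paste(names(model$coefs), collapse = ", "),
         ") but no newdata supplied", call. = FALSE)
  miss <- setdiff(names(model$coefs), names(newdata))
  if (length(miss))
    stop("newdata lacks covariate column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  lp <- as.numeric(as.matrix(newdata[names(model$coefs)]) %*% model$coefs)
  if (!is.null(n) && length(lp) == 1L) lp <- rep(lp, n)
  if (!is.null(n) && length(lp) != n)
    stop("newdata has ", length(lp), " rows; expected 1 or ", n, call. = FALSE)
  lp
}

# Baseline cumulative hazard H0(t) for PH families (vectorized in t).
base_cumhaz <- function(model, t) {
  p <- model$params
  switch(model$family,
         exponential = p[["rate"]] * t,
         weibull = p[["rate"]] * t^p[["shape"]],
         gompertz = {
           g <- p[["shape"]]
           if (g == 0) p[["rate"]] * t
           else p[["rate"]] / g * (exp(g * t) - 1)
         },
         stop("base_cumhaz: not a PH family"))
}

# Inverse of the baseline cumulative hazard; Inf where H exceeds H0(Inf)
# (improper negative-shape Gompertz).
base_inv_cumhaz <- function(model, H) {
  p <- model$params
  switch(model$family,
         exponential = H / p[["rate"]],
         weibull = (H / p[["rate"]])^(1 / p[["shape"]]),
         gompertz = {
           g <- p[["shape"]]
           if (g == 0) return(H / p[["rate"]])
           z <- g * H / p[["rate"]]
           out <- ifelse(z <= -1, Inf, log1p(pmax(z, -1)) / g)
           out
         },
         stop("base_inv_cumhaz: not a PH family"))
}

base_hazard <- function(model, t) {
  p <- model$params
  switch(model$family,
         exponential = rep(p[["rate"]], length(t)),
         weibull = p[["rate"]] * p[["shape"]] * t^(p[["shape"]] - 1),
         gompertz = p[["rate"]] * exp(p[["shape"]] * t),
         stop("base_hazard: not a PH family"))
}

# AFT baseline survival, hazard and survival-quantile (t0 with S0(t0) = s).
aft_base_surv <- function(model, t) {
  p <- model$params
  switch(model$family,
         loglogistic = 1 / (1 + (t / p[["scale"]])^p[["shape"]]),
         lognormal = stats::plnorm(t, p[["meanlog"]], p[["sdlog"]],
                                   lower.tail = FALSE))
}

aft_base_hazard <- function(model, t) {
  p <- model$params
  switch(model$family,
         loglogistic = {
           a <- p[["shape"]]; s <- p[["scale"]]
           (a / s) * (t / s)^(a - 1) / (1 + (t / s)^a)
         },
         lognormal = {
           S <- stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE)
           ifelse(S > 0, stats::dlnorm(t, p[["meanlog"]], p[["sdlog"]]) / S, Inf)
         })
}

aft_base_qsurv <- function(model, s) {
  p <- model$params
  switch(model$family,
         loglogistic = p[["scale"]] * ((1 - s) / s)^(1 / p[["shape"]]),
         lognormal = stats::qlnorm(s, p[["meanlog"]], p[["sdlog"]],
                                   lower.tail = FALSE))
}

#' Hazard, survival and cumulative hazard of a transition model
#'
#' Evaluate the hazard rate (events per month), survival probability, or
#' cumulative hazard of a [parametric_model()] or a wear-out composite
#' ([compose_wearout()]) at times `t`, for the covariate values in `newdata`.
#'
#' @param object A `parametric_model` or `composite_hazard`.
#' @param t Vector of non-negative times in months.
#' @param newdata Optional single-row data frame (or `NULL`) with the numeric
#'   covariate columns the model was defined with.
#' @param ... Unused.
#' @return Numeric vector, one value per element of `t`.
#' @export
hazard_rate <- function(object, t, newdata = NULL, ...) UseMethod("hazard_rate")

#' @rdname hazard_rate
#' @export
surv_prob <- function(object, t, newdata = NULL, ...) UseMethod("surv_prob")

#' @rdname hazard_rate
#' @export
cum_hazard <- function(object, t, newdata = NULL, ...) UseMethod("cum_hazard")

check_times <- function(t) {
  if (any(t < 0)) stop("times must be non-negative", call. = FALSE)
  t
}

#' @export
hazard_rate.parametric_model <- function(object, t, newdata = NULL, ...) {
  check_times(t)
  lp <- linear_predictor(object, newdata, n = 1L)
  if (is_ph(object)) {
    base_hazard(object, t) * exp(lp) * object$hr
  } else {
    aft_base_hazard(object, t * exp(-lp)) * exp(-lp)
  }
}

#' @export
cum_hazard.parametric_model <- function(object, t, newdata = NULL, ...) {
  check_times(t)
  lp <- linear_predictor(object, newdata, n = 1L)
  if (is_ph(object)) {
    base_cumhaz(object, t) * exp(lp) * object$hr
  } else {
    -log(aft_base_surv(object, t * exp(-lp)))
  }
}

#' @export
surv_prob.parametric_model <- function(object, t, newdata = NULL, ...) {
  exp(-cum_hazard(object, t, newdata))
}

# Invert the covariate-adjusted cumulative hazard: time at which the
# cumulative hazard reaches H (per patient; H and lp vectors of length n).
# Returns Inf where H exceeds the total mass (improper distributions).
invert_cumhaz <- function(model, H, lp) {
  if (is_ph(model)) {
    base_inv_cumhaz(model, H / (exp(lp) * model$hr))
  } else {
    aft_base_qsurv(model, exp(-H)) * exp(lp)
  }
}

#' Sample event times from a transition model
#'
#' Draws `n` independent event times by inverse-probability-integral transform
#' on the cumulative hazard: with \eqn{E \sim \mathrm{Exp}(1)}, the event time
#' is \eqn{t = H^{-1}(E \mid x)}. For improper distributions (negative-shape
#' Gompertz, where a fraction of patients never experience the event) the draw
#' is `Inf` with probability \eqn{S(\infty)}.
#'
#' Uses the current R random-number stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param object A `parametric_model` or `composite_hazard`.
#' @param n Number of draws.
#' @param newdata Optional data frame of covariates with 1 or `n` rows.
#' @param ... Unused.
#' @return Numeric vector of length `n` of times in months (possibly `Inf`).
#' @export
sample_event_time <- function(object, n, newdata = NULL, ...) {
  UseMethod("sample_event_time")
}

#' @export
sample_event_time.parametric_model <- function(object, n, newdata = NULL, ...) {
  if (n == 0) return(numeric(0))
  lp <- linear_predictor(object, newdata, n = n)
  E <- stats::rexp(n)
  invert_cumhaz(object, E, lp)
}
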