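flexsurv_dist <- function(family) {
  switch(family,
         exponential = "exp",
         weibull = "weibullPH",   # PH parameterization: H0(t) = scale * t^shape
         gompertz = "gompertz",
         loglogistic = "llogis",
         lognormal = "lnorm",
         stop("unknown family '", family, "'", call. = FALSE))
}

# flexsurv parameter name -> package parameter name
flexsurv_param_map <- function(family) {
  switch(family,
         exponential = c(rate = "rate"),
         weibull = c(shape = "shape", scale = "rate"),
         gompertz = c(shape = "shape", rate = "rate"),
         loglogistic = c(shape = "shape", scale = "scale"),
         lognormal = c(meanlog = "meanlog", sdlog = "sdlog"))
}

#' Fit a parametric model to the rows of one transition
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{\mathrm{events}} \log h(t_i \mid x_i) + \sum_{\mathrm{all}} \log S(t_i \mid x_i)}
#' for a single transition of the pathway, via [flexsurv::flexsurvreg()].
#' Covariates enter on the log-hazard scale for PH families (exponential,
#' Weibull in PH form, Gompertz) and on the log time-ratio scale for the AFT
#' families (log-logistic, log-normal), matching the conventions of
#' [parametric_model()].
#'
#' @param rows Long-format transition rows from [prep_multistate()] (or any
#'   data frame with `time`, `status` and the covariate columns). If a
#'   `transition` column is present it must be homogeneous or `transition`
#'   must be given.
#' @param family Distribution family (see [parametric_model()]).
#' @param covariates Character vector of covariate column names (may be empty).
#' @param transition Optional transition label to filter `rows` by.
#' @return An object of class `transition_fit`: a list with the fitted
#'   [parametric_model()] (`$model`), the coefficient table with standard
#'   errors and Wald p-values (`$coef_table`), `$loglik`, `$AIC`, counts
#'   (`$n`, `$n_event`), and the flexsurv fit (`$fit`).
#' @export
fit_transition <- function(rows, family, covariates = character(0),
                           transition = NULL) {
  if (!is.null(transition)) rows <- rows[rows$transition == transition, , drop = FALSE]
  if (!is.null(rows$transition)) {
    lab <- unique(rows$transition)
    if (length(lab) > 1L)
      stop("rows span several transitions; pass `transition`", call. = FALSE)
  } else lab <- transition %||% NA_character_
  if (nrow(rows) == 0L) stop("no rows to fit", call. = FALSE)
  if (sum(rows$status) == 0)
    stop("cannot estimate transition '", lab, "': all observations censored",
         call. = FALSE)
  fam <- match.arg(family, ph_families_and_aft())
  # covariates without variation (or collinear with others) in this
  # transition's rows are inestimable; drop them and record the fact
  dropped <- character(0)
  if (length(covariates)) {
    keep <- vapply(covariates, function(v)
      length(unique(rows[[v]])) > 1L, logical(1))
    dropped <- covariates[!keep]
    covariates <- covariates[keep]
    if (length(covariates) > 1L) {
      X <- as.matrix(rows[covariates])
      qr_x <- qr(cbind(1, X))
      if (qr_x$rank < ncol(X) + 1L) {
        indep <- setdiff(qr_x$pivot[seq_len(qr_x$rank)] - 1L, 0L)
        coll <- setdiff(covariates, covariates[indep])
        dropped <- c(dropped, coll)
        covariates <- setdiff(covariates, coll)
      }
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, status) ~",
    if (length(covariates)) paste(covariates, collapse = " + ") else "1"))
  run_fit <- function(...) flexsurv::flexsurvreg(fml, data = rows,
                                                 dist = flexsurv_dist(fam), ...)
  fit <- tryCatch(run_fit(), error = function(e) e)
  if (inherits(fit, "error")) {
    # retry from crude moment starting values (helps sparse transitions)
    crude <- sum(rows$status) / sum(rows$time)
    inits <- switch(fam,
                    exponential = crude,
                    weibull = c(1, crude),
                    gompertz = c(0, crude),
                    loglogistic = c(1, 1 / crude),
                    lognormal = c(log(1 / crude), 1))
    fit <- tryCatch(run_fit(inits = c(inits, rep(0, length(covariates)))),
                    error = function(e)
                      stop("estimation failed for transition '", lab,
                           "' (", fam, "): ", conditionMessage(e),
                           call. = FALSE))
  }
  converged <- is.null(fit$opt$convergence) || fit$opt$convergence == 0
  pmap <- flexsurv_param_map(fam)
  params <- fit$res[names(pmap), "est"]
  names(params) <- unname(pmap)
  coefs <- NULL
  coef_table <- NULL
  if (length(covariates)) {
    est <- fit$res.t[covariates, "est"]
    se <- fit$res.t[covariates, "se"]
    p <- 2 * stats::pnorm(-abs(est / se))
    coef_table <- data.frame(term = covariates, estimate = est, se = se,
                             p_value = p, row.names = NULL)
    coefs <- stats::setNames(est, covariates)
  }
  base_table <- data.frame(
    term = names(params),
    estimate = unname(params),
    se = fit$res[names(pmap), "se"],
    lower = fit$res[names(pmap), "L95%"],
    upper = fit$res[names(pmap), "U95%"],
    row.names = NULL)
  structure(list(
    transition = lab,
    family = fam,
    model = parametric_model(fam, params, coefs = coefs),
    covariates = covariates,
    coef_table = coef_table,
    base_table = base_table,
    loglik = as.numeric(stats::logLik(fit)),
    AIC = stats::AIC(fit),
    n = nrow(rows),
    n_event = sum(rows$status),
    converged = converged,
    dropped = dropped,
    fit = fit
  ), class = "transition_fit")
}

#' @export
print.transition_fit <- function(x, ...) {
  cat(sprintf("Transition fit: %s (%s), n = %d, events = %d\n",
              x$transition, x$family, x$n, x$n_event))
  print(x$base_table, digits = 4)
  if (!is.null(x$coef_table)) print(x$coef_table, digits = 4)
  if (length(x$dropped))
    cat("  dropped (no variation/collinear):",
        paste(x$dropped, collapse = ", "), "\n")
  cat(sprintf("logLik = %.2f, AIC = %.2f%s\n", x$loglik, x$AIC,
              if (!x$converged) " [did not converge]" else ""))
  invisible(x)
}

#' Backward covariate selection for a transition model
#'
#' Starting from the full candidate set, repeatedly refits the model and
#' removes the covariate with the largest Wald p-value above `alpha` until
#' every remaining covariate is significant at `alpha`. Wald tests (one fit
#' per step) make the procedure deterministic given the data; ties are broken
#' alphabetically.
#'
#' @inheritParams fit_transition
#' @param candidates Character vector of candidate covariate names.
#' @param alpha Retention cutoff p-value in (0, 1); covariates with
#'   p > `alpha` are eligible for removal. `alpha = 1` retains everything.
#' @return A `transition_fit` for the selected covariate set.
#' @export
backward_select <- function(rows, family, candidates, alpha = 0.05,
                            transition = NULL) {
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 && alpha <= 1))
    stop("alpha must lie in (0, 1]", call. = FALSE)
  current <- sort(unique(candidates))
  repeat {
    fit <- fit_transition(rows, family, current, transition = transition)
    current <- fit$covariates   # inestimable candidates were dropped inside
    if (length(current) == 0L) return(fit)
    p <- fit$coef_table$p_value
    names(p) <- fit$coef_table$term
    worst <- sort(p, decreasing = TRUE)
    if (worst[1] <= alpha) return(fit)
    current <- setdiff(current, names(worst)[1])
  }
}

#' Fit the treatment-decision model
#'
#' Logistic regression for the probability that a newly diagnosed patient
#' starts first-line systemic treatment (as opposed to best supportive care),
#' as a function of baseline attributes. Used by the cohort simulator to draw
#' the treated-vs-BSC split.
#'
#' @param registry Registry data frame (see [read_registry()]); a patient is
#'   treated when `t_l1t` is non-missing.
#' @param covariates Character vector of derived covariate names
#'   (see [derive_covariates()]); may be empty for an intercept-only model.
#' @return Object of class `treatment_decision`: coefficients, their table,
#'   and a `separation` flag (complete or quasi-complete separation detected).
#' @export
fit_treatment_decision <- function(registry,
                                   covariates = c("age65", "sex_female",
                                                  "ps_bad", "cci")) {
  reg <- derive_covariates(as.data.frame(registry))
  reg$._treated <- as.numeric(!is.na(suppressWarnings(as.numeric(reg$t_l1t))))
  if (length(unique(reg$._treated)) < 2L)
    stop("both treated and BSC patients are required to fit the decision model",
         call. = FALSE)
  fml <- stats::as.formula(paste(
    "._treated ~",
    if (length(covariates)) paste(covariates, collapse = " + ") else "1"))
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(fml, data = reg, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separation <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (any(abs(stats::coef(fit)) > 15)) separation <- TRUE
  sm <- summary(fit)$coefficients
  structure(list(
    coefs = stats::coef(fit),
    covariates = covariates,
    coef_table = data.frame(term = rownames(sm), estimate = sm[, 1],
                            se = sm[, 2], p_value = sm[, 4], row.names = NULL),
    separation = separation,
    n = nrow(reg),
    n_treated = sum(reg$._treated)
  ), class = "treatment_decision")
}

#' @export
print.treatment_decision <- function(x, ...) {
  cat(sprintf("Treatment decision model (logistic): n = %d, treated = %d (%.1f%%)%s\n",
              x$n, x$n_treated, 100 * x$n_treated / x$n,
              if (x$separation) " [separation detected]" else ""))
  print(x$coef_table, digits = 4)
  invisible(x)
}

#' Probability of starting first-line treatment
#'
#' @param object A `treatment_decision` fit.
#' @param newdata Data frame containing the model's covariate columns.
#' @return Vector of probabilities of being treated (vs BSC).
#' @export
predict_decision <- function(object, newdata) {
  stopifnot(inherits(object, "treatment_decision"))
  lp <- rep(object$coefs[["(Intercept)"]], nrow(newdata))
  for (v in object$covariates) lp <- lp + object$coefs[[v]] * newdata[[v]]
  stats::plogis(lp)
}
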