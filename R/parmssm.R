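#' Default family and candidate-covariate plan for the pathway
#'
#' The shipped plan encodes the distribution choices used for each transition
#' of the pathway: log-logistic for time from diagnosis to first-line start,
#' log-normal for time from diagnosis to death under best supportive care,
#' Gompertz for the two transitions leaving first-line treatment, and
#' exponential for the later lines (the third-line transition has few
#' patients, so the one-parameter family is used). Candidate covariates are
#' the derived numeric attributes of [derive_covariates()].
#'
#' @return Named list, one entry per transition, each with `family` and
#'   `covariates` (candidates for backward selection).
#' @export
default_transition_plan <- function() {
  covs <- c("age65", "sex_female", "ps_bad", "cci")
  list(
    diag_l1t = list(family = "loglogistic", covariates = covs),
    diag_death_bsc = list(family = "lognormal", covariates = covs),
    l1t_l2t = list(family = "gompertz", covariates = covs),
    l1t_death = list(family = "gompertz", covariates = covs),
    l2t_l3t = list(family = "exponential", covariates = covs),
    l2t_death = list(family = "exponential", covariates = covs),
    l3t_death = list(family = "exponential", covariates = covs)
  )
}

#' Fit the parametric multistate model to a patient registry
#'
#' The central fitting function of the package. From a one-row-per-patient
#' registry it (1) expands the data into long-format transition rows with
#' line-local clocks ([prep_multistate()]), (2) fits a parametric survival
#' model to each of the seven pathway transitions by right-censored maximum
#' likelihood, with backward covariate selection at cutoff `alpha`
#' ([backward_select()]), and (3) fits the logistic treatment-decision model
#' ([fit_treatment_decision()]). The registry's attribute table is retained
#' for empirical resampling of baseline populations.
#'
#' The fitted object is simulated with [simulate.parmssm()], which runs the
#' discrete-event simulation from diagnosis to death.
#'
#' @param registry Registry data frame (see [read_registry()]).
#' @param plan Transition plan as in [default_transition_plan()].
#' @param decision_covariates Candidates for the treatment-decision model.
#' @param alpha Backward-selection cutoff p-value; `alpha = 1` keeps all
#'   candidates.
#' @param backward Set `FALSE` to skip selection and keep all candidates.
#' @return An object of class `parmssm` with components `transitions` (named
#'   list of `transition_fit`), `decision` (`treatment_decision`),
#'   `attributes` (the registry attribute pool) and `n`.
#' @examples
#' reg <- generate_registry(registry_spec(n = 300), seed = 1)
#' fit <- fit_parmssm(reg)
#' fit
#' @export
fit_parmssm <- function(registry,
                        plan = default_transition_plan(),
                        decision_covariates = c("age65", "sex_female",
                                                "ps_bad", "cci"),
                        alpha = 0.05,
                        backward = TRUE) {
  stopifnot(all(pathway_transitions() %in% names(plan)))
  rows <- prep_multistate(registry)
  fits <- lapply(pathway_transitions(), function(tr) {
    pl <- plan[[tr]]
    sub <- rows[rows$transition == tr, , drop = FALSE]
    if (backward)
      backward_select(sub, pl$family, pl$covariates, alpha = alpha)
    else
      fit_transition(sub, pl$family, pl$covariates)
  })
  names(fits) <- pathway_transitions()
  decision <- fit_treatment_decision(registry, decision_covariates)
  attrs <- derive_covariates(as.data.frame(registry))[
    , c("year", "age", "sex", "ps", "cci",
        "age65", "sex_female", "ps_bad", "year0")]
  structure(list(
    transitions = fits,
    decision = decision,
    attributes = attrs,
    n = nrow(registry),
    rejected = attr(rows, "rejected"),
    call = match.call()
  ), class = "parmssm")
}

#' @export
print.parmssm <- function(x, ...) {
  cat("Parametric multistate pathway model (7 transitions)\n")
  cat(sprintf("  fitted to %d patients (%d treated, %d BSC)\n", x$n,
              x$decision$n_treated, x$n - x$decision$n_treated))
  for (tr in names(x$transitions)) {
    f <- x$transitions[[tr]]
    kept <- if (length(f$covariates)) paste(f$covariates, collapse = ", ")
            else "(none)"
    cat(sprintf("  %-15s %-12s events %4d/%4d  covariates: %s\n",
                tr, f$family, f$n_event, f$n, kept))
  }
  invisible(x)
}

#' @export
summary.parmssm <- function(object, ...) {
  tabs <- lapply(names(object$transitions), function(tr) {
    f <- object$transitions[[tr]]
    base <- f$base_table
    base$transition <- tr
    base$kind <- "parameter"
    cov <- f$coef_table
    if (!is.null(cov)) {
      cov$transition <- tr
      cov$kind <- "covariate"
      cov$lower <- cov$estimate - 1.96 * cov$se
      cov$upper <- cov$estimate + 1.96 * cov$se
      cov$p_value <- NULL
      base <- rbind(base[c("transition", "kind", "term", "estimate", "se",
                           "lower", "upper")],
                    cov[c("transition", "kind", "term", "estimate", "se",
                          "lower", "upper")])
    } else {
      base <- base[c("transition", "kind", "term", "estimate", "se",
                     "lower", "upper")]
    }
    base
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  structure(list(table = out,
                 decision = object$decision$coef_table,
                 loglik = sum(vapply(object$transitions, `[[`, 0, "loglik")),
                 n = object$n),
            class = "summary.parmssm")
}

#' @export
print.summary.parmssm <- function(x, ...) {
  cat("Transition models (estimates with 95% CIs):\n")
  print(x$table, digits = 4)
  cat(sprintf("\nTotal transition log-likelihood: %.2f (n = %d)\n",
              x$loglik, x$n))
  cat("\nTreatment-decision model:\n")
  print(x$decision, digits = 4)
  invisible(x)
}

#' @export
coef.parmssm <- function(object, ...) {
  lapply(object$transitions, function(f)
    c(f$model$params, f$model$coefs))
}

#' @export
logLik.parmssm <- function(object, ...) {
  ll <- sum(vapply(object$transitions, `[[`, 0, "loglik"))
  df <- sum(vapply(object$transitions, function(f)
    length(f$model$params) + length(f$model$coefs), 0))
  structure(ll, df = df, class = "logLik")
}

# named list of parametric_model objects from a parmssm fit
transition_models <- function(object) {
  stopifnot(inherits(object, "parmssm"))
  lapply(object$transitions, `[[`, "model")
}
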