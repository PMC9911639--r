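#' Specification of a synthetic patient registry
#'
#' Describes the data-generating process for a synthetic registry with the
#' structure the fitting pipeline expects: one row per patient with baseline
#' attributes, a treated-vs-BSC decision, up to three treatment lines and
#' administrative censoring at an end-of-follow-up date. The defaults emulate
#' a real-world teaching-hospital registry of advanced non-squamous NSCLC
#' diagnosed 2008-2014 and followed to early 2017: about 65% of patients
#' receive best supportive care with a median survival around 2.3 months,
#' treated patients start first-line treatment a median of about 1 month
#' after diagnosis and have a median overall survival in the 7-month range,
#' and nearly all patients have died by the end of follow-up. All parameter
#' values are synthetic defaults chosen to reproduce those magnitudes, not
#' estimates from any real dataset.
#'
#' @param n Number of patients.
#' @param years Calendar years of diagnosis (uniform).
#' @param age_mean,age_sd,age_range Age-at-diagnosis distribution (normal,
#'   truncated to `age_range`).
#' @param p_male Probability of male sex.
#' @param p_ps_bad Probability of bad-or-unknown performance status.
#' @param cci_lambda Poisson mean of the Charlson comorbidity index score.
#' @param decision Named coefficients of the logistic treated-vs-BSC model
#'   (on the derived covariates; see [derive_covariates()]).
#' @param models Named list of true transition models
#'   (see [pathway_transitions()]).
#' @param follow_up_end End of follow-up as a decimal calendar year.
#' @return List of class `registry_spec`.
#' @export
registry_spec <- function(n = 2196,
                          years = 2008:2014,
                          age_mean = 66, age_sd = 9.5,
                          age_range = c(30, 92),
                          p_male = 0.55,
                          p_ps_bad = 0.40,
                          cci_lambda = 1.0,
                          decision = c("(Intercept)" = -0.05,
                                       ps_bad = -1.2, age65 = -0.04,
                                       cci = -0.10),
                          models = default_true_models(),
                          follow_up_end = 2017.083) {
  stopifnot(n >= 1, length(years) >= 1, age_sd > 0,
            p_male >= 0, p_male <= 1, p_ps_bad >= 0, p_ps_bad <= 1)
  miss <- setdiff(pathway_transitions(), names(models))
  if (length(miss))
    stop("models lacks transition(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  structure(list(n = n, years = years, age_mean = age_mean, age_sd = age_sd,
                 age_range = age_range, p_male = p_male, p_ps_bad = p_ps_bad,
                 cci_lambda = cci_lambda, decision = decision,
                 models = models, follow_up_end = follow_up_end),
            class = "registry_spec")
}

#' Default true transition models of the synthetic registry
#'
#' The family choices mirror the pathway model's defaults (log-logistic
#' diagnosis-to-first-line, log-normal BSC survival, Gompertz first-line
#' transitions, exponential later lines); magnitudes are synthetic (see
#' [registry_spec()]).
#'
#' @return Named list of [parametric_model()] objects.
#' @export
default_true_models <- function() {
  list(
    diag_l1t = parametric_model("loglogistic", c(shape = 2.2, scale = 1.0),
                                coefs = c(sex_female = -0.10)),
    diag_death_bsc = parametric_model("lognormal",
                                      c(meanlog = 0.85, sdlog = 1.10),
                                      coefs = c(ps_bad = -0.35,
                                                sex_female = -0.15)),
    l1t_l2t = parametric_model("gompertz", c(shape = -0.05, rate = 0.085),
                               coefs = c(sex_female = -0.30, age65 = -0.015)),
    l1t_death = parametric_model("gompertz", c(shape = 0.010, rate = 0.075),
                                 coefs = c(ps_bad = 0.50)),
    l2t_l3t = parametric_model("exponential", c(rate = 0.055),
                               coefs = c(sex_female = -0.30, age65 = -0.020)),
    l2t_death = parametric_model("exponential", c(rate = 0.110),
                                 coefs = c(sex_female = -0.20)),
    l3t_death = parametric_model("exponential", c(rate = 0.130))
  )
}

# attribute sampler used by the generator (consumes the current RNG stream)
sample_spec_attributes <- function(spec, n) {
  age <- pmin(pmax(stats::rnorm(n, spec$age_mean, spec$age_sd),
                   spec$age_range[1]), spec$age_range[2])
  data.frame(
    year = sample(spec$years, n, replace = TRUE),
    age = age,
    sex = ifelse(stats::runif(n) < spec$p_male, "male", "female"),
    ps = ifelse(stats::runif(n) < spec$p_ps_bad, "bad_unknown", "good"),
    cci = stats::rpois(n, spec$cci_lambda),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic patient registry
#'
#' Samples baseline attributes, the treated-vs-BSC decision, and the full
#' disease pathway from the true transition models of a [registry_spec()],
#' then applies administrative censoring at the end of follow-up: deaths
#' after the censoring date become censored observations, and treatment
#' lines starting after it are unobserved (a treated-arm patient whose
#' first line would start after the censoring date appears as a censored
#' untreated patient).
#'
#' @param spec A [registry_spec()].
#' @param seed Integer seed; identical spec and seed give a byte-identical
#'   registry.
#' @param life_table Optional [life_table()]; when supplied, death from
#'   other causes competes with the disease pathway in the generated data.
#' @return Registry data frame (columns of [read_registry()]), with the
#'   spec attached as attribute `"spec"`.
#' @export
generate_registry <- function(spec, seed, life_table = NULL) {
  stopifnot(inherits(spec, "registry_spec"))
  set.seed(child_seed(seed, "synth"))
  n <- spec$n
  attrs <- derive_covariates(sample_spec_attributes(spec, n))
  # diagnosis date within the year; censoring time in months from diagnosis
  diag_date <- attrs$year + stats::runif(n)
  censor <- (spec$follow_up_end - diag_date) * 12
  if (all(censor <= 0))
    stop("degenerate spec: end of follow-up precedes every diagnosis",
         call. = FALSE)
  censor <- pmax(censor, 0.01)

  lp <- rep(spec$decision[["(Intercept)"]], n)
  for (v in setdiff(names(spec$decision), "(Intercept)"))
    lp <- lp + spec$decision[[v]] * attrs[[v]]
  treated <- stats::runif(n) < stats::plogis(lp)
  t_doc <- if (!is.null(life_table))
    sample_background_time(life_table, attrs$age, attrs$sex)
  else rep(Inf, n)

  t_l1t <- rep(NA_real_, n)
  t_death <- rep(NA_real_, n)
  if (any(!treated)) {
    tb <- sample_event_time(spec$models$diag_death_bsc, sum(!treated),
                            attrs[!treated, , drop = FALSE])
    t_death[!treated] <- pmin(tb, t_doc[!treated])
  }
  if (any(treated))
    t_l1t[treated] <- sample_event_time(spec$models$diag_l1t, sum(treated),
                                        attrs[treated, , drop = FALSE])
  paths <- simulate_treated_paths(attrs[treated, , drop = FALSE],
                                  t_l1t[treated], t_doc[treated],
                                  spec$models, strategy = NULL)
  t_l2t <- rep(NA_real_, n); t_l3t <- rep(NA_real_, n)
  t_l2t[treated] <- paths$t_l2t
  t_l3t[treated] <- paths$t_l3t
  t_death[treated] <- paths$t_death
  # a treated-arm patient pre-empted by other-cause death has no t_l1t
  t_l1t[treated][is.na(paths$treatment1)] <- NA_real_

  # administrative censoring
  dead <- as.numeric(!is.na(t_death) & t_death <= censor)
  t_l1t[!is.na(t_l1t) & t_l1t > censor] <- NA_real_
  t_l2t[is.na(t_l1t) | (!is.na(t_l2t) & t_l2t > censor)] <- NA_real_
  t_l3t[is.na(t_l2t) | (!is.na(t_l3t) & t_l3t > censor)] <- NA_real_
  t_obs <- ifelse(dead == 1, t_death, censor)

  out <- data.frame(id = seq_len(n),
                    year = attrs$year, age = attrs$age, sex = attrs$sex,
                    ps = attrs$ps, cci = attrs$cci,
                    t_l1t = t_l1t, t_l2t = t_l2t, t_l3t = t_l3t,
                    t_death = t_obs, dead = dead,
                    stringsAsFactors = FALSE)
  attr(out, "spec") <- spec
  out
}

#' Generate a synthetic life table
#'
#' Annual other-cause mortality rising exponentially with age (a Gompertz-like
#' schedule), with a constant male-to-female mortality ratio.
#'
#' @param base_rate Annual mortality probability of a 40-year-old female.
#' @param age_gradient Log-linear increase per year of age (0 gives a flat
#'   table).
#' @param sex_ratio Male/female mortality ratio.
#' @param ages Integer ages to tabulate (the last acts as the terminal band).
#' @return A [life_table()].
#' @export
generate_life_table <- function(base_rate = 0.0015, age_gradient = 0.09,
                                sex_ratio = 1.4, ages = 30:100) {
  if (base_rate < 0 || base_rate >= 1)
    stop("base_rate must lie in [0, 1)", call. = FALSE)
  qf <- pmin(base_rate * exp(age_gradient * (ages - 40)), 0.95)
  qm <- pmin(qf * sex_ratio, 0.95)
  life_table(data.frame(
    sex = rep(c("female", "male"), each = length(ages)),
    age = rep(ages, 2),
    qx = c(qf, qm)))
}
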