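# Shared fixtures and independent oracles used across the suite.

# Brute-force product-limit estimator: explicit risk sets, no survfit.
km_brute_force <- function(time, event) {
  ut <- sort(unique(time[event == 1]))
  surv <- numeric(length(ut))
  s <- 1
  for (k in seq_along(ut)) {
    n_risk <- sum(time >= ut[k])
    d <- sum(time == ut[k] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[k] <- s
  }
  data.frame(time = ut, surv = surv)
}

# A three-patient registry covering all seven transitions by hand.
hand_registry <- function() {
  data.frame(
    id = 1:3,
    year = c(2010, 2011, 2012),
    age = c(60, 70, 55),
    sex = c("male", "female", "male"),
    ps = c("good", "bad_unknown", "good"),
    cci = c(0, 2, 1),
    #            treated, full path      BSC dead        treated, censored in L2
    t_l1t = c(1.0, NA, 2.0),
    t_l2t = c(4.0, NA, 6.5),
    t_l3t = c(9.0, NA, NA),
    t_death = c(15.0, 2.3, 30.0),
    dead = c(1, 1, 0),
    stringsAsFactors = FALSE)
}

# Exponential-only transition set (analytically tractable pathway).
exp_models <- function(r_l1 = 2, r_bsc = 0.3, r12 = 0.08, r1d = 0.08,
                       r23 = 0.05, r2d = 0.12, r3d = 0.15) {
  list(
    diag_l1t = parametric_model("exponential", c(rate = r_l1)),
    diag_death_bsc = parametric_model("exponential", c(rate = r_bsc)),
    l1t_l2t = parametric_model("exponential", c(rate = r12)),
    l1t_death = parametric_model("exponential", c(rate = r1d)),
    l2t_l3t = parametric_model("exponential", c(rate = r23)),
    l2t_death = parametric_model("exponential", c(rate = r2d)),
    l3t_death = parametric_model("exponential", c(rate = r3d))
  )
}

# Minimal attribute pool with the derived covariate columns.
tiny_pool <- function(n = 4) {
  derive_covariates(data.frame(
    year = rep(2010, n),
    age = seq(55, 75, length.out = n),
    sex = rep(c("male", "female"), length.out = n),
    ps = rep(c("good", "bad_unknown"), length.out = n),
    cci = rep(0:1, length.out = n)))
}

# Mean overall survival (from first-line start) of the all-exponential
# pathway, by absorbing-Markov phase-type algebra: E[OS] = sojourn in L1
# plus the probability-weighted downstream sojourns.
phase_type_mean_os <- function(r12, r1d, r23, r2d, r3d) {
  e1 <- 1 / (r12 + r1d)
  p12 <- r12 / (r12 + r1d)
  e2 <- 1 / (r23 + r2d)
  p23 <- r23 / (r23 + r2d)
  e3 <- 1 / r3d
  e1 + p12 * (e2 + p23 * e3)
}
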