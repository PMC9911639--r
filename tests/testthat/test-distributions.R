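# Closed-form hazard/survival of every family against flexsurv's published
# distribution functions, plus the proportional-hazards and improper-Gompertz
# contracts the engine relies on.

test_that("hazard and survival match independent distribution functions", {
  tt <- c(0.01, 0.5, 1, 3, 7.5, 20, 60)
  cases <- list(
    list(m = parametric_model("exponential", c(rate = 0.13)),
         S = function(t) pexp(t, 0.13, lower.tail = FALSE),
         h = function(t) flexsurv::hexp(t, 0.13)),
    list(m = parametric_model("weibull", c(shape = 1.4, rate = 0.05)),
         S = function(t) flexsurv::pweibullPH(t, 1.4, 0.05, lower.tail = FALSE),
         h = function(t) flexsurv::hweibullPH(t, 1.4, 0.05)),
    list(m = parametric_model("gompertz", c(shape = 0.06, rate = 0.02)),
         S = function(t) flexsurv::pgompertz(t, 0.06, 0.02, lower.tail = FALSE),
         h = function(t) flexsurv::hgompertz(t, 0.06, 0.02)),
    list(m = parametric_model("gompertz", c(shape = -0.08, rate = 0.05)),
         S = function(t) flexsurv::pgompertz(t, -0.08, 0.05, lower.tail = FALSE),
         h = function(t) flexsurv::hgompertz(t, -0.08, 0.05)),
    list(m = parametric_model("loglogistic", c(shape = 2.2, scale = 4)),
         S = function(t) flexsurv::pllogis(t, 2.2, 4, lower.tail = FALSE),
         h = function(t) flexsurv::hllogis(t, 2.2, 4)),
    list(m = parametric_model("lognormal", c(meanlog = 1.2, sdlog = 0.8)),
         S = function(t) plnorm(t, 1.2, 0.8, lower.tail = FALSE),
         h = function(t) flexsurv::hlnorm(t, 1.2, 0.8)))
  for (cs in cases) {
    expect_equal(surv_prob(cs$m, tt), cs$S(tt), tolerance = 1e-10)
    expect_equal(hazard_rate(cs$m, tt), cs$h(tt), tolerance = 1e-8)
    expect_identical(surv_prob(cs$m, 0), 1)
    expect_true(all(diff(surv_prob(cs$m, tt)) <= 0))
    expect_true(all(hazard_rate(cs$m, tt) >= 0))
  }
})

test_that("survival equals exp(-integrated hazard) for every family", {
  models <- list(
    parametric_model("exponential", c(rate = 0.2)),
    parametric_model("weibull", c(shape = 0.8, rate = 0.1)),
    parametric_model("gompertz", c(shape = 0.05, rate = 0.03)),
    parametric_model("gompertz", c(shape = -0.1, rate = 0.05)),
    parametric_model("loglogistic", c(shape = 1.7, scale = 6)),
    parametric_model("lognormal", c(meanlog = 1.5, sdlog = 1.1)))
  for (m in models) {
    for (t_end in c(2, 11, 40)) {
      H <- stats::integrate(function(u) hazard_rate(m, u), 0, t_end,
                            rel.tol = 1e-10)$value
      expect_equal(surv_prob(m, t_end), exp(-H), tolerance = 1e-6)
    }
  }
})

test_that("exponential hazard is constant and gompertz shape 0 degenerates to it", {
  me <- parametric_model("exponential", c(rate = 0.1))
  expect_equal(hazard_rate(me, c(0, 1, 50, 1000)), rep(0.1, 4))
  mg <- parametric_model("gompertz", c(shape = 0, rate = 0.1))
  tt <- c(0, 0.3, 5, 42)
  expect_equal(hazard_rate(mg, tt), hazard_rate(me, tt))
  expect_equal(surv_prob(mg, tt), surv_prob(me, tt))
  expect_equal(surv_prob(me, 10), exp(-1), tolerance = 1e-12)
})

test_that("PH covariates and hr multiplier scale the hazard exactly", {
  m0 <- parametric_model("gompertz", c(shape = 0.04, rate = 0.05))
  m1 <- parametric_model("gompertz", c(shape = 0.04, rate = 0.05),
                         coefs = c(x = log(2)))
  tt <- c(0.1, 2, 9, 33)
  expect_equal(hazard_rate(m1, tt, data.frame(x = 1)),
               2 * hazard_rate(m0, tt), tolerance = 1e-12)
  # multiplying hr by k multiplies the hazard by exactly k at all t
  for (k in c(0.25, 3)) {
    mk <- parametric_model("gompertz", c(shape = 0.04, rate = 0.05), hr = k)
    expect_equal(hazard_rate(mk, tt), k * hazard_rate(m0, tt),
                 tolerance = 1e-12)
  }
})

test_that("negative-shape gompertz has the closed-form cure mass", {
  m <- parametric_model("gompertz", c(shape = -0.1, rate = 0.05))
  s_inf <- exp(0.05 / (-0.1))          # exp(rate/shape): limit of S(t)
  expect_equal(surv_prob(m, 1e9), s_inf, tolerance = 1e-12)
  set.seed(71)
  x <- sample_event_time(m, 1e5)
  p_hat <- mean(is.infinite(x))
  expect_lt(abs(p_hat - s_inf), 4 * sqrt(s_inf * (1 - s_inf) / 1e5))
})

test_that("inverse-CDF sampling is deterministic under a seed and has the right mean", {
  m <- parametric_model("exponential", c(rate = 0.2))
  set.seed(9); a <- sample_event_time(m, 1000)
  set.seed(9); b <- sample_event_time(m, 1000)
  expect_identical(a, b)
  set.seed(10)
  x <- sample_event_time(m, 1e5)
  expect_lt(abs(mean(x) - 5), 3 * 5 / sqrt(1e5))   # SE of the mean = 1/(rate sqrt n)
})

test_that("AFT covariates accelerate time rather than scale hazard", {
  m <- parametric_model("lognormal", c(meanlog = 1, sdlog = 0.5),
                        coefs = c(z = 0.7))
  # S(t | z) = S0(t * exp(-0.7 z))
  expect_equal(surv_prob(m, 8, data.frame(z = 1)),
               plnorm(8 * exp(-0.7), 1, 0.5, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(parametric_model("lognormal", c(meanlog = 1, sdlog = 0.5),
                                hr = 2), "AFT")
})

test_that("model validation rejects bad inputs and evaluation rejects bad calls", {
  expect_error(parametric_model("exponential", c(rate = -1)), "positive")
  expect_error(parametric_model("weibull", c(shape = 1)), "needs parameters")
  expect_error(parametric_model("gompertz", c(shape = 0.1, rate = 0), hr = 1),
               "positive")
  expect_error(parametric_model("exponential", c(rate = 1), hr = -2),
               "positive")
  m <- parametric_model("exponential", c(rate = 1), coefs = c(x = 0.5))
  expect_error(hazard_rate(m, 1), "newdata")
  expect_error(hazard_rate(m, 1, data.frame(y = 1)), "x")
  expect_error(hazard_rate(m, -1, data.frame(x = 1)), "non-negative")
})
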