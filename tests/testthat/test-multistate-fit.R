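# Long-format multistate preparation and right-censored maximum likelihood.

test_that("prep_multistate reproduces a hand-enumerated transition table", {
  rows <- prep_multistate(hand_registry())
  # patient 1: full path DIAG->L1T(1)->L2T(4)->L3T(9)->death(15)
  p1 <- rows[rows$id == 1, c("transition", "time", "status", "status_type")]
  expect_setequal(p1$transition, c("diag_l1t", "l1t_l2t", "l1t_death",
                                   "l2t_l3t", "l2t_death", "l3t_death"))
  expect_equal(p1$time[p1$transition == "l1t_l2t"], 3)     # 4 - 1, line-local
  expect_equal(p1$status[p1$transition == "l1t_l2t"], 1)
  expect_equal(p1$time[p1$transition == "l1t_death"], 3)
  expect_equal(p1$status[p1$transition == "l1t_death"], 0)
  expect_equal(p1$status_type[p1$transition == "l1t_death"], "competing")
  expect_equal(p1$time[p1$transition == "l3t_death"], 6)   # 15 - 9
  expect_equal(p1$status[p1$transition == "l3t_death"], 1)
  # patient 2: BSC death at 2.3 => single row
  p2 <- rows[rows$id == 2, ]
  expect_equal(nrow(p2), 1L)
  expect_equal(p2$transition, "diag_death_bsc")
  expect_equal(p2$time, 2.3)
  expect_equal(p2$status, 1)
  # patient 3: censored alive in L2 at 30 => both L2 exits admin-censored
  p3 <- rows[rows$id == 3, ]
  expect_equal(p3$time[p3$transition == "l2t_l3t"], 23.5)  # 30 - 6.5
  expect_equal(p3$status[p3$transition == "l2t_l3t"], 0)
  expect_equal(p3$status_type[p3$transition == "l2t_l3t"], "admin")
  # p1: diag_l1t + two L1 exits + two L2 exits + L3 death = 6 rows;
  # p2: one BSC row; p3: diag_l1t + two L1 exits + two L2 exits = 5 rows
  expect_equal(nrow(rows), 6 + 1 + 5)
})

test_that("a treated-then-dead patient is censored for the next line at death", {
  reg <- hand_registry()[1, ]
  reg$t_l2t <- NA; reg$t_l3t <- NA; reg$t_death <- 8; reg$dead <- 1
  rows <- prep_multistate(reg)
  expect_equal(rows$time[rows$transition == "diag_l1t"], 1)
  expect_equal(rows$time[rows$transition == "l1t_l2t"], 7)
  expect_equal(rows$status[rows$transition == "l1t_l2t"], 0)
  expect_equal(rows$time[rows$transition == "l1t_death"], 7)
  expect_equal(rows$status[rows$transition == "l1t_death"], 1)
})

test_that("inconsistent records are rejected with diagnostics", {
  reg <- hand_registry()
  reg$t_l2t[1] <- 0.5                      # L2 before L1
  reg$t_l1t[3] <- NA                       # L2 without L1
  rows <- prep_multistate(reg)
  rej <- attr(rows, "rejected")
  expect_setequal(rej$id, c("1", "3"))
  expect_true(any(grepl("non-increasing", rej$reason)))
  expect_true(any(grepl("predecessor", rej$reason)))
  expect_true(all(rows$id == 2))
})

test_that("prep_multistate conserves person-time by state occupancy", {
  reg <- generate_registry(registry_spec(n = 400), seed = 7)
  rows <- prep_multistate(reg)
  for (i in sample(nrow(reg), 50)) {
    r <- reg[i, ]
    pr <- rows[rows$id == r$id, ]
    if (is.na(r$t_l1t)) {
      expect_equal(sum(pr$time), r$t_death)
    } else {
      # follow-up decomposes into one exposure per occupied state (the two
      # competing rows of a line share the same exposure, count it once)
      state_of <- c(diag_l1t = "diag", l1t_l2t = "l1t", l1t_death = "l1t",
                    l2t_l3t = "l2t", l2t_death = "l2t", l3t_death = "l3t")
      per_state <- tapply(pr$time, state_of[pr$transition], function(v) v[1])
      expect_equal(sum(per_state), r$t_death, tolerance = 1e-8)
    }
  }
})

test_that("exponential MLE equals events over exposure, all-censored errors", {
  rows <- data.frame(transition = "l3t_death",
                     time = c(rep(9, 10), rep(1, 10)),
                     status = rep(c(1, 0), each = 10))
  # 10 events, 100 person-months => rate 0.1
  fit <- fit_transition(rows, "exponential")
  expect_equal(unname(fit$model$params["rate"]), 0.1, tolerance = 1e-5)
  expect_equal(fit$n_event, 10)
  rows$status <- 0
  expect_error(fit_transition(rows, "exponential"), "censored")
  expect_error(fit_transition(rows[0, ], "exponential"), "no rows")
})

test_that("weibull parameters are recovered from censored data", {
  set.seed(51)
  n <- 2000
  true_shape <- 1.3; true_scale <- 10
  t_true <- rweibull(n, true_shape, true_scale)
  cens <- runif(n, 0, 25)
  rows <- data.frame(time = pmin(t_true, cens),
                     status = as.numeric(t_true <= cens))
  fit <- fit_transition(rows, "weibull")
  # package uses the PH form: H(t) = rate * t^shape, so rate = scale^-shape
  expect_equal(unname(fit$model$params["shape"]), true_shape, tolerance = 0.1)
  expect_equal(unname(fit$model$params["rate"]), true_scale^(-true_shape),
               tolerance = 0.15)
  bt <- fit$base_table
  expect_true(bt$lower[bt$term == "shape"] < true_shape &&
                true_shape < bt$upper[bt$term == "shape"])
})

test_that("backward selection keeps strong effects and drops null ones", {
  gen <- function(seed) {
    set.seed(seed)
    n <- 2000
    x_strong <- rbinom(n, 1, 0.5)
    x_null <- rnorm(n)
    rate <- 0.1 * exp(log(2) * x_strong)
    data.frame(time = rexp(n, rate), status = 1,
               x_strong = x_strong, x_null = x_null)
  }
  kept_strong <- 0; dropped_null <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    fit <- backward_select(gen(600 + r), "exponential",
                           c("x_strong", "x_null"), alpha = 0.05)
    kept_strong <- kept_strong + ("x_strong" %in% fit$covariates)
    dropped_null <- dropped_null + (!"x_null" %in% fit$covariates)
  }
  expect_gte(kept_strong / reps, 0.95)
  expect_gte(dropped_null / reps, 0.85)   # ~5% type-I retention expected
})

test_that("backward selection degenerate settings behave as documented", {
  d <- data.frame(time = rexp(300, 0.2), status = 1,
                  a = rnorm(300), b = rnorm(300))
  all_kept <- backward_select(d, "exponential", c("a", "b"), alpha = 1)
  expect_setequal(all_kept$covariates, c("a", "b"))
  none <- backward_select(d, "exponential", character(0))
  expect_length(none$covariates, 0)
  expect_error(backward_select(d, "exponential", "a", alpha = 0), "alpha")
  # identical input => identical selected covariate set
  s1 <- backward_select(d, "exponential", c("a", "b"), alpha = 0.05)
  s2 <- backward_select(d, "exponential", c("a", "b"), alpha = 0.05)
  expect_identical(s1$covariates, s2$covariates)
})

test_that("treatment-decision model recovers known coefficients", {
  set.seed(52)
  n <- 5000
  x <- rnorm(n)
  p <- plogis(-0.6 + 0.8 * x)
  reg <- data.frame(year = 2010, age = 65 + 10 * x, sex = "male",
                    ps = "good", cci = 0,
                    t_l1t = ifelse(runif(n) < p, 1, NA),
                    t_l2t = NA, t_l3t = NA, t_death = 10, dead = 1)
  fit <- fit_treatment_decision(reg, covariates = "age65")
  # age65 = 10 x => coefficient 0.8 / 10, recovered within +-0.1 on the
  # original scale (0.0125 here)
  expect_lt(abs(unname(fit$coefs["age65"]) - 0.08), 0.0125)
  # intercept-only model: treated fraction 35% => logit(0.35)
  fit0 <- fit_treatment_decision(
    data.frame(year = 2010, age = 65, sex = "male", ps = "good", cci = 0,
               t_l1t = c(rep(1, 3500), rep(NA, 6500)),
               t_l2t = NA, t_l3t = NA, t_death = 10, dead = 1),
    covariates = character(0))
  expect_equal(unname(fit0$coefs["(Intercept)"]), qlogis(0.35),
               tolerance = 1e-6)
  expect_equal(unname(predict_decision(fit0, data.frame(x = 1))), 0.35,
               tolerance = 1e-9)
  # single-class outcome errors
  reg_all <- reg; reg_all$t_l1t <- 1
  expect_error(fit_treatment_decision(reg_all), "both")
})
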