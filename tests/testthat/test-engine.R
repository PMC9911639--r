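# The discrete-event core: trajectory structure, competing transitions,
# background mortality, reproducibility, summaries.

test_that("BSC patients have DIAG-Death trajectories and treated ones respect order", {
  models <- exp_models()
  pool <- tiny_pool()
  coh <- simulate_cohort(2000, models, decision = 0.5, attributes = pool,
                         seed = 101)
  long <- trajectories_long(coh)
  bsc_ids <- coh$id[!coh$treated]
  expect_true(all(table(long$id[long$id %in% bsc_ids]) == 2))  # DIAG + Death
  # every trajectory: strictly increasing times, Death terminal, <= 3 lines
  for (i in sample(coh$id, 200)) {
    tr <- long[long$id == i, ]
    expect_true(all(diff(tr$time_months) > 0) || nrow(tr) == 2)
    expect_equal(tr$event[nrow(tr)], "Death")
    expect_lte(sum(tr$event %in% c("L1T", "L2T", "L3T")), 3)
  }
  # line ordering is never skipped
  expect_true(all(is.na(coh$t_l3t) | !is.na(coh$t_l2t)))
  expect_true(all(is.na(coh$t_l2t) | !is.na(coh$t_l1t)))
  expect_true(all(coh$t_death >= coh$t_l1t, na.rm = TRUE))
})

test_that("zero disease hazards leave only background mortality", {
  tiny <- 1e-12
  models <- exp_models(r12 = tiny, r1d = tiny, r23 = tiny, r2d = tiny,
                       r3d = tiny)
  lt <- life_table(data.frame(sex = rep(c("male", "female"), each = 2),
                              age = rep(c(50, 51), 2), qx = 1 - exp(-0.5)))
  pool <- tiny_pool()
  pool$age <- 50
  coh <- simulate_cohort(500, models, decision = 1, attributes = pool,
                         life_table = lt, seed = 102)
  expect_true(all(coh$cause == "other"))
  # death times are the life-table times, exponential rate 0.5/yr
  expect_lt(abs(mean(coh$t_death) / 12 - 2), 0.3)
})

test_that("the fraction progressing to L2T matches the competing-exponential oracle", {
  models <- exp_models(r12 = 0.08, r1d = 0.04)
  pool <- tiny_pool()
  coh <- simulate_cohort(1e5, models, decision = 1, attributes = pool,
                         seed = 103)
  p_hat <- mean(!is.na(coh$t_l2t))
  p <- 0.08 / 0.12
  expect_lt(abs(p_hat - p), 3 * sqrt(p * (1 - p) / 1e5))
})

test_that("simulation is reproducible under a seed and streams are split", {
  fitobj <- local({
    reg <- generate_registry(registry_spec(n = 800), seed = 5)
    fit_parmssm(reg)
  })
  lt <- generate_life_table()
  a <- simulate(fitobj, nsim = 500, seed = 7, life_table = lt)
  b <- simulate(fitobj, nsim = 500, seed = 7, life_table = lt)
  expect_identical(a, b)
  c2 <- simulate(fitobj, nsim = 500, seed = 8, life_table = lt)
  expect_false(identical(a$t_death, c2$t_death))
})

test_that("the BSC subgroup is identical across strategies under a shared seed", {
  fitobj <- local({
    reg <- generate_registry(registry_spec(n = 800), seed = 5)
    fit_parmssm(reg)
  })
  lt <- generate_life_table()
  st <- default_strategy()
  np <- simulate(fitobj, nsim = 2000, seed = 11, life_table = lt)
  pp <- simulate(fitobj, nsim = 2000, seed = 11, strategy = st,
                 life_table = lt)
  expect_identical(np$treated, pp$treated)
  i <- !np$treated
  expect_identical(np$t_death[i], pp$t_death[i])
  expect_identical(np$cause[i], pp$cause[i])
})

test_that("summaries reproduce hand-computed medians and means", {
  coh <- structure(data.frame(
    id = 1:4,
    year = 2010, age = 65, sex = "male", ps = "good", cci = 0,
    age65 = 0, sex_female = 0, ps_bad = 0,
    treated = c(TRUE, TRUE, TRUE, FALSE),
    driver = NA_character_, pdl1 = NA_character_,
    treatment1 = c("chemo", "chemo", "chemo", NA),
    treatment2 = NA_character_, treatment3 = NA_character_,
    long_term = FALSE,
    t_l1t = c(1, 1, 1, NA), t_l2t = NA_real_, t_l3t = NA_real_,
    t_death = c(3, 5, 13, 4), cause = "disease",
    stringsAsFactors = FALSE), class = c("nsclc_cohort", "data.frame"))
  sm <- summarize_cohort(coh)
  treated <- sm[sm$subgroup == "Treated (all)", ]
  expect_equal(treated$n, 3)
  expect_equal(treated$median_os, 4)       # OS from L1T: {2, 4, 12}
  expect_equal(treated$mean_os, 6)
  bsc <- sm[sm$subgroup == "BSC", ]
  expect_equal(bsc$n, 1)
  expect_equal(bsc$median_os, 4)           # BSC OS runs from diagnosis
  expect_true(is.na(bsc$median_pfs))
  # an all-BSC cohort has an empty treated row
  coh2 <- coh; coh2$treated <- FALSE; coh2$t_l1t <- NA_real_
  coh2$treatment1 <- NA_character_
  sm2 <- summarize_cohort(coh2)
  expect_equal(sm2$n[sm2$subgroup == "Treated (all)"], 0)
  expect_true(is.na(sm2$median_os[sm2$subgroup == "Treated (all)"]))
})

test_that("mean OS matches the phase-type oracle for an all-exponential pathway", {
  r12 <- 0.08; r1d <- 0.08; r23 <- 0.05; r2d <- 0.12; r3d <- 0.15
  models <- exp_models(r12 = r12, r1d = r1d, r23 = r23, r2d = r2d, r3d = r3d)
  coh <- simulate_cohort(1e5, models, decision = 1, attributes = tiny_pool(),
                         seed = 104)
  os <- endpoint_times(coh, "os1")
  target <- phase_type_mean_os(r12, r1d, r23, r2d, r3d)
  expect_lt(abs(mean(os) - target), 3 * stats::sd(os) / sqrt(length(os)))
})

test_that("simulate_patient runs a single fixed-attribute patient", {
  models <- exp_models()
  p <- simulate_patient(
    data.frame(year = 2012, age = 70, sex = "female", ps = "good", cci = 1),
    treated = FALSE, models = models, seed = 105)
  expect_equal(nrow(p), 1L)
  expect_false(p$treated)
  expect_true(is.finite(p$t_death))
  long <- trajectories_long(p)
  expect_equal(long$event, c("DIAG", "Death"))
})

test_that("missing transition models are reported", {
  m <- exp_models(); m$l2t_death <- NULL
  expect_error(simulate_cohort(10, m, 1, tiny_pool()), "l2t_death")
})
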