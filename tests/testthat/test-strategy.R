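# Biomarker assignment, decision-tree resolution, hazard modifiers and
# mixture-cure membership.

test_that("the shipped strategy validates and resolves the documented pathways", {
  st <- default_strategy()
  # ALK: alectinib first line, lorlatinib after it
  expect_equal(resolve_treatment("alk", "lt1", 1, NULL, st), "alectinib")
  expect_equal(resolve_treatment("alk", "lt1", 2, "alectinib", st),
               "lorlatinib")
  # BRAF second line resolves through the PD-L1 branch
  expect_equal(resolve_treatment("braf", "ge50", 1, NULL, st),
               "dabrafenib_trametinib")
  expect_equal(resolve_treatment("braf", "ge50", 2, "dabrafenib_trametinib",
                                 st), "pembrolizumab")
  # no driver, PD-L1 >= 50%: pembrolizumab-containing first line, then chemo
  t1 <- resolve_treatment("none", "ge50", 1, NULL, st, u = 0.1)
  expect_equal(t1, "pembrolizumab")
  expect_equal(resolve_treatment("none", "ge50", 1, NULL, st, u = 0.9),
               "pembro_chemo")
  expect_equal(resolve_treatment("none", "ge50", 2, "pembrolizumab", st),
               "chemo")
  # KRAS routes through the PD-L1 branch (no targeted first-line therapy)
  expect_equal(resolve_treatment("kras", "pd1_49", 1, NULL, st),
               "pembro_chemo")
  # third line is always chemotherapy
  expect_equal(resolve_treatment("alk", "ge50", 3, "lorlatinib", st), "chemo")
  # classic-EGFR mixture is deterministic given the uniform draw
  expect_equal(resolve_treatment("egfr_classic", "lt1", 1, NULL, st, u = 0.2),
               "gefitinib")
  expect_equal(resolve_treatment("egfr_classic", "lt1", 1, NULL, st, u = 0.7),
               "erlotinib")
})

test_that("transition modifiers combine treatment, prognosis, wear-out and cure", {
  st <- default_strategy()
  g <- build_transition_modifiers("gefitinib", "egfr_classic", st, line = 1)
  expect_equal(g$hr_next, 0.43 * 0.82)
  expect_equal(g$hr_death, 0.43 * 0.82)
  expect_equal(g$wearout, 15)
  expect_equal(g$cure, 0)
  p <- build_transition_modifiers("pembrolizumab", "none", st, line = 1)
  expect_equal(p$hr_next, 0.5)
  expect_equal(p$cure, 0.23)
  expect_equal(p$wearout, Inf)
  # alectinib benefit is durable
  expect_equal(build_transition_modifiers("alectinib", "alk", st)$wearout, Inf)
  # chemotherapy is the identity
  ch <- build_transition_modifiers("chemo", "none", st)
  expect_equal(ch$hr_next, 1); expect_equal(ch$cure, 0)
  # prognostic effects apply in line 1 only
  expect_equal(build_transition_modifiers("chemo", "egfr_classic", st,
                                          line = 2)$hr_next, 1)
  expect_equal(build_transition_modifiers("chemo", "egfr_classic", st,
                                          line = 1)$hr_next, 0.82)
  expect_error(build_transition_modifiers("nonexistent", "none", st),
               "no hazard ratio")
})

test_that("strategy validation enumerates violations including totality", {
  st <- unclass(default_strategy())
  st$line1_treatments <- NULL; st$line2_treatments <- NULL
  bad <- st
  bad$hr$gefitinib <- -0.4
  bad$prevalence$alk <- 0.5                # sum != 1
  bad$tree$pdl1_line1$lt1 <- NULL          # unreachable PD-L1 category
  err <- tryCatch(validate_strategy(bad), error = conditionMessage)
  expect_match(err, "hazard ratios must be positive")
  expect_match(err, "sum to 1")
  expect_match(err, "pdl1_line1 lacks category 'lt1'")
  bad2 <- st
  bad2$cure$pembrolizumab <- 1.2
  expect_error(validate_strategy(bad2), "\\[0, 1\\]")
  bad3 <- st
  bad3$tree$line1$ros1 <- NULL
  expect_error(validate_strategy(bad3), "lacks driver 'ros1'")
  bad4 <- st
  bad4$hr$lorlatinib <- NULL
  expect_error(validate_strategy(bad4), "hr table lacks")
})

test_that("strategies round-trip through YAML with validation on load", {
  st <- default_strategy()
  path <- tempfile(fileext = ".yaml")
  write_strategy(st, path)
  st2 <- load_strategy(path)
  expect_equal(st2$hr, st$hr)
  expect_equal(st2$tree, st$tree)
  expect_equal(st2$cure, st$cure)
  # a corrupted file fails with a named error
  raw <- yaml::read_yaml(path)
  raw$hr$chemo <- 0
  yaml::write_yaml(raw, path)
  expect_error(load_strategy(path), "positive")
})

test_that("biomarker assignment matches the configured distributions", {
  set.seed(61)
  st <- default_strategy()
  bm <- assign_biomarkers(1e5, st$prevalence, st$pdl1)
  expect_lt(abs(mean(bm$driver == "egfr_classic") - 0.071), 0.005)
  expect_lt(abs(mean(bm$pdl1 == "ge50") - 0.30), 0.006)
  # degenerate prevalence: everyone ALK
  prev1 <- lapply(st$prevalence, function(x) 0)
  prev1$alk <- 1
  bm1 <- assign_biomarkers(50, prev1, st$pdl1)
  expect_true(all(bm1$driver == "alk"))
  expect_equal(nrow(assign_biomarkers(0, st$prevalence, st$pdl1)), 0L)
  prevbad <- st$prevalence; prevbad$alk <- 0.5
  expect_error(assign_biomarkers(10, prevbad, st$pdl1), "sum to 1")
})

test_that("long-term survivor assignment is Bernoulli(f) with exact edges", {
  expect_false(any(assign_longterm(1000, 0)))
  expect_true(all(assign_longterm(1000, 1)))
  set.seed(62)
  expect_lt(abs(mean(assign_longterm(1e5, 0.23)) - 0.23), 0.004)
  expect_error(assign_longterm(10, 1.5), "\\[0, 1\\]")
})
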