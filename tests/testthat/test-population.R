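test_that("population generation is seeded, sized and spec-checked", {
  spec <- population_spec(25, fw_range = c(27, 38), seed = 7)
  p1 <- generate_population(spec)
  p2 <- generate_population(spec)
  expect_length(p1, 25)
  expect_identical(p1, p2)
  fw <- vapply(p1, `[[`, numeric(1), "fw")
  expect_true(all(fw >= 27 & fw <= 38))
  # individual fu follows each individual's FW
  b <- plasma_binding_model()
  fus <- vapply(p1, function(ind) ind$cp$fu, numeric(1))
  expect_equal(fus, fraction_unbound(fw, b), tolerance = 1e-9)
  expect_error(population_spec(10, fw_range = c(1, 11)), "seed")
})

test_that("sampled intrinsic-clearance variability recovers the input CV", {
  spec <- population_spec(5000, variability = list(CLint = 0.35, CL_TSspec = 0.25,
                                                   body_weight = 0.15),
                          seed = 11)
  pop <- generate_population(spec)
  cl <- vapply(pop, function(ind) ind$cp$CLint[["CYP1A2"]], numeric(1))
  cv <- sd(cl) / mean(cl)
  expect_gt(cv, 0.32); expect_lt(cv, 0.38)
  bw <- vapply(pop, function(ind) ind$phys$body_weight, numeric(1))
  expect_gt(sd(bw) / mean(bw), 0.12); expect_lt(sd(bw) / mean(bw), 0.18)
})

test_that("geometric mean matches the log-normal closed form", {
  set.seed(3)
  x <- rlnorm(1e4, meanlog = 1.2, sdlog = 0.5)
  expect_equal(geometric_mean(x), exp(1.2), tolerance = 0.02)
  expect_error(geometric_mean(c(1, -1)), "positive")
})

test_that("population summaries collapse for identical inputs and nest percentiles", {
  sims <- replicate(5, fx("sim_single"), simplify = FALSE)
  s <- population_summary(sims)
  expect_equal(s$bands$p05, s$bands$p95)
  expect_equal(s$bands$p50, fx("sim_single")$plasma_concentration)
  # nested bands for a genuinely variable population
  spec <- population_spec(8, seed = 5)
  pop <- generate_population(spec)
  sims2 <- lapply(pop, function(ind) {
    simulate_pbpk(build_model(ind$phys, ind$cp, fx("scaling")),
                  dosing_regimen(10), t_end = 96, dt = 0.5)
  })
  s2 <- population_summary(sims2, lapply(sims2, pk_metrics, mode = "single"))
  expect_true(all(s2$bands$p05 <= s2$bands$p50 + 1e-12))
  expect_true(all(s2$bands$p50 <= s2$bands$p95 + 1e-12))
  expect_true(is.finite(s2$gm_metrics[["AUC"]]))
  expect_error(population_summary(list(sims2[[1]],
                                       simulate_pbpk(fx("model"), dosing_regimen(10),
                                                     t_end = 48, dt = 0.5))),
               "common time grid")
})

test_that("trimester populations reproduce the representative relative changes", {
  # matched (common-random-number) populations: same seed for the pregnant
  # and baseline groups so the clearance variability cancels in the ratio
  n <- 200
  seed <- 20260927
  base_pop <- generate_population(population_spec(n, seed = seed))
  t3_pop <- generate_population(population_spec(n, fw_range = c(27, 38),
                                                seed = seed))
  auc_one <- function(ind) {
    sim <- simulate_pbpk(build_model(ind$phys, ind$cp, fx("scaling")),
                         dosing_regimen(10), t_end = 504, dt = 0.5)
    pk_metrics(sim, "single")$AUC   # equals AUC_tau at steady state (linear PK)
  }
  auc_b <- vapply(base_pop, auc_one, numeric(1))
  auc_3 <- vapply(t3_pop, auc_one, numeric(1))
  pop_change <- 100 * (geometric_mean(auc_3) / geometric_mean(auc_b) - 1)
  rep_change <- relative_change(pk_metrics(fx_ss_fw(34)), pk_metrics(fx("sim_ss")))[["AUC"]]
  expect_lt(abs(pop_change - rep_change), 4)
})
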