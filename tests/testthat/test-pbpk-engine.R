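test_that("model assembly is structurally sound", {
  model <- fx("model")
  # 18 maternal drug compartments + 1 lumen-solid bookkeeping state
  drug_states <- setdiff(model$states, paste0("elim_", c(
    "CYP1A2", "CYP3A4", "CYP2C8", "FMO3", "UGT1A4", "GFR", "TS")))
  expect_length(drug_states, 19)
  expect_equal(max(abs(colSums(model$A))), 0, tolerance = 1e-12)
  # pregnant model gains the gestational compartments
  ph <- pregnancy_physiology(fx("phys"), 34)
  mp <- build_model(ph, pregnant_compound_params(fx("cp"), 34, "table2_canonical"),
                    fx("scaling"))
  expect_true(all(c("uterus", "placenta", "mammary", "fetus") %in% mp$states))
})

test_that("simulation is deterministic, mass-conserving and dose-linear", {
  model <- fx("model")
  sim <- fx("sim_single")
  expect_lt(mass_balance_error(sim), 1e-6)
  sim2 <- simulate_pbpk(model, dosing_regimen(10), t_end = 504)
  expect_identical(sim$plasma_concentration, sim2$plasma_concentration)
  # strict dose proportionality of the linear system
  s20 <- simulate_pbpk(model, dosing_regimen(20), t_end = 504)
  expect_equal(s20$plasma_concentration, 2 * sim$plasma_concentration,
               tolerance = 1e-10)
  m1 <- pk_metrics(sim, "single"); m2 <- pk_metrics(s20, "single")
  expect_equal(m2$AUC / m1$AUC, 2, tolerance = 1e-6)
  expect_equal(m2$Cmax / m1$Cmax, 2, tolerance = 1e-10)
  expect_true(all(sim$amounts > -1e-9))
})

test_that("with no elimination the dose is conserved and distribution plateaus", {
  cp <- fx("cp")
  cp$GFR_fraction <- 0
  cp$CL_TSspec_L_per_min <- 0
  no_elim <- list(s = stats::setNames(rep(0, 5), names(cp$CLint)))
  m <- build_model(fx("phys"), cp, no_elim)
  sim <- simulate_pbpk(m, dosing_regimen(10), t_end = 2000, dt = 0.5)
  expect_lt(mass_balance_error(sim), 1e-9)
  expect_equal(sum(sim$eliminated[nrow(sim$eliminated), ]), 0)
  # plasma approaches dose / Vss
  dose_umol <- sim$dose_events$amount_umol[1]
  vss <- sum(m$VK) + m$V[["gut_lumen"]] * 0  # all drug ends in perfused space
  c_inf <- dose_umol / vss * cp$MW
  n <- length(sim$time)
  expect_equal(sim$plasma_concentration[n], c_inf, tolerance = 1e-3)
})

test_that("matrix-exponential and lsoda paths agree and tolerances are converged", {
  model <- fx("model")
  reg <- dosing_regimen(10)
  s_me <- simulate_pbpk(model, reg, t_end = 168, dt = 0.5)
  s_ls <- simulate_pbpk(model, reg, t_end = 168, dt = 0.5, method = "lsoda")
  expect_equal(s_ls$plasma_concentration, s_me$plasma_concentration,
               tolerance = 1e-5)
  auc <- function(s) pracma::trapz(s$time, s$plasma_concentration)
  s_tight <- simulate_pbpk(model, reg, t_end = 168, dt = 0.5, method = "lsoda",
                           rtol = 5e-9, atol = 5e-11)
  expect_lt(abs(auc(s_tight) - auc(s_ls)) / auc(s_ls), 1e-3)
})

test_that("repeated dosing reaches steady state and obeys superposition", {
  ss <- fx("sim_ss")
  expect_false(is.null(ss$ss_interval))
  expect_lt(mass_balance_error(ss), 1e-6)
  mss <- pk_metrics(ss)
  msingle <- pk_metrics(fx("sim_single"), "single")
  # AUC over the steady-state interval equals single-dose AUC_0-inf (linear PK)
  expect_equal(mss$AUC / msingle$AUC, 1, tolerance = 0.01)
  # explicit superposition: the steady-state profile equals the sum of
  # time-shifted single-dose profiles
  single <- fx("sim_single")
  dt <- 0.1
  n_int <- round(24 / dt)
  n_dose <- nrow(ss$dose_events)
  super <- numeric(n_int + 1)
  for (k in seq_len(n_dose)) {
    off <- round((ss$ss_interval[1] - ss$dose_events$time[k]) / dt)
    seg <- single$plasma_concentration[off + seq_len(n_int + 1)]
    seg[is.na(seg)] <- 0
    super <- super + seg
  }
  in_int <- ss$time >= ss$ss_interval[1] - 1e-9 & ss$time <= ss$ss_interval[2] + 1e-9
  expect_equal(ss$plasma_concentration[in_int], super, tolerance = 0.01)
  # convergence failure is reported
  expect_error(simulate_to_steady_state(fx("model"), dosing_regimen(10, 24, 40),
                                        conv_tol = 1e-9, max_doses = 5),
               "steady state")
})

test_that("a one-compartment reduction reproduces the analytic AUC", {
  # collapsing distribution: analytic AUC = F * Dose / CL with F the
  # hepatic availability and CL the calibrated systemic clearance
  sc <- fx("scaling")
  f_h <- 1 - sc$CL_hepatic / sc$Q_h
  dose_ng <- 10 * 1e6
  auc_analytic <- f_h * dose_ng / (sc$CL_total * 1000)
  m <- pk_metrics(fx("sim_single"), "single")
  expect_equal(m$AUC, auc_analytic, tolerance = 0.02)
})

test_that("simulation export writes tidy CSVs", {
  tmp1 <- withr::local_tempfile(fileext = ".csv")
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  export_simulation(fx("sim_single"), tmp1, tmp2)
  conc <- read.csv(tmp1)
  expect_named(conc, c("time_h", "plasma_ng_per_mL"))
  amts <- read.csv(tmp2)
  expect_named(amts, c("time_h", "compartment", "amount_umol"))
  expect_true("liver" %in% amts$compartment)
})
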