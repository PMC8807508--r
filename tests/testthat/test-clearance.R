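test_that("Rowland-Matin algebra: limits, the reported DDI case, and inversion", {
  # no inhibition
  expect_equal(rowland_matin_aucr(0.8, 0.6, 0), 1)
  # complete inhibition of a pathway carrying half the clearance
  expect_equal(rowland_matin_aucr(1, 0.5, Inf), 2)
  # the observed AUC ratio of 1.76 with fm = 0.5 implies r ~ 6.33
  r <- uniroot(function(r) rowland_matin_aucr(1, 0.5, r) - 1.76,
               c(0.1, 100), tol = 1e-12)$root
  expect_equal(r, 6.33, tolerance = 1e-3)
  expect_equal(solve_fm_from_aucr(1.76, r), 0.5, tolerance = 1e-9)
  # inversion limits
  expect_equal(solve_fm_from_aucr(2, Inf), 0.5)
  expect_equal(solve_fm_from_aucr(1, 5), 0)
  expect_error(solve_fm_from_aucr(0.9, 5), "aucr")
  expect_error(solve_fm_from_aucr(1.5, 0), "no solution")
  # round-trip identity on a grid of the shared domain
  for (fm in c(0.1, 0.3, 0.5, 0.8)) {
    for (r in c(0.5, 2, 10)) {
      aucr <- rowland_matin_aucr(1, fm, r)
      expect_equal(solve_fm_from_aucr(aucr, r), fm, tolerance = 1e-9)
    }
  }
})

test_that("renal clearance components scale as specified", {
  cp <- fx("cp"); phys <- fx("phys")
  rc <- renal_clearance(cp, phys)
  expect_equal(rc$filtration, cp$fu * phys$GFR)
  expect_equal(rc$secretion, cp$fu * 0.31 * phys$kidney_volume * 60)
  cp0 <- cp; cp0$fu <- 1e-12
  expect_lt(renal_clearance(cp0, phys)$filtration, 1e-10)
  ph2 <- phys; ph2$kidney_volume <- 2 * phys$kidney_volume
  expect_equal(renal_clearance(cp, ph2)$secretion, 2 * rc$secretion)
})

test_that("clearance calibration reproduces the published dose-fraction decomposition", {
  bd <- clearance_breakdown(fx("sim_single"))
  expect_equal(sum(bd$fractions), 1, tolerance = 1e-9)
  expect_equal(bd$fractions[["CYP1A2"]], 0.50, tolerance = 0.02)
  expect_equal(bd$fractions[["UGT1A4"]], 0.23, tolerance = 0.02)
  expect_equal(bd$renal, 0.07, tolerance = 0.01)
  expect_gt(bd$eliminated_fraction_of_dose, 0.95)
})

test_that("breakdown fractions are dose-independent and homogeneous in CLint", {
  model <- fx("model")
  f <- lapply(c(5, 10, 20), function(d) {
    clearance_breakdown(simulate_pbpk(model, dosing_regimen(d), t_end = 504))$fractions
  })
  expect_equal(f[[1]], f[[2]], tolerance = 1e-9)
  expect_equal(f[[2]], f[[3]], tolerance = 1e-9)
  # common scaling of all CLint leaves hepatic flux ratios unchanged
  cp2 <- fx("cp"); cp2$CLint <- cp2$CLint * 1.5
  m2 <- build_model(fx("phys"), cp2, fx("scaling"))
  f2 <- clearance_breakdown(simulate_pbpk(m2, dosing_regimen(10), t_end = 504))$fractions
  hep <- c("CYP1A2", "CYP3A4", "CYP2C8", "FMO3", "UGT1A4")
  expect_equal(f2[hep] / sum(f2[hep]), f[[2]][hep] / sum(f[[2]][hep]),
               tolerance = 1e-6)
})

test_that("static inhibition scales one pathway and matches the DDI algebra", {
  cp <- fx("cp")
  expect_identical(apply_static_inhibition(cp, "CYP1A2", 0), cp)
  expect_equal(apply_static_inhibition(cp, "CYP1A2", 1)$CLint[["CYP1A2"]],
               cp$CLint[["CYP1A2"]] / 2)
  expect_equal(apply_static_inhibition(cp, "CYP1A2", Inf)$CLint[["CYP1A2"]], 0)
  expect_error(apply_static_inhibition(cp, "CYP9Z9", 1), "unknown enzyme")
  # near-complete CYP1A2 inhibition: the simulated AUC ratio approaches the
  # Rowland-Matin prediction for the simulated fraction metabolized
  base <- pk_metrics(fx("sim_single"), "single")
  m_i <- build_model(fx("phys"), apply_static_inhibition(cp, "CYP1A2", Inf),
                     fx("scaling"))
  inh <- pk_metrics(simulate_pbpk(m_i, dosing_regimen(10), t_end = 504), "single")
  aucr_sim <- inh$AUC / base$AUC
  fm <- clearance_breakdown(fx("sim_single"))$fractions[["CYP1A2"]]
  expect_equal(aucr_sim, rowland_matin_aucr(1, fm, Inf), tolerance = 0.05)
})
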