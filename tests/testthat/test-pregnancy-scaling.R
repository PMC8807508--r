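test_that("KA calibration reproduces the reference fu and the trimester row", {
  b <- plasma_binding_model()
  expect_equal(fraction_unbound(0, b), 0.07, tolerance = 1e-9)
  expect_equal(round(fraction_unbound(6, b), 3), 0.075)
  expect_equal(round(fraction_unbound(20, b), 3), 0.085)
  expect_equal(round(fraction_unbound(34, b), 3), 0.091)
  # strictly increasing, bounded above by the asymptotic-albumin value
  fw <- seq(0, 40, 0.5)
  fu <- fraction_unbound(fw, b)
  expect_true(all(diff(fu) > 0))
  lim <- 1 / (1 + b$KA * 31.7 / b$MW_albumin * 1e6)
  expect_true(all(fu < lim))
  expect_error(fraction_unbound(6, structure(list(), class = "plasma_binding_model")),
               "calibrated")
})

test_that("enzyme activity trajectories evaluate to their known values", {
  expect_equal(cyp1a2_activity_change(0), 0)
  expect_equal(cyp1a2_activity_change(20), -43.76)
  expect_equal(cyp1a2_activity_change(34), -60.5404)
  expect_equal(ugt1a4_activity_change(0), 0)
  expect_equal(ugt1a4_activity_change(6), 40.80792)
  expect_equal(ugt1a4_activity_change(20), 74.74)
  expect_equal(cyp3a4_activity(0), 1.00736)
  expect_equal(cyp3a4_activity(20), 1.56816)
  expect_equal(cyp3a4_activity(34), 2.00832)
  expect_equal(fmo3_activity(6), 1)
  expect_equal(fmo3_activity(34), 7.11 / 4.05)
  expect_equal(fmo3_activity(34, mode = "literature"), 1.58)
})

test_that("canonical trimester parameter sets match the printed table bit-exactly", {
  cp <- fx("cp")
  expected <- list(
    `6` = list(fu = 0.075, CLint = c(CYP1A2 = 22.40, CYP3A4 = 0.89,
                                     CYP2C8 = 2.14, FMO3 = 4.05, UGT1A4 = 28.24)),
    `20` = list(fu = 0.085, CLint = c(CYP1A2 = 14.13, CYP3A4 = 1.28,
                                      CYP2C8 = 2.14, FMO3 = 4.05, UGT1A4 = 35.04)),
    `34` = list(fu = 0.091, CLint = c(CYP1A2 = 9.87, CYP3A4 = 1.64,
                                      CYP2C8 = 2.14, FMO3 = 7.11, UGT1A4 = 36.91))
  )
  for (fw in c(6, 20, 34)) {
    p <- pregnant_compound_params(cp, fw, "table2_canonical")
    expect_identical(p$fu, expected[[as.character(fw)]]$fu)
    expect_identical(p$CLint, expected[[as.character(fw)]]$CLint)
    # composite intrinsic clearance alters by less than 20 %
    expect_lt(abs(sum(p$CLint) / sum(cp$CLint) - 1), 0.20)
  }
  # enzyme scaling applied to baseline values reproduces the printed entries
  expect_equal(20.06 * (1 + ugt1a4_activity_change(6) / 100), 28.24,
               tolerance = 1e-3)
  expect_equal(0.82 * cyp3a4_activity(34), 1.64, tolerance = 5e-3)
})

test_that("equation mode is continuous, leaves CYP2C8 unchanged and warns off-grid", {
  cp <- fx("cp")
  p0 <- pregnant_compound_params(cp, 0, "equation_generated")
  expect_equal(p0$fu, cp$fu, tolerance = 1e-9)
  expect_equal(p0$CLint[["CYP2C8"]], cp$CLint[["CYP2C8"]])
  expect_equal(p0$CLint[["CYP3A4"]], cp$CLint[["CYP3A4"]] * 1.00736)
  expect_equal(p0$CLint[["CYP1A2"]], cp$CLint[["CYP1A2"]])
  # continuity in FW (FMO3 steps at the third-trimester onset by design,
  # so continuity is checked for the other components)
  fw <- seq(0, 40, by = 0.05)
  cl <- vapply(fw, function(w) {
    p <- pregnant_compound_params(cp, w, "equation_generated")
    sum(p$CLint[c("CYP1A2", "CYP3A4", "CYP2C8", "UGT1A4")]) + p$fu
  }, numeric(1))
  expect_lt(max(abs(diff(cl))), 0.1)
  expect_warning(p <- pregnant_compound_params(cp, 15, "table2_canonical"),
                 "falling back")
  expect_equal(p$fu, fraction_unbound(15, plasma_binding_model()))
})

test_that("weighted cubic fit recovers the trajectory and responds to weights", {
  pts <- generate_lamotrigine_points(noise_sd = 0)
  expect_identical(sort(unique(pts$weight)), c(7, 11, 53))
  co <- fit_ugt1a4_cubic(pts$FW, pts$percent_change, pts$weight)
  expect_equal(unname(co), c(8.669, -0.339, 0.00462), tolerance = 1e-6)
  # noisy recovery under the study-size weights (seeded, parameter-recovery)
  noisy <- generate_lamotrigine_points(noise_sd = 10, seed = 42)
  con <- fit_ugt1a4_cubic(noisy$FW, noisy$percent_change, noisy$weight)
  expect_lt(abs(con[["a1"]] - 8.669), 2)
  expect_lt(abs(con[["a2"]] + 0.339), 0.25)
  # equal vs study-size weights give different normal equations
  ceq <- fit_ugt1a4_cubic(noisy$FW, noisy$percent_change)
  expect_false(isTRUE(all.equal(unname(con), unname(ceq))))
  expect_error(fit_ugt1a4_cubic(c(1, 2, 3), c(1, 2, 3)), "4 points")
  expect_error(fit_ugt1a4_cubic(rep(5, 5), rnorm(5)), "rank")
})

test_that("activity profile export covers the FW grid", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  out <- export_activity_profiles(tmp, FW = seq(0, 38, 2))
  expect_true(file.exists(tmp))
  back <- read.csv(tmp)
  expect_equal(back$UGT1A4, 1 + ugt1a4_activity_change(back$FW) / 100,
               tolerance = 1e-8)
})
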