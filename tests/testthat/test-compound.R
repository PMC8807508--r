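test_that("default olanzapine parameter set is the published one", {
  cp <- fx("cp")
  expect_identical(cp$logP, 2.85)
  expect_identical(cp$fu, 0.07)
  expect_identical(cp$MW, 312.4)
  expect_identical(cp$pKa, 7.24)
  expect_identical(cp$solubility_ug_per_mL, 145.4)
  expect_identical(cp$dissolution_t50_min, 10)
  expect_identical(cp$transcellular_permeability_cm_per_min, 3.85e-6)
  expect_identical(unname(cp$CLint),
                   c(26.67, 0.82, 2.14, 4.05, 20.06))
  expect_equal(sum(cp$CLint), 53.74)
  expect_identical(cp$GFR_fraction, 1.0)
  expect_identical(cp$CL_TSspec_L_per_min, 0.31)
})

test_that("compound parameters round-trip through the structured text format", {
  cp <- fx("cp")
  tmp <- withr::local_tempfile(fileext = ".tsv")
  keys <- c("logP", "MW_g_per_mol", "pKa", "fu", "solubility_ug_per_mL",
            "dissolution_t50_min", "transcellular_permeability_cm_per_min",
            paste0("CLint_", names(cp$CLint), "_L_per_h"),
            "GFR_fraction", "CL_TSspec_L_per_min")
  vals <- c(cp$logP, cp$MW, cp$pKa, cp$fu, cp$solubility_ug_per_mL,
            cp$dissolution_t50_min, cp$transcellular_permeability_cm_per_min,
            unname(cp$CLint), cp$GFR_fraction, cp$CL_TSspec_L_per_min)
  writeLines(c("key\tvalue", paste(keys, format(vals, digits = 15), sep = "\t")), tmp)
  cp2 <- read_compound_parameters(tmp)
  expect_equal(cp2$CLint, cp$CLint)
  expect_equal(cp2$fu, cp$fu)
})

test_that("ionized fraction follows Henderson-Hasselbalch for a base", {
  expect_equal(ionized_fraction(7.24, 7.24), 0.5)
  expect_equal(ionized_fraction(7.24, 7.4), 0.409, tolerance = 1e-3)
  expect_gt(ionized_fraction(7.24, 1.0), 0.999999)
  expect_error(ionized_fraction(7.24, 15), "pH")
})

test_that("partition coefficients are positive, plasma-symmetric and monotone in logP", {
  cp <- fx("cp")
  tc <- tissue_composition()
  kp <- partition_coefficients(cp, tc)
  expect_true(all(is.finite(kp) & kp > 0))
  # a tissue with plasma's own composition partitions 1:1
  tc2 <- rbind(tc, within(tc[tc$organ == "plasma", ], organ <- "plasmalike"))
  expect_equal(unname(partition_coefficients(cp, tc2)[["plasmalike"]]), 1)
  # lipid-rich adipose exceeds a hypothetical water-only tissue
  tc3 <- rbind(tc, data.frame(organ = "wateronly", f_water = 1,
                              f_neutral_lipid = 0, f_phospholipid = 0,
                              f_protein = 0, pH = 7.4))
  kp3 <- partition_coefficients(cp, tc3)
  expect_gt(kp3[["adipose"]], kp3[["wateronly"]])
  # with no lipid or protein, only unbound drug partitions: the
  # unbound-referenced Kp collapses to the water/ion-trapping ratio (1 at
  # plasma pH)
  expect_equal(unname(kp3[["wateronly"]]) / cp$fu, 1)
  # monotone non-decreasing in logP
  prev <- NULL
  for (lp in c(1, 2, 3, 4)) {
    cpl <- cp; cpl$logP <- lp
    k <- partition_coefficients(cpl, tc)
    if (!is.null(prev)) expect_true(all(k >= prev - 1e-12))
    prev <- k
  }
  # missing organ composition is a configuration error
  expect_error(build_model(fx("phys"), cp, fx("scaling"),
                           tc = tc[tc$organ != "liver", ]), "liver")
})
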