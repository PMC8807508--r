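# Gestational scaling of plasma protein binding and enzyme activities.
#
# Protein binding follows a single-site albumin association model whose
# equilibrium constant KA is solved once at the calibration week so the
# model reproduces the measured non-pregnant fu exactly; the gestational
# albumin decline then drives fu upward. Enzyme activities follow probe-
# substrate trajectories: caffeine apparent clearance for CYP1A2,
# lamotrigine apparent clearance for UGT1A4 (weighted cubic fit),
# a midazolam-based polynomial for CYP3A4, a late-pregnancy step for FMO3;
# CYP2C8 is left unchanged for lack of quantitative data.

# canonical trimester parameter sets (fertilization weeks 6 / 20 / 34)
.table2 <- list(
  FW = c(6, 20, 34),
  fu = c(0.075, 0.085, 0.091),
  CLint = rbind(
    CYP1A2 = c(22.40, 14.13, 9.87),
    CYP3A4 = c(0.89, 1.28, 1.64),
    CYP2C8 = c(2.14, 2.14, 2.14),
    FMO3   = c(4.05, 4.05, 7.11),
    UGT1A4 = c(28.24, 35.04, 36.91)
  )
)

#' Albumin binding model for gestational fraction unbound
#'
#' Single-site equilibrium association with albumin:
#' `fu = 1 / (1 + KA * P / MW_albumin)` where `P` is the gestational
#' albumin concentration (g/L, converted to umol/L via `MW_albumin`) and
#' `KA` (per umol/L) is solved so that `fu(calibration_FW) = fu_ref`.
#' Calibration is at FW 0 (albumin 46.4 g/L), which reproduces the
#' canonical trimester fu values 0.075 / 0.085 / 0.091.
#'
#' @param fu_ref measured non-pregnant unbound fraction.
#' @param calibration_FW fertilization week at which `fu_ref` was measured.
#' @param MW_albumin molecular weight of albumin, g/mol.
#' @return a `plasma_binding_model` with the solved `KA`.
#' @export
plasma_binding_model <- function(fu_ref = 0.07, calibration_FW = 0,
                                 MW_albumin = 66500) {
  stopifnot(fu_ref > 0, fu_ref <= 1, calibration_FW >= 0, MW_albumin > 0)
  P_uM <- albumin_concentration(calibration_FW) / MW_albumin * 1e6
  KA <- (1 / fu_ref - 1) / P_uM
  structure(list(KA = KA, MW_albumin = MW_albumin, fu_ref = fu_ref,
                 calibration_FW = calibration_FW),
            class = "plasma_binding_model")
}

#' Fraction unbound at a given fertilization week
#'
#' @param FW fertilization week(s) >= 0.
#' @param binding a [plasma_binding_model()].
#' @return unbound fraction(s), strictly increasing in FW.
#' @export
#' @examples
#' fraction_unbound(34)  # ~0.091
fraction_unbound <- function(FW, binding = plasma_binding_model()) {
  if (!inherits(binding, "plasma_binding_model") || is.null(binding$KA)) {
    stop("binding model is not calibrated", call. = FALSE)
  }
  P_uM <- albumin_concentration(FW) / binding$MW_albumin * 1e6
  1 / (1 + binding$KA * P_uM)
}

#' CYP1A2 activity change during pregnancy
#'
#' Quadratic trajectory from caffeine apparent clearance:
#' `0.0291 FW^2 - 2.77 FW`, in percent (negative during pregnancy).
#'
#' @param FW fertilization week(s) >= 0.
#' @return percent change relative to the non-pregnant baseline.
#' @export
cyp1a2_activity_change <- function(FW) {
  stopifnot(all(FW >= 0))
  0.0291 * FW^2 - 2.77 * FW
}

#' UGT1A4 activity change during pregnancy
#'
#' Cubic through the origin fitted to lamotrigine apparent-clearance
#' changes, weighted by study size:
#' `8.669 FW - 0.339 FW^2 + 0.00462 FW^3`, in percent.
#'
#' @inheritParams cyp1a2_activity_change
#' @return percent change relative to baseline.
#' @export
ugt1a4_activity_change <- function(FW) {
  stopifnot(all(FW >= 0))
  8.669 * FW - 0.339 * FW^2 + 0.00462 * FW^3
}

#' CYP3A4 activity multiplier during pregnancy
#'
#' Induction trajectory derived from midazolam modeling:
#' `1.00736 + 0.00564 FW + 0.00172 FW^2 - 0.00003 FW^3` (multiplier, ~1 at
#' baseline).
#'
#' @inheritParams cyp1a2_activity_change
#' @return activity multiplier.
#' @export
cyp3a4_activity <- function(FW) {
  stopifnot(all(FW >= 0))
  1.00736 + 0.00564 * FW + 0.00172 * FW^2 - 0.00003 * FW^3
}

#' FMO3 activity multiplier during pregnancy
#'
#' FMO3 activity (nicotine N'-oxidation) rises in late pregnancy only; the
#' trajectory is a step at the start of the third trimester (FW 27).
#' `"table2"` mode uses the canonical third-trimester intrinsic-clearance
#' ratio 7.11/4.05 (+75.6 %); `"literature"` mode uses the +58 % reported
#' for the probe. The two sources disagree; the canonical mode matches the
#' printed trimester parameter set.
#'
#' @inheritParams cyp1a2_activity_change
#' @param mode `"table2"` (default) or `"literature"`.
#' @return activity multiplier (1 before FW 27).
#' @export
fmo3_activity <- function(FW, mode = c("table2", "literature")) {
  stopifnot(all(FW >= 0))
  mode <- match.arg(mode)
  late <- if (mode == "table2") 7.11 / 4.05 else 1.58
  ifelse(FW >= 27, late, 1)
}

#' Gestational compound parameters
#'
#' Replaces `fu` and the five intrinsic clearances of a baseline compound
#' parameter set with their values at fertilization week `FW`. In
#' `"table2_canonical"` mode at FW 6, 20 or 34 the canonical printed
#' trimester values are used bit-exactly; at any other FW the call falls
#' back to `"equation_generated"` mode (with a warning), which evaluates
#' the continuous activity trajectories. CYP2C8 is never changed.
#'
#' @param base baseline `compound_parameters`.
#' @param FW fertilization week >= 0.
#' @param mode `"table2_canonical"` or `"equation_generated"`.
#' @param binding plasma binding model for the equation mode.
#' @return `compound_parameters` at `FW`.
#' @export
pregnant_compound_params <- function(base, FW,
                                     mode = c("table2_canonical", "equation_generated"),
                                     binding = plasma_binding_model(fu_ref = base$fu)) {
  validate_compound(base)
  stopifnot(is.numeric(FW), length(FW) == 1, FW >= 0)
  mode <- match.arg(mode)
  cp <- base
  cp$fertilization_week <- FW
  if (mode == "table2_canonical") {
    i <- match(FW, .table2$FW)
    if (is.na(i)) {
      warning("table2_canonical mode is only defined at FW 6/20/34; ",
              "falling back to equation mode at FW ", FW, call. = FALSE)
      mode <- "equation_generated"
    } else {
      cp$fu <- .table2$fu[i]
      cp$CLint <- .table2$CLint[, i]
      return(cp)
    }
  }
  cp$fu <- fraction_unbound(FW, binding)
  f <- c(
    CYP1A2 = max(0, 1 + cyp1a2_activity_change(FW) / 100),
    CYP3A4 = cyp3a4_activity(FW),
    CYP2C8 = 1,
    FMO3 = fmo3_activity(FW),
    UGT1A4 = 1 + ugt1a4_activity_change(FW) / 100
  )
  cp$CLint <- base$CLint * f[names(base$CLint)]
  cp
}

#' Weighted cubic fit of UGT1A4 activity change
#'
#' Weighted least-squares cubic through the origin (no intercept), with
#' fertilization week as the independent variable and study sample size as
#' weight — the functional form of the UGT1A4 trajectory.
#'
#' @param FW fertilization weeks of the observations.
#' @param percent_change observed percent change in apparent clearance.
#' @param weights positive study-size weights.
#' @return named coefficients `c(a1, a2, a3)` of
#'   `a1 FW + a2 FW^2 + a3 FW^3`.
#' @export
fit_ugt1a4_cubic <- function(FW, percent_change, weights = rep(1, length(FW))) {
  if (length(FW) < 4) stop("need at least 4 points", call. = FALSE)
  if (length(percent_change) != length(FW) || length(weights) != length(FW)) {
    stop("FW, percent_change and weights must have equal length", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  X <- cbind(FW, FW^2, FW^3)
  if (qr(X)$rank < 3) stop("rank-deficient design: FW values do not identify a cubic",
                           call. = FALSE)
  fit <- stats::lm.wfit(X, percent_change, w = weights)
  stats::setNames(fit$coefficients, c("a1", "a2", "a3"))
}

#' Export enzyme activity multipliers over a fertilization-week grid
#'
#' Writes a CSV with one row per FW and one column per enzyme multiplier
#' plus the unbound fraction, for plotting.
#'
#' @param path output CSV path.
#' @param FW fertilization-week grid.
#' @param binding plasma binding model.
#' @return the exported data frame, invisibly.
#' @export
export_activity_profiles <- function(path, FW = seq(0, 40, by = 0.5),
                                     binding = plasma_binding_model()) {
  out <- data.frame(
    FW = FW,
    fu = fraction_unbound(FW, binding),
    CYP1A2 = 1 + cyp1a2_activity_change(FW) / 100,
    CYP3A4 = cyp3a4_activity(FW),
    CYP2C8 = 1,
    FMO3 = fmo3_activity(FW),
    UGT1A4 = 1 + ugt1a4_activity_change(FW) / 100
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
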