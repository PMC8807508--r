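# Model-evaluation statistics: fold errors and GMFE, goodness-of-fit
# binning, and local sensitivity analysis.

#' Geometric mean fold error
#'
#' `GMFE = 10 ^ (mean |log10(predicted / observed)|)`. Always >= 1; a
#' value below 2 is the conventional adequacy bound for PBPK predictions.
#'
#' @param predicted,observed positive paired values.
#' @return the GMFE.
#' @export
#' @examples
#' gmfe(c(2, 1), c(1, 1))  # 10^(mean(|log10 2|, 0)) = sqrt(2) ~ 1.41
gmfe <- function(predicted, observed) {
  if (length(predicted) != length(observed)) stop("length mismatch", call. = FALSE)
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("gmfe requires positive values", call. = FALSE)
  }
  10^(mean(abs(log10(predicted / observed))))
}

#' Fold-error table for predicted/observed PK parameter pairs
#'
#' @param pairs data frame with columns `study_id`, `metric`, `predicted`,
#'   `observed`.
#' @return a `fold_error_table`: the rows with a recomputed `fold_error`
#'   column (predicted / observed) and per-metric GMFE.
#' @export
fold_error_table <- function(pairs) {
  stopifnot(all(c("study_id", "metric", "predicted", "observed") %in% names(pairs)))
  pairs$fold_error <- pairs$predicted / pairs$observed
  g <- vapply(split(pairs, pairs$metric), function(d) {
    gmfe(d$predicted, d$observed)
  }, numeric(1))
  structure(list(rows = pairs, gmfe = g), class = "fold_error_table")
}

#' @export
print.fold_error_table <- function(x, ...) {
  cat("<fold_error_table>", nrow(x$rows), "pairs\n  GMFE:",
      paste(names(x$gmfe), sprintf("%.3f", x$gmfe), collapse = ", "), "\n")
  invisible(x)
}

#' Goodness of fit of predicted vs observed values
#'
#' Fractions of pairs whose ratio lies within 2-fold and 1.25-fold, and
#' the mean absolute prediction error `mean(|pred - obs| / obs)`.
#'
#' @param predicted,observed positive paired values.
#' @return list with `frac_within_2fold`, `frac_within_1.25fold`, `mape`.
#' @export
goodness_of_fit <- function(predicted, observed) {
  if (any(predicted <= 0) || any(observed <= 0)) {
    stop("goodness_of_fit requires positive values", call. = FALSE)
  }
  ratio <- predicted / observed
  list(
    frac_within_2fold = mean(ratio >= 0.5 & ratio <= 2),
    frac_within_1.25fold = mean(ratio >= 0.8 & ratio <= 1.25),
    mape = mean(abs(predicted - observed) / observed)
  )
}

.clint_setter <- function(enzyme) {
  force(enzyme)
  function(cp, f) { cp$CLint[[enzyme]] <- cp$CLint[[enzyme]] * f; cp }
}

.sens_setters <- list(
  fu = function(cp, f) { cp$fu <- cp$fu * f; cp },
  logP = function(cp, f) { cp$logP <- cp$logP * f; cp },
  pKa = function(cp, f) { cp$pKa <- cp$pKa * f; cp },
  permeability = function(cp, f) {
    cp$transcellular_permeability_cm_per_min <-
      cp$transcellular_permeability_cm_per_min * f; cp },
  dissolution_t50 = function(cp, f) { cp$dissolution_t50_min <- cp$dissolution_t50_min * f; cp },
  CL_TSspec = function(cp, f) { cp$CL_TSspec_L_per_min <- cp$CL_TSspec_L_per_min * f; cp },
  CLint_CYP1A2 = .clint_setter("CYP1A2"),
  CLint_CYP3A4 = .clint_setter("CYP3A4"),
  CLint_CYP2C8 = .clint_setter("CYP2C8"),
  CLint_FMO3 = .clint_setter("FMO3"),
  CLint_UGT1A4 = .clint_setter("UGT1A4")
)

.sens_endpoint <- function(cp, phys, scaling, dose_mg, endpoint, dt) {
  model <- build_model(phys, cp, scaling)
  if (endpoint == "auc_single") {
    sim <- simulate_pbpk(model, dosing_regimen(dose_mg), t_end = 504, dt = dt)
    nca(sim$time, sim$plasma_concentration, dose_mg, "single")$AUC
  } else {
    reg <- dosing_regimen(dose_mg, interval_h = 24, n_doses = 10)
    sim <- simulate_pbpk(model, reg, t_end = 216 + 504, dt = dt)
    keep <- sim$time >= 216
    nca(sim$time[keep] - 216, sim$plasma_concentration[keep], dose_mg,
        "single")$AUC
  }
}

#' Local sensitivity analysis
#'
#' One-sided relative perturbation of each parameter by `delta`
#' (default +10 %), reporting `S = (dAUC/AUC) / (dp/p)`. A coefficient of
#' +1 means a 10 % parameter increase raises the AUC by 10 %. Two
#' endpoints mirror the model-evaluation practice: AUC to infinity after a
#' single dose, and AUC from the time of the 10th (last) daily dose to
#' infinity after multiple administrations. The clearance scaling is held
#' at its baseline calibration so a perturbation acts as a biological
#' change, not a re-calibration. A simulation failure under perturbation
#' flags that entry as NA rather than failing the analysis.
#'
#' @param cp baseline `compound_parameters`.
#' @param phys `physiology_state`.
#' @param parameters character vector of parameter names (see details:
#'   `fu`, `logP`, `pKa`, `permeability`, `dissolution_t50`, `CL_TSspec`,
#'   `CLint_<ENZYME>`, `dose`).
#' @param delta relative perturbation in (0, 0.5].
#' @param endpoint `"auc_single"` or `"auc_ss_last_dose"`.
#' @param dose_mg dose, mg.
#' @param scaling clearance scaling (baseline calibration).
#' @param dt simulation output step, h.
#' @return a `sensitivity_report` data frame with columns `parameter`,
#'   `sensitivity`, `delta`.
#' @export
sensitivity_analysis <- function(cp = default_olanzapine(),
                                 phys = reference_physiology("female", 30),
                                 parameters = c("fu", "logP", "pKa",
                                                "CLint_CYP1A2", "CLint_UGT1A4"),
                                 delta = 0.1,
                                 endpoint = c("auc_single", "auc_ss_last_dose"),
                                 dose_mg = 10,
                                 scaling = calibrate_clearance_scaling(cp, phys),
                                 dt = 0.2) {
  endpoint <- match.arg(endpoint)
  stopifnot(delta > 0, delta <= 0.5)
  base_auc <- .sens_endpoint(cp, phys, scaling, dose_mg, endpoint, dt)
  sens <- vapply(parameters, function(p) {
    auc <- tryCatch({
      if (p == "dose") {
        .sens_endpoint(cp, phys, scaling, dose_mg * (1 + delta), endpoint, dt)
      } else {
        setter <- .sens_setters[[p]]
        if (is.null(setter)) stop("unknown parameter: ", p, call. = FALSE)
        .sens_endpoint(setter(cp, 1 + delta), phys, scaling, dose_mg,
                       endpoint, dt)
      }
    }, error = function(e) {
      warning("sensitivity entry failed for ", p, ": ", conditionMessage(e),
              call. = FALSE)
      NA_real_
    })
    (auc - base_auc) / base_auc / delta
  }, numeric(1))
  out <- data.frame(parameter = parameters, sensitivity = sens, delta = delta,
                    row.names = NULL)
  out <- out[order(-abs(out$sensitivity)), ]
  structure(out, class = c("sensitivity_report", "data.frame"),
            endpoint = endpoint)
}
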