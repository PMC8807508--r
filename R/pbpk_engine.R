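# Whole-body PBPK engine.
#
# Oral dosing enters a single gut-lumen compartment as undissolved drug,
# dissolves first-order (half-time = the 50%-dissolution time), is absorbed
# first-order into the gut wall (transcellular permeability x effective
# small-intestinal surface area), drains via the portal vein into the
# liver, and distributes perfusion-limited with composition-based Kp.
# Hepatic metabolism (five enzymes) acts on the unbound liver
# concentration via the calibrated in-vivo scaling; renal filtration and
# tubular secretion act on the unbound kidney concentration. All
# processes are first-order, so the assembled system is linear and
# time-invariant between dosing events; the default integrator propagates
# the exact matrix exponential on a fixed output grid, with
# deSolve::lsoda available as an alternative path.

.elim_pathways <- c(.enzymes, "GFR", "TS")

# matrix exponential propagator; Matrix's scaling-and-squaring Pade
# implementation conserves the zero column sums of the system matrix to
# machine precision, which the mass-balance invariant relies on
.expm <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Dosing regimen
#'
#' @param dose_mg dose per administration, mg (> 0).
#' @param interval_h dosing interval in hours (required when `n_doses > 1`).
#' @param n_doses number of administrations.
#' @param route only `"oral"` is supported.
#' @return a `dosing_regimen` object.
#' @export
dosing_regimen <- function(dose_mg, interval_h = NULL, n_doses = 1,
                           route = "oral") {
  stopifnot(dose_mg > 0, n_doses >= 1)
  route <- match.arg(route, "oral")
  if (n_doses > 1 && (is.null(interval_h) || interval_h <= 0)) {
    stop("interval_h must be positive for repeated dosing", call. = FALSE)
  }
  structure(list(route = route, dose_mg = dose_mg, interval_h = interval_h,
                 n_doses = n_doses), class = "dosing_regimen")
}

#' Assemble the whole-body model
#'
#' Builds the linear ODE system for a physiology / compound pairing. The
#' maternal layout has 18 drug-containing compartments (gut lumen solid +
#' dissolved, 14 perfused organs, arterial/venous/portal blood); in
#' pregnancy the uterus, placenta, mammary gland and a lumped
#' non-eliminating fetal compartment are added. Cumulative elimination is
#' tracked per pathway for mass balance and fraction-metabolized output.
#'
#' @param phys `physiology_state`.
#' @param cp `compound_parameters`.
#' @param scaling per-enzyme in-vivo scaling from
#'   [calibrate_clearance_scaling()]; the default is the baseline
#'   olanzapine calibration, which must be reused unchanged for
#'   gestational parameter sets.
#' @param tc tissue composition table.
#' @param absorption_surface_area_cm2 effective small-intestinal surface
#'   area (default 6e5 cm^2 = 60 m^2, the textbook effective absorptive
#'   area including villous amplification).
#' @param fetal_exchange_L_per_h placental-fetal exchange clearance for
#'   the lumped fetal compartment (only used when present).
#' @return a `pbpk_model` with the system matrix and bookkeeping indices.
#' @export
build_model <- function(phys, cp, scaling = calibrate_clearance_scaling(),
                        tc = tissue_composition(),
                        absorption_surface_area_cm2 = 6e5,
                        fetal_exchange_L_per_h = 2) {
  validate_physiology(phys)
  validate_compound(cp)

  organs <- names(phys$organ_volumes)
  organs <- organs[!organs %in% c("arterial_blood", "venous_blood",
                                  "portal_blood", "gut_lumen")]
  organs <- organs[phys$organ_volumes[organs] > 0]

  kp <- partition_coefficients(cp, tc)
  missing <- setdiff(organs, names(kp))
  if (length(missing)) stop("no tissue composition for: ",
                            paste(missing, collapse = ", "), call. = FALSE)

  states <- c("gut_lumen_solid", "gut_lumen_dissolved", organs,
              "arterial_blood", "venous_blood", "portal_blood",
              paste0("elim_", .elim_pathways))
  n <- length(states)
  idx <- stats::setNames(seq_len(n), states)

  V <- phys$organ_volumes
  Kp <- c(stats::setNames(kp[organs], organs),
          arterial_blood = 1, venous_blood = 1, portal_blood = 1)
  VK <- V[c(organs, "arterial_blood", "venous_blood", "portal_blood")] *
    Kp[c(organs, "arterial_blood", "venous_blood", "portal_blood")]

  q <- phys$blood_flows
  splanchnic <- c("stomach", "spleen", "pancreas", "gut_wall")
  Q_pv <- sum(q[splanchnic])
  Q_h <- q[["hepatic_artery"]] + Q_pv
  periph <- setdiff(organs, c("lung", "liver", splanchnic, "fetus"))

  A <- matrix(0, n, n, dimnames = list(states, states))
  add <- function(to, from, rate) A[idx[[to]], idx[[from]]] <<- A[idx[[to]], idx[[from]]] + rate
  # rate constants are clearances divided by the source distribution volume
  out_of <- function(organ, CL) CL / VK[[organ]]

  # absorption chain
  kd <- log(2) / (cp$dissolution_t50_min / 60)
  CL_abs <- cp$transcellular_permeability_cm_per_min * 60 *
    absorption_surface_area_cm2 / 1000              # L/h on lumen concentration
  ka <- CL_abs / V[["gut_lumen"]]
  add("gut_lumen_solid", "gut_lumen_solid", -kd)
  add("gut_lumen_dissolved", "gut_lumen_solid", kd)
  add("gut_lumen_dissolved", "gut_lumen_dissolved", -ka)
  add("gut_wall", "gut_lumen_dissolved", ka)

  # lung: venous return -> lung -> arterial
  CO <- phys$cardiac_output
  add("lung", "venous_blood", CO / V[["venous_blood"]])
  add("venous_blood", "venous_blood", -CO / V[["venous_blood"]])
  add("arterial_blood", "lung", out_of("lung", CO))
  add("lung", "lung", -out_of("lung", CO))

  # peripheral organs: arterial -> organ -> venous
  for (org in periph) {
    add(org, "arterial_blood", q[[org]] / V[["arterial_blood"]])
    add("arterial_blood", "arterial_blood", -q[[org]] / V[["arterial_blood"]])
    add("venous_blood", org, out_of(org, q[[org]]))
    add(org, org, -out_of(org, q[[org]]))
  }
  # splanchnic organs: arterial -> organ -> portal vein
  for (org in splanchnic) {
    add(org, "arterial_blood", q[[org]] / V[["arterial_blood"]])
    add("arterial_blood", "arterial_blood", -q[[org]] / V[["arterial_blood"]])
    add("portal_blood", org, out_of(org, q[[org]]))
    add(org, org, -out_of(org, q[[org]]))
  }
  add("liver", "portal_blood", Q_pv / V[["portal_blood"]])
  add("portal_blood", "portal_blood", -Q_pv / V[["portal_blood"]])
  add("liver", "arterial_blood", q[["hepatic_artery"]] / V[["arterial_blood"]])
  add("arterial_blood", "arterial_blood", -q[["hepatic_artery"]] / V[["arterial_blood"]])
  add("venous_blood", "liver", out_of("liver", Q_h))
  add("liver", "liver", -out_of("liver", Q_h))

  # hepatic metabolism on unbound liver concentration (plasma-referenced)
  X_E <- cp$fu * scaling$s[.enzymes] * cp$CLint[.enzymes]
  for (e in .enzymes) {
    add(paste0("elim_", e), "liver", out_of("liver", X_E[[e]]))
    add("liver", "liver", -out_of("liver", X_E[[e]]))
  }
  # renal elimination on unbound kidney concentration
  rc <- renal_clearance(cp, phys)
  add("elim_GFR", "kidney", out_of("kidney", rc$filtration))
  add("kidney", "kidney", -out_of("kidney", rc$filtration))
  add("elim_TS", "kidney", out_of("kidney", rc$secretion))
  add("kidney", "kidney", -out_of("kidney", rc$secretion))

  # lumped fetal compartment exchanges with the placenta, non-eliminating
  if ("fetus" %in% organs) {
    add("fetus", "placenta", out_of("placenta", fetal_exchange_L_per_h))
    add("placenta", "placenta", -out_of("placenta", fetal_exchange_L_per_h))
    add("placenta", "fetus", out_of("fetus", fetal_exchange_L_per_h))
    add("fetus", "fetus", -out_of("fetus", fetal_exchange_L_per_h))
  }

  if (max(abs(colSums(A))) > 1e-9) stop("internal error: mass not conserved in system matrix")

  structure(list(
    A = A, states = states, organs = organs, V = V, Kp = Kp, VK = VK,
    phys = phys, cp = cp, scaling = scaling,
    venous_index = idx[["venous_blood"]],
    elim_index = idx[paste0("elim_", .elim_pathways)],
    lumen_index = idx[c("gut_lumen_solid", "gut_lumen_dissolved")],
    ka = ka, kd = kd
  ), class = "pbpk_model")
}

#' @export
print.pbpk_model <- function(x, ...) {
  cat(sprintf("<pbpk_model> %s, FW %.1f: %d drug compartments + %d elimination pathways\n",
              x$cp$name, x$phys$fertilization_week,
              length(x$states) - length(x$elim_index), length(x$elim_index)))
  invisible(x)
}

.dose_umol <- function(model, dose_mg) dose_mg * 1000 / model$cp$MW

.check_solubility <- function(model, dose_mg) {
  conc_ug_mL <- dose_mg * 1000 / (model$V[["gut_lumen"]] * 1000)
  if (conc_ug_mL > model$cp$solubility_ug_per_mL) {
    warning("dose exceeds luminal solubility (", round(conc_ug_mL, 1),
            " vs ", model$cp$solubility_ug_per_mL,
            " ug/mL); dissolution treated as non-limiting anyway", call. = FALSE)
  }
}

.sim_result <- function(model, times, Y, dose_times, dose_umol, ss_interval = NULL) {
  conc <- unname(Y[, model$venous_index] / model$V[["venous_blood"]] * model$cp$MW)
  structure(list(
    time = times,
    plasma_concentration = conc,            # ng/mL
    amounts = Y[, setdiff(seq_along(model$states), model$elim_index), drop = FALSE],
    eliminated = {
      E <- Y[, model$elim_index, drop = FALSE]
      colnames(E) <- .elim_pathways
      E
    },
    dose_events = data.frame(time = dose_times,
                             amount_umol = rep(dose_umol, length(dose_times))),
    ss_interval = ss_interval,
    model = model
  ), class = "pbpk_sim")
}

#' @export
print.pbpk_sim <- function(x, ...) {
  cat(sprintf("<pbpk_sim> %d doses, t in [0, %.1f] h, Cmax %.2f ng/mL\n",
              nrow(x$dose_events), max(x$time), max(x$plasma_concentration)))
  if (!is.null(x$ss_interval)) {
    cat(sprintf("  steady-state interval: [%.0f, %.0f] h\n",
                x$ss_interval[1], x$ss_interval[2]))
  }
  invisible(x)
}

.propagate <- function(model, y0, n_steps, dt, P = NULL) {
  if (is.null(P)) P <- .expm(model$A * dt)
  Y <- matrix(0, n_steps + 1, length(y0))
  Y[1, ] <- y0
  y <- y0
  for (k in seq_len(n_steps)) {
    y <- P %*% y
    Y[k + 1, ] <- y
  }
  Y
}

#' Simulate a dosing regimen
#'
#' Integrates the model over `[0, t_end]` on a fixed output grid. The
#' default method propagates the exact matrix exponential of the linear
#' system; `"lsoda"` uses the stiff-capable integrator from deSolve with
#' the analytic Jacobian (useful for cross-checking and for tolerance
#' studies).
#'
#' @param model a `pbpk_model`.
#' @param regimen a `dosing_regimen`.
#' @param t_end end of simulation, h.
#' @param dt output grid spacing, h (dose times must fall on the grid).
#' @param method `"matexp"` or `"lsoda"`.
#' @param rtol,atol tolerances for the lsoda path (amounts in umol).
#' @return a `pbpk_sim` with the time grid, venous plasma concentration
#'   (ng/mL), compartment amounts (umol) and cumulative elimination per
#'   pathway.
#' @export
simulate_pbpk <- function(model, regimen, t_end, dt = 0.1,
                          method = c("matexp", "lsoda"),
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "pbpk_model"), inherits(regimen, "dosing_regimen"),
            t_end > 0)
  method <- match.arg(method)
  .check_solubility(model, regimen$dose_mg)
  dose <- .dose_umol(model, regimen$dose_mg)
  dose_times <- if (regimen$n_doses > 1) {
    (seq_len(regimen$n_doses) - 1) * regimen$interval_h
  } else 0
  dose_times <- dose_times[dose_times < t_end]
  times <- seq(0, t_end, by = dt)
  n <- length(model$states)

  if (method == "matexp") {
    di <- round(dose_times / dt) + 1L
    if (max(abs(dose_times - (di - 1L) * dt)) > 1e-9) {
      stop("dose times must fall on the output grid", call. = FALSE)
    }
    P <- .expm(model$A * dt)
    Y <- matrix(0, length(times), n)
    y <- numeric(n)
    for (k in seq_along(times)) {
      if (k %in% di) y[1] <- y[1] + dose
      Y[k, ] <- y
      if (k < length(times)) y <- as.vector(P %*% y)
    }
  } else {
    parms <- list(A = model$A)
    rhs <- function(t, y, p) list(as.vector(p$A %*% y))
    jac <- function(t, y, p) p$A
    events <- data.frame(var = "gut_lumen_solid", time = dose_times,
                         value = dose, method = "add")
    y0 <- stats::setNames(numeric(n), model$states)
    out <- deSolve::lsoda(y0, times, rhs, parms, jacfunc = jac,
                          jactype = "fullusr", rtol = rtol, atol = atol,
                          events = list(data = events))
    Y <- unname(out[, -1, drop = FALSE])
  }
  .sim_result(model, times, Y, dose_times, dose)
}

#' Simulate repeated dosing to steady state
#'
#' Propagates interval by interval until the AUC over successive dosing
#' intervals changes by less than `conv_tol` (relative), up to `max_doses`
#' administrations. The last simulated interval is flagged as the
#' steady-state interval. An optional drug-free washout can be appended
#' (for terminal half-life estimation at steady state).
#'
#' @param model a `pbpk_model`.
#' @param regimen a `dosing_regimen` with a dosing interval.
#' @param conv_tol relative AUC change defining convergence.
#' @param max_doses cap on the number of administrations.
#' @param dt output grid spacing, h.
#' @param washout_h drug-free follow-up after the steady-state interval, h.
#' @return a `pbpk_sim` with `ss_interval` set.
#' @export
simulate_to_steady_state <- function(model, regimen, conv_tol = 0.005,
                                     max_doses = 40, dt = 0.1, washout_h = 0) {
  stopifnot(inherits(regimen, "dosing_regimen"))
  if (is.null(regimen$interval_h)) stop("regimen must have a dosing interval", call. = FALSE)
  .check_solubility(model, regimen$dose_mg)
  tau <- regimen$interval_h
  n_steps <- round(tau / dt)
  if (abs(n_steps * dt - tau) > 1e-9) stop("interval must be a multiple of dt", call. = FALSE)
  dose <- .dose_umol(model, regimen$dose_mg)
  P <- .expm(model$A * dt)
  vi <- model$venous_index
  Vv <- model$V[["venous_blood"]]

  y <- numeric(length(model$states))
  blocks <- list()
  auc_prev <- NA_real_
  converged <- FALSE
  n_dosed <- 0
  for (d in seq_len(max_doses)) {
    y[1] <- y[1] + dose
    Y <- .propagate(model, y, n_steps, dt, P)
    y <- Y[n_steps + 1, ]
    blocks[[d]] <- Y[-(n_steps + 1), , drop = FALSE]
    conc <- Y[, vi] / Vv * model$cp$MW
    auc <- pracma::trapz(seq(0, tau, by = dt), conc)
    n_dosed <- d
    if (!is.na(auc_prev) && abs(auc - auc_prev) / auc_prev < conv_tol) {
      converged <- TRUE
      break
    }
    auc_prev <- auc
  }
  if (!converged) {
    stop("steady state not reached within ", max_doses, " doses", call. = FALSE)
  }
  Y_all <- do.call(rbind, blocks)
  Y_all <- rbind(Y_all, y)   # closing grid point of the last interval
  if (washout_h > 0) {
    W <- .propagate(model, y, round(washout_h / dt), dt, P)
    Y_all <- rbind(Y_all[-nrow(Y_all), , drop = FALSE], W)
  }
  times <- seq(0, by = dt, length.out = nrow(Y_all))
  dose_times <- (seq_len(n_dosed) - 1) * tau
  .sim_result(model, times, Y_all, dose_times, dose,
              ss_interval = c((n_dosed - 1) * tau, n_dosed * tau))
}

#' Mass-balance error of a simulation
#'
#' Maximum over the output grid of |drug in body + eliminated + lumen -
#' administered| relative to the total administered amount.
#'
#' @param sim a `pbpk_sim`.
#' @return the maximum relative mass-balance error.
#' @export
mass_balance_error <- function(sim) {
  administered <- vapply(sim$time, function(t) {
    sum(sim$dose_events$amount_umol[sim$dose_events$time <= t + 1e-9])
  }, numeric(1))
  total <- rowSums(sim$amounts) + rowSums(sim$eliminated)
  ok <- administered > 0
  max(abs(total[ok] - administered[ok]) / administered[ok])
}

#' Export a simulation as tidy CSV files
#'
#' Writes the venous plasma concentration series and (optionally) the
#' per-compartment amounts in long format.
#'
#' @param sim a `pbpk_sim`.
#' @param conc_path CSV path for `(time_h, plasma_ng_per_mL)`.
#' @param amounts_path optional CSV path for
#'   `(time_h, compartment, amount_umol)`.
#' @param thin write every `thin`-th grid point (the default grid is dense).
#' @return invisibly, the concentration data frame.
#' @export
export_simulation <- function(sim, conc_path, amounts_path = NULL, thin = 10) {
  keep <- seq(1, length(sim$time), by = thin)
  conc <- data.frame(time_h = sim$time[keep],
                     plasma_ng_per_mL = sim$plasma_concentration[keep])
  utils::write.csv(conc, conc_path, row.names = FALSE)
  if (!is.null(amounts_path)) {
    comp <- setdiff(sim$model$states, paste0("elim_", .elim_pathways))
    long <- do.call(rbind, lapply(seq_along(comp), function(j) {
      data.frame(time_h = sim$time[keep], compartment = comp[j],
                 amount_umol = sim$amounts[keep, j])
    }))
    utils::write.csv(long, amounts_path, row.names = FALSE)
  }
  invisible(conc)
}
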