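# Non-compartmental analysis and trimester-vs-baseline comparisons.

.auc_lin_up_log_down <- function(time, conc) {
  dt <- diff(time)
  c1 <- conc[-length(conc)]
  c2 <- conc[-1]
  seg <- ifelse(c2 < c1 & c1 > 0 & c2 > 0,
                dt * (c1 - c2) / log(c1 / c2),   # log-down
                dt * (c1 + c2) / 2)              # linear up / flat
  sum(seg)
}

.terminal_slope <- function(time, conc, max_points = 50) {
  i_max <- which.max(conc)
  t <- time[-seq_len(i_max)]
  y <- conc[-seq_len(i_max)]
  keep <- y > 0
  t <- t[keep]; y <- y[keep]
  n <- length(t)
  if (n < 3) stop("not enough points after Cmax for a terminal slope", call. = FALSE)
  ks <- 3:min(max_points, n)
  best <- NULL
  best_r2 <- -Inf
  for (k in ks) {
    tt <- t[(n - k + 1):n]
    yy <- log(y[(n - k + 1):n])
    fit <- stats::lm.fit(cbind(1, tt), yy)
    r2 <- 1 - sum(fit$residuals^2) / sum((yy - mean(yy))^2)
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.finite(adj) && adj > best_r2) {
      best_r2 <- adj
      best <- fit
    }
  }
  lambda_z <- unname(-best$coefficients[2])
  if (!is.finite(lambda_z) || lambda_z <= 0) {
    stop("non-decaying tail: terminal slope could not be estimated", call. = FALSE)
  }
  lambda_z
}

#' Non-compartmental analysis of a concentration-time profile
#'
#' Cmax/tmax by grid maximum; AUC by the linear-up/log-down trapezoid. In
#' `"single"` mode the AUC is extrapolated to infinity from the terminal
#' log-linear slope (fitted over the last 3+ points, extended while the
#' adjusted r-squared improves) and `CL/F = dose / AUC_0_inf`. In
#' `"steady_state"` mode the profile must be one dosing interval at steady
#' state: AUC is the interval AUC (no extrapolation), the trough is the
#' concentration at the end of the interval, and `CL/F = dose / AUC_tau`.
#'
#' @param time time grid, h (>= 5 points, strictly increasing).
#' @param conc concentrations, ng/mL.
#' @param dose_mg administered dose (per interval in steady-state mode).
#' @param mode `"single"` or `"steady_state"`.
#' @return a `pk_metrics` list: `Cmax` (ng/mL), `tmax` (h), `AUC`
#'   (ng*h/mL; 0-inf or tau-ss), `t_half` (h; NA in steady-state mode),
#'   `CL_F` (L/h), `C_trough` (ng/mL; steady state only),
#'   `AUC_extrap_frac` (single mode).
#' @export
nca <- function(time, conc, dose_mg, mode = c("single", "steady_state")) {
  mode <- match.arg(mode)
  stopifnot(length(time) == length(conc), length(time) >= 5,
            all(diff(time) > 0), all(conc >= 0), dose_mg > 0)
  cmax <- max(conc)
  tmax <- time[which.max(conc)]
  auc_obs <- .auc_lin_up_log_down(time, conc)
  if (mode == "single") {
    lambda_z <- .terminal_slope(time, conc)
    auc <- auc_obs + conc[length(conc)] / lambda_z
    metrics <- list(Cmax = cmax, tmax = tmax, AUC = auc,
                    t_half = log(2) / lambda_z,
                    CL_F = dose_mg * 1e6 / auc / 1000,
                    C_trough = NA_real_,
                    AUC_extrap_frac = conc[length(conc)] / lambda_z / auc)
  } else {
    metrics <- list(Cmax = cmax, tmax = tmax - time[1], AUC = auc_obs,
                    t_half = NA_real_,
                    CL_F = dose_mg * 1e6 / auc_obs / 1000,
                    C_trough = conc[length(conc)],
                    AUC_extrap_frac = 0)
  }
  structure(metrics, class = "pk_metrics", mode = mode)
}

#' @export
print.pk_metrics <- function(x, ...) {
  cat(sprintf("<pk_metrics> (%s) Cmax %.2f ng/mL at %.2f h, AUC %.1f ng*h/mL, CL/F %.2f L/h",
              attr(x, "mode"), x$Cmax, x$tmax, x$AUC, x$CL_F))
  if (!is.na(x$t_half)) cat(sprintf(", t1/2 %.1f h", x$t_half))
  if (!is.na(x$C_trough)) cat(sprintf(", Ctrough %.2f ng/mL", x$C_trough))
  cat("\n")
  invisible(x)
}

#' PK metrics of a simulation
#'
#' Convenience wrapper running [nca()] on a `pbpk_sim`. For a single-dose
#' simulation the full profile is used with tail extrapolation. For a
#' steady-state simulation the flagged steady-state interval is analyzed;
#' if the simulation carries a drug-free washout beyond that interval, the
#' terminal half-life is estimated from it.
#'
#' @param sim a `pbpk_sim`.
#' @param mode `"single"` or `"steady_state"` (defaults to steady state
#'   when the simulation has a flagged interval).
#' @return a `pk_metrics` list.
#' @export
pk_metrics <- function(sim, mode = NULL) {
  stopifnot(inherits(sim, "pbpk_sim"))
  dose_mg <- sim$dose_events$amount_umol[1] * sim$model$cp$MW / 1000
  if (is.null(mode)) {
    mode <- if (is.null(sim$ss_interval)) "single" else "steady_state"
  }
  if (mode == "single") {
    return(nca(sim$time, sim$plasma_concentration, dose_mg, "single"))
  }
  if (is.null(sim$ss_interval)) stop("simulation has no flagged steady-state interval", call. = FALSE)
  in_int <- sim$time >= sim$ss_interval[1] - 1e-9 & sim$time <= sim$ss_interval[2] + 1e-9
  m <- nca(sim$time[in_int], sim$plasma_concentration[in_int], dose_mg,
           "steady_state")
  tail <- sim$time > sim$ss_interval[2] + 1e-9
  if (sum(tail) >= 10) {
    lambda_z <- .terminal_slope(sim$time[tail], sim$plasma_concentration[tail])
    m$t_half <- log(2) / lambda_z
  }
  m
}

#' Relative change of PK metrics versus baseline
#'
#' `100 * (pregnant - baseline) / baseline` for each shared finite metric.
#'
#' @param pregnant,baseline `pk_metrics` of the same mode and dose.
#' @return named vector of percent changes.
#' @export
relative_change <- function(pregnant, baseline) {
  stopifnot(inherits(pregnant, "pk_metrics"), inherits(baseline, "pk_metrics"))
  if (!identical(attr(pregnant, "mode"), attr(baseline, "mode"))) {
    stop("metrics must be of the same mode", call. = FALSE)
  }
  keys <- c("Cmax", "tmax", "AUC", "t_half", "CL_F", "C_trough")
  out <- vapply(keys, function(k) {
    p <- pregnant[[k]]; b <- baseline[[k]]
    if (is.na(p) || is.na(b) || b == 0) NA_real_ else 100 * (p - b) / b
  }, numeric(1))
  out[!is.na(out)]
}

#' Write PK metrics to a one-row-per-scenario CSV
#'
#' @param metrics named list of `pk_metrics` (names become scenario labels).
#' @param path output CSV path.
#' @return the exported data frame, invisibly.
#' @export
export_metrics <- function(metrics, path) {
  rows <- lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(scenario = nm, Cmax_ng_mL = m$Cmax, tmax_h = m$tmax,
               AUC_ng_h_mL = m$AUC, t_half_h = m$t_half, CL_F_L_h = m$CL_F,
               C_trough_ng_mL = m$C_trough)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
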