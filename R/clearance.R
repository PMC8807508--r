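# Elimination processes: hepatic per-enzyme metabolism, renal filtration
# and tubular secretion, fraction-metabolized bookkeeping, and the
# Rowland-Matin DDI algebra.

#' AUC ratio under competitive inhibition (Rowland-Matin)
#'
#' `AUCR = Fg_ratio / (fm / (1 + r) + (1 - fm))` with
#' `fm = fm_total * fm_cyp1a2`, the fraction of total clearance that is
#' CYP1A2-mediated hepatic metabolism, and `r = Iu/Ki` the unbound
#' inhibitor concentration over its inhibition constant.
#'
#' @param fm_total total hepatically metabolized fraction of clearance.
#' @param fm_cyp1a2 within-liver share of metabolism via the inhibited
#'   enzyme.
#' @param r inhibition ratio `Iu/Ki`, >= 0 (may be `Inf`).
#' @param Fg_ratio ratio of gut availabilities with/without inhibitor
#'   (default 1, no gut-wall metabolism modeled).
#' @return the AUC ratio (inhibited / control).
#' @export
#' @examples
#' rowland_matin_aucr(1, 0.5, Inf)  # 2.0
rowland_matin_aucr <- function(fm_total, fm_cyp1a2, r, Fg_ratio = 1) {
  stopifnot(fm_total >= 0, fm_total <= 1, fm_cyp1a2 >= 0, fm_cyp1a2 <= 1,
            r >= 0, Fg_ratio > 0)
  fm <- fm_total * fm_cyp1a2
  inhibited <- if (is.infinite(r)) 0 else fm / (1 + r)
  Fg_ratio / (inhibited + (1 - fm))
}

#' Fraction metabolized implied by an observed AUC ratio
#'
#' Inverts the Rowland-Matin relation for `fm = fm_total * fm_cyp1a2`:
#' `fm = (1 - Fg_ratio / aucr) * (1 + r) / r`.
#'
#' @param aucr observed AUC ratio, >= 1.
#' @param r inhibition ratio `Iu/Ki` (> 0; may be `Inf`).
#' @param Fg_ratio gut availability ratio.
#' @return the implied fraction metabolized, in `[0, 1]`.
#' @export
#' @examples
#' solve_fm_from_aucr(2, Inf)  # 0.5
solve_fm_from_aucr <- function(aucr, r, Fg_ratio = 1) {
  if (aucr < 1) stop("aucr must be >= 1", call. = FALSE)
  if (r == 0) {
    if (aucr > Fg_ratio) stop("no solution: aucr > Fg_ratio with r = 0", call. = FALSE)
    return(0)
  }
  fm <- if (is.infinite(r)) 1 - Fg_ratio / aucr else
    (1 - Fg_ratio / aucr) * (1 + r) / r
  if (fm < -1e-12 || fm > 1 + 1e-12) {
    stop("implied fraction metabolized outside [0, 1]: ", signif(fm, 4), call. = FALSE)
  }
  min(max(fm, 0), 1)
}

#' Renal clearance components
#'
#' Glomerular filtration of unbound drug plus kidney-volume-normalized
#' tubular secretion acting on unbound drug:
#' `CL_R = GFR_fraction * GFR * fu + CL_TSspec * V_kidney * 60 * fu` (L/h).
#' Both terms scale with the unbound fraction; the secretion term is
#' normalized to kidney volume, so in pregnancy it changes only through
#' `fu` and kidney growth.
#'
#' @param cp `compound_parameters`.
#' @param phys `physiology_state`.
#' @return list with `filtration`, `secretion` and `total` (L/h).
#' @export
renal_clearance <- function(cp, phys) {
  validate_compound(cp)
  stopifnot(inherits(phys, "physiology_state"))
  filtration <- cp$GFR_fraction * phys$GFR * cp$fu
  secretion <- cp$CL_TSspec_L_per_min * phys$kidney_volume * 60 * cp$fu
  list(filtration = filtration, secretion = secretion,
       total = filtration + secretion)
}

#' Middle-out calibration of per-enzyme in-vivo clearance scaling
#'
#' The whole-body-normalized intrinsic clearances are published, but the
#' platform-internal expression scaling that maps them to in-vivo hepatic
#' elimination is not. This function solves for per-enzyme scaling factors
#' `s_E` — fixed properties of the baseline liver — such that a single
#' oral dose simulated in the reference adult reproduces the published
#' mass-balance clearance decomposition: per-enzyme dose fractions
#' (`fm_targets`) and the renally excreted fraction (`fR_target`), with
#' the renal side computed mechanistically by [renal_clearance()].
#'
#' The hepatic side uses the well-stirred identity for a perfusion-limited
#' liver: systemic hepatic clearance `CL_H = Q_h X / (Q_h + X)` where
#' `X = fu * sum(s_E * CLint_E)` and `Q_h` is total liver blood flow.
#' Because orally absorbed drug passes the liver once before reaching the
#' systemic circulation, the renally excreted dose fraction is
#' `(1 - CL_H/Q_h) * CL_R / (CL_H + CL_R)`; this is solved for `X`.
#'
#' The factors are calibrated once at baseline and are *not* re-fitted in
#' pregnancy: gestational change enters only through `fu(FW)` and the
#' scaled `CLint_E(FW)`.
#'
#' @param cp baseline `compound_parameters`.
#' @param phys baseline reference `physiology_state`.
#' @return list with per-enzyme scaling `s`, `CL_renal`, `CL_hepatic`,
#'   `CL_total` (systemic, L/h), total liver blood flow `Q_h`, and the
#'   intrinsic total `X_hepatic`.
#' @export
calibrate_clearance_scaling <- function(cp = default_olanzapine(),
                                        phys = reference_physiology("female", 30)) {
  validate_compound(cp)
  q <- phys$blood_flows
  Q_h <- q[["hepatic_artery"]] + q[["gut_wall"]] + q[["spleen"]] +
    q[["pancreas"]] + q[["stomach"]]
  Q_k <- q[["kidney"]]
  X_R <- renal_clearance(cp, phys)$total
  CL_R <- Q_k * X_R / (Q_k + X_R)   # systemic renal clearance (kidney perfusion-limited)

  fm <- cp$fm_targets
  fR <- cp$fR_target
  shares <- fm / sum(fm)
  fR_frac <- fR / (fR + sum(fm))    # normalize the printed fractions to sum 1

  fR_sim <- function(CL_H) (1 - CL_H / Q_h) * CL_R / (CL_H + CL_R)
  lo <- 1e-6; hi <- Q_h * (1 - 1e-6)
  if (fR_sim(lo) < fR_frac) stop("renal terms too small to reach the target fR", call. = FALSE)
  CL_H <- stats::uniroot(function(x) fR_sim(x) - fR_frac, c(lo, hi), tol = 1e-12)$root
  X_H <- Q_h * CL_H / (Q_h - CL_H)

  s <- (shares[names(cp$CLint)] * X_H) / (cp$fu * cp$CLint)
  list(s = s, CL_renal = CL_R, CL_hepatic = CL_H, CL_total = CL_H + CL_R,
       Q_h = Q_h, X_hepatic = X_H)
}

#' Static competitive inhibition of one enzyme
#'
#' Scales one enzyme's intrinsic clearance by `1 / (1 + r)` with
#' `r = Iu/Ki`, the steady-state stand-in for co-administration of a
#' competitive inhibitor.
#'
#' @param cp `compound_parameters`.
#' @param enzyme one of the five metabolizing enzymes.
#' @param r inhibition ratio >= 0 (may be `Inf`).
#' @return modified `compound_parameters`.
#' @export
apply_static_inhibition <- function(cp, enzyme, r) {
  validate_compound(cp)
  if (!(enzyme %in% names(cp$CLint))) {
    stop("unknown enzyme: ", enzyme, call. = FALSE)
  }
  if (r < 0) stop("r must be >= 0", call. = FALSE)
  cp$CLint[[enzyme]] <- if (is.infinite(r)) 0 else cp$CLint[[enzyme]] / (1 + r)
  cp
}

#' Clearance pathway breakdown from a simulation
#'
#' Integrates each elimination flux over the simulation and reports the
#' fraction of the total eliminated amount per pathway (five enzymes,
#' glomerular filtration, tubular secretion; `renal` is their sum). If the
#' simulation did not run long enough to eliminate (nearly) all drug, the
#' remaining body burden is allocated by the terminal flux shares and a
#' warning is issued.
#'
#' @param sim a `pbpk_sim` from [simulate_pbpk()].
#' @return a `clearance_breakdown` list: `fractions` (named, sums to 1),
#'   `renal`, and `eliminated_fraction_of_dose`.
#' @export
clearance_breakdown <- function(sim) {
  stopifnot(inherits(sim, "pbpk_sim"))
  E <- sim$eliminated
  n <- nrow(E)
  e_end <- E[n, ]
  dosed <- sum(sim$dose_events$amount_umol)
  eliminated <- sum(e_end)
  remaining <- dosed - eliminated
  if (remaining / dosed > 0.10) {
    warning("only ", round(100 * eliminated / dosed, 1),
            "% of the dose eliminated; extrapolating the tail by terminal flux shares",
            call. = FALSE)
  }
  # terminal flux per pathway from the last grid step
  flux <- pmax(e_end - E[n - 1, ], 0)
  w <- if (sum(flux) > 0) flux / sum(flux) else e_end / eliminated
  total <- e_end + remaining * w
  fractions <- total / sum(total)
  renal <- sum(fractions[c("GFR", "TS")])
  structure(list(fractions = fractions, renal = renal,
                 eliminated_fraction_of_dose = eliminated / dosed),
            class = "clearance_breakdown")
}

#' @export
print.clearance_breakdown <- function(x, ...) {
  cat("<clearance_breakdown> fraction of eliminated dose per pathway:\n")
  print(round(x$fractions, 4))
  cat(sprintf("  renal (fR): %.3f\n", x$renal))
  invisible(x)
}
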