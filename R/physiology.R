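# Reference adult physiology and its gestational transformation.
#
# The body is represented by the standard small-molecule whole-body layout:
# lung, brain, heart, kidney, liver, gut (lumen + wall), stomach, spleen,
# pancreas, muscle, adipose, skin, bone, gonads, arterial/venous/portal blood.
# Pregnancy adds uterus, placenta, mammary gland, a lumped non-eliminating
# fetal compartment and (volume only) amniotic fluid.

#' Plasma albumin concentration during pregnancy
#'
#' Exponential decline of maternal plasma albumin with fertilization week
#' (FW, gestational week minus 2): `14.7 * exp(-0.0454 * FW) + 31.7` g/L.
#' At FW = 0 this gives the non-pregnant reference value (46.4 g/L) and it
#' decays towards an asymptote of 31.7 g/L.
#'
#' @param FW fertilization week(s), numeric >= 0.
#' @return albumin concentration in g/L, same length as `FW`.
#' @export
#' @examples
#' albumin_concentration(0)   # 46.4
#' albumin_concentration(34)  # 34.84
albumin_concentration <- function(FW) {
  if (any(!is.finite(FW)) || any(FW < 0)) {
    stop("FW must be finite and >= 0", call. = FALSE)
  }
  14.7 * exp(-0.0454 * FW) + 31.7
}

#' Load the reference physiology constants table
#'
#' Reads the versioned key-value constants file shipped with the package
#' (or a user override with the same layout: `key`, `female`, `male`
#' columns, units embedded in the key names).
#'
#' @param path optional path to an override file.
#' @return data frame of constants.
#' @export
read_physiology_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "physiology_reference.tsv", package = "olapbpk")
  }
  if (!nzchar(path) || !file.exists(path)) stop("physiology constants file not found", call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

.phys_const <- function(tab, key, sex) {
  i <- match(key, tab$key)
  if (is.na(i)) stop("missing physiology constant: ", key, call. = FALSE)
  as.numeric(tab[[sex]][i])
}

# organ inventory of the non-pregnant layout (drug-containing, perfused)
.maternal_organs <- c(
  "lung", "brain", "heart", "kidney", "liver", "gut_wall", "stomach",
  "spleen", "pancreas", "muscle", "adipose", "skin", "bone", "gonads"
)
.gestational_organs <- c("uterus", "placenta", "mammary", "fetus")

#' Reference (non-pregnant) adult physiology
#'
#' Builds a complete adult body from the literature-based constants table:
#' organ volumes, organ blood flows, cardiac output (defined as the sum of
#' all arterial draws so that venous return balances exactly), GFR,
#' hematocrit and plasma albumin. Fertilization week is 0.
#'
#' @param sex `"female"` or `"male"`.
#' @param age age in years, must lie in `[18, 65]`.
#' @param constants optional constants table from [read_physiology_constants()].
#' @return a `physiology_state` object.
#' @export
reference_physiology <- function(sex = c("female", "male"), age = 30,
                                 constants = NULL) {
  sex <- match.arg(sex)
  if (!is.numeric(age) || length(age) != 1 || age < 18 || age > 65) {
    stop("age must be a single value in [18, 65]", call. = FALSE)
  }
  tab <- if (is.null(constants)) read_physiology_constants() else constants

  vol_keys <- paste0("volume_", c(.maternal_organs,
                                  "arterial_blood", "venous_blood",
                                  "portal_blood", "gut_lumen"), "_L")
  vols <- vapply(vol_keys, .phys_const, numeric(1), tab = tab, sex = sex)
  names(vols) <- sub("^volume_(.*)_L$", "\\1", vol_keys)

  flow_organs <- c("brain", "heart", "kidney", "muscle", "adipose", "skin",
                   "bone", "gonads", "stomach", "spleen", "pancreas",
                   "gut_wall", "hepatic_artery")
  flows <- vapply(paste0("flow_", flow_organs, "_L_per_h"),
                  .phys_const, numeric(1), tab = tab, sex = sex)
  names(flows) <- flow_organs

  state <- structure(list(
    fertilization_week = 0,
    sex = sex,
    age = age,
    organ_volumes = vols,
    blood_flows = flows,
    cardiac_output = sum(flows),
    GFR = .phys_const(tab, "gfr_L_per_h", sex),
    kidney_volume = vols[["kidney"]],
    liver_volume = vols[["liver"]],
    albumin = albumin_concentration(0),
    hematocrit = .phys_const(tab, "hematocrit_frac", sex),
    body_weight = .phys_const(tab, "body_weight_kg", sex),
    amniotic_fluid_volume = 0
  ), class = "physiology_state")
  validate_physiology(state)
  state
}

#' @export
print.physiology_state <- function(x, ...) {
  cat(sprintf("<physiology_state> %s, age %g, FW %.1f\n", x$sex, x$age,
              x$fertilization_week))
  cat(sprintf("  body weight %.1f kg, CO %.1f L/h, GFR %.2f L/h, albumin %.1f g/L\n",
              x$body_weight, x$cardiac_output, x$GFR, x$albumin))
  cat(sprintf("  %d drug-containing compartments\n",
              sum(x$organ_volumes > 0) + 0L))
  invisible(x)
}

#' Validate a physiology state
#'
#' Checks the structural invariants: strictly positive volumes and flows,
#' venous return (sum of arterial draws) equal to cardiac output to 1e-6
#' relative, and albumin consistent with [albumin_concentration()] at the
#' stored fertilization week.
#'
#' @param state a `physiology_state`.
#' @return `state`, invisibly; errors if an invariant is violated.
#' @export
validate_physiology <- function(state) {
  stopifnot(inherits(state, "physiology_state"))
  if (any(state$organ_volumes <= 0)) stop("non-positive organ volume", call. = FALSE)
  if (any(state$blood_flows <= 0)) stop("non-positive blood flow", call. = FALSE)
  rel <- abs(sum(state$blood_flows) - state$cardiac_output) / state$cardiac_output
  if (rel > 1e-6) stop("blood flows do not balance cardiac output", call. = FALSE)
  alb <- albumin_concentration(state$fertilization_week)
  if (abs(state$albumin - alb) > 1e-9 * alb) {
    stop("albumin inconsistent with stored fertilization week", call. = FALSE)
  }
  invisible(state)
}

# Gestational trajectories (smooth polynomial functions of FW, after the
# pregnancy-physiology literature; all equal their baseline value at FW = 0).
.gest <- list(
  weight_gain_kg   = function(FW) 0.272 * FW + 0.0022 * FW^2,
  gfr_mult         = function(FW) 1 + 0.0229 * FW - 0.000233 * FW^2,
  hematocrit_shift = function(FW) -0.0018 * FW,
  blood_vol_mult   = function(FW) 1 + 0.009 * FW,
  kidney_vol_mult  = function(FW) 1 + 0.004 * FW,
  adipose_vol_add  = function(FW) 0.06 * FW,
  kidney_flow_mult = function(FW) 1 + 0.009 * FW,
  skin_flow_mult   = function(FW) 1 + 0.012 * FW,
  adipose_flow_mult= function(FW) 1 + 0.006 * FW,
  muscle_flow_mult = function(FW) 1 + 0.004 * FW,
  uterus_vol_L     = function(FW) 7.1e-4 * FW^2,
  placenta_vol_L   = function(FW) 4.5e-4 * FW^2,
  fetus_vol_L      = function(FW) 3.5 * (FW / 38)^3,
  amniotic_vol_L   = function(FW) 5.5e-4 * FW^2,
  mammary_vol_L    = function(FW) 0.012 * FW,
  uterus_flow_Lh   = function(FW) 0.005 * FW^2,
  placenta_flow_Lh = function(FW) 0.024 * FW^2,
  mammary_flow_Lh  = function(FW) 0.03 * FW
)

#' Apply gestational changes to a reference female physiology
#'
#' Transforms a non-pregnant female reference state to fertilization week
#' `FW`: plasma albumin follows [albumin_concentration()]; body weight,
#' GFR, renal/cutaneous blood flows, blood volume and hematocrit follow
#' smooth literature-based trajectories; the gestational compartments
#' (uterus, placenta, mammary gland, lumped fetus, amniotic fluid) grow
#' from zero. The absolute liver blood flow (hepatic artery and the
#' splanchnic flows draining into the portal vein) is left unchanged.
#' Cardiac output is re-derived as the sum of all arterial draws, so flow
#' balance holds at every FW.
#'
#' @param base female `physiology_state` at FW 0.
#' @param FW fertilization week, in `[0, 40]`.
#' @return a `physiology_state` at `FW`. At `FW = 0` the input is returned
#'   unchanged.
#' @export
pregnancy_physiology <- function(base, FW) {
  stopifnot(inherits(base, "physiology_state"))
  if (base$sex != "female" || base$fertilization_week != 0) {
    stop("base must be a non-pregnant female reference state", call. = FALSE)
  }
  if (!is.numeric(FW) || length(FW) != 1 || FW < 0 || FW > 40) {
    stop("FW must be a single value in [0, 40]", call. = FALSE)
  }
  if (FW == 0) return(base)

  st <- base
  st$fertilization_week <- FW
  st$albumin <- albumin_concentration(FW)
  st$GFR <- base$GFR * .gest$gfr_mult(FW)
  st$hematocrit <- base$hematocrit + .gest$hematocrit_shift(FW)
  st$body_weight <- base$body_weight + .gest$weight_gain_kg(FW)
  st$amniotic_fluid_volume <- .gest$amniotic_vol_L(FW)

  v <- st$organ_volumes
  v[["kidney"]] <- v[["kidney"]] * .gest$kidney_vol_mult(FW)
  v[["adipose"]] <- v[["adipose"]] + .gest$adipose_vol_add(FW)
  v[["arterial_blood"]] <- v[["arterial_blood"]] * .gest$blood_vol_mult(FW)
  v[["venous_blood"]] <- v[["venous_blood"]] * .gest$blood_vol_mult(FW)
  v[["uterus"]] <- .gest$uterus_vol_L(FW)
  v[["placenta"]] <- .gest$placenta_vol_L(FW)
  v[["mammary"]] <- .gest$mammary_vol_L(FW)
  v[["fetus"]] <- .gest$fetus_vol_L(FW)
  st$organ_volumes <- v
  st$kidney_volume <- v[["kidney"]]

  q <- st$blood_flows
  q[["kidney"]] <- q[["kidney"]] * .gest$kidney_flow_mult(FW)
  q[["skin"]] <- q[["skin"]] * .gest$skin_flow_mult(FW)
  q[["adipose"]] <- q[["adipose"]] * .gest$adipose_flow_mult(FW)
  q[["muscle"]] <- q[["muscle"]] * .gest$muscle_flow_mult(FW)
  # liver supply (hepatic artery + portal tributaries) deliberately unchanged
  q[["uterus"]] <- .gest$uterus_flow_Lh(FW)
  q[["placenta"]] <- .gest$placenta_flow_Lh(FW)
  q[["mammary"]] <- .gest$mammary_flow_Lh(FW)
  st$blood_flows <- q
  st$cardiac_output <- sum(q)

  validate_physiology(st)
  st
}
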