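# Virtual populations: seeded sampling of anthropometry, gestational age
# and clearance variability, and summaries of population simulations.

#' Population specification
#'
#' @param n number of individuals (>= 1).
#' @param age_range age range in years.
#' @param fw_range fertilization-week range (omit / NULL for a
#'   non-pregnant reference population).
#' @param variability named CV fractions: `CLint` (log-normal, applied to
#'   each hepatic enzyme independently), `CL_TSspec` (tubular secretion),
#'   `body_weight` (anthropometric scaling).
#' @param seed integer seed; mandatory for reproducibility.
#' @return a `population_spec`.
#' @export
population_spec <- function(n, age_range = c(20, 40), fw_range = NULL,
                            variability = list(CLint = 0.35,
                                               CL_TSspec = 0.25,
                                               body_weight = 0.15),
                            seed) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n >= 1, all(unlist(variability) >= 0))
  structure(list(n = as.integer(n), age_range = age_range,
                 fw_range = fw_range, variability = variability,
                 seed = as.integer(seed)), class = "population_spec")
}

.cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# scale a reference body by a relative size factor: volumes linearly,
# flows and GFR allometrically (exponent 0.75)
.scale_body <- function(phys, f) {
  phys$organ_volumes <- phys$organ_volumes * f
  phys$kidney_volume <- phys$organ_volumes[["kidney"]]
  phys$liver_volume <- phys$organ_volumes[["liver"]]
  phys$body_weight <- phys$body_weight * f
  phys$blood_flows <- phys$blood_flows * f^0.75
  phys$cardiac_output <- sum(phys$blood_flows)
  phys$GFR <- phys$GFR * f^0.75
  phys
}

#' Generate a virtual population
#'
#' Samples `n` individuals: age uniform in `age_range`, body size
#' log-normal around the reference (volumes scaled linearly, flows and GFR
#' with exponent 0.75), per-enzyme intrinsic-clearance multipliers
#' log-normal (median-preserving) with the configured CVs, and — for
#' pregnant populations — fertilization week uniform in `fw_range` with
#' the gestational physiology and the continuous (equation-mode) compound
#' scaling applied at each individual's FW.
#'
#' @param spec a [population_spec()].
#' @param base_cp baseline compound parameters.
#' @param base_phys reference female physiology.
#' @return list of individuals, each `list(phys, cp, fw)`; the spec is
#'   attached as an attribute.
#' @export
generate_population <- function(spec, base_cp = default_olanzapine(),
                                base_phys = reference_physiology("female", 30)) {
  stopifnot(inherits(spec, "population_spec"))
  set.seed(spec$seed)
  v <- spec$variability
  binding <- plasma_binding_model(fu_ref = base_cp$fu)
  out <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
    f <- stats::rlnorm(1, 0, .cv_to_sdlog(v$body_weight %||% 0))
    fw <- if (is.null(spec$fw_range)) 0 else
      stats::runif(1, spec$fw_range[1], spec$fw_range[2])
    phys <- .scale_body(base_phys, f)
    phys$age <- age
    if (fw > 0) phys <- pregnancy_physiology(phys, fw)
    cp <- if (fw > 0) {
      pregnant_compound_params(base_cp, fw, "equation_generated", binding)
    } else base_cp
    mult <- stats::rlnorm(length(cp$CLint), 0, .cv_to_sdlog(v$CLint %||% 0))
    cp$CLint <- cp$CLint * mult
    cp$CL_TSspec_L_per_min <- cp$CL_TSspec_L_per_min *
      stats::rlnorm(1, 0, .cv_to_sdlog(v$CL_TSspec %||% 0))
    out[[i]] <- list(phys = phys, cp = cp, fw = fw)
  }
  attr(out, "spec") <- spec
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric mean
#'
#' @param x positive values.
#' @return `exp(mean(log(x)))`.
#' @export
geometric_mean <- function(x) {
  if (any(x <= 0)) stop("geometric mean requires positive values", call. = FALSE)
  exp(mean(log(x)))
}

#' Summarize population simulations
#'
#' Per-time median and 5th-95th percentile bands of the plasma
#' concentration across individuals, plus geometric means of the
#' per-individual PK metrics.
#'
#' @param sims list of `pbpk_sim` on a common time grid.
#' @param metrics optional list of `pk_metrics` (one per individual) to
#'   summarize as geometric means.
#' @return list with `bands` (data frame `time`, `p05`, `p50`, `p95`) and
#'   `gm_metrics` (named vector or NULL).
#' @export
population_summary <- function(sims, metrics = NULL) {
  stopifnot(length(sims) >= 2)
  t0 <- sims[[1]]$time
  same <- vapply(sims, function(s) length(s$time) == length(t0) &&
                   max(abs(s$time - t0)) < 1e-9, logical(1))
  if (!all(same)) stop("simulations are not on a common time grid", call. = FALSE)
  C <- vapply(sims, function(s) s$plasma_concentration,
              numeric(length(t0)))
  qs <- apply(C, 1, stats::quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
  bands <- data.frame(time = t0, p05 = qs[1, ], p50 = qs[2, ], p95 = qs[3, ])
  gm <- NULL
  if (!is.null(metrics)) {
    keys <- c("Cmax", "AUC", "CL_F", "C_trough", "t_half")
    gm <- vapply(keys, function(k) {
      x <- vapply(metrics, function(m) m[[k]] %||% NA_real_, numeric(1))
      x <- x[is.finite(x) & x > 0]
      if (length(x)) geometric_mean(x) else NA_real_
    }, numeric(1))
  }
  list(bands = bands, gm_metrics = gm)
}

#' Export population outputs as CSV
#'
#' Writes the sampled individual parameters and/or the summary bands.
#'
#' @param population from [generate_population()].
#' @param summary from [population_summary()].
#' @param parameters_path,bands_path output CSV paths (either may be NULL).
#' @return invisibly NULL.
#' @export
export_population <- function(population = NULL, summary = NULL,
                              parameters_path = NULL, bands_path = NULL) {
  if (!is.null(population) && !is.null(parameters_path)) {
    rows <- lapply(seq_along(population), function(i) {
      ind <- population[[i]]
      data.frame(id = i, fw = ind$fw, body_weight_kg = ind$phys$body_weight,
                 fu = ind$cp$fu,
                 t(ind$cp$CLint))
    })
    utils::write.csv(do.call(rbind, rows), parameters_path, row.names = FALSE)
  }
  if (!is.null(summary) && !is.null(bands_path)) {
    utils::write.csv(summary$bands, bands_path, row.names = FALSE)
  }
  invisible(NULL)
}
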