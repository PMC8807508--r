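# Scenario layer: resolve a small configuration into a complete,
# deterministic simulation and write tabular reports. The numbered driver
# scripts under analysis/ are thin narratives over this layer.

.trimester_fw <- c(`1` = 6, `2` = 20, `3` = 34)

#' Run a simulation scenario
#'
#' A scenario names a physiology (fertilization week or trimester), a
#' dosing regimen, a parameter mode and an execution mode. Representative
#' scenarios run the single representative individual; population
#' scenarios sample a seeded virtual population and write summary bands.
#' Every run writes a concentration CSV, a metrics CSV and a plain-text
#' log of the resolved parameters; pregnant scenarios also write the
#' relative changes versus the matching non-pregnant baseline.
#'
#' @param config a named list or the path to a YAML file with fields:
#'   `name`; `trimester` (1-3) or `fw` (fertilization week, 0 = baseline);
#'   `dose_mg` (default 10); `interval_h` (omit for a single dose);
#'   `parameter_mode` (`"table2_canonical"` default);
#'   `mode` (`"representative"` default or `"population"`); `n`
#'   (population size); `seed` (default 1); `t_end` (single-dose horizon,
#'   default 504 h).
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the computed metrics (and relative
#'   changes for pregnant scenarios).
#' @export
run_scenario <- function(config, out_dir = ".") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$name)) stop("scenario config needs a name", call. = FALSE)
  bad <- setdiff(names(config),
                 c("name", "trimester", "fw", "dose_mg", "interval_h",
                   "parameter_mode", "mode", "n", "seed", "t_end"))
  if (length(bad)) stop("unknown scenario keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  fw <- if (!is.null(config$trimester)) {
    .trimester_fw[[as.character(config$trimester)]]
  } else config$fw %||% 0
  dose <- config$dose_mg %||% 10
  mode <- config$mode %||% "representative"
  pmode <- config$parameter_mode %||% "table2_canonical"
  seed <- config$seed %||% 1
  t_end <- config$t_end %||% 504
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, config$name)

  base_phys <- reference_physiology("female", 30)
  base_cp <- default_olanzapine()
  scaling <- calibrate_clearance_scaling(base_cp, base_phys)
  phys <- pregnancy_physiology(base_phys, fw)
  cp <- if (fw > 0) pregnant_compound_params(base_cp, fw, pmode) else base_cp

  run_one <- function(ph, cpi) {
    model <- build_model(ph, cpi, scaling)
    if (is.null(config$interval_h)) {
      sim <- simulate_pbpk(model, dosing_regimen(dose), t_end = t_end)
    } else {
      sim <- simulate_to_steady_state(
        model, dosing_regimen(dose, config$interval_h, n_doses = 40),
        washout_h = 168)
    }
    sim
  }

  result <- list(name = config$name, fw = fw)
  if (mode == "representative") {
    sim <- run_one(phys, cp)
    export_simulation(sim, paste0(pre, "_concentration.csv"))
    m <- pk_metrics(sim)
    result$metrics <- m
    if (fw > 0) {
      m0 <- pk_metrics(run_one(base_phys, base_cp))
      result$baseline_metrics <- m0
      result$relative_change <- relative_change(m, m0)
      utils::write.csv(
        data.frame(metric = names(result$relative_change),
                   percent_change = as.numeric(result$relative_change)),
        paste0(pre, "_relative_change.csv"), row.names = FALSE)
      export_metrics(list(pregnant = m, baseline = m0),
                     paste0(pre, "_metrics.csv"))
    } else {
      export_metrics(stats::setNames(list(m), config$name),
                     paste0(pre, "_metrics.csv"))
    }
  } else {
    n <- config$n %||% 100
    fw_range <- if (fw > 0) c(max(fw - 5, 1), min(fw + 4, 38)) else NULL
    pop <- generate_population(population_spec(n, fw_range = fw_range, seed = seed))
    sims <- lapply(pop, function(ind) run_one(ind$phys, ind$cp))
    mets <- lapply(sims, pk_metrics)
    summ <- population_summary(sims, mets)
    result$summary <- summ
    export_population(pop, summ,
                      parameters_path = paste0(pre, "_individuals.csv"),
                      bands_path = paste0(pre, "_bands.csv"))
    utils::write.csv(data.frame(metric = names(summ$gm_metrics),
                                geometric_mean = as.numeric(summ$gm_metrics)),
                     paste0(pre, "_metrics.csv"), row.names = FALSE)
  }

  log <- c(
    sprintf("scenario: %s", config$name),
    sprintf("fertilization_week: %g", fw),
    sprintf("parameter_mode: %s", if (fw > 0) pmode else "baseline"),
    sprintf("dose_mg: %g", dose),
    sprintf("interval_h: %s", config$interval_h %||% "single dose"),
    sprintf("mode: %s", mode),
    sprintf("seed: %d", as.integer(seed)),
    sprintf("fu: %.4f", cp$fu),
    sprintf("CLint_L_per_h: %s",
            paste(names(cp$CLint), sprintf("%.3f", cp$CLint), collapse = ", ")),
    sprintf("CL_total_baseline_L_per_h: %.3f", scaling$CL_total),
    sprintf("body_weight_kg: %.2f", phys$body_weight),
    sprintf("cardiac_output_L_per_h: %.1f", phys$cardiac_output),
    sprintf("GFR_L_per_h: %.3f", phys$GFR),
    sprintf("albumin_g_per_L: %.2f", phys$albumin)
  )
  writeLines(log, paste0(pre, "_parameters.log"))
  invisible(result)
}

#' Path of a bundled scenario configuration
#'
#' @param name scenario name, e.g. `"baseline_single_10mg"` or
#'   `"trimester3_qd"`.
#' @return path to the bundled YAML file.
#' @export
bundled_scenario <- function(name) {
  p <- system.file("extdata", "scenarios", paste0(name, ".yaml"),
                   package = "olapbpk")
  if (!nzchar(p)) stop("no bundled scenario named ", name, call. = FALSE)
  p
}
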