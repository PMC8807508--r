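# Shared fixtures, built once per test run and cached. Everything is
# generated in code; the only file fixture is the packaged validation
# pair table.

.fx <- new.env(parent = emptyenv())

fx <- function(name) {
  if (!exists(name, envir = .fx)) {
    assign(name, switch(
      name,
      phys = reference_physiology("female", 30),
      cp = default_olanzapine(),
      scaling = calibrate_clearance_scaling(fx("cp"), fx("phys")),
      model = build_model(fx("phys"), fx("cp"), fx("scaling")),
      sim_single = simulate_pbpk(fx("model"), dosing_regimen(10), t_end = 504),
      sim_ss = simulate_to_steady_state(
        fx("model"), dosing_regimen(10, 24, 40),
        conv_tol = 5e-4, washout_h = 168),
      stop("unknown fixture: ", name)
    ), envir = .fx)
  }
  get(name, envir = .fx)
}

# steady-state run for a canonical trimester week, cached
fx_ss_fw <- function(fw) {
  key <- paste0("sim_ss_fw", fw)
  if (!exists(key, envir = .fx)) {
    ph <- pregnancy_physiology(fx("phys"), fw)
    cpp <- pregnant_compound_params(fx("cp"), fw, "table2_canonical")
    m <- build_model(ph, cpp, fx("scaling"))
    assign(key,
           simulate_to_steady_state(m, dosing_regimen(10, 24, 40),
                                    conv_tol = 5e-4, washout_h = 168),
           envir = .fx)
  }
  get(key, envir = .fx)
}
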