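# Cache for expensive fixtures shared across test files (one process).
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, expr, envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

nominal_params <- function() ha_params()
nominal_ss <- function() cached("ss", find_steady_state(ha_params()))
control_stim <- function() {
  cached("stim_control", run_stimulation(ha_params(), "control"))
}
antagonist_stim <- function() {
  cached("stim_antagonist", run_stimulation(ha_params(), "antagonist"))
}
halflife_result <- function() cached("halflife", run_half_life(ha_params()))
load_result <- function() cached("load", run_histidine_load(ha_params()))
dietary_result <- function() {
  cached("dietary", run_dietary(ha_params(), factors = c(1 / 3, 1, 8 / 3)))
}
oscillation_result <- function() {
  cached("oscillation",
         suppressMessages(run_oscillation_variant(ha_params())))
}
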