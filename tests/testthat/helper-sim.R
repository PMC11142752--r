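# Scaled-down simulation configurations for module tests. Generator
# parameters (coupling, concentration, read depth) stay at package defaults;
# only the problem *size* shrinks to keep the default test run fast. The
# acceptance suite runs the full-scale settings.

small_config <- function(seed = 1, ...) {
  sim_config(n_samples = 120, n_events = 300, n_informative = 80,
             seed = seed, ...)
}

tiny_config <- function(seed = 1, ...) {
  sim_config(n_samples = 40, n_events = 60, n_informative = 20,
             sc_n_patients = 2, sc_cells_per_state = 20,
             n_rbp_total = 40, n_rbp_coupled = 10,
             seed = seed, ...)
}
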