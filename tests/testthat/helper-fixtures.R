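# Shared fixtures, generated once per test run and cached in this
# environment.  Everything is built in code; no stored data files.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# one healthy-baseline steady run (60 s, defaults)
base_simulation <- function() fixture("base_sim", function() {
  simulate_lpm(circulation_params())
})

# a short HF run used where only a converged cycle is needed
hf_simulation <- function() fixture("hf_sim", function() {
  simulate_lpm(circulation_params(overrides = list(Emax_LV = 1.0)),
               solver_config(t_end = 20))
})

# small synthetic dataset shared by datagen / estimator / metrics tests
small_dataset <- function() fixture("small_ds", function() {
  generate_dataset(sampling_spec(M = 48, seed = 5))
})

# a deliberately tiny network spec for fast training tests
tiny_spec <- function() network_spec(channels = c(2, 4, 8),
                                     mlp_hidden = c(8, 8),
                                     head = c(32, 16))

# hand-built simulation_result with constant traces, for indicator units
constant_result <- function(flow = 83.333, ap = 100, T = 0.8) {
  n <- 321
  time <- seq(0, 4 * T, length.out = n)
  nodes <- c("RA", "RV", "LA", "LV", "AO", "SAT", "SAR", "SVN", "PAS",
             "PAT", "PCP", "PVN")
  prs <- matrix(ap, n, 12, dimnames = list(NULL, nodes))
  vol <- matrix(50, n, 12, dimnames = list(NULL, nodes))
  vol[, "LV"] <- 40 + 80 * (sin(pi * time / T))^2 # ESV 40, EDV 120
  flows <- matrix(0, n, 6,
                  dimnames = list(NULL, c("TV", "PV", "MV", "AV", "AOBR",
                                          "PUMP")))
  flows[, "AV"] <- flow
  structure(list(time = time, volumes = vol, pressures = prs,
                 flows = flows, suction = rep(FALSE, n),
                 final_state = numeric(13),
                 params = circulation_params(T = T),
                 solver = solver_config(t_end = 4 * T)),
            class = "simulation_result")
}
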