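# shared fixtures for the test suite; everything is generated in code

ref_params <- gc7_reference_params()

noiseless_design <- function(replicates = 1) {
  simulation_design(replicates = replicates, noise_type = "none")
}

noiseless_grid <- function(mode = "noncompetitive", params = ref_params,
                           replicates = 1) {
  simulate_rate_grid(params, mode, noiseless_design(replicates))
}

# independent oracle for the Morrison fraction: solve the binding quadratic
# [EI]^2 - (E + I + K)[EI] + E*I = 0 with polyroot and take the physical
# root (the one in [0, min(E, I)]), then 1 - [EI]/E
morrison_oracle <- function(E, I, K) {
  if (I == 0) return(1)
  roots <- Re(polyroot(c(E * I, -(E + I + K), 1)))
  EI <- min(roots)
  1 - EI / E
}

write_grid_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

rel_err <- function(x, truth) abs(x / truth - 1)
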