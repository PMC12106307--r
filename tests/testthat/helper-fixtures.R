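# Shared fixtures and independent oracles.

fixture_env <- new.env(parent = emptyenv())

# Committed calibrated parameter set (loaded once per test run).
fixture_params <- function() {
  if (is.null(fixture_env$params)) {
    fixture_env$params <- load_config(default_config_path())
  }
  fixture_env$params
}

# Independent brute-force accumulation oracle: explicit per-cycle loop over
# the occupancy rows, kept deliberately free of the vectorized package path.
oracle_totals <- function(occ, state_cost, state_utility, annual_rate,
                          weighting = "half", cycles_per_year = 12) {
  n_cycles <- nrow(occ) - 1
  total_cost <- 0
  total_qalys <- 0
  for (t in seq_len(n_cycles)) {
    m <- switch(weighting,
      half  = (occ[t, ] + occ[t + 1, ]) / 2,
      end   = occ[t + 1, ],
      start = occ[t, ]
    )
    d <- (1 + annual_rate)^(-t / cycles_per_year)
    total_cost <- total_cost + d * sum(m * state_cost)
    total_qalys <- total_qalys + d * sum(m * state_utility) / 12
  }
  list(cost = total_cost, qalys = total_qalys)
}

# Two-state alive/dead matrix with a constant monthly death probability.
two_state_matrix <- function(p_death) {
  build_transition_matrix(
    data.frame(from = "alive", to = "death", prob = p_death),
    states = c("alive", "death")
  )
}

# A minimal parameter set whose live dynamics are fully hand-checkable:
# only the entry state and death are ever occupied.
toy_params <- function(p_death_mono = 0.05, p_death_combo = 0.03) {
  params <- default_parameters()
  entry <- params$states[1]
  params$transitions$mono <- data.frame(from = entry, to = "death",
                                        prob = p_death_mono)
  params$transitions$combo <- data.frame(from = entry, to = "death",
                                         prob = p_death_combo)
  params
}
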