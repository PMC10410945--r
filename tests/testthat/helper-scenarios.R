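# Published Alzheimer inputs, rebuilt in code so unit tests do not depend
# on the shipped YAML file.
table1_matrix <- function() {
  transition_matrix(rbind(
    mild     = c(mild = 0.774, moderate = 0.158, severe = 0.013, death = 0.055),
    moderate = c(mild = 0.070, moderate = 0.501, severe = 0.214, death = 0.215),
    severe   = c(mild = 0.001, moderate = 0.027, severe = 0.492, death = 0.480),
    death    = c(mild = 0.000, moderate = 0.000, severe = 0.000, death = 1.000)
  ))
}

ad_utilities <- c(mild = 0.73, moderate = 0.69, severe = 0.27, death = 0)
soc_costs <- c(mild = 3140, moderate = 9460, severe = 16956, death = 0)

soc_strategy <- function() {
  strategy("SoC", table1_matrix(), state_rewards(soc_costs, ad_utilities))
}

perturb_rate <- function(scenario, rate) {
  scenario$discount$rate <- rate
  scenario
}

# minimal evaluated-strategy stub for incremental-comparison tests
fake_eval <- function(name, cost, qaly) {
  structure(list(strategy = name, total_cost = cost, total_qaly = qaly),
            class = "cea_eval")
}

trace_occ_row <- function(trace, at_cycle) {
  unlist(trace[trace$cycle == at_cycle, attr(trace, "states")])
}

# a batch of random synthetic scenarios with varying size and seed
random_scenarios <- function(n, n_states = NULL, seed_offset = 0) {
  lapply(seq_len(n), function(i) {
    k <- if (is.null(n_states)) 2 + (i %% 5) else n_states
    generate_scenario(scenario_blueprint(
      n_states = k, seed = i + seed_offset,
      progression_ordering = i %% 2 == 0))
  })
}
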