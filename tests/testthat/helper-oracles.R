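# independent oracles used to validate the cohort engine and the synthesis

# agent-based microsimulation through the same per-cycle transition matrices:
# each of n_agents follows an independent Markov chain, realised as
# multinomial count transitions; at any cycle the state counts are exactly
# multinomial around the cohort-trace occupancy
microsim_trace <- function(ps, strategy, record, n_agents, seed) {
  set.seed(seed)
  st <- ps$settings
  n_cycles <- round(st$horizon_years / st$cycle_length_years)
  s <- health_states()
  counts <- round(n_agents * ps$start_state_distribution[s])
  out <- matrix(0, n_cycles + 1L, 6L, dimnames = list(NULL, s))
  out[1L, ] <- counts / n_agents
  for (t in seq_len(n_cycles)) {
    m <- build_transition_matrix(ps, strategy, t - 1L, record)
    newc <- setNames(numeric(6L), s)
    for (from in s) {
      if (counts[[from]] > 0)
        newc <- newc + rmultinom(1L, counts[[from]], m[from, ])[, 1L]
    }
    counts <- newc
    out[t + 1L, ] <- counts / n_agents
  }
  out
}

# closed-form E[max(X, 0)] for X ~ Normal(mu, sd): the normal loss function
expected_pos_part_normal <- function(mu, sd) {
  mu * pnorm(mu / sd) + sd * dnorm(mu / sd)
}
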