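# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

ref_ps <- function() {
  if (is.null(.fixture_cache$ps))
    .fixture_cache$ps <- make_reference_parameter_set()
  .fixture_cache$ps
}

ref_evidence <- function() {
  if (is.null(.fixture_cache$ev))
    .fixture_cache$ev <- generate_reference_evidence()
  .fixture_cache$ev
}

# a parameter set with every spec fixed (zero parameter uncertainty), an
# immortal life table and simple two-destination dynamics; useful wherever a
# test needs exact hand-computable results
fixed_ps <- function(discount_rate = 0.03, horizon_years = 10,
                     hsuv = c(ACUTE = 0.5, REMISSION = 0.8, RELAPSE = 0.6,
                              RESISTANT = 0.4, PNS = 0.5),
                     cost = c(ACUTE = 100, REMISSION = 10, RELAPSE = 50,
                              RESISTANT = 80, PNS = 20),
                     program = c(eip = 7, cmht = 3),
                     rr_remission = 1.25, rr_relapse = 0.6,
                     lt = generate_life_table(a = 0)) {
  rows <- list(
    ACUTE = c(ACUTE = 0.5, REMISSION = 0.5, RESISTANT = 0, PNS = 0),
    REMISSION = c(REMISSION = 0.9, RELAPSE = 0.1, PNS = 0),
    RELAPSE = c(RELAPSE = 0.6, REMISSION = 0.4, RESISTANT = 0),
    RESISTANT = c(RESISTANT = 1, REMISSION = 0),
    PNS = c(PNS = 1, RELAPSE = 0))
  fx <- function(v) dist_spec("fixed", v)
  al <- c("ACUTE", "REMISSION", "RELAPSE", "RESISTANT", "PNS")
  parameter_set(
    transitions = list(cmht = rows, eip = rows),
    hsuv = lapply(as.list(hsuv[al]), fx),
    state_cost = lapply(as.list(cost[al]), fx),
    program_cost = list(eip = fx(program[["eip"]]), cmht = fx(program[["cmht"]])),
    hazard_ratio = lapply(setNames(as.list(rep(1, 5)), al), fx),
    rr = list(remission = fx(rr_remission), relapse = fx(rr_relapse)),
    effect_targets = list(remission = list(from = "ACUTE", to = "REMISSION"),
                          relapse = list(from = "REMISSION", to = "RELAPSE")),
    settings = economic_settings(discount_rate_annual = discount_rate,
                                 horizon_years = horizon_years),
    life_table = lt,
    start_age = 20)
}

# build a strategy_outcome by hand (for economics unit tests)
make_outcome <- function(cost, qaly, strategy = "eip", horizon = 10, r = 0.03) {
  structure(list(strategy = strategy, cost_disc = cost, qaly_disc = qaly,
                 cost_undisc = cost, qaly_undisc = qaly, life_years = horizon,
                 horizon_years = horizon, discount_rate_annual = r),
            class = "strategy_outcome")
}

# build a psa_result directly from per-iteration outcomes (and optionally a
# parameter matrix), bypassing the model run
make_psa <- function(cost_eip, qaly_eip, cost_cmht, qaly_cmht,
                     params = NULL, wtp_grid = c(0, 5e5, 1e6)) {
  n <- length(cost_eip)
  structure(list(
    n = n,
    outcomes = data.frame(iter = seq_len(n), cost_eip = cost_eip,
                          qaly_eip = qaly_eip, cost_cmht = cost_cmht,
                          qaly_cmht = qaly_cmht),
    params = params, wtp_grid = wtp_grid, master_seed = NA_integer_,
    n_capped = 0L), class = "psa_result")
}
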