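#' Resolve a parameter set to concrete point values
#'
#' Collapses every [dist_spec()] in a [parameter_set()] to its point value
#' (the distribution mean), producing the deterministic parameter record used
#' by the base-case analysis. Probabilistic analyses produce records of the
#' same shape via [sample_parameters()].
#'
#' @param ps A [parameter_set()].
#' @return A list of class `param_record` with elements `trans` (per
#'   strategy, per from-state destination shares conditional on survival),
#'   `hsuv`, `state_cost`, `hazard_ratio` (named numeric over alive states),
#'   `program_cost` (named numeric, `eip`/`cmht`), `rr_remission`,
#'   `rr_relapse`.
#' @export
resolve_parameters <- function(ps) {
  validate_parameter_set(ps)
  al <- alive_states()
  num_block <- function(b) vapply(b[al], spec_mean, numeric(1))
  trans <- lapply(ps$transitions, function(tr)
    lapply(tr[al], function(spec)
      if (is_dist_spec(spec)) spec_mean(spec) else spec))
  structure(list(
    trans = trans,
    hsuv = num_block(ps$hsuv),
    state_cost = num_block(ps$state_cost),
    hazard_ratio = num_block(ps$hazard_ratio),
    program_cost = c(eip = spec_mean(ps$program_cost$eip),
                     cmht = spec_mean(ps$program_cost$cmht)),
    rr_remission = spec_mean(ps$rr$remission),
    rr_relapse = spec_mean(ps$rr$relapse)
  ), class = "param_record")
}

#' Apply a treatment-effect risk ratio to a transition row
#'
#' Multiplies the probability of moving into `target_state` by the risk
#' ratio (capping the product at 1) and redistributes the complement
#' proportionally across the remaining destinations, so the row still sums
#' to 1. A capped product is flagged via the `"capped"` attribute; the PSA
#' surfaces the total count of such events.
#'
#' @param baseline_row Named numeric vector of destination probabilities
#'   summing to 1.
#' @param rr Risk ratio, `> 0` (`0` is allowed and removes the transition).
#' @param target_state Name of the destination the risk ratio acts on.
#' @return Adjusted row of the same names, summing to 1, with logical
#'   attribute `capped`.
#' @export
#' @examples
#' apply_treatment_effect(c(REMISSION = 0.4, ACUTE = 0.6), 1.25, "REMISSION")
apply_treatment_effect <- function(baseline_row, rr, target_state) {
  if (rr < 0) stop("rr must be non-negative", call. = FALSE)
  if (!target_state %in% names(baseline_row))
    stop("target_state '", target_state, "' not among destinations", call. = FALSE)
  if (abs(sum(baseline_row) - 1) > 1e-9)
    stop("baseline_row must sum to 1", call. = FALSE)
  p <- baseline_row[[target_state]]
  new_p <- rr * p
  capped <- new_p > 1
  if (capped) new_p <- 1
  out <- baseline_row
  others <- setdiff(names(baseline_row), target_state)
  if (p < 1) {
    out[others] <- baseline_row[others] * (1 - new_p) / (1 - p)
  } else {
    out[others] <- 0
  }
  out[target_state] <- new_p
  attr(out, "capped") <- capped
  out
}

# internal: effect-adjusted destination shares for one strategy at one cycle
adjusted_shares <- function(ps, record, strategy, cycle_index) {
  shares <- record$trans[[strategy]]
  if (strategy != "eip") return(list(shares = shares, n_capped = 0L))
  cl <- ps$settings$cycle_length_years
  if (!is.null(ps$effect_duration_years) &&
      cycle_index * cl >= ps$effect_duration_years)
    return(list(shares = shares, n_capped = 0L))
  n_capped <- 0L
  for (oc in c("remission", "relapse")) {
    tgt <- ps$effect_targets[[oc]]
    rr <- if (oc == "remission") record$rr_remission else record$rr_relapse
    row <- shares[[tgt$from]]
    if (tgt$to %in% names(row)) {
      row <- apply_treatment_effect(row, rr, tgt$to)
      n_capped <- n_capped + as.integer(attr(row, "capped"))
      attr(row, "capped") <- NULL
      shares[[tgt$from]] <- row
    }
  }
  list(shares = shares, n_capped = n_capped)
}

#' Build the transition matrix for one strategy, cycle and age
#'
#' Death is applied first, competing-risk style: each alive state's per-cycle
#' death probability is [annual_rate_to_cycle_prob()] at the life-table rate
#' for the cohort's current age times the state's hazard ratio; the surviving
#' mass is then allocated across the allowed destinations in proportion to
#' the (treatment-effect-adjusted) baseline destination shares.
#'
#' @param ps A [parameter_set()].
#' @param strategy `"eip"` or `"cmht"`.
#' @param cycle_index Non-negative integer; the cohort's age at this cycle is
#'   `start_age + cycle_index * cycle_length`.
#' @param record Optional `param_record` (default: point estimates via
#'   [resolve_parameters()]).
#' @return 6 x 6 row-stochastic matrix of class `transition_matrix`, with
#'   integer attribute `n_capped`.
#' @export
build_transition_matrix <- function(ps, strategy = c("cmht", "eip"),
                                    cycle_index = 0L, record = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(record)) record <- resolve_parameters(ps)
  s <- health_states(); al <- alive_states()
  st <- ps$settings
  age <- ps$start_age + cycle_index * st$cycle_length_years
  rate <- lookup_mortality_rate(ps$life_table, age)
  adj <- adjusted_shares(ps, record, strategy, cycle_index)
  m <- matrix(0, 6L, 6L, dimnames = list(s, s))
  for (from in al) {
    shares <- adj$shares[[from]]
    if (any(shares < -1e-12) || abs(sum(shares) - 1) > 1e-9)
      stop("destination shares for state ", from,
           " must be non-negative and sum to 1", call. = FALSE)
    pd <- annual_rate_to_cycle_prob(rate, record$hazard_ratio[[from]],
                                    st$cycle_length_years)
    m[from, names(shares)] <- (1 - pd) * pmax(shares, 0)
    m[from, "DEAD"] <- m[from, "DEAD"] + pd
  }
  m["DEAD", "DEAD"] <- 1
  structure(m, class = c("transition_matrix", "matrix"), n_capped = adj$n_capped)
}

#' Run the cohort through the Markov model
#'
#' Propagates the starting state distribution through the per-cycle
#' transition matrices by repeated vector-matrix products. Deterministic
#' given its inputs.
#'
#' @inheritParams build_transition_matrix
#' @param horizon_years Optional override of the settings horizon (must be a
#'   multiple of the cycle length).
#' @return A `(cycles + 1) x 6` occupancy matrix of class `cohort_trace`;
#'   row 0 is the start distribution. Attributes: `times` (years at each
#'   row), `strategy`, `n_capped`.
#' @export
run_cohort <- function(ps, strategy = c("cmht", "eip"), record = NULL,
                       horizon_years = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(record)) record <- resolve_parameters(ps)
  st <- ps$settings
  h <- if (is.null(horizon_years)) st$horizon_years else horizon_years
  n_cycles <- round(h / st$cycle_length_years)
  if (abs(n_cycles * st$cycle_length_years - h) > 1e-9)
    stop("horizon_years must be a multiple of the cycle length", call. = FALSE)
  s <- health_states()
  trace <- matrix(0, n_cycles + 1L, 6L, dimnames = list(0:n_cycles, s))
  occ <- check_state_vector(ps$start_state_distribution)
  trace[1L, ] <- occ
  # matrices only change with the life-table rate and the treatment-effect
  # window, so rebuild only when either changes
  cl <- st$cycle_length_years
  cyc <- 0:(n_cycles - 1L)
  rates <- lookup_mortality_rate(ps$life_table, ps$start_age + cyc * cl)
  eff_on <- if (is.null(ps$effect_duration_years)) rep(TRUE, n_cycles)
            else cyc * cl < ps$effect_duration_years
  n_capped <- 0L
  m <- NULL
  key_prev <- NA_character_
  for (t in seq_len(n_cycles)) {
    key <- paste(rates[t], eff_on[t])
    if (!identical(key, key_prev)) {
      m <- build_transition_matrix(ps, strategy, t - 1L, record)
      n_capped <- n_capped + attr(m, "n_capped")
      key_prev <- key
    }
    occ <- as.numeric(occ %*% m)
    trace[t + 1L, ] <- occ
  }
  structure(trace, class = c("cohort_trace", "matrix"),
            times = (0:n_cycles) * st$cycle_length_years,
            strategy = strategy, n_capped = n_capped)
}

#' Accumulate discounted costs and QALYs over a cohort trace
#'
#' QALYs are the sum over cycles and alive states of occupancy times the
#' state's HSUV times the cycle length, discounted per cycle; costs
#' accumulate the per-cycle state costs plus the strategy's program cost for
#' every alive person, discounted at the same rate. By default cycle `t` is
#' valued at its start-of-cycle occupancy (row `t`, discount factor at `t`);
#' with `half_cycle_correction = TRUE` in the settings, the trapezoidal
#' average of rows `t` and `t + 1` is used instead.
#'
#' @param trace A [run_cohort()] trace.
#' @param ps The [parameter_set()] that produced it.
#' @param strategy `"eip"` or `"cmht"`.
#' @param record Optional `param_record` (default: point estimates).
#' @return A list of class `strategy_outcome`: `strategy`, `cost_disc`,
#'   `qaly_disc`, `cost_undisc`, `qaly_undisc`, `life_years`,
#'   `horizon_years`, `discount_rate_annual`.
#' @export
accumulate_outcomes <- function(trace, ps, strategy = c("cmht", "eip"),
                                record = NULL) {
  strategy <- match.arg(strategy)
  if (is.null(record)) record <- resolve_parameters(ps)
  stopifnot(inherits(trace, "cohort_trace"))
  al <- alive_states()
  st <- ps$settings
  cl <- st$cycle_length_years
  n_cycles <- nrow(trace) - 1L
  occ <- unclass(trace)[, al, drop = FALSE]
  per_cycle <- if (st$half_cycle_correction) {
    (occ[1:n_cycles, , drop = FALSE] + occ[2:(n_cycles + 1L), , drop = FALSE]) / 2
  } else {
    occ[1:n_cycles, , drop = FALSE]
  }
  hs <- record$hsuv[al]
  if (anyNA(hs)) stop("missing HSUV for an alive state", call. = FALSE)
  cost_state <- record$state_cost[al]
  if (anyNA(cost_state)) stop("missing cost for an alive state", call. = FALSE)
  df <- discount_factor(0:(n_cycles - 1L), st$discount_rate_annual, cl)

  qaly_cycle <- as.numeric(per_cycle %*% hs) * cl
  alive_tot <- rowSums(per_cycle)
  cost_cycle <- as.numeric(per_cycle %*% cost_state) +
    alive_tot * record$program_cost[[strategy]]

  structure(list(
    strategy = strategy,
    cost_disc = sum(cost_cycle * df),
    qaly_disc = sum(qaly_cycle * df),
    cost_undisc = sum(cost_cycle),
    qaly_undisc = sum(qaly_cycle),
    life_years = sum(alive_tot) * cl,
    horizon_years = n_cycles * cl,
    discount_rate_annual = st$discount_rate_annual
  ), class = "strategy_outcome")
}

#' @export
print.strategy_outcome <- function(x, ...) {
  cat(sprintf("Strategy %s over %g y (r = %.1f%%):\n", toupper(x$strategy),
              x$horizon_years, 100 * x$discount_rate_annual))
  cat(sprintf("  discounted cost %s, discounted QALYs %.4f\n",
              format(round(x$cost_disc), big.mark = ","), x$qaly_disc))
  cat(sprintf("  undiscounted cost %s, undiscounted QALYs %.4f, life-years %.3f\n",
              format(round(x$cost_undisc), big.mark = ","), x$qaly_undisc,
              x$life_years))
  invisible(x)
}

#' Run one strategy end to end
#'
#' Convenience wrapper: [run_cohort()] then [accumulate_outcomes()].
#'
#' @inheritParams run_cohort
#' @return A `strategy_outcome`.
#' @export
run_strategy <- function(ps, strategy = c("cmht", "eip"), record = NULL,
                         horizon_years = NULL) {
  strategy <- match.arg(strategy)
  tr <- run_cohort(ps, strategy, record, horizon_years)
  out <- accumulate_outcomes(tr, ps, strategy, record)
  out$n_capped <- attr(tr, "n_capped")
  out
}

#' Long-format export of a cohort trace
#'
#' @param trace A `cohort_trace`.
#' @param ps The originating [parameter_set()] (for the start age).
#' @return data.frame with columns `cycle`, `age`, `state`, `occupancy`.
#' @export
trace_to_long <- function(trace, ps) {
  stopifnot(inherits(trace, "cohort_trace"))
  times <- attr(trace, "times")
  s <- colnames(trace)
  data.frame(
    cycle = rep(seq_len(nrow(trace)) - 1L, times = length(s)),
    age = rep(ps$start_age + times, times = length(s)),
    state = rep(s, each = nrow(trace)),
    occupancy = as.numeric(unclass(trace))
  )
}
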