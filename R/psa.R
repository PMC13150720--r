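#' Deterministic base-case analysis
#'
#' Runs both strategies at the parameter set's point values (optionally with
#' pooled risk ratios supplied from a fitted synthesis) and returns the
#' incremental analysis.
#'
#' @param ps A [parameter_set()].
#' @param rr_remission,rr_relapse Optional point risk ratios overriding the
#'   parameter set's spec means (typically posterior medians from
#'   [fit_power_prior()]).
#' @param horizon_years Optional horizon override.
#' @return An `incremental_result`.
#' @export
base_case <- function(ps, rr_remission = NULL, rr_relapse = NULL,
                      horizon_years = NULL) {
  record <- resolve_parameters(ps)
  if (!is.null(rr_remission)) record$rr_remission <- rr_remission
  if (!is.null(rr_relapse)) record$rr_relapse <- rr_relapse
  incremental_analysis(run_strategy(ps, "eip", record, horizon_years),
                       run_strategy(ps, "cmht", record, horizon_years))
}

#' Draw one coherent parameter record for the PSA
#'
#' Samples every uncertain parameter once from its [dist_spec()]: Dirichlet
#' rows for competing transitions, beta for utilities and single
#' probabilities, gamma for costs, lognormal for hazard ratios. When the
#' EIP transition spec is identical to the CMHT one (the shared
#' natural-history baseline), the same draw is reused for both strategies,
#' so that within an iteration the strategies differ only through the risk
#' ratios and strategy-specific costs (common random numbers).
#'
#' Uses R's active RNG stream; [run_psa()] seeds it per iteration.
#'
#' @param ps A [parameter_set()].
#' @param rr_remission,rr_relapse Risk-ratio values for this iteration
#'   (e.g. paired posterior draws); if `NULL`, drawn from the parameter
#'   set's `rr` specs.
#' @return A `param_record` (as [resolve_parameters()]) with an additional
#'   `"flat"` attribute: a named numeric vector of every sampled scalar,
#'   retained per iteration for EVPPI.
#' @export
sample_parameters <- function(ps, rr_remission = NULL, rr_relapse = NULL) {
  al <- alive_states()
  flat <- c()
  draw_row <- function(spec) {
    if (!is_dist_spec(spec)) return(spec)  # fixed row
    x <- spec_sample(spec, 1L)
    if (is.matrix(x)) stats::setNames(as.numeric(x), colnames(x)) else x
  }
  trans <- list()
  trans$cmht <- lapply(ps$transitions$cmht[al], draw_row)
  trans$eip <- lapply(al, function(from) {
    if (identical(ps$transitions$eip[[from]], ps$transitions$cmht[[from]]))
      trans$cmht[[from]]
    else draw_row(ps$transitions$eip[[from]])
  })
  names(trans$eip) <- al
  for (from in al) {
    v <- trans$cmht[[from]]
    flat[paste0("trans.", from, ".", names(v))] <- v
    if (!identical(trans$eip[[from]], v)) {
      w <- trans$eip[[from]]
      flat[paste0("trans_eip.", from, ".", names(w))] <- w
    }
  }
  draw_block <- function(block, prefix, lo = -Inf, hi = Inf) {
    v <- vapply(block[al], function(sp) spec_sample(sp, 1L), numeric(1))
    v <- pmin(pmax(v, lo), hi)
    flat[paste0(prefix, ".", al)] <<- v
    v
  }
  hsuv <- draw_block(ps$hsuv, "hsuv", 0, 1)
  state_cost <- draw_block(ps$state_cost, "cost", 0, Inf)
  hazard_ratio <- draw_block(ps$hazard_ratio, "hr", 1e-12, Inf)
  program_cost <- c(eip = spec_sample(ps$program_cost$eip, 1L),
                    cmht = spec_sample(ps$program_cost$cmht, 1L))
  flat[c("program_cost.eip", "program_cost.cmht")] <- program_cost
  if (is.null(rr_remission)) rr_remission <- spec_sample(ps$rr$remission, 1L)
  if (is.null(rr_relapse)) rr_relapse <- spec_sample(ps$rr$relapse, 1L)
  flat["rr_remission"] <- rr_remission
  flat["rr_relapse"] <- rr_relapse
  structure(list(trans = trans, hsuv = hsuv, state_cost = state_cost,
                 hazard_ratio = hazard_ratio, program_cost = program_cost,
                 rr_remission = rr_remission, rr_relapse = rr_relapse),
            class = "param_record", flat = flat)
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo propagation of parameter uncertainty: per iteration, one
#' coherent parameter draw is made, both strategies are run on that same
#' draw, and discounted costs and QALYs are accumulated. Per-iteration RNG
#' streams are derived from the master seed through a seed table, so the
#' result is reproducible bit-for-bit regardless of execution order.
#'
#' @param ps A [parameter_set()].
#' @param remission_draws,relapse_draws Optional numeric vectors of length
#'   `n` of posterior risk-ratio draws (see [posterior_rr_draws()]), paired
#'   by index; if `NULL`, risk ratios are drawn from the parameter set's
#'   `rr` specs.
#' @param n Number of iterations (the reference analysis uses 5000).
#' @param master_seed Integer master seed.
#' @return An object of class `psa_result`: `n`, `outcomes` (data.frame
#'   `iter`, `cost_eip`, `qaly_eip`, `cost_cmht`, `qaly_cmht`), `params`
#'   (matrix of per-iteration sampled values, for EVPPI), `wtp_grid`,
#'   `master_seed`, `n_capped` (risk-ratio capping events).
#' @export
run_psa <- function(ps, remission_draws = NULL, relapse_draws = NULL,
                    n = 5000L, master_seed = 1L) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  for (nm in c("remission_draws", "relapse_draws")) {
    v <- get(nm)
    if (!is.null(v) && length(v) != n)
      stop(nm, " must have length n = ", n, call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(master_seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

  cost_e <- qaly_e <- cost_c <- qaly_c <- numeric(n)
  params <- NULL
  n_capped <- 0L
  for (i in seq_len(n)) {
    set.seed(sub_seeds[i])
    rec <- tryCatch(
      sample_parameters(ps,
                        if (!is.null(remission_draws)) remission_draws[i],
                        if (!is.null(relapse_draws)) relapse_draws[i]),
      error = function(e) stop("PSA iteration ", i, " failed: ",
                               conditionMessage(e), call. = FALSE))
    oe <- run_strategy(ps, "eip", rec)
    oc <- run_strategy(ps, "cmht", rec)
    n_capped <- n_capped + oe$n_capped
    cost_e[i] <- oe$cost_disc; qaly_e[i] <- oe$qaly_disc
    cost_c[i] <- oc$cost_disc; qaly_c[i] <- oc$qaly_disc
    fl <- attr(rec, "flat")
    if (is.null(params)) {
      params <- matrix(NA_real_, n, length(fl),
                       dimnames = list(NULL, names(fl)))
    }
    params[i, ] <- fl
  }
  structure(list(
    n = n,
    outcomes = data.frame(iter = seq_len(n), cost_eip = cost_e,
                          qaly_eip = qaly_e, cost_cmht = cost_c,
                          qaly_cmht = qaly_c),
    params = params,
    wtp_grid = ps$settings$wtp_grid,
    master_seed = master_seed,
    n_capped = n_capped
  ), class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  d <- x$outcomes
  de <- d$qaly_eip - d$qaly_cmht
  dc <- d$cost_eip - d$cost_cmht
  cat(sprintf("PSA: %d iterations (master seed %d)\n", x$n, x$master_seed))
  cat(sprintf("  mean delta cost %s, mean delta QALYs %.4f\n",
              format(round(mean(dc)), big.mark = ","), mean(de)))
  q <- quadrant_shares(x)
  cat(sprintf("  plane shares NE %.1f%%, SE %.1f%%, NW %.1f%%, SW %.1f%%\n",
              100 * q["NE"], 100 * q["SE"], 100 * q["NW"], 100 * q["SW"]))
  if (x$n_capped > 0)
    cat(sprintf("  note: %d risk-ratio capping events\n", x$n_capped))
  invisible(x)
}

#' @export
plot.psa_result <- function(x, ...) {
  d <- x$outcomes
  graphics::plot(d$qaly_eip - d$qaly_cmht, d$cost_eip - d$cost_cmht,
                 pch = ".", cex = 2, xlab = "Incremental QALYs",
                 ylab = "Incremental cost", ...)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

# ---- deterministic sensitivity analysis -------------------------------------

# set one scalar parameter in a record by dotted name; transition shares are
# renormalized so the row still sums to 1
set_record_value <- function(record, name, value) {
  parts <- strsplit(name, ".", fixed = TRUE)[[1L]]
  head <- parts[1L]
  if (head %in% c("trans", "trans_eip")) {
    if (length(parts) != 3L) stop("bad transition parameter name: ", name,
                                  call. = FALSE)
    if (value < 0 || value > 1)
      stop("transition share for ", name, " must lie in [0, 1]", call. = FALSE)
    strategies <- if (head == "trans") c("cmht", "eip") else "eip"
    for (strat in strategies) {
      row <- record$trans[[strat]][[parts[2L]]]
      p <- row[[parts[3L]]]
      others <- setdiff(names(row), parts[3L])
      row[others] <- if (p < 1) row[others] * (1 - value) / (1 - p)
                     else rep((1 - value) / length(others), length(others))
      row[parts[3L]] <- value
      record$trans[[strat]][[parts[2L]]] <- row
    }
  } else if (head == "hsuv") {
    if (value < 0 || value > 1) stop("HSUV must lie in [0, 1]", call. = FALSE)
    record$hsuv[[parts[2L]]] <- value
  } else if (head == "cost") {
    if (value < 0) stop("state cost must be non-negative", call. = FALSE)
    record$state_cost[[parts[2L]]] <- value
  } else if (head == "hr") {
    if (value <= 0) stop("hazard ratio must be positive", call. = FALSE)
    record$hazard_ratio[[parts[2L]]] <- value
  } else if (head == "program_cost") {
    if (value < 0) stop("program cost must be non-negative", call. = FALSE)
    record$program_cost[[parts[2L]]] <- value
  } else if (name %in% c("rr_remission", "rr_relapse")) {
    if (value <= 0) stop("risk ratio must be positive", call. = FALSE)
    record[[name]] <- value
  } else {
    stop("unknown parameter name: ", name, call. = FALSE)
  }
  record
}

# run the deterministic model for one record and return the incremental result
run_record <- function(ps, record, horizon_years = NULL) {
  incremental_analysis(run_strategy(ps, "eip", record, horizon_years),
                       run_strategy(ps, "cmht", record, horizon_years))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the deterministic model with each named parameter set to its low
#' and high bound, all else held at the base case, reporting the ICER and
#' the incremental net benefit at a reference threshold. Parameters are
#' addressed by dotted names matching the PSA parameter record:
#' `hsuv.<STATE>`, `cost.<STATE>`, `hr.<STATE>`, `program_cost.<strategy>`,
#' `rr_remission`, `rr_relapse`, and `trans.<FROM>.<TO>` (the destination
#' share, renormalizing the rest of the row).
#'
#' @param ps A [parameter_set()].
#' @param sweeps List of `list(name = , low = , high = )`.
#' @param lambda_ref Reference willingness-to-pay for the net-benefit
#'   column (default: midpoint of the WTP grid).
#' @return data.frame of class `tornado_table` with one row per sweep,
#'   sorted by decreasing net-benefit range.
#' @export
one_way_sa <- function(ps, sweeps, lambda_ref = NULL) {
  if (is.null(lambda_ref)) lambda_ref <- stats::median(ps$settings$wtp_grid)
  base_rec <- resolve_parameters(ps)
  rows <- lapply(sweeps, function(sw) {
    stopifnot(all(c("name", "low", "high") %in% names(sw)))
    res <- lapply(c(sw$low, sw$high), function(v) {
      rec <- set_record_value(base_rec, sw$name, v)
      run_record(ps, rec)
    })
    nb <- vapply(res, function(r)
      net_benefit(r$delta_qaly, r$delta_cost, lambda_ref), numeric(1))
    data.frame(parameter = sw$name, low = sw$low, high = sw$high,
               icer_low = res[[1L]]$icer, icer_high = res[[2L]]$icer,
               nb_low = nb[1L], nb_high = nb[2L],
               nb_range = abs(nb[2L] - nb[1L]))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$nb_range), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda_ref") <- lambda_ref
  class(out) <- c("tornado_table", "data.frame")
  out
}

#' Scenario analyses
#'
#' Re-runs the deterministic incremental analysis under named scenarios:
#' alternative horizons (including `"lifetime"`, i.e. until the cohort
#' reaches age 80) and/or point overrides of parameters.
#'
#' @param ps A [parameter_set()].
#' @param scenarios List of `list(name = , horizon_years = , overrides = )`;
#'   `horizon_years` may be a number or `"lifetime"`, `overrides` an
#'   optional named list of parameter values (dotted names as in
#'   [one_way_sa()]).
#' @return data.frame with one row per scenario: `scenario`,
#'   `horizon_years`, `delta_cost`, `delta_qaly`, `icer`, `dominance`.
#' @export
run_scenarios <- function(ps, scenarios) {
  rows <- lapply(scenarios, function(sc) {
    h <- sc$horizon_years
    if (identical(h, "lifetime")) h <- 80 - ps$start_age
    if (is.null(h)) h <- ps$settings$horizon_years
    rec <- resolve_parameters(ps)
    for (nm in names(sc$overrides))
      rec <- set_record_value(rec, nm, sc$overrides[[nm]])
    r <- run_record(ps, rec, horizon_years = h)
    data.frame(scenario = sc$name, horizon_years = h,
               delta_cost = r$delta_cost, delta_qaly = r$delta_qaly,
               icer = r$icer, dominance = r$dominance)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
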