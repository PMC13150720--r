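#' Incremental cost-effectiveness analysis of EIP vs CMHT
#'
#' Computes the incremental cost `delta_cost = C_EIP - C_CMHT`, incremental
#' effect `delta_qaly = E_EIP - E_CMHT`, classifies dominance, and reports
#' the ICER `delta_cost / delta_qaly` where the ratio is meaningful (the
#' trade-off quadrants). When one strategy dominates, or both differences
#' are zero, the ICER is `NA` and the classification carries the decision.
#'
#' @param eip,cmht `strategy_outcome` objects from the same parameter set
#'   and horizon.
#' @return A list of class `incremental_result`: `delta_cost`, `delta_qaly`,
#'   `icer` (`NA` when undefined), `dominance` (one of `"dominant"`,
#'   `"dominated"`, `"trade_off_ne"`, `"trade_off_sw"`, `"no_difference"`),
#'   plus the per-strategy costs/QALYs.
#' @export
incremental_analysis <- function(eip, cmht) {
  stopifnot(inherits(eip, "strategy_outcome"), inherits(cmht, "strategy_outcome"))
  if (abs(eip$horizon_years - cmht$horizon_years) > 1e-9)
    stop("strategy outcomes have mismatched horizons", call. = FALSE)
  dc <- eip$cost_disc - cmht$cost_disc
  de <- eip$qaly_disc - cmht$qaly_disc
  dominance <-
    if (dc == 0 && de == 0) "no_difference"
    else if (dc <= 0 && de >= 0) "dominant"
    else if (dc >= 0 && de <= 0) "dominated"
    else if (de > 0) "trade_off_ne"
    else "trade_off_sw"
  icer <- if (dominance %in% c("trade_off_ne", "trade_off_sw")) dc / de else NA_real_
  structure(list(delta_cost = dc, delta_qaly = de, icer = icer,
                 dominance = dominance,
                 cost_eip = eip$cost_disc, qaly_eip = eip$qaly_disc,
                 cost_cmht = cmht$cost_disc, qaly_cmht = cmht$qaly_disc,
                 horizon_years = eip$horizon_years),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat(sprintf("Incremental analysis (EIP vs CMHT), %g-y horizon\n",
              x$horizon_years))
  cat(sprintf("  delta cost: %s   delta QALYs: %.4f\n",
              format(round(x$delta_cost), big.mark = ","), x$delta_qaly))
  if (is.na(x$icer)) {
    cat(sprintf("  ICER: not reported (%s)\n", x$dominance))
  } else {
    cat(sprintf("  ICER: %s per QALY (%s)\n",
                format(round(x$icer), big.mark = ","), x$dominance))
  }
  invisible(x)
}

#' Incremental net monetary benefit
#'
#' `NB(lambda) = lambda * delta_qaly - delta_cost`: the incremental benefit
#' valued at the willingness-to-pay threshold `lambda`, minus the
#' incremental cost. Linear in `lambda`, and zero exactly at
#' `lambda = ICER` when `delta_qaly > 0`.
#'
#' @param delta_qaly Incremental QALYs (vectorized).
#' @param delta_cost Incremental cost (vectorized).
#' @param lambda Willingness to pay per QALY, `>= 0` (vectorized).
#' @return Net monetary benefit in currency units.
#' @export
net_benefit <- function(delta_qaly, delta_cost, lambda) {
  if (any(lambda < 0)) stop("lambda must be non-negative", call. = FALSE)
  lambda * delta_qaly - delta_cost
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay threshold, the fraction of PSA iterations in
#' which EIP has the higher net monetary benefit; exact ties contribute 0.5.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Non-empty vector of thresholds (default: the parameter
#'   set's grid stored in the PSA).
#' @return data.frame of class `ceac_curve` with columns `lambda`,
#'   `prob_eip`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "psa_result"))
  if (is.null(wtp_grid)) wtp_grid <- psa$wtp_grid
  if (length(wtp_grid) == 0L) stop("wtp_grid is empty", call. = FALSE)
  if (psa$n < 1L) stop("PSA has no iterations", call. = FALSE)
  d <- psa$outcomes
  prob <- vapply(wtp_grid, function(l) {
    nb_e <- l * d$qaly_eip - d$cost_eip
    nb_c <- l * d$qaly_cmht - d$cost_cmht
    mean((nb_e > nb_c) + 0.5 * (nb_e == nb_c))
  }, numeric(1))
  structure(data.frame(lambda = wtp_grid, prob_eip = prob),
            class = c("ceac_curve", "data.frame"))
}

#' @export
plot.ceac_curve <- function(x, ...) {
  graphics::plot(x$lambda, x$prob_eip, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (per QALY)",
                 ylab = "P(EIP cost-effective)", ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Cost-effectiveness plane quadrant shares
#'
#' Shares of PSA iterations falling in each quadrant of the
#' (incremental QALY, incremental cost) plane: NE (more effective, more
#' costly), SE (more effective, cheaper: EIP dominates), NW (less effective,
#' more costly: CMHT dominates), SW (less effective, cheaper). Points on a
#' boundary are split evenly between the adjacent quadrants, so the shares
#' always sum to 1.
#'
#' @param psa A [run_psa()] result.
#' @return Named numeric vector `(NE, SE, NW, SW)` summing to 1.
#' @export
quadrant_shares <- function(psa) {
  stopifnot(inherits(psa, "psa_result"))
  d <- psa$outcomes
  de <- d$qaly_eip - d$qaly_cmht
  dc <- d$cost_eip - d$cost_cmht
  east <- (de > 0) + 0.5 * (de == 0)
  north <- (dc > 0) + 0.5 * (dc == 0)
  c(NE = mean(east * north), SE = mean(east * (1 - north)),
    NW = mean((1 - east) * north), SW = mean((1 - east) * (1 - north)))
}
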