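#' Net-benefit matrix at a fixed willingness to pay
#'
#' Converts a PSA into the iterations x strategies matrix of net monetary
#' benefit `lambda * QALY - cost` that all value-of-information measures are
#' computed from.
#'
#' @param psa A [run_psa()] result.
#' @param lambda Willingness to pay per QALY, `>= 0`.
#' @return `n x 2` numeric matrix with columns `eip`, `cmht`.
#' @export
nb_matrix <- function(psa, lambda) {
  stopifnot(inherits(psa, "psa_result"))
  if (lambda < 0) stop("lambda must be non-negative", call. = FALSE)
  d <- psa$outcomes
  cbind(eip = lambda * d$qaly_eip - d$cost_eip,
        cmht = lambda * d$qaly_cmht - d$cost_cmht)
}

#' Per-person expected value of perfect information
#'
#' `EVPI = E[max_s NB_s] - max_s E[NB_s]`: the expected gain from learning
#' every parameter before choosing a strategy. Non-negative by Jensen's
#' inequality; tiny negative floating-point results are clamped to 0.
#'
#' @param nb An iterations x strategies net-benefit matrix
#'   (see [nb_matrix()]).
#' @return EVPI per person, in currency units.
#' @export
#' @examples
#' evpi(cbind(A = c(10, 0), B = c(0, 4)))  # E[max] = 7, max E = 5 -> 2
evpi <- function(nb) {
  nb <- as.matrix(nb)
  if (ncol(nb) < 2L) stop("need at least 2 strategies", call. = FALSE)
  if (!all(is.finite(nb))) stop("net-benefit matrix has non-finite entries",
                                call. = FALSE)
  max(mean(apply(nb, 1L, max)) - max(colMeans(nb)), 0)
}

#' Population expected value of perfect information
#'
#' Scales the per-person EVPI to the population that the decision affects:
#' each future year's incident cases are discounted back to the present, and
#' the current year (t = 0) is undiscounted.
#'
#' @param evpi_per_person Per-person EVPI (currency).
#' @param annual_incident_cases Incident cases per year.
#' @param years Number of years the decision is relevant for.
#' @param r Annual discount rate, fraction.
#' @return Population EVPI:
#'   `evpi_per_person * sum_{t=0}^{years-1} annual_incident_cases / (1+r)^t`.
#' @export
population_evpi <- function(evpi_per_person, annual_incident_cases, years, r) {
  if (any(c(evpi_per_person, annual_incident_cases, years) < 0) || r < 0)
    stop("all inputs must be non-negative", call. = FALSE)
  if (years == 0) return(0)
  evpi_per_person * sum(annual_incident_cases / (1 + r)^(0:(years - 1L)))
}

#' Partial EVPI for a parameter group (regression estimator)
#'
#' Single-loop regression-based EVPPI: for each strategy, the conditional
#' expectation of net benefit given the group's sampled values is estimated
#' by an additive spline regression (thin-plate splines via `mgcv::gam`;
#' parameters with few distinct values enter linearly), and
#' `EVPPI = E[max_s fitted_s] - max_s E[fitted_s]`. The standard error is a
#' nonparametric bootstrap over iterations of the fitted-value matrix.
#'
#' @param psa A [run_psa()] result (with its per-iteration parameter
#'   records).
#' @param lambda Willingness to pay per QALY.
#' @param group Character vector of parameter names (columns of
#'   `psa$params`), e.g. `c("rr_remission", "rr_relapse")`.
#' @param n_boot Bootstrap resamples for the standard error (default 200).
#' @param seed Seed for the bootstrap resampling.
#' @return List of class `evppi_result`: `group`, `estimate`, `se`,
#'   `lambda`.
#' @export
evppi <- function(psa, lambda, group, n_boot = 200L, seed = 1L) {
  stopifnot(inherits(psa, "psa_result"))
  missing_cols <- setdiff(group, colnames(psa$params))
  if (length(missing_cols))
    stop("unknown parameter(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  nb <- nb_matrix(psa, lambda)
  x <- psa$params[, group, drop = FALSE]
  keep <- apply(x, 2L, function(v) stats::var(v) > 0)
  if (!any(keep)) {
    warning("parameter group has zero variance; EVPPI is 0", call. = FALSE)
    return(structure(list(group = group, estimate = 0, se = 0,
                          lambda = lambda), class = "evppi_result"))
  }
  x <- x[, keep, drop = FALSE]
  df <- as.data.frame(x)
  names(df) <- paste0("x", seq_len(ncol(df)))
  terms <- vapply(seq_len(ncol(df)), function(j) {
    if (length(unique(df[[j]])) >= 10L) sprintf("s(x%d)", j)
    else sprintf("x%d", j)
  }, character(1))
  form_rhs <- paste(terms, collapse = " + ")
  fitted <- vapply(colnames(nb), function(s) {
    df$y <- nb[, s]
    fit <- mgcv::gam(stats::as.formula(paste("y ~", form_rhs)), data = df)
    as.numeric(stats::fitted(fit))
  }, numeric(nrow(nb)))

  stat <- function(f) max(mean(apply(f, 1L, max)) - max(colMeans(f)), 0)
  est <- stat(fitted)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  boots <- replicate(n_boot, {
    idx <- sample.int(nrow(fitted), replace = TRUE)
    stat(fitted[idx, , drop = FALSE])
  })
  structure(list(group = group, estimate = est, se = stats::sd(boots),
                 lambda = lambda), class = "evppi_result")
}

#' @export
print.evppi_result <- function(x, ...) {
  cat(sprintf("EVPPI{%s} at lambda %s: %s (SE %s)\n",
              paste(x$group, collapse = ", "),
              format(x$lambda, big.mark = ","),
              format(round(x$estimate), big.mark = ","),
              format(round(x$se), big.mark = ",")))
  invisible(x)
}

#' Full value-of-information analysis
#'
#' Computes the per-person EVPI at the given threshold, scales it to the
#' affected population, and evaluates partial EVPI for each named parameter
#' group.
#'
#' @param psa A [run_psa()] result.
#' @param lambda Willingness to pay per QALY.
#' @param annual_incident_cases Incident cases per year entering the
#'   population scaling (e.g. incidence rate x eligible population).
#' @param years Years the decision remains relevant.
#' @param r Annual discount rate for the population scaling.
#' @param groups Named list of character vectors: parameter groups for
#'   EVPPI (may be empty).
#' @param n_boot,seed Passed to [evppi()].
#' @return List of class `voi_result`: `lambda`, `evpi_per_person`,
#'   `population_evpi` (with its inputs), and `evppi` (data.frame `group`,
#'   `estimate`, `se`).
#' @export
voi_analysis <- function(psa, lambda, annual_incident_cases, years = 10,
                         r = 0.03, groups = list(), n_boot = 200L,
                         seed = 1L) {
  e <- evpi(nb_matrix(psa, lambda))
  pop <- population_evpi(e, annual_incident_cases, years, r)
  ev_tab <- NULL
  if (length(groups)) {
    rows <- lapply(names(groups), function(g) {
      r_g <- evppi(psa, lambda, groups[[g]], n_boot = n_boot, seed = seed)
      data.frame(group = g, estimate = r_g$estimate, se = r_g$se)
    })
    ev_tab <- do.call(rbind, rows)
  }
  structure(list(lambda = lambda, evpi_per_person = e,
                 population_evpi = pop,
                 population_inputs = list(
                   annual_incident_cases = annual_incident_cases,
                   years = years, discount_rate = r),
                 evppi = ev_tab),
            class = "voi_result")
}

#' @export
print.voi_result <- function(x, ...) {
  cat(sprintf("Value of information at lambda %s per QALY\n",
              format(x$lambda, big.mark = ",")))
  cat(sprintf("  per-person EVPI: %s\n",
              format(round(x$evpi_per_person), big.mark = ",")))
  cat(sprintf("  population EVPI: %s (%.0f cases/y over %d y at %.1f%%)\n",
              format(round(x$population_evpi), big.mark = ","),
              x$population_inputs$annual_incident_cases,
              x$population_inputs$years,
              100 * x$population_inputs$discount_rate))
  if (!is.null(x$evppi)) {
    cat("  partial EVPI by group:\n")
    for (i in seq_len(nrow(x$evppi)))
      cat(sprintf("    %-28s %s (SE %s)\n", x$evppi$group[i],
                  format(round(x$evppi$estimate[i]), big.mark = ","),
                  format(round(x$evppi$se[i]), big.mark = ",")))
  }
  invisible(x)
}
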