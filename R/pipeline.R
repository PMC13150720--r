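#' Write a run record
#'
#' Every output directory produced by the pipeline contains exactly one
#' `run_record.json` capturing the command, the resolved settings, every
#' seed, the package version and a timestamp, so a rerun with the same
#' record reproduces all stochastic outputs exactly.
#'
#' @param dir Output directory.
#' @param command Name of the entry point that produced the outputs.
#' @param seeds Named list of seeds used.
#' @param settings Resolved settings/config snapshot (list).
#' @param outputs Character vector of files written.
#' @return The record, invisibly.
#' @export
write_run_record <- function(dir, command, seeds, settings, outputs) {
  rec <- list(command = command,
              package = "eipcea",
              version = as.character(utils::packageVersion("eipcea")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seeds = seeds, settings = settings,
              outputs = as.character(outputs))
  jsonlite::write_json(rec, file.path(dir, "run_record.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(rec)
}

#' Run the deterministic base case and write its report
#'
#' Runs both strategies at the point estimates (optionally with pooled risk
#' ratios from fitted syntheses), writes the incremental summary JSON, the
#' per-strategy outcome table and the long-format cohort traces, plus a run
#' record.
#'
#' @param ps A [parameter_set()].
#' @param out_dir Output directory (created if needed).
#' @param rr_remission,rr_relapse Optional pooled risk ratios (posterior
#'   medians); defaults to the parameter set's spec means.
#' @param horizon_years Optional horizon override.
#' @return The `incremental_result`, invisibly.
#' @export
run_base_case <- function(ps, out_dir, rr_remission = NULL,
                          rr_relapse = NULL, horizon_years = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  record <- resolve_parameters(ps)
  if (!is.null(rr_remission)) record$rr_remission <- rr_remission
  if (!is.null(rr_relapse)) record$rr_relapse <- rr_relapse
  outs <- lapply(c(eip = "eip", cmht = "cmht"), function(strat) {
    tr <- run_cohort(ps, strat, record, horizon_years)
    utils::write.csv(trace_to_long(tr, ps),
                     file.path(out_dir, paste0("trace_", strat, ".csv")),
                     row.names = FALSE, quote = FALSE)
    accumulate_outcomes(tr, ps, strat, record)
  })
  inc <- incremental_analysis(outs$eip, outs$cmht)
  outcome_tab <- do.call(rbind, lapply(outs, function(o)
    data.frame(strategy = o$strategy, cost_disc = o$cost_disc,
               qaly_disc = o$qaly_disc, cost_undisc = o$cost_undisc,
               qaly_undisc = o$qaly_undisc, life_years = o$life_years)))
  utils::write.csv(outcome_tab, file.path(out_dir, "outcomes.csv"),
                   row.names = FALSE, quote = FALSE)
  summary_json <- list(
    delta_cost = inc$delta_cost, delta_qaly = inc$delta_qaly,
    icer = if (is.na(inc$icer)) NULL else inc$icer,
    icer_usd_ppp = if (is.na(inc$icer)) NULL
                   else inc$icer / ps$settings$ppp_clp_per_usd,
    dominance = inc$dominance,
    cost_eip = inc$cost_eip, qaly_eip = inc$qaly_eip,
    cost_cmht = inc$cost_cmht, qaly_cmht = inc$qaly_cmht,
    horizon_years = inc$horizon_years,
    rr_remission = record$rr_remission, rr_relapse = record$rr_relapse)
  jsonlite::write_json(summary_json,
                       file.path(out_dir, "incremental_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_run_record(out_dir, "run_base_case",
                   seeds = list(),
                   settings = c(unclass(ps$settings),
                                list(horizon_override = horizon_years,
                                     rr_remission = record$rr_remission,
                                     rr_relapse = record$rr_relapse)),
                   outputs = c("trace_eip.csv", "trace_cmht.csv",
                               "outcomes.csv", "incremental_summary.json"))
  invisible(inc)
}

#' Run the whole evaluation pipeline and write every artifact
#'
#' Orchestrates all stages on one parameter set and evidence base:
#' the power-prior syntheses for remission and relapse (at the requested
#' weight), the deterministic base case at the posterior-median risk
#' ratios, the probabilistic sensitivity analysis with risk-ratio draws
#' taken from the posteriors, the acceptability curve, the plane quadrant
#' shares, and the value-of-information analysis. Each stage's tables are
#' written under `out_dir`, with a single run record tying the seeds
#' together; a stage failure halts the pipeline with the stage name while
#' preserving earlier outputs.
#'
#' @param ps A [parameter_set()] (e.g. [make_reference_parameter_set()]).
#' @param evidence Evidence base as [generate_reference_evidence()]
#'   returns: `remission`/`relapse` study data frames and a `cohort` list.
#' @param out_dir Output directory.
#' @param n_psa PSA iterations (reference analysis: 5000).
#' @param seed Master seed driving the sampler and every Monte Carlo stage.
#' @param a0 Power-prior weight for the observational cohort.
#' @param annual_incident_cases Incident cases per year for the population
#'   EVPI.
#' @param evppi_groups Named list of parameter groups for partial EVPI
#'   (default: the treatment effects, the remission HSUV and the
#'   relapse-management cost).
#' @return List with every stage's in-memory result, invisibly.
#' @export
run_full_pipeline <- function(ps, evidence, out_dir, n_psa = 5000L,
                              seed = 1L, a0 = 1,
                              annual_incident_cases = 18.9e-5 * 20.1e6,
                              evppi_groups = list(
                                treatment_effects = c("rr_remission",
                                                      "rr_relapse"),
                                hsuv_remission = "hsuv.REMISSION",
                                cost_relapse = "cost.RELAPSE")) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  sampler <- list(seed = seed)
  fit_rem <- stage("synthesis_remission",
    fit_power_prior(evidence$remission, evidence$cohort$remission, a0 = a0,
                    sampler = sampler, outcome = "remission"))
  fit_rel <- stage("synthesis_relapse",
    fit_power_prior(evidence$relapse, evidence$cohort$relapse, a0 = a0,
                    sampler = sampler, outcome = "relapse"))
  for (f in list(fit_rem, fit_rel)) {
    utils::write.csv(
      data.frame(draw = seq_len(nrow(f$draws)), rr = f$draws[, "rr"]),
      file.path(out_dir, paste0("draws_", f$outcome, ".csv")),
      row.names = FALSE, quote = FALSE)
    jsonlite::write_json(
      list(outcome = f$outcome, a0 = f$a0, summary = as.list(f$summary),
           diagnostics = as.list(f$diagnostics), converged = f$converged),
      file.path(out_dir, paste0("synthesis_", f$outcome, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  inc <- stage("base_case",
    run_base_case(ps, out_dir,
                  rr_remission = fit_rem$summary[["median"]],
                  rr_relapse = fit_rel$summary[["median"]]))

  rem_draws <- posterior_rr_draws(fit_rem, n_psa, seed = seed, resample = TRUE)
  rel_draws <- posterior_rr_draws(fit_rel, n_psa, seed = seed + 1L,
                                  resample = TRUE)
  psa <- stage("psa", run_psa(ps, rem_draws, rel_draws, n = n_psa,
                              master_seed = seed))
  d <- psa$outcomes
  utils::write.csv(
    data.frame(iter = d$iter, delta_qaly = d$qaly_eip - d$qaly_cmht,
               delta_cost = d$cost_eip - d$cost_cmht),
    file.path(out_dir, "plane.csv"), row.names = FALSE, quote = FALSE)

  cc <- stage("ceac", ceac(psa))
  utils::write.csv(data.frame(lambda = cc$lambda, prob_eip = cc$prob_eip),
                   file.path(out_dir, "ceac.csv"),
                   row.names = FALSE, quote = FALSE)
  quad <- quadrant_shares(psa)

  gdp_pc_clp <- 15923 * ps$settings$ppp_clp_per_usd
  voi <- stage("voi",
    voi_analysis(psa, lambda = gdp_pc_clp,
                 annual_incident_cases = annual_incident_cases,
                 years = ps$settings$horizon_years,
                 r = ps$settings$discount_rate_annual,
                 groups = evppi_groups, seed = seed))
  jsonlite::write_json(
    list(lambda = voi$lambda, evpi_per_person = voi$evpi_per_person,
         population_inputs = voi$population_inputs,
         population_evpi = voi$population_evpi,
         evppi = voi$evppi, quadrant_shares = as.list(quad)),
    file.path(out_dir, "voi.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  write_run_record(out_dir, "run_full_pipeline",
                   seeds = list(master = seed, sampler = seed,
                                rr_draws = c(seed, seed + 1L)),
                   settings = c(unclass(ps$settings),
                                list(n_psa = n_psa, a0 = a0,
                                     annual_incident_cases =
                                       annual_incident_cases)),
                   outputs = list.files(out_dir))
  invisible(list(fit_remission = fit_rem, fit_relapse = fit_rel,
                 base_case = inc, psa = psa, ceac = cc,
                 quadrant_shares = quad, voi = voi))
}
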