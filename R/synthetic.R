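#' Generate a synthetic meta-analytic dataset
#'
#' Simulates two-arm study-level binomial data under the same random-effects
#' structure the synthesis assumes: per study a log risk ratio
#' `delta_i ~ Normal(mu_log_rr, tau^2)`, a control risk drawn uniformly from
#' `control_risk_range`, a treatment risk `min(control_risk * exp(delta_i),
#' 0.99)`, and binomial event counts. Defaults emulate the evidence base of
#' the evaluation: six two-arm studies of roughly 2000 participants in
#' total.
#'
#' @param k Number of studies.
#' @param mu_log_rr True pooled log risk ratio.
#' @param tau Between-study SD on the log-RR scale.
#' @param n_range Integer range for each arm's size (uniform).
#' @param control_risk_range Range of the control-arm risk (uniform).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return Data frame with columns `study_id`, `events_treatment`,
#'   `n_treatment`, `events_control`, `n_control`; integer attribute
#'   `n_truncated` counts studies whose treatment risk was truncated at
#'   0.99 (also warned about).
#' @export
generate_meta_dataset <- function(k = 6L, mu_log_rr = log(1.3), tau = 0.15,
                                  n_range = c(120L, 220L),
                                  control_risk_range = c(0.3, 0.5),
                                  seed = 1L) {
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (any(control_risk_range <= 0 | control_risk_range >= 1))
    stop("control risks must lie in (0, 1)", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_t <- sample(n_range[1L]:n_range[2L], k, replace = TRUE)
  n_c <- sample(n_range[1L]:n_range[2L], k, replace = TRUE)
  p_c <- stats::runif(k, control_risk_range[1L], control_risk_range[2L])
  delta <- stats::rnorm(k, mu_log_rr, tau)
  p_t_raw <- p_c * exp(delta)
  trunc <- p_t_raw > 0.99
  if (any(trunc))
    warning(sum(trunc), " study treatment risk(s) truncated at 0.99",
            call. = FALSE)
  p_t <- pmin(p_t_raw, 0.99)
  out <- data.frame(
    study_id = sprintf("study_%02d", seq_len(k)),
    events_treatment = stats::rbinom(k, n_t, p_t), n_treatment = n_t,
    events_control = stats::rbinom(k, n_c, p_c), n_control = n_c)
  attr(out, "n_truncated") <- sum(trunc)
  out
}

#' Generate a synthetic single-arm observational cohort
#'
#' Binomial remission and relapse counts for a cohort of FEP patients
#' (default n = 82, the size of the observational cohort the evaluation
#' emulates).
#'
#' @param n Cohort size.
#' @param remission_prob,relapse_prob True outcome probabilities in
#'   `[0, 1]`.
#' @param seed Integer seed.
#' @return List with elements `remission` and `relapse`, each
#'   `list(events, n, outcome)`.
#' @export
generate_cohort <- function(n = 82L, remission_prob = 0.55,
                            relapse_prob = 0.15, seed = 1L) {
  if (remission_prob < 0 || remission_prob > 1 ||
      relapse_prob < 0 || relapse_prob > 1)
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  list(remission = list(events = stats::rbinom(1L, n, remission_prob), n = n,
                        outcome = "remission"),
       relapse = list(events = stats::rbinom(1L, n, relapse_prob), n = n,
                      outcome = "relapse"))
}

#' Generate a synthetic Gompertz life table
#'
#' Annual mortality rates `rate(age) = a * exp(b * age)`, capped below 1 —
#' a smooth, seed-free stand-in for a national life table. The defaults are
#' chosen so that remaining life expectancy at age 20 is about 60 years
#' (a population with average life expectancy around 80).
#'
#' @param max_age Last tabulated age.
#' @param a Baseline hazard at age 0 (`a = 0` gives an immortal cohort).
#' @param b Log-linear slope of mortality with age.
#' @return A [life_table()] over ages `0:max_age`.
#' @export
generate_life_table <- function(max_age = 100L, a = 3.835e-5, b = 0.09) {
  if (a < 0 || b < 0) stop("a and b must be non-negative", call. = FALSE)
  ages <- 0:max_age
  life_table(ages, pmin(a * exp(b * ages), 1))
}

#' Reference parameter set (synthetic fixture)
#'
#' Builds the complete, validated parameter set that plays the role of the
#' evaluation's parameter tables: plausible stand-in values for the Chilean
#' FEP pathway, explicitly not transcriptions of any published table (the
#' config slots accept drop-in replacements). EIP differs from CMHT through
#' the treatment-effect risk ratios and a higher per-cycle program cost.
#' The construction is calibrated: the deterministic base case must land in
#' the north-east quadrant with an incremental benefit between 0.1 and 0.5
#' QALYs over 10 years, and the function errors if it does not.
#'
#' @param check_calibration If `TRUE` (default), run the base case and
#'   enforce the calibration gate.
#' @return A [parameter_set()] with a `manifest` attribute recording every
#'   generator input (see [fixture_manifest()]).
#' @export
make_reference_parameter_set <- function(check_calibration = TRUE) {
  al <- alive_states()
  dir_spec <- function(...) {
    p <- c(...)
    dist_spec("dirichlet", p)
  }
  baseline <- list(
    ACUTE = dir_spec(ACUTE = 50, REMISSION = 35, RESISTANT = 8, PNS = 7),
    REMISSION = dir_spec(REMISSION = 135, RELAPSE = 12, PNS = 3),
    RELAPSE = dir_spec(RELAPSE = 55, REMISSION = 35, RESISTANT = 10),
    RESISTANT = dir_spec(RESISTANT = 97, REMISSION = 3),
    PNS = dir_spec(PNS = 95, RELAPSE = 5)
  )
  hsuv <- list(
    ACUTE = beta_spec_from_moments(0.45, 0.05),
    REMISSION = beta_spec_from_moments(0.82, 0.04),
    RELAPSE = beta_spec_from_moments(0.57, 0.05),
    RESISTANT = beta_spec_from_moments(0.48, 0.05),
    PNS = beta_spec_from_moments(0.55, 0.05)
  )
  state_cost <- list(
    ACUTE = gamma_spec_from_moments(1200000, 240000),
    REMISSION = gamma_spec_from_moments(180000, 36000),
    # relapse cost mixes inpatient and outpatient management:
    # 0.35 * 3,600,000 + 0.65 * 450,000 per cycle
    RELAPSE = gamma_spec_from_moments(1552500, 310500),
    RESISTANT = gamma_spec_from_moments(850000, 170000),
    PNS = gamma_spec_from_moments(350000, 70000)
  )
  program_cost <- list(
    eip = gamma_spec_from_moments(235000, 35250),
    cmht = gamma_spec_from_moments(110000, 16500)
  )
  hazard_ratio <- list(
    ACUTE = lognormal_spec_from_ci(2.5, 1.5, 4.0),
    REMISSION = lognormal_spec_from_ci(1.3, 1.0, 1.8),
    RELAPSE = lognormal_spec_from_ci(2.5, 1.5, 4.0),
    RESISTANT = lognormal_spec_from_ci(3.0, 2.0, 4.5),
    PNS = lognormal_spec_from_ci(2.2, 1.4, 3.5)
  )
  rr <- list(remission = lognormal_spec_from_ci(1.25, 1.05, 1.58),
             relapse = lognormal_spec_from_ci(0.51, 0.25, 0.79))
  ps <- parameter_set(
    transitions = list(cmht = baseline, eip = baseline),
    hsuv = hsuv, state_cost = state_cost, program_cost = program_cost,
    hazard_ratio = hazard_ratio, rr = rr,
    effect_targets = list(remission = list(from = "ACUTE", to = "REMISSION"),
                          relapse = list(from = "REMISSION", to = "RELAPSE")),
    settings = economic_settings(),
    life_table = generate_life_table(),
    start_age = 20
  )
  if (check_calibration) {
    bc <- base_case(ps)
    ok <- bc$delta_cost > 0 && bc$delta_qaly > 0.1 && bc$delta_qaly < 0.5
    if (!ok)
      stop(sprintf(paste0("reference parameter set failed calibration: ",
                          "delta cost %.0f, delta QALYs %.4f (need cost > 0 ",
                          "and QALYs in (0.1, 0.5))"),
                   bc$delta_cost, bc$delta_qaly), call. = FALSE)
  }
  attr(ps, "manifest") <- fixture_manifest(
    list(generator = "make_reference_parameter_set",
         life_table = list(a = 3.835e-5, b = 0.09, max_age = 100),
         calibration_checked = check_calibration))
  ps
}

#' Reference synthetic evidence base
#'
#' The meta-analytic datasets and cohort counts the pipeline's synthesis
#' runs on when no real study data are supplied: six two-arm studies per
#' outcome (~2000 participants in total) with between-study heterogeneity
#' on the log-RR scale, plus one single-arm cohort of n = 82. The true
#' remission effect is moderate (RR 1.3) and the true relapse effect
#' protective (RR 0.7); the cohort's outcome rates imply stronger effects
#' than the aggregate, so downweighting it visibly moves the pooled
#' estimate.
#'
#' @param seed Integer seed for all generators.
#' @return List with `remission` and `relapse` (each a
#'   [generate_meta_dataset()] data.frame), `cohort`
#'   (a [generate_cohort()] list), and a `manifest` attribute.
#' @export
generate_reference_evidence <- function(seed = 20180101L) {
  spec_rem <- list(k = 6L, mu_log_rr = log(1.3), tau = 0.15,
                   n_range = c(120L, 220L), control_risk_range = c(0.30, 0.50),
                   seed = seed)
  spec_rel <- list(k = 6L, mu_log_rr = log(0.7), tau = 0.20,
                   n_range = c(120L, 220L), control_risk_range = c(0.25, 0.45),
                   seed = seed + 1L)
  cohort_spec <- list(n = 82L, remission_prob = 0.55, relapse_prob = 0.15,
                      seed = seed + 2L)
  out <- list(remission = do.call(generate_meta_dataset, spec_rem),
              relapse = do.call(generate_meta_dataset, spec_rel),
              cohort = do.call(generate_cohort, cohort_spec))
  attr(out, "manifest") <- fixture_manifest(
    list(generator = "generate_reference_evidence", remission = spec_rem,
         relapse = spec_rel, cohort = cohort_spec))
  out
}

#' Build a fixture manifest
#'
#' A manifest records every generator parameter (and, for written files,
#' their MD5 checksums) so that a fixture can be regenerated bit-for-bit
#' and stale copies detected.
#'
#' @param params Named list of generator parameters.
#' @param files Optional named character vector of file paths to checksum.
#' @return List of class `fixture_manifest` with `version`, `params`, and
#'   `md5` (named checksums, if files given).
#' @export
fixture_manifest <- function(params, files = NULL) {
  m <- list(version = as.character(utils::packageVersion("eipcea")),
            params = params)
  if (!is.null(files)) m$md5 <- vapply(files, function(f)
    unname(tools::md5sum(f)), character(1))
  structure(m, class = "fixture_manifest")
}

#' Write the reference fixture to disk
#'
#' Writes the reference config YAML, life-table CSV, per-outcome study CSVs
#' and a `manifest.json` (with generator parameters and MD5 checksums of
#' every written file) into a directory.
#'
#' @param dir Destination directory (created if needed).
#' @param seed Seed forwarded to [generate_reference_evidence()].
#' @return The manifest, invisibly.
#' @export
write_reference_fixture <- function(dir, seed = 20180101L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- make_reference_parameter_set()
  ev <- generate_reference_evidence(seed)
  paths <- c(config = file.path(dir, "config.yaml"),
             life_table = file.path(dir, "life_table.csv"),
             studies_remission = file.path(dir, "studies_remission.csv"),
             studies_relapse = file.path(dir, "studies_relapse.csv"))
  write_parameter_set(ps, paths[["config"]], paths[["life_table"]])
  write_study_data(ev$remission, paths[["studies_remission"]],
                   cohort = ev$cohort$remission)
  write_study_data(ev$relapse, paths[["studies_relapse"]],
                   cohort = ev$cohort$relapse)
  manifest <- fixture_manifest(
    list(generator = "write_reference_fixture", seed = seed), files = paths)
  jsonlite::write_json(unclass(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
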