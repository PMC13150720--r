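#' Economic evaluation settings
#'
#' Settings shared by every stage of the evaluation: discount rate, cycle
#' structure, horizon, willingness-to-pay (WTP) grid and currency reporting.
#'
#' @param discount_rate_annual Annual discount rate, fraction in `[0, 1)`.
#'   Applied identically to costs and QALYs.
#' @param cycle_length_years Cycle length in years (default 0.25, i.e.
#'   3-month cycles).
#' @param horizon_years Time horizon in years; must be an integer multiple of
#'   the cycle length.
#' @param wtp_grid Non-negative, sorted vector of WTP thresholds
#'   (currency per QALY) at which acceptability is evaluated.
#' @param currency_label Currency of all costs (default `"CLP"`,
#'   2018 Chilean pesos).
#' @param ppp_clp_per_usd Purchasing-power-parity conversion factor used only
#'   for reporting costs in USD.
#' @param half_cycle_correction Logical; if `TRUE`, outcomes use a
#'   trapezoidal within-cycle correction (average of start- and end-of-cycle
#'   occupancy). Default `FALSE`.
#' @return A list of class `economic_settings`.
#' @export
economic_settings <- function(discount_rate_annual = 0.03,
                              cycle_length_years = 0.25,
                              horizon_years = 10,
                              wtp_grid = seq(0, 2e7, by = 5e5),
                              currency_label = "CLP",
                              ppp_clp_per_usd = 403.87,
                              half_cycle_correction = FALSE) {
  if (discount_rate_annual < 0 || discount_rate_annual >= 1)
    stop("discount_rate_annual must be in [0, 1)", call. = FALSE)
  if (cycle_length_years <= 0) stop("cycle_length_years must be > 0", call. = FALSE)
  n_cycles <- horizon_years / cycle_length_years
  if (horizon_years <= 0 || abs(n_cycles - round(n_cycles)) > 1e-9)
    stop("horizon_years must be a positive integer multiple of cycle_length_years",
         call. = FALSE)
  if (is.unsorted(wtp_grid) || any(wtp_grid < 0))
    stop("wtp_grid must be non-negative and sorted", call. = FALSE)
  structure(list(discount_rate_annual = discount_rate_annual,
                 cycle_length_years = cycle_length_years,
                 horizon_years = horizon_years,
                 wtp_grid = wtp_grid,
                 currency_label = currency_label,
                 ppp_clp_per_usd = ppp_clp_per_usd,
                 half_cycle_correction = isTRUE(half_cycle_correction)),
            class = "economic_settings")
}

#' Assemble and validate the full model parameterization
#'
#' A `parameter_set` is the single source of truth consumed by every stage:
#' transition structure and baseline transition uncertainty, health-state
#' utility values (HSUVs), per-cycle state and program costs, state-specific
#' mortality hazard ratios, treatment-effect risk-ratio specs and their
#' target transitions, economic settings, the life table, and the cohort's
#' starting age and state distribution.
#'
#' Transition uncertainty is expressed per strategy as one Dirichlet
#' [dist_spec()] per originating alive state over its allowed non-dead
#' destinations (i.e. destination shares conditional on surviving the
#' cycle); mortality is layered on top from the life table and hazard
#' ratios. Both strategies share the natural-history baseline unless the
#' config overrides one of them; the strategies differ through the
#' treatment-effect risk ratios and the program cost.
#'
#' @param transitions Named list with elements `cmht` and `eip`; each is a
#'   named list (by from-state) of Dirichlet specs whose parameter names are
#'   the allowed non-dead destinations.
#' @param hsuv Named list (alive states) of specs with support in `[0, 1]`.
#' @param state_cost Named list (alive states) of non-negative cost specs,
#'   per cycle.
#' @param program_cost Named list with elements `eip` and `cmht`: per-cycle
#'   program cost specs.
#' @param hazard_ratio Named list (alive states) of positive specs
#'   multiplying the age-specific mortality rate.
#' @param rr Named list with elements `remission` and `relapse`: risk-ratio
#'   specs used when posterior draws are not supplied directly.
#' @param effect_targets Named list with elements `remission` and `relapse`,
#'   each `list(from = , to = )` naming the transition the risk ratio acts on.
#' @param settings An [economic_settings()].
#' @param life_table A [life_table()].
#' @param start_age Cohort age in years at model entry.
#' @param start_state_distribution Named numeric over the six states, summing
#'   to 1.
#' @param adjacency 6 x 6 logical mask of allowed transitions
#'   (default [default_adjacency()]).
#' @param effect_duration_years `NULL` (risk ratios act over the whole
#'   horizon) or a positive number of years after which they revert to 1.
#' @return A validated list of class `parameter_set`.
#' @export
parameter_set <- function(transitions, hsuv, state_cost, program_cost,
                          hazard_ratio, rr, effect_targets,
                          settings, life_table, start_age = 20,
                          start_state_distribution = c(ACUTE = 1, REMISSION = 0,
                                                       RELAPSE = 0, RESISTANT = 0,
                                                       PNS = 0, DEAD = 0),
                          adjacency = default_adjacency(),
                          effect_duration_years = NULL) {
  ps <- structure(list(transitions = transitions, hsuv = hsuv,
                       state_cost = state_cost, program_cost = program_cost,
                       hazard_ratio = hazard_ratio, rr = rr,
                       effect_targets = effect_targets, settings = settings,
                       life_table = life_table, start_age = start_age,
                       start_state_distribution = start_state_distribution,
                       adjacency = adjacency,
                       effect_duration_years = effect_duration_years),
                  class = "parameter_set")
  validate_parameter_set(ps)
}

#' Validate a parameter set
#'
#' Checks every structural invariant and returns the object invisibly
#' unchanged; any violation raises an error naming the offending key.
#'
#' @param ps A [parameter_set()].
#' @return `ps`, invisibly on success.
#' @export
validate_parameter_set <- function(ps) {
  if (!inherits(ps, "parameter_set")) stop("not a parameter_set", call. = FALSE)
  s <- health_states(); al <- alive_states()

  adj <- ps$adjacency
  if (!is.matrix(adj) || !identical(dim(adj), c(6L, 6L)) ||
      !identical(rownames(adj), s) || !identical(colnames(adj), s))
    stop("adjacency must be a 6x6 logical matrix indexed by the health states",
         call. = FALSE)
  if (!isTRUE(adj["DEAD", "DEAD"]) || any(adj["DEAD", al]))
    stop("adjacency: DEAD must be absorbing", call. = FALSE)
  if (!all(adj[al, "DEAD"]))
    stop("adjacency: death must be reachable from every alive state", call. = FALSE)

  if (!inherits(ps$settings, "economic_settings"))
    stop("settings must be an economic_settings object", call. = FALSE)
  if (!inherits(ps$life_table, "life_table"))
    stop("life_table must be a life_table object", call. = FALSE)
  if (!is.numeric(ps$start_age) || ps$start_age < 0)
    stop("start_age must be a non-negative number", call. = FALSE)

  sd0 <- check_state_vector(ps$start_state_distribution,
                            "start_state_distribution")
  if (any(sd0 < 0) || abs(sum(sd0) - 1) > 1e-9)
    stop("start_state_distribution must be non-negative and sum to 1",
         call. = FALSE)

  if (!is.list(ps$transitions) || !setequal(names(ps$transitions), c("cmht", "eip")))
    stop("transitions must have elements 'cmht' and 'eip'", call. = FALSE)
  for (strat in c("cmht", "eip")) {
    tr <- ps$transitions[[strat]]
    if (!setequal(names(tr), al))
      stop("transitions$", strat, " must have one spec per alive state",
           call. = FALSE)
    for (from in al) {
      spec <- tr[[from]]
      allowed <- s[adj[from, ] & s != "DEAD"]
      if (is_dist_spec(spec) && spec$kind == "dirichlet") {
        if (!setequal(names(spec$parameters), allowed))
          stop("transitions$", strat, "$", from,
               ": dirichlet destinations must be exactly {",
               paste(allowed, collapse = ", "), "}", call. = FALSE)
      } else if (is.numeric(spec) && !is_dist_spec(spec)) {
        # a bare named vector fixes the row (no sampling uncertainty)
        if (!setequal(names(spec), allowed) || any(spec < 0) ||
            abs(sum(spec) - 1) > 1e-9)
          stop("transitions$", strat, "$", from,
               ": fixed row must be non-negative shares over {",
               paste(allowed, collapse = ", "), "} summing to 1",
               call. = FALSE)
      } else {
        stop("transitions$", strat, "$", from,
             " must be a dirichlet spec or a fixed named share vector",
             call. = FALSE)
      }
    }
  }

  check_spec_block <- function(block, nm, lo = -Inf, hi = Inf) {
    if (!setequal(names(block), al))
      stop(nm, " must have one spec per alive state", call. = FALSE)
    for (st in al) {
      spec <- block[[st]]
      if (!is_dist_spec(spec)) stop(nm, "$", st, " is not a dist_spec", call. = FALSE)
      m <- spec_mean(spec)
      if (m < lo || m > hi)
        stop(nm, "$", st, ": point value ", signif(m, 6),
             " outside [", lo, ", ", hi, "]", call. = FALSE)
    }
  }
  check_spec_block(ps$hsuv, "hsuv", 0, 1)
  check_spec_block(ps$state_cost, "state_cost", 0, Inf)
  check_spec_block(ps$hazard_ratio, "hazard_ratio", 1e-12, Inf)

  if (!setequal(names(ps$program_cost), c("eip", "cmht")))
    stop("program_cost must have elements 'eip' and 'cmht'", call. = FALSE)
  for (strat in c("eip", "cmht")) {
    spec <- ps$program_cost[[strat]]
    if (!is_dist_spec(spec) || spec_mean(spec) < 0)
      stop("program_cost$", strat, " must be a non-negative spec", call. = FALSE)
  }

  if (!setequal(names(ps$rr), c("remission", "relapse")))
    stop("rr must have elements 'remission' and 'relapse'", call. = FALSE)
  for (oc in c("remission", "relapse")) {
    if (!is_dist_spec(ps$rr[[oc]]) || spec_mean(ps$rr[[oc]]) <= 0)
      stop("rr$", oc, " must be a positive spec", call. = FALSE)
    tgt <- ps$effect_targets[[oc]]
    if (is.null(tgt) || !all(c("from", "to") %in% names(tgt)))
      stop("effect_targets$", oc, " must be list(from=, to=)", call. = FALSE)
    if (!isTRUE(adj[tgt$from, tgt$to]))
      stop("effect_targets$", oc, ": transition ", tgt$from, " -> ", tgt$to,
           " is not in the adjacency mask", call. = FALSE)
  }

  if (!is.null(ps$effect_duration_years) &&
      (!is.numeric(ps$effect_duration_years) || ps$effect_duration_years <= 0))
    stop("effect_duration_years must be NULL or a positive number", call. = FALSE)

  invisible(ps)
}

#' @export
print.parameter_set <- function(x, ...) {
  st <- x$settings
  cat("Parameter set: six-state FEP cohort model\n")
  cat(sprintf("  horizon %g y, cycles of %g y, discount %.1f%%/y, start age %g\n",
              st$horizon_years, st$cycle_length_years,
              100 * st$discount_rate_annual, x$start_age))
  cat(sprintf("  currency %s (PPP %.2f per USD); WTP grid: %d points in [%g, %g]\n",
              st$currency_label, st$ppp_clp_per_usd, length(st$wtp_grid),
              min(st$wtp_grid), max(st$wtp_grid)))
  cat(sprintf("  base-case RR remission %.3f, RR relapse %.3f\n",
              spec_mean(x$rr$remission), spec_mean(x$rr$relapse)))
  invisible(x)
}

# ---- YAML config I/O --------------------------------------------------------

spec_to_list <- function(spec) {
  p <- as.list(spec$parameters)
  if (is.null(names(spec$parameters))) p <- unname(p)
  list(kind = spec$kind, parameters = p)
}

spec_from_list <- function(x, key) {
  if (is.list(x) && !("kind" %in% names(x)) &&
      all(vapply(x, is.numeric, logical(1)))) {
    return(unlist(x))  # fixed transition row written as a named map
  }
  if (!is.list(x) || !setequal(names(x), c("kind", "parameters")))
    stop("config key '", key, "': a distribution spec needs fields ",
         "'kind' and 'parameters'", call. = FALSE)
  p <- unlist(x$parameters)
  dist_spec(x$kind, p)
}

adjacency_to_list <- function(adj) {
  s <- rownames(adj)
  stats::setNames(lapply(s, function(from) as.list(s[adj[from, ]])), s)
}

adjacency_from_list <- function(x) {
  s <- health_states()
  if (!setequal(names(x), s))
    stop("config key 'adjacency': must list all six states", call. = FALSE)
  adj <- matrix(FALSE, 6L, 6L, dimnames = list(s, s))
  for (from in s) {
    to <- unlist(x[[from]])
    if (!all(to %in% s))
      stop("config key 'adjacency$", from, "': unknown state(s) ",
           paste(setdiff(to, s), collapse = ", "), call. = FALSE)
    adj[from, to] <- TRUE
  }
  adj
}

reject_unknown_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop("config ", where, ": unknown key(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
}

#' Write a parameter set to a YAML config (and life-table CSV)
#'
#' @param ps A [parameter_set()].
#' @param config_path Destination YAML path.
#' @param life_table_path Optional destination for the life-table CSV; if
#'   `NULL` the life table is not written.
#' @return `config_path`, invisibly.
#' @export
write_parameter_set <- function(ps, config_path, life_table_path = NULL) {
  validate_parameter_set(ps)
  block <- function(b) lapply(b, function(sp)
    if (is_dist_spec(sp)) spec_to_list(sp) else as.list(sp))
  cfg <- list(
    settings = unclass(ps$settings),
    start_age = ps$start_age,
    start_state_distribution = as.list(ps$start_state_distribution),
    adjacency = adjacency_to_list(ps$adjacency),
    transitions = lapply(ps$transitions, block),
    hsuv = block(ps$hsuv),
    state_cost = block(ps$state_cost),
    program_cost = block(ps$program_cost),
    hazard_ratio = block(ps$hazard_ratio),
    rr = block(ps$rr),
    effect_targets = ps$effect_targets,
    effect_duration_years = ps$effect_duration_years
  )
  yaml::write_yaml(cfg, config_path, precision = 15L)
  if (!is.null(life_table_path)) write_life_table(ps$life_table, life_table_path)
  invisible(config_path)
}

#' Load a parameter set from a YAML config and a life-table CSV
#'
#' The config schema mirrors the [parameter_set()] constructor; unknown keys
#' anywhere in the file are rejected with an error naming them, and every
#' structural invariant is re-validated after loading.
#'
#' @param config_path Path to the YAML model config.
#' @param life_table_path Path to the life-table CSV
#'   (`age,annual_mortality_rate`).
#' @return A validated [parameter_set()].
#' @export
load_parameter_set <- function(config_path, life_table_path) {
  if (!file.exists(config_path)) stop("config not found: ", config_path, call. = FALSE)
  cfg <- yaml::read_yaml(config_path)
  top <- c("settings", "start_age", "start_state_distribution", "adjacency",
           "transitions", "hsuv", "state_cost", "program_cost",
           "hazard_ratio", "rr", "effect_targets", "effect_duration_years")
  reject_unknown_keys(cfg, top, "top level")
  missing <- setdiff(setdiff(top, "effect_duration_years"), names(cfg))
  if (length(missing))
    stop("config is missing key(s): ", paste(missing, collapse = ", "),
         call. = FALSE)

  st <- cfg$settings
  reject_unknown_keys(st, names(formals(economic_settings)), "settings")
  settings <- do.call(economic_settings,
                      c(st[setdiff(names(st), "wtp_grid")],
                        list(wtp_grid = unlist(st$wtp_grid))))

  block <- function(b, nm) {
    stats::setNames(lapply(names(b), function(k)
      spec_from_list(b[[k]], paste0(nm, "$", k))), names(b))
  }
  parameter_set(
    transitions = stats::setNames(
      lapply(names(cfg$transitions), function(strat)
        block(cfg$transitions[[strat]], paste0("transitions$", strat))),
      names(cfg$transitions)),
    hsuv = block(cfg$hsuv, "hsuv"),
    state_cost = block(cfg$state_cost, "state_cost"),
    program_cost = block(cfg$program_cost, "program_cost"),
    hazard_ratio = block(cfg$hazard_ratio, "hazard_ratio"),
    rr = block(cfg$rr, "rr"),
    effect_targets = cfg$effect_targets,
    settings = settings,
    life_table = read_life_table(life_table_path),
    start_age = cfg$start_age,
    start_state_distribution = unlist(cfg$start_state_distribution),
    adjacency = adjacency_from_list(cfg$adjacency),
    effect_duration_years = cfg$effect_duration_years
  )
}

#' Read study-level evidence from CSV
#'
#' The CSV schema is long format with header `study_id,arm,events,n`, where
#' `arm` is `eip`, `control`, or `cohort` (single-arm observational rows).
#' Two-arm studies must have exactly one `eip` and one `control` row.
#'
#' @param path CSV path.
#' @param cohort_outcome Label attached to cohort rows (`"remission"` or
#'   `"relapse"`); purely descriptive.
#' @return A list with `studies` (data.frame: `study_id`,
#'   `events_treatment`, `n_treatment`, `events_control`, `n_control`) and
#'   `cohort` (`NULL`, or list with `events`, `n`, `outcome`).
#' @export
read_study_data <- function(path, cohort_outcome = "remission") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study_id", "arm", "events", "n")
  if (!identical(names(df), need))
    stop("study CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!all(df$arm %in% c("eip", "control", "cohort")))
    stop("study CSV: arm must be one of eip, control, cohort", call. = FALSE)
  if (any(df$events < 0 | df$events > df$n | df$n <= 0))
    stop("study CSV: need 0 <= events <= n and n > 0", call. = FALSE)
  coh <- df[df$arm == "cohort", , drop = FALSE]
  two <- df[df$arm != "cohort", , drop = FALSE]
  ids <- unique(two$study_id)
  studies <- do.call(rbind, lapply(ids, function(id) {
    tt <- two[two$study_id == id & two$arm == "eip", ]
    cc <- two[two$study_id == id & two$arm == "control", ]
    if (nrow(tt) != 1L || nrow(cc) != 1L)
      stop("study ", id, " must have exactly one eip and one control row",
           call. = FALSE)
    data.frame(study_id = id, events_treatment = tt$events, n_treatment = tt$n,
               events_control = cc$events, n_control = cc$n)
  }))
  cohort <- NULL
  if (nrow(coh) > 0) {
    if (nrow(coh) > 1L) stop("at most one cohort row is supported", call. = FALSE)
    cohort <- list(events = coh$events, n = coh$n, outcome = cohort_outcome)
  }
  list(studies = studies, cohort = cohort)
}

#' Write study-level evidence to CSV
#'
#' @param studies Data frame as returned in `read_study_data()$studies`.
#' @param path CSV destination.
#' @param cohort Optional list with `events` and `n` for a single-arm
#'   cohort row.
#' @return `path`, invisibly.
#' @export
write_study_data <- function(studies, path, cohort = NULL) {
  long <- do.call(rbind, lapply(seq_len(nrow(studies)), function(i) {
    s <- studies[i, ]
    data.frame(study_id = s$study_id, arm = c("eip", "control"),
               events = c(s$events_treatment, s$events_control),
               n = c(s$n_treatment, s$n_control))
  }))
  if (!is.null(cohort)) {
    long <- rbind(long, data.frame(study_id = "cohort", arm = "cohort",
                                   events = cohort$events, n = cohort$n))
  }
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
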