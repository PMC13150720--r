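test_that("treatment effect scales the target and renormalizes the rest", {
  row <- c(REMISSION = 0.4, ACUTE = 0.6)
  expect_equal(apply_treatment_effect(row, 1, "REMISSION"), row,
               ignore_attr = TRUE)
  out <- apply_treatment_effect(row, 1.25, "REMISSION")
  expect_equal(unname(out[c("REMISSION", "ACUTE")]), c(0.5, 0.5),
               ignore_attr = TRUE)
  # rr = 0 removes the transition and returns its mass proportionally
  row3 <- c(RELAPSE = 0.2, REMISSION = 0.3, PNS = 0.5)
  out0 <- apply_treatment_effect(row3, 0, "RELAPSE")
  expect_equal(unname(out0["RELAPSE"]), 0)
  expect_equal(unname(out0["REMISSION"]) / unname(out0["PNS"]), 0.3 / 0.5)
  expect_equal(sum(out0), 1)
  # capping: rr * p > 1
  capped <- apply_treatment_effect(c(A = 0.8, B = 0.2), 2, "A")
  expect_true(attr(capped, "capped"))
  expect_equal(unname(capped["A"]), 1)
  expect_equal(sum(capped), 1)
})

test_that("transition matrices are row-stochastic with DEAD absorbing", {
  ps <- ref_ps()
  for (cy in c(0L, 17L, 39L)) {
    m <- build_transition_matrix(ps, "eip", cy)
    expect_true(all(abs(rowSums(m) - 1) < 1e-12))
    expect_true(all(m >= 0 & m <= 1))
    expect_equal(unname(m["DEAD", ]), c(0, 0, 0, 0, 0, 1))
    # mask respected: disallowed destinations stay zero
    expect_true(all(m[!ps$adjacency] == 0))
  }
})

test_that("an immortal life table gives a zero death column", {
  ps <- fixed_ps()
  m <- build_transition_matrix(ps, "cmht", 0L)
  al <- setdiff(health_states(), "DEAD")
  expect_equal(unname(m[al, "DEAD"]), rep(0, 5))
})

test_that("the matrix equals an independently hand-assembled one", {
  ps <- ref_ps()
  rec <- resolve_parameters(ps)
  m <- build_transition_matrix(ps, "cmht", 0L, rec)
  # independent assembly: death first from the life table, then survivors
  # split by the baseline Dirichlet-mean shares
  rate <- ps$life_table$annual_mortality_rate[ps$life_table$age == 20]
  for (from in c("ACUTE", "REMISSION", "RESISTANT")) {
    hr <- spec_mean(ps$hazard_ratio[[from]])
    pd <- 1 - exp(-rate * hr * 0.25)
    alpha <- ps$transitions$cmht[[from]]$parameters
    shares <- alpha / sum(alpha)
    expect_equal(m[from, "DEAD"], pd, tolerance = 1e-14)
    expect_equal(m[from, names(shares)], (1 - pd) * shares,
                 tolerance = 1e-14, ignore_attr = TRUE)
  }
  # EIP at cycle 0 applies the remission RR to ACUTE -> REMISSION
  me <- build_transition_matrix(ps, "eip", 0L, rec)
  hrA <- spec_mean(ps$hazard_ratio$ACUTE)
  pdA <- 1 - exp(-rate * hrA * 0.25)
  sh <- ps$transitions$cmht$ACUTE$parameters
  sh <- sh / sum(sh)
  p_rem <- min(rec$rr_remission * sh[["REMISSION"]], 1)
  expect_equal(me["ACUTE", "REMISSION"], (1 - pdA) * p_rem, tolerance = 1e-12)
})

test_that("the cohort trace conserves mass and absorbs into death", {
  ps <- ref_ps()
  tr <- run_cohort(ps, "eip")
  expect_equal(dim(tr), c(41L, 6L))  # 40 quarterly transitions + start row
  expect_true(all(abs(rowSums(tr) - 1) < 1e-10))
  expect_true(all(unclass(tr) >= 0))
  expect_true(all(diff(tr[, "DEAD"]) >= 0))
  # person-time cannot exceed the horizon
  out <- accumulate_outcomes(tr, ps, "eip")
  expect_lte(out$life_years, 10 + 1e-9)
  expect_lte(out$qaly_disc, out$qaly_undisc)
  expect_lte(out$cost_disc, out$cost_undisc)
})

test_that("identity dynamics leave the cohort where it starts", {
  ps <- fixed_ps()
  rec <- resolve_parameters(ps)
  for (from in names(rec$trans$cmht)) {
    row <- rec$trans$cmht[[from]]
    row[] <- 0
    row[from] <- 1
    rec$trans$cmht[[from]] <- row
  }
  tr <- run_cohort(ps, "cmht", rec)
  expect_true(all(tr[, "ACUTE"] == 1))
  expect_true(all(tr[, colnames(tr) != "ACUTE"] == 0))
})

test_that("full health, no mortality and no discounting give exactly 10 QALYs", {
  ps <- fixed_ps(discount_rate = 0,
                 hsuv = c(ACUTE = 1, REMISSION = 1, RELAPSE = 1,
                          RESISTANT = 1, PNS = 1))
  tr <- run_cohort(ps, "cmht")
  out <- accumulate_outcomes(tr, ps, "cmht")
  expect_equal(out$qaly_disc, 10, tolerance = 1e-12)
  expect_equal(out$qaly_undisc, 10, tolerance = 1e-12)
  # and zero payoffs accumulate to zero
  ps0 <- fixed_ps(cost = c(ACUTE = 0, REMISSION = 0, RELAPSE = 0,
                           RESISTANT = 0, PNS = 0), program = c(eip = 0, cmht = 0))
  expect_identical(accumulate_outcomes(run_cohort(ps0, "cmht"), ps0,
                                       "cmht")$cost_disc, 0)
})

test_that("a two-cycle model matches a hand-computed ledger", {
  ps <- fixed_ps(horizon_years = 0.5)
  tr <- run_cohort(ps, "cmht")
  out <- accumulate_outcomes(tr, ps, "cmht")
  # cycle 0: everyone ACUTE; cycle 1: 50/50 ACUTE/REMISSION (no deaths)
  df1 <- 1.03^-0.25
  qaly_hand <- 1 * 0.5 * 0.25 +
    (0.5 * 0.5 + 0.5 * 0.8) * 0.25 * df1
  cost_hand <- (100 + 3) +
    (0.5 * 100 + 0.5 * 10 + 3) * df1
  expect_equal(out$qaly_disc, qaly_hand, tolerance = 1e-12)
  expect_equal(out$cost_disc, cost_hand, tolerance = 1e-12)
})

test_that("payoff and discount monotonicity hold on the fixture", {
  ps <- ref_ps()
  rec <- resolve_parameters(ps)
  base <- accumulate_outcomes(run_cohort(ps, "cmht", rec), ps, "cmht", rec)
  rec_up <- rec
  rec_up$hsuv["REMISSION"] <- rec$hsuv[["REMISSION"]] + 0.05
  up <- accumulate_outcomes(run_cohort(ps, "cmht", rec_up), ps, "cmht", rec_up)
  expect_gt(up$qaly_disc, base$qaly_disc)
  ps_r <- ref_ps()
  ps_r$settings$discount_rate_annual <- 0.06
  hi_r <- accumulate_outcomes(run_cohort(ps_r, "cmht", rec), ps_r, "cmht", rec)
  expect_lt(hi_r$qaly_disc, base$qaly_disc)
  expect_lt(hi_r$cost_disc, base$cost_disc)
})

test_that("beneficial risk ratios give EIP at least CMHT's QALYs", {
  ps <- ref_ps()  # RR_remission > 1, RR_relapse < 1, shared payoffs
  rec <- resolve_parameters(ps)
  eip <- accumulate_outcomes(run_cohort(ps, "eip", rec), ps, "eip", rec)
  cmht <- accumulate_outcomes(run_cohort(ps, "cmht", rec), ps, "cmht", rec)
  expect_gte(eip$qaly_disc, cmht$qaly_disc)
})

test_that("treatment effects can be limited to the first years", {
  ps <- ref_ps()
  ps$effect_duration_years <- 2
  m_early <- build_transition_matrix(ps, "eip", 0L)
  m_late <- build_transition_matrix(ps, "eip", 8L)   # t = 2 y: effect off
  m_cmht <- build_transition_matrix(ps, "cmht", 8L)
  expect_false(isTRUE(all.equal(m_early["ACUTE", "REMISSION"],
                                m_cmht["ACUTE", "REMISSION"])))
  expect_equal(m_late, m_cmht, ignore_attr = TRUE)
})
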