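test_that("with every spec fixed the PSA collapses to the base case", {
  ps <- fixed_ps(lt = generate_life_table())  # real mortality, fixed params
  psa <- run_psa(ps, n = 3, master_seed = 42)
  bc <- base_case(ps)
  d <- psa$outcomes
  expect_equal(var(d$cost_eip), 0)
  expect_equal(var(d$qaly_cmht), 0)
  expect_identical(d$cost_eip[1] - d$cost_cmht[1], bc$delta_cost)
  expect_identical(d$qaly_eip[1] - d$qaly_cmht[1], bc$delta_qaly)
})

test_that("the PSA is bit-reproducible under its master seed", {
  ps <- ref_ps()
  p1 <- run_psa(ps, n = 20, master_seed = 123)
  p2 <- run_psa(ps, n = 20, master_seed = 123)
  expect_identical(p1$outcomes, p2$outcomes)
  expect_identical(p1$params, p2$params)
  p3 <- run_psa(ps, n = 20, master_seed = 124)
  expect_false(identical(p1$outcomes, p3$outcomes))
})

test_that("sampled records respect supports and the common-draw contract", {
  ps <- ref_ps()
  set.seed(9)
  for (i in 1:25) {
    rec <- sample_parameters(ps)
    expect_true(all(rec$hsuv >= 0 & rec$hsuv <= 1))
    expect_true(all(rec$state_cost >= 0))
    expect_true(all(rec$hazard_ratio > 0))
    for (from in names(rec$trans$cmht)) {
      expect_equal(sum(rec$trans$cmht[[from]]), 1, tolerance = 1e-12)
      # both strategies share the same natural-history draw
      expect_identical(rec$trans$cmht[[from]], rec$trans$eip[[from]])
    }
  }
  # the flat record keeps every sampled scalar for EVPPI
  fl <- attr(sample_parameters(ps), "flat")
  expect_true(all(c("rr_remission", "rr_relapse", "hsuv.REMISSION",
                    "cost.RELAPSE", "program_cost.eip") %in% names(fl)))
})

test_that("supplied posterior draws are paired into iterations by index", {
  ps <- ref_ps()
  rem <- c(1.1, 1.2, 1.3)
  rel <- c(0.5, 0.6, 0.7)
  psa <- run_psa(ps, rem, rel, n = 3, master_seed = 5)
  expect_equal(unname(psa$params[, "rr_remission"]), rem)
  expect_equal(unname(psa$params[, "rr_relapse"]), rel)
  expect_error(run_psa(ps, rem, rel, n = 5), "length n")
})

test_that("PSA means agree with the deterministic run for near-linear payoffs", {
  ps <- ref_ps()
  psa <- run_psa(ps, n = 600, master_seed = 31)
  bc <- base_case(ps)
  d <- psa$outcomes
  de <- d$qaly_eip - d$qaly_cmht
  dc <- d$cost_eip - d$cost_cmht
  expect_lt(abs(mean(de) - bc$delta_qaly), 4 * sd(de) / sqrt(length(de)))
  expect_lt(abs(mean(dc) - bc$delta_cost), 4 * sd(dc) / sqrt(length(dc)))
})

test_that("one-way sweeps reproduce the base case at zero width and sort by leverage", {
  ps <- ref_ps()
  bc <- base_case(ps)
  rec <- resolve_parameters(ps)
  tor <- one_way_sa(ps, list(
    list(name = "hsuv.REMISSION", low = rec$hsuv[["REMISSION"]],
         high = rec$hsuv[["REMISSION"]]),
    list(name = "program_cost.eip", low = 180000, high = 290000)),
    lambda_ref = 6430822)
  zero <- tor[tor$parameter == "hsuv.REMISSION", ]
  expect_equal(zero$icer_low, bc$icer, tolerance = 1e-9)
  expect_equal(zero$icer_high, bc$icer, tolerance = 1e-9)
  expect_equal(zero$nb_range, 0, tolerance = 1e-6)
  expect_true(all(diff(tor$nb_range) <= 0))
})

test_that("one-way sweeps move the ICER in the expected direction", {
  ps <- ref_ps()
  rec <- resolve_parameters(ps)
  h <- rec$hsuv[["REMISSION"]]
  tor <- one_way_sa(ps, list(
    list(name = "hsuv.REMISSION", low = h - 0.05, high = h + 0.05)))
  # a higher remission utility raises the incremental benefit, lowering the ICER
  expect_gt(tor$icer_low, tor$icer_high)
  # sweeping the EIP program cost moves costs only
  tor2 <- one_way_sa(ps, list(
    list(name = "program_cost.eip", low = 200000, high = 280000)))
  expect_gt(tor2$icer_high, tor2$icer_low)
  expect_error(one_way_sa(ps, list(list(name = "hsuv.REMISSION",
                                        low = -0.1, high = 0.5))),
               "\\[0, 1\\]")
})

test_that("scenario horizons nest: identity at 10 y, more accumulation at 20 y", {
  ps <- ref_ps()
  sc <- run_scenarios(ps, list(
    list(name = "base", horizon_years = 10),
    list(name = "h20", horizon_years = 20),
    list(name = "lifetime", horizon_years = "lifetime")))
  bc <- base_case(ps)
  expect_equal(sc$icer[sc$scenario == "base"], bc$icer, tolerance = 1e-9)
  expect_equal(sc$horizon_years[sc$scenario == "lifetime"], 60)
  # undiscounted QALYs grow with the horizon for both strategies
  for (strat in c("eip", "cmht")) {
    q10 <- run_strategy(ps, strat, horizon_years = 10)$qaly_undisc
    q20 <- run_strategy(ps, strat, horizon_years = 20)$qaly_undisc
    expect_gte(q20, q10)
  }
})
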