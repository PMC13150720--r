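test_that("the ICER is the ratio of unrounded increments", {
  eip <- make_outcome(24000000 + 1327054, 5.70 + 0.24)
  cmht <- make_outcome(24000000, 5.70, strategy = "cmht")
  inc <- incremental_analysis(eip, cmht)
  expect_equal(inc$delta_cost, 1327054, tolerance = 1e-9)
  expect_equal(inc$delta_qaly, 0.24, tolerance = 1e-9)
  expect_equal(inc$icer, 1327054 / 0.24, tolerance = 1e-9)
  expect_equal(inc$dominance, "trade_off_ne")
})

test_that("dominance suppresses the ICER", {
  dom <- incremental_analysis(make_outcome(-1, 0.1), make_outcome(0, 0, "cmht"))
  expect_equal(dom$dominance, "dominant")
  expect_true(is.na(dom$icer))
  domd <- incremental_analysis(make_outcome(5, -0.1), make_outcome(0, 0, "cmht"))
  expect_equal(domd$dominance, "dominated")
  expect_true(is.na(domd$icer))
  none <- incremental_analysis(make_outcome(10, 2), make_outcome(10, 2, "cmht"))
  expect_equal(none$dominance, "no_difference")
  expect_true(is.na(none$icer))
  expect_error(incremental_analysis(make_outcome(1, 1, horizon = 10),
                                    make_outcome(1, 1, "cmht", horizon = 20)),
               "mismatched horizons")
})

test_that("net benefit is linear in lambda and zero at the ICER", {
  expect_equal(net_benefit(0.24, 1327054, 0), -1327054)
  expect_equal(net_benefit(0.24, 1327054, 1327054 / 0.24), 0, tolerance = 1e-6)
  # at a threshold of one GDP per capita (in CLP) the printed increments
  # give a positive net benefit
  expect_equal(net_benefit(0.24, 1327054, 6430800), 216338, tolerance = 1e-9)
  lams <- c(0, 1e6, 2e6, 5e6)
  nb <- net_benefit(0.3, 1e6, lams)
  expect_equal(diff(nb) / diff(lams), rep(0.3, 3), tolerance = 1e-12)
})

test_that("the acceptability curve attains its analytic limits", {
  set.seed(2)
  n <- 4000
  dq <- rnorm(n, 0.2, 0.3)
  dc <- rnorm(n, 1e6, 2e6)
  psa <- make_psa(cost_eip = 2e7 + dc, qaly_eip = 5 + dq,
                  cost_cmht = rep(2e7, n), qaly_cmht = rep(5, n))
  cc <- ceac(psa, c(0, 1e6, 1e12))
  expect_true(all(cc$prob_eip >= 0 & cc$prob_eip <= 1))
  expect_equal(cc$prob_eip[1], mean(dc < 0))            # lambda = 0
  expect_equal(cc$prob_eip[3], mean(dq > 0))            # lambda -> infinity
  # degenerate point mass with higher EIP net benefit
  one <- make_psa(10, 2, 5, 1)
  expect_equal(ceac(one, 100)$prob_eip, 1)
  expect_error(ceac(psa, numeric(0)), "empty")
})

test_that("quadrant shares partition the plane", {
  n <- 1e5
  set.seed(3)
  dq <- rnorm(n); dc <- rnorm(n)
  psa <- make_psa(cost_eip = dc, qaly_eip = dq,
                  cost_cmht = rep(0, n), qaly_cmht = rep(0, n))
  q <- quadrant_shares(psa)
  expect_equal(sum(q), 1, tolerance = 1e-12)
  sigma <- sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(q - 0.25) < 3 * sigma))
  # all strictly north-east
  ne <- make_psa(cost_eip = c(2, 3), qaly_eip = c(1, 1),
                 cost_cmht = c(0, 0), qaly_cmht = c(0, 0))
  expect_equal(unname(quadrant_shares(ne)), c(1, 0, 0, 0))
  # boundary points split evenly
  tie <- make_psa(cost_eip = 1, qaly_eip = 0, cost_cmht = 1, qaly_cmht = 0)
  expect_equal(unname(quadrant_shares(tie)), rep(0.25, 4))
})

test_that("net-benefit and ICER-threshold decisions agree when gains are positive", {
  set.seed(4)
  for (i in 1:50) {
    dq <- runif(1, 0.01, 0.5)
    dc <- runif(1, -2e6, 5e6)
    lam <- runif(1, 0, 2e7)
    nb_rule <- net_benefit(dq, dc, lam) > 0
    icer_rule <- dc / dq < lam
    expect_identical(nb_rule, icer_rule)
  }
})
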