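test_that("EVPI matches exhaustive enumeration on a toy matrix", {
  # two equiprobable draws: E[max] = (10 + 4)/2 = 7, best single = 5
  nb <- cbind(A = c(10, 0), B = c(0, 4))
  expect_equal(evpi(nb), 2)
  # zero variance: knowing everything changes nothing
  expect_equal(evpi(cbind(A = c(3, 3), B = c(1, 1))), 0)
  # translation invariance
  expect_equal(evpi(nb + 1e6), evpi(nb))
  expect_error(evpi(cbind(A = 1:3)), "at least 2 strategies")
  expect_error(evpi(cbind(A = c(1, NA), B = c(0, 0))), "non-finite")
})

test_that("population EVPI follows the discounted geometric series", {
  expect_equal(population_evpi(100, 0, 10, 0.03), 0)
  expect_equal(population_evpi(100, 1000, 10, 0), 1e6)
  closed_form <- 1e5 * (1 - 1.03^-10) / (1 - 1.03^-1)
  got <- population_evpi(100, 1000, 10, 0.03)
  expect_equal(got, closed_form, tolerance = 1e-12)
  expect_equal(round(got), 878611)
  # linear in both the per-person value and the incidence
  expect_equal(population_evpi(200, 1000, 10, 0.03), 2 * got)
  expect_equal(population_evpi(100, 2000, 10, 0.03), 2 * got)
})

test_that("regression EVPPI recovers the closed form for linear net benefit", {
  # NB_eip = b * theta with theta ~ N(0, 1), NB_cmht = 0:
  # EVPI = EVPPI(theta) = b * E[max(Z, 0)] = b / sqrt(2*pi)
  set.seed(21)
  n <- 4000
  theta <- rnorm(n)
  b <- 1000
  psa <- make_psa(cost_eip = -b * theta, qaly_eip = rep(0, n),
                  cost_cmht = rep(0, n), qaly_cmht = rep(0, n),
                  params = cbind(theta = theta, dummy = rnorm(n)))
  ev_all <- evppi(psa, lambda = 1, group = "theta", seed = 2)
  analytic <- b * expected_pos_part_normal(0, 1)
  sample_oracle <- evpi(nb_matrix(psa, 1))
  expect_lt(abs(ev_all$estimate - sample_oracle) / sample_oracle, 0.05)
  expect_lt(abs(ev_all$estimate - analytic) / analytic, 0.10)
  # a parameter independent of net benefit carries no information value
  ev_dummy <- evppi(psa, lambda = 1, group = "dummy", seed = 2)
  expect_lt(ev_dummy$estimate, max(2 * ev_dummy$se, 0.02 * sample_oracle))
})

test_that("EVPPI of everything approaches EVPI and is bounded by it", {
  set.seed(22)
  n <- 3000
  th1 <- rnorm(n); th2 <- rnorm(n)
  nb_e <- 800 * th1 + 300 * th2
  psa <- make_psa(cost_eip = -nb_e, qaly_eip = rep(0, n),
                  cost_cmht = rep(0, n), qaly_cmht = rep(0, n),
                  params = cbind(th1 = th1, th2 = th2))
  total <- evpi(nb_matrix(psa, 1))
  ev_all <- evppi(psa, 1, c("th1", "th2"), seed = 3)
  expect_lt(abs(ev_all$estimate - total), 2 * ev_all$se + 0.02 * total)
  ev_one <- evppi(psa, 1, "th1", seed = 3)
  expect_lte(ev_one$estimate, total * 1.02)
  expect_gt(ev_one$estimate, 0)
  # zero-variance group warns and returns 0
  psa0 <- make_psa(cost_eip = -nb_e, qaly_eip = rep(0, n),
                   cost_cmht = rep(0, n), qaly_cmht = rep(0, n),
                   params = cbind(th1 = th1, const = rep(1, n)))
  expect_warning(z <- evppi(psa0, 1, "const"), "zero variance")
  expect_equal(z$estimate, 0)
})

test_that("the assembled VOI analysis is internally consistent", {
  set.seed(23)
  n <- 1500
  th <- rnorm(n)
  psa <- make_psa(cost_eip = 1e6 - 5e5 * th, qaly_eip = rep(0.2, n) + 0.1 * th,
                  cost_cmht = rep(0, n), qaly_cmht = rep(0, n),
                  params = cbind(th = th))
  v <- voi_analysis(psa, lambda = 6.4e6, annual_incident_cases = 3800,
                    years = 10, r = 0.03, groups = list(theta = "th"))
  e <- evpi(nb_matrix(psa, 6.4e6))
  expect_equal(v$evpi_per_person, e)
  expect_equal(v$population_evpi,
               population_evpi(e, 3800, 10, 0.03), tolerance = 1e-12)
  expect_equal(v$evppi$group, "theta")
  expect_lte(v$evppi$estimate, e * 1.05)
})
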