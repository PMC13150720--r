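sampler_fast <- list(n_chains = 2L, n_adapt = 300L, n_warmup = 400L,
                     n_iter = 600L, seed = 11L)

test_that("input validation catches malformed evidence", {
  ev <- ref_evidence()
  expect_error(fit_power_prior(ev$remission[1, ], NULL), "at least 2")
  bad <- ev$remission
  bad$events_treatment[1] <- bad$n_treatment[1] + 5
  expect_error(fit_power_prior(bad, NULL), "invalid study counts")
  expect_error(fit_power_prior(ev$remission, ev$cohort$remission, a0 = 1.4),
               "a0 must lie")
})

test_that("a large null-heterogeneity dataset recovers the true risk ratio", {
  # parameter-recovery oracle: two mega-studies at true RR 2, tau = 0;
  # large-sample consistency pins the posterior median near the truth
  mega <- generate_meta_dataset(k = 2L, mu_log_rr = log(2), tau = 0,
                                n_range = c(100000L, 100000L),
                                control_risk_range = c(0.199, 0.201),
                                seed = 5L)
  fit <- fit_power_prior(mega, cohort = NULL, a0 = 0, sampler = sampler_fast)
  expect_true(fit$converged)
  expect_lt(abs(fit$summary[["median"]] - 2) / 2, 0.02)
})

test_that("posterior draws resample reproducibly from the fit", {
  ev <- ref_evidence()
  fit <- fit_power_prior(ev$remission, ev$cohort$remission, a0 = 0.5,
                         sampler = sampler_fast)
  d1 <- posterior_rr_draws(fit, 500, seed = 3)
  d2 <- posterior_rr_draws(fit, 500, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1 > 0))
  expect_lt(abs(median(d1) - fit$summary[["median"]]), 0.05)
  n_stored <- nrow(fit$draws)
  expect_error(posterior_rr_draws(fit, n_stored + 1), "resample")
  big <- posterior_rr_draws(fit, n_stored + 100, seed = 1, resample = TRUE)
  expect_length(big, n_stored + 100)
})

test_that("downweighting interpolates between excluding and including the cohort", {
  # the synthetic cohort's relapse rate is well below the aggregate studies',
  # so the pooled RR must decrease monotonically as the cohort gains weight
  ev <- ref_evidence()
  curve <- weight_sensitivity_curve(ev$relapse, ev$cohort$relapse,
                                    a0_grid = c(0, 0.5, 1),
                                    sampler = list(n_chains = 2L,
                                                   n_adapt = 500L,
                                                   n_warmup = 800L,
                                                   n_iter = 1500L, seed = 11L),
                                    outcome = "relapse")
  expect_s3_class(curve, "power_prior_curve")
  expect_true(all(diff(curve$median) < 0))
  expect_true(curve$median[2] < curve$median[1] &&
                curve$median[2] > curve$median[3])
  expect_true(all(curve$lo95 <= curve$median & curve$median <= curve$hi95))
})

test_that("zero-cell studies are continuity-corrected and still fit", {
  studies <- data.frame(
    study_id = c("s1", "s2", "s3"),
    events_treatment = c(12L, 0L, 20L), n_treatment = c(50L, 40L, 60L),
    events_control = c(8L, 5L, 15L), n_control = c(50L, 40L, 60L))
  fit <- fit_power_prior(studies, cohort = NULL, a0 = 0,
                         sampler = sampler_fast)
  expect_equal(fit$n_corrected, 1L)
  expect_true(all(is.finite(fit$summary)))
  expect_true(fit$summary[["lo95"]] < fit$summary[["hi95"]])
})

test_that("convergence diagnostics are reported and sane on the fixture", {
  ev <- ref_evidence()
  fit <- fit_power_prior(ev$remission, ev$cohort$remission, a0 = 1,
                         sampler = sampler_fast)
  expect_true(fit$converged)
  expect_lt(fit$diagnostics[["rhat_mu"]], 1.05)
  expect_gt(fit$diagnostics[["ess_mu"]], 100)
  s <- summary(fit)
  expect_setequal(s$parameter, c("mu", "tau", "rr"))
  expect_true(all(s$lo95 <= s$median & s$median <= s$hi95))
  co <- coef(fit)
  expect_equal(unname(exp(co["mu"])), unname(co["rr"]), tolerance = 1e-6)
})
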