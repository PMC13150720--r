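test_that("generators are deterministic under their seeds", {
  a <- generate_meta_dataset(seed = 77)
  b <- generate_meta_dataset(seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, generate_meta_dataset(seed = 78)))
  ca <- generate_cohort(seed = 5)
  cb <- generate_cohort(seed = 5)
  expect_identical(ca, cb)
})

test_that("the pooled empirical risk ratio converges to the generator truth", {
  # law of large numbers: many large homogeneous studies
  d <- generate_meta_dataset(k = 50L, mu_log_rr = log(1.5), tau = 0,
                             n_range = c(10000L, 10000L),
                             control_risk_range = c(0.25, 0.35), seed = 9L)
  rr_hat <- (sum(d$events_treatment) / sum(d$n_treatment)) /
    (sum(d$events_control) / sum(d$n_control))
  expect_lt(abs(rr_hat - 1.5) / 1.5, 0.02)
  expect_true(all(d$events_treatment <= d$n_treatment))
  expect_identical(attr(d, "n_truncated"), 0L)
})

test_that("a null effect leaves arm-level event proportions similar", {
  d <- generate_meta_dataset(k = 30L, mu_log_rr = 0, tau = 0,
                             n_range = c(5000L, 5000L),
                             control_risk_range = c(0.3, 0.4), seed = 13L)
  p_t <- sum(d$events_treatment) / sum(d$n_treatment)
  p_c <- sum(d$events_control) / sum(d$n_control)
  expect_lt(abs(p_t - p_c), 0.01)
})

test_that("cohort generation hits binomial boundaries and moments", {
  full <- generate_cohort(remission_prob = 1, seed = 1)
  expect_equal(full$remission$events, 82)
  means <- vapply(1:2000, function(s)
    generate_cohort(remission_prob = 0.5, seed = s)$remission$events,
    numeric(1))
  se <- sqrt(82 * 0.25) / sqrt(2000)
  expect_lt(abs(mean(means) - 41), 3 * se)
})

test_that("the synthetic life table is a plausible survival schedule", {
  lt <- generate_life_table()
  expect_true(all(diff(lt$annual_mortality_rate) >= 0))
  expect_true(all(lt$annual_mortality_rate >= 0 &
                    lt$annual_mortality_rate <= 1))
  zero <- generate_life_table(a = 0)
  expect_true(all(zero$annual_mortality_rate == 0))
  # remaining life expectancy at 20 ~ 60 years (population LE around 80):
  # independent trapezoidal integral of survival from the table itself
  ages <- 20:100
  haz <- lookup_mortality_rate(lt, ages)
  surv <- exp(-cumsum(c(0, haz[-length(haz)])))
  e20 <- sum((surv[-1] + surv[-length(surv)]) / 2)
  expect_lt(abs(e20 - 60), 1.5)
})

test_that("the reference parameter set passes its calibration gate", {
  ps <- ref_ps()
  bc <- base_case(ps)
  expect_gt(bc$delta_cost, 0)
  expect_gt(bc$delta_qaly, 0.1)
  expect_lt(bc$delta_qaly, 0.5)
  expect_s3_class(attr(ps, "manifest"), "fixture_manifest")
})

test_that("fixture files regenerate bit-identically and carry checksums", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- write_reference_fixture(d1)
  m2 <- write_reference_fixture(d2)
  expect_identical(unname(m1$md5), unname(m2$md5))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  # manifests detect staleness: checksums match the files on disk
  files <- file.path(d1, c("config.yaml", "life_table.csv",
                           "studies_remission.csv", "studies_relapse.csv"))
  expect_identical(unname(tools::md5sum(files)), unname(m1$md5))
  # and the written fixture loads back into a valid parameter set
  ps <- load_parameter_set(file.path(d1, "config.yaml"),
                           file.path(d1, "life_table.csv"))
  expect_s3_class(ps, "parameter_set")
})
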