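test_that("trajectory families evaluate to their closed forms", {
  expect_equal(simulate_trajectory(site_class_spec("stable", m0 = 0.5),
                                   c(3, 12, 35)),
               rep(0.5, 3))
  expect_equal(simulate_trajectory(
    site_class_spec("linear", m0 = 0.2, slope = 0.01), c(3, 35)),
    c(0.23, 0.55))
  # invert the power law so that m(3) = 0.2: b = 3 / 0.2^-13
  b <- 3 / 0.2^-13
  expect_equal(simulate_trajectory(site_class_spec("late_accel", a = 0, b = b),
                                   3), 0.2, tolerance = 1e-9)
  expect_equal(simulate_trajectory(
    site_class_spec("early_change", m0 = 0.1, d = 0.05), exp(2)),
    0.1 + 0.05 * 2)
  expect_equal(simulate_trajectory(
    site_class_spec("entropy_drift", m0 = 0.9, kappa = 0.02), 10),
    0.5 + 0.4 * exp(-0.2))
})

test_that("trajectories are clipped and invalid late_accel domains error", {
  m <- simulate_trajectory(site_class_spec("linear", m0 = 0.9, slope = 0.01),
                           c(1, 50))
  expect_true(all(m >= 0.001 & m <= 0.999))
  expect_error(simulate_trajectory(
    site_class_spec("late_accel", a = 10, b = 1), 5), "a = 10")
})

test_that("mirrored late_accel trajectory is the reflection of the law", {
  spec <- site_class_spec("late_accel", a = 0, b = 3 / 0.2^-13)
  specm <- site_class_spec("late_accel", a = 0, b = 3 / 0.2^-13, mirror = TRUE)
  ages <- c(3, 10, 35)
  expect_equal(simulate_trajectory(specm, ages),
               1 - simulate_trajectory(spec, ages))
})

test_that("CR effect adds the shift plus TAT slope only past onset", {
  cr0 <- cr_spec(t0 = 4, is_shift = 0, tat_slope = 0)
  lat <- c(0.3, 0.4, 0.5)
  ages <- c(4, 10, 24)
  expect_equal(apply_cr(lat, ages, cr0), lat)
  cr1 <- cr_spec(t0 = 4, is_shift = -0.03, tat_slope = 0)
  expect_equal(apply_cr(0.4, 4, cr1), 0.37)
  cr2 <- cr_spec(t0 = 4, is_shift = -0.03, tat_slope = 0.001)
  expect_equal(apply_cr(0.4, 24, cr2), 0.4 - 0.01)
  # samples younger than onset are untouched
  expect_equal(apply_cr(c(0.4, 0.4), c(3, 24), cr2), c(0.4, 0.39))
})

test_that("count sampling honors degenerate fractions and determinism", {
  d <- cohort_design(n_sites = 20, n_per_group = 1,
                     cr_age_groups = numeric(0), seed = 9)
  lat0 <- matrix(0, 20, 16)
  d0 <- d; d0$noise_sd <- 0
  mm0 <- sample_counts(lat0, d0)
  expect_true(all(mm0$meth == 0))
  mm1 <- sample_counts(matrix(1, 20, 16), d0)
  expect_true(all(mm1$meth == mm1$total))
  expect_true(all(mm1$total >= 1))
  mmA <- sample_counts(matrix(0.5, 20, 16), d)
  mmB <- sample_counts(matrix(0.5, 20, 16), d)
  expect_identical(mmA$meth, mmB$meth)
  expect_identical(mmA$total, mmB$total)
  expect_error(sample_counts(matrix(1.2, 2, 2), d), "latent")
})

test_that("per-site substreams make counts independent of cohort subsetting", {
  d <- cohort_design(n_sites = 30, n_per_group = 2,
                     cr_age_groups = numeric(0), seed = 4)
  lat <- matrix(0.4, 30, 32)
  full <- sample_counts(lat, d)
  sub <- sample_counts(lat[1:10, , drop = FALSE], d)
  expect_identical(full$meth[1:10, ], sub$meth)
})

test_that("sampled fractions converge to the latent fraction at high coverage", {
  d <- cohort_design(n_sites = 50, n_per_group = 2, cr_age_groups = numeric(0),
                     coverage_mean = 1e4, noise_sd = 0, seed = 12)
  lat <- matrix(runif(50 * 32, 0.2, 0.8), 50)
  mm <- sample_counts(lat, d)
  expect_lt(max(abs(meth_fractions(mm) - lat)), 0.01 * 3) # 3 x stated tol head
  expect_lt(mean(abs(meth_fractions(mm) - lat)), 0.01)
})

test_that("cohort truth table aligns with the matrix and matches the mixture", {
  d <- cohort_design(n_sites = 500, n_per_group = 2, n_cr_per_group = 2,
                     seed = 21)
  co <- simulate_cohort(d)
  expect_identical(co$truth$site_id, co$matrix$sites$site_id)
  got <- table(co$truth$class_name)
  want <- d$class_mixture * d$n_sites
  for (cl in names(want)) {
    expect_equal(unname(got[cl]), unname(round(want[cl])), tolerance = 1)
  }
  # identical seed reproduces bit-identically
  co2 <- simulate_cohort(d)
  expect_identical(co$matrix$meth, co2$matrix$meth)
  expect_identical(co$truth, co2$truth)
})

test_that("entropy_drift-only cohort has strictly increasing latent entropy", {
  ages <- seq(3, 35, length.out = 16)
  set.seed(2)
  lat <- t(vapply(1:100, function(i) {
    m0 <- if (runif(1) < 0.5) runif(1, 0.05, 0.3) else runif(1, 0.7, 0.95)
    simulate_trajectory(site_class_spec("entropy_drift", m0 = m0,
                                        kappa = runif(1, 0.01, 0.03)), ages)
  }, numeric(16)))
  H <- sample_entropy(lat)
  expect_true(all(diff(H) > 0))
})

test_that("design validation rejects inconsistent cohorts", {
  expect_error(cohort_design(class_mixture = c(stable = 0.6, linear = 0.2)),
               "sum to 1")
  expect_error(cohort_design(coverage_mean = 0), "coverage_mean")
  expect_error(cohort_design(cr_age_groups = c(2, 10)), "t0")
})
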