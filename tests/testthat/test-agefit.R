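test_that("per-site linear fit matches the closed-form simple regression", {
  fit <- fit_site_linear(c(0.1, 0.2, 0.4, 0.5), c(3, 12, 24, 35))
  expect_equal(fit$slope, 7.6 / 585, tolerance = 1e-12)
  set.seed(31)
  for (trial in 1:50) {
    n <- sample(5:40, 1)
    x <- runif(n, 3, 35)
    y <- runif(n)
    got <- fit_site_linear(y, x)
    want <- simple_reg_oracle(y, x)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("noiseless lines and constant sites are recovered exactly", {
  ages <- seq(3, 35, length.out = 12)
  fit <- fit_site_linear(0.2 + 0.01 * ages, ages)
  expect_equal(fit$slope, 0.01, tolerance = 1e-12)
  expect_equal(fit$intercept, 0.2, tolerance = 1e-12)
  expect_equal(fit_site_linear(rep(0.4, 12), ages)$slope, 0)
})

test_that("confounders are adjusted for and collinearity is reported", {
  set.seed(5)
  n <- 60
  ages <- runif(n, 3, 35)
  sex <- rep(0:1, n / 2)
  y <- 0.3 + 0.004 * ages + 0.1 * sex + rnorm(n, 0, 0.01)
  fit <- fit_site_linear(y, ages, data.frame(sex = sex))
  expect_lt(abs(fit$slope - 0.004), 3 * fit$se)
  ref <- lm(y ~ ages + sex)
  expect_equal(fit$slope, unname(coef(ref)["ages"]), tolerance = 1e-10)
  expect_error(fit_site_linear(y, ages, data.frame(a2 = ages)),
               "collinear")
})

test_that("BH adjustment matches the brute-force step-up oracle", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(adjust_pvalues(0.2), 0.2)
  expect_equal(adjust_pvalues(rep(1, 5)), rep(1, 5))
  expect_error(adjust_pvalues(c(0.5, 1.2)), "\\[0, 1\\]")
  base <- c(0.001, 0.02, 0.11, 0.24, 0.5, 0.93)
  perms <- matrix(unlist(combinat_perms(6)), ncol = 6, byrow = TRUE)
  for (r in seq_len(nrow(perms))) {
    p <- base[perms[r, ]]
    expect_equal(adjust_pvalues(p), bh_oracle(p))
  }
})

test_that("transformation grid selects the generating family", {
  ages <- rep(seq(3, 35, length.out = 16), each = 6)
  # noiseless linear data: tie-break lands on (age, 1)
  g <- fit_transform_grid(0.2 + 0.004 * ages, ages)
  expect_equal(g$best_response, "age")
  expect_equal(g$best_power, 1)
  # singleton grid is trivially selected
  g1 <- fit_transform_grid(runif(length(ages)), ages, grid = 1,
                           responses = "age")
  expect_equal(g1$best_power, 1)
  # the inverse power law is recovered when predictor noise is small enough
  # for the -13 transform to remain identifiable
  set.seed(77)
  n <- 100
  ag <- rep(seq(3, 35, length.out = 16), length.out = n)
  hits <- 0
  for (s in 1:60) {
    m_start <- runif(1, 0.6, 0.9)
    m_end <- max(0.15, m_start - runif(1, 0.2, 0.4))
    b <- 32 / (m_end^-13 - m_start^-13)
    a <- 3 - b * m_start^-13
    m <- simulate_trajectory(site_class_spec("late_accel", a = a, b = b), ag) +
      rnorm(n, 0, 0.001)
    gg <- fit_transform_grid(m, ag)
    hits <- hits + (gg$best_response == "age" && gg$best_power == -13)
  }
  expect_gte(hits / 60, 0.9)
})

test_that("dynamics labels follow the model-family rule", {
  expect_equal(classify_dynamics("age", -13, TRUE), "late_accelerating")
  expect_equal(classify_dynamics("age", -5, TRUE), "late_accelerating")
  expect_equal(classify_dynamics("ln_age", 1, TRUE), "early_change")
  expect_equal(classify_dynamics("age", 1, TRUE), "linear")
  expect_error(classify_dynamics("age", 1, FALSE), "significant")
})

test_that("global trend reflects the balance of gain and loss sites", {
  ages <- rep(seq(3, 35, length.out = 16), each = 3)
  set.seed(9)
  gain <- outer(rep(0.004, 20), ages) + 0.2
  loss <- outer(rep(-0.004, 30), ages) + 0.8
  fr <- rbind(gain, loss) + matrix(rnorm(50 * length(ages), 0, 0.005), 50)
  gt <- global_trend(fr, ages)
  expect_lt(gt$slope, 0)
  expect_lt(gt$p, 0.05)
  stable <- matrix(0.5, 30, length(ages)) +
    matrix(rnorm(30 * length(ages), 0, 0.01), 30)
  gts <- global_trend(stable, ages)
  expect_gt(gts$p, 0.01)
  expect_error(global_trend(matrix(0.5, 5, 1), 3), "insufficient|samples")
})

test_that("site-set permutation comparison behaves at its extremes", {
  fr <- rbind(matrix(0, 100, 10), matrix(1, 100, 10))
  rownames(fr) <- paste0("s", 1:200)
  same <- compare_site_set_means(1:50, 1:50, fr, n_perm = 99)
  expect_equal(same$difference, 0)
  expect_equal(same$p, 1)
  sep <- compare_site_set_means(1:100, 101:200, fr, n_perm = 9999, seed = 2)
  expect_equal(sep$p, 1 / 10000)
  sep2 <- compare_site_set_means(1:100, 101:200, fr, n_perm = 9999, seed = 2)
  expect_identical(sep$p, sep2$p)
  expect_error(compare_site_set_means(1:2, 3:4, fr, n_perm = 0), "n_perm")
})

test_that("full age-model table flags directions at the BH threshold", {
  ages <- rep(seq(3, 35, length.out = 16), each = 9)
  set.seed(101)
  S <- 400
  slopes <- c(rep(0.005, 100), rep(-0.005, 100), rep(0, 200))
  i0 <- ifelse(slopes > 0, 0.2, ifelse(slopes < 0, 0.8, 0.5))
  fr <- pmin(pmax(outer(slopes, ages) + i0 +
                    matrix(rnorm(S * length(ages), 0, 0.05), S), 0), 1)
  rownames(fr) <- paste0("s", 1:S)
  fits <- fit_age_models(fr, control_sheet(ages))
  expect_true(all(fits$q >= fits$p))
  expect_gt(mean(fits$direction[1:100] == "gain"), 0.9)
  expect_gt(mean(fits$direction[101:200] == "loss"), 0.9)
  fdr <- sum(fits$direction[201:400] != "none") /
    max(1, sum(fits$direction != "none"))
  expect_lte(fdr, 0.1)
  expect_true(all(fits$dynamics[fits$direction == "none"] == "none"))
})
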