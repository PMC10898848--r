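test_that("weighted median honours its defining conventions", {
  # equal weights, odd n: the ordinary sample median
  x <- c(3, 1, 4, 1, 5)
  expect_equal(weighted_median(x, rep(1, 5), interpolate = FALSE), median(x))
  # a dominant first weight pins the median at that point
  expect_equal(weighted_median(c(1, 2, 10), c(0.6, 0.2, 0.2),
                               interpolate = FALSE), 1)
  expect_error(weighted_median(numeric(0), numeric(0)), "empty")
  expect_error(weighted_median(1:3, c(1, -1, 1)), "positive")
})

test_that("the order-statistic weighted median minimises the weighted L1 loss", {
  set.seed(77)
  for (i in 1:100) {
    x <- runif(7, 0, 10)
    w <- runif(7, 0.1, 3)
    m <- weighted_median(x, w, interpolate = FALSE)
    grid <- seq(min(x), max(x), length.out = 4001)
    loss <- vapply(grid, function(g) sum(w * abs(x - g)), 0)
    best <- min(loss)
    expect_lte(sum(w * abs(x - m)), best + 1e-6 * (1 + best))
  }
})

test_that("weighted median is shift/scale equivariant, bounded, and resistant", {
  set.seed(5)
  x <- rnorm(9)
  w <- runif(9, 0.5, 2)
  for (interp in c(TRUE, FALSE)) {
    m <- weighted_median(x, w, interpolate = interp)
    expect_gte(m, min(x))
    expect_lte(m, max(x))
    expect_equal(weighted_median(x + 3, w, interpolate = interp), m + 3)
    expect_equal(weighted_median(2 * x, w, interpolate = interp), 2 * m)
  }
  # moving the largest value further out does not move the median
  x2 <- x
  x2[which.max(x)] <- max(x) + 1e6
  expect_equal(weighted_median(x2, w), weighted_median(x, w))
})

test_that("K45 adaptive weighted average matches the published analysis", {
  awa <- adaptive_weighted_average(kc_fixture("K45"), seed = 11)
  expect_equal(awa$kcrv, 226.5, tolerance = 0.001)
  expect_equal(awa$tau$tau, 0.601, tolerance = 0.002)
  expect_equal(awa$internal_std_unc, 0.5, tolerance = 0.03)
  expect_gt(awa$bootstrap_std_unc, awa$internal_std_unc)
  expect_equal(awa$std_unc, awa$bootstrap_std_unc)
})

test_that("AWA bootstrap sd approaches the internal formula when tau = 0, nu = Inf", {
  st <- toy_study(c(10.0, 10.05, 9.95, 10.02), u = c(0.5, 0.5, 0.5, 0.5))
  expect_identical(dl_tau(st)$tau, 0)
  awa <- adaptive_weighted_average(st, n_boot = 50000, seed = 4)
  internal <- weighted_mean_est(st)$internal_std_unc
  expect_equal(awa$bootstrap_std_unc, internal, tolerance = 0.05)
})

test_that("bootstrap draws are bit-reproducible given the seed", {
  a <- adaptive_weighted_average(kc_fixture("K45"), n_boot = 500, seed = 9)
  b <- adaptive_weighted_average(kc_fixture("K45"), n_boot = 500, seed = 9)
  expect_identical(a$draws, b$draws)
  c1 <- weighted_median_consensus(kc_fixture("K145_Zn"), n_boot = 500,
                                  seed = 9)
  c2 <- weighted_median_consensus(kc_fixture("K145_Zn"), n_boot = 500,
                                  seed = 9)
  expect_identical(c1$draws, c2$draws)
})

test_that("K145 Zn weighted median matches the published consensus", {
  wm <- weighted_median_consensus(kc_fixture("K145_Zn"), seed = 11)
  expect_equal(wm$bootstrap, "nonparametric") # auto picks nonparametric at n = 19
  expect_equal(wm$kcrv, 457.55, tolerance = 0.5)
  expect_equal(wm$std_unc, 1.65, tolerance = 0.15)
})

test_that("the bagged weighted median is nearly unbiased on symmetric studies", {
  st <- toy_study(100 + seq(-7, 7), u = 1) # 15 labs, symmetric, equal u
  wm <- weighted_median_consensus(st, seed = 3) # auto -> nonparametric
  expect_lt(abs(wm$kcrv - 100), 0.5)
  expect_lt(abs(wm$bias), 0.5)
})

test_that("bootstrap mode auto switches on the number of participants", {
  small <- toy_study(c(1, 2, 3, 4), u = 1)
  expect_equal(weighted_median_consensus(small, n_boot = 300,
                                         seed = 1)$bootstrap, "parametric")
  expect_error(weighted_median_consensus(small, bootstrap = "nonparametric"),
               "at least 5")
})

test_that("consensus estimators are location/scale equivariant", {
  st <- kc_fixture("CCEM_RF_K25W")
  shifted <- kc_study(tibble::tibble(lab = st$lab, value = 10 + 5 * st$value,
                                     u = 5 * st$u))
  awa0 <- adaptive_weighted_average(st, n_boot = 2000, seed = 5)
  awa1 <- adaptive_weighted_average(shifted, n_boot = 2000, seed = 5)
  expect_equal(awa1$kcrv, 10 + 5 * awa0$kcrv, tolerance = 1e-8)
  expect_equal(awa1$std_unc, 5 * awa0$std_unc, tolerance = 1e-8)
  expect_equal(awa1$tau$tau, 5 * awa0$tau$tau, tolerance = 1e-8)

  wm0 <- weighted_median_consensus(st, n_boot = 2000, seed = 5)
  wm1 <- weighted_median_consensus(shifted, n_boot = 2000, seed = 5)
  expect_equal(wm1$kcrv, 10 + 5 * wm0$kcrv, tolerance = 1e-8)
  expect_equal(wm1$std_unc, 5 * wm0$std_unc, tolerance = 1e-8)
})

test_that("the consensus draws average back to the reported KCRV", {
  awa <- adaptive_weighted_average(kc_fixture("K45"), seed = 2)
  mc_se <- sd(awa$draws$mu) / sqrt(awa$n_draws)
  expect_lt(abs(mean(awa$draws$mu) - awa$kcrv), max(3 * mc_se, 0.05))
})
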