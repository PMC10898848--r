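test_that("weighted mean reduces to the arithmetic mean in the right limits", {
  st <- toy_study(c(10, 12, 14), u = 1)
  wm <- weighted_mean_est(st)
  expect_equal(wm$estimate, 12)
  expect_equal(unname(wm$weights), rep(1 / 3, 3))

  # tau -> infinity washes out unequal weights
  st2 <- toy_study(c(10, 12, 20), u = c(0.1, 1, 5))
  big_tau <- 1e6 * max(st2$u)
  expect_equal(weighted_mean_est(st2, tau = big_tau)$estimate, mean(st2$value),
               tolerance = 1e-6)
})

test_that("the K45 internal uncertainty is about 0.5 mg/kg", {
  expect_equal(weighted_mean_est(kc_fixture("K45"))$internal_std_unc, 0.5,
               tolerance = 0.03)
})

test_that("Cochran's Q matches the published K45 and K145 values", {
  q45 <- cochran_q(kc_fixture("K45"))
  expect_equal(q45$statistic, 3.92, tolerance = 0.005)
  expect_equal(q45$dof, 3L)
  expect_equal(q45$p_value, 0.27, tolerance = 0.005)
  expect_false(q45$reject)
  expect_equal(cochran_q(kc_fixture("K145_Zn"))$p_value, 0.96,
               tolerance = 0.005)
})

test_that("Q is zero for identical values and transforms correctly", {
  st <- toy_study(c(5, 5), u = c(1, 2))
  q <- cochran_q(st)
  expect_equal(q$statistic, 0)
  expect_equal(q$p_value, 1)

  base <- toy_study(c(1, 3, 7, 8), u = c(0.5, 1, 0.8, 2))
  q0 <- cochran_q(base)$statistic
  shifted <- toy_study(base$value + 100, u = base$u)
  expect_equal(cochran_q(shifted)$statistic, q0)
  scaled_x <- toy_study(3 * base$value, u = base$u)
  expect_equal(cochran_q(scaled_x)$statistic, 9 * q0)
  scaled_both <- toy_study(3 * base$value, u = 3 * base$u)
  expect_equal(cochran_q(scaled_both)$statistic, q0)
})

test_that("DerSimonian-Laird tau matches its closed form and metafor", {
  expect_equal(dl_tau(kc_fixture("K45"))$tau, 0.601, tolerance = 0.002)

  # independent scalar evaluation of the moment formula on a toy study
  x <- c(0, 1, 2)
  u <- c(0.1, 0.1, 0.1)
  w <- 1 / u^2
  q <- sum(w * (x - weighted.mean(x, w))^2)
  tau_hand <- sqrt(max(0, (q - 2) / (sum(w) - sum(w^2) / sum(w))))
  expect_equal(dl_tau(toy_study(x, u))$tau, tau_hand)

  skip_if_not_installed("metafor")
  for (nm in c("K45", "K88", "CCEM_RF_K25W")) {
    st <- kc_included(kc_fixture(nm))
    fit <- metafor::rma(yi = st$value, sei = st$u, method = "DL")
    expect_equal(dl_tau(kc_fixture(nm))$tau, sqrt(fit$tau2), tolerance = 1e-6)
  }
})

test_that("tau is exactly zero whenever Q does not exceed its dof", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    st <- toy_study(rnorm(n, 100, 0.05), u = runif(n, 0.5, 2))
    q <- cochran_q(st)
    if (q$statistic <= n - 1) {
      expect_identical(dl_tau(st)$tau, 0)
    }
  }
  # DL weighted average with tau = 0 equals the plain weighted mean
  st0 <- toy_study(c(10, 10.1, 9.9), u = c(1, 2, 1.5))
  expect_identical(dl_tau(st0)$tau, 0)
  awa <- adaptive_weighted_average(st0, n_boot = 200, seed = 1)
  expect_equal(awa$kcrv, weighted_mean_est(st0)$estimate)
})

test_that("Q-profile interval matches the K45 caption, a grid-scan oracle, and metafor", {
  ci <- tau_qprofile(kc_fixture("K45"))
  expect_equal(ci$ci_low, 0, tolerance = 0.01)
  expect_equal(ci$ci_high, 8.8, tolerance = 0.2)

  # brute-force oracle: scan Q(tau) over a fine grid on a 5-lab toy study
  st <- toy_study(c(1.2, 3.4, 2.2, 5.1, 4.4), u = c(0.3, 0.6, 0.4, 1.0, 0.8))
  inc <- st
  qfun <- function(tau) {
    w <- 1 / (inc$u^2 + tau^2)
    xb <- sum(w * inc$value) / sum(w)
    sum(w * (inc$value - xb)^2)
  }
  grid <- seq(0, 50, by = 1e-3)
  qg <- vapply(grid, qfun, 0)
  hi <- grid[which.min(abs(qg - qchisq(0.025, 4)))]
  lo <- grid[which.min(abs(qg - qchisq(0.975, 4)))]
  ci2 <- tau_qprofile(st)
  expect_equal(ci2$ci_high, hi, tolerance = 1e-2)
  expect_equal(ci2$ci_low, lo, tolerance = 1e-2)

  skip_if_not_installed("metafor")
  fit <- metafor::rma(yi = inc$value, sei = inc$u, method = "DL")
  mci <- metafor::confint.rma.uni(fit)$random
  expect_equal(ci2$ci_low, mci["tau", "ci.lb"], tolerance = 1e-3)
  expect_equal(ci2$ci_high, mci["tau", "ci.ub"], tolerance = 1e-3)
})

test_that("the profiled Q decreases monotonically in tau on the fixtures", {
  for (nm in c("K45", "K88", "K30_1")) {
    inc <- kc_included(kc_fixture(nm))
    taus <- seq(0, 5 * max(inc$u), length.out = 50)
    qs <- vapply(taus, function(tau) {
      w <- 1 / (inc$u^2 + tau^2)
      xb <- sum(w * inc$value) / sum(w)
      sum(w * (inc$value - xb)^2)
    }, 0)
    expect_true(all(diff(qs) < 0))
  }
})

test_that("identical values give a zero lower bound for tau", {
  st <- toy_study(rep(7, 4), u = c(1, 2, 1, 2))
  ci <- tau_qprofile(st)
  expect_equal(ci$ci_low, 0)
})
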