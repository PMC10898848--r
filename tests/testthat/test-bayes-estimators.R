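# Azzalini skew-t density, used only as an independent oracle here
dskew_t <- function(x, xi, omega, alpha, nu) {
  z <- (x - xi) / omega
  2 / omega * dt(z, nu) * pt(alpha * z * sqrt((nu + 1) / (nu + z^2)), nu + 1)
}

test_that("the mean-zero offset really centres the skew-t (quadrature oracle)", {
  for (par in list(c(1, 3, 10), c(2.5, -4, 6), c(0.7, 8, 25))) {
    omega <- par[1]; alpha <- par[2]; nu <- par[3]
    xi <- skew_t_mean_zero_offset(omega, alpha, nu)
    mean_num <- integrate(function(x) x * dskew_t(x, xi, omega, alpha, nu),
                          -Inf, Inf, rel.tol = 1e-9)$value
    expect_equal(mean_num, 0, tolerance = 1e-6)
  }
  expect_equal(skew_t_mean_zero_offset(1, 0, 10), 0)
  expect_equal(skew_t_mean_zero_offset(2, -3, 8),
               -skew_t_mean_zero_offset(2, 3, 8))
  expect_error(skew_t_mean_zero_offset(1, 1, 0.5), "exceed 1")
})

test_that("a homogeneous study recovers the weighted mean when tau is pinned", {
  st <- toy_study(c(10.01, 9.98, 10.03, 10.00, 9.97, 10.02), u = 0.05)
  fit <- fit_hier(st, "gauss",
                  spec = hier_model_spec(prior_tau_scale = 1e-9),
                  control = test_mcmc(seed = 2))
  wm <- weighted_mean_est(st)
  expect_equal(fit$kcrv, wm$estimate, tolerance = 3 * fit$std_unc / sqrt(400))
  expect_equal(fit$std_unc, wm$internal_std_unc, tolerance = 0.15)
})

test_that("hierarchical fits are location/scale equivariant within MC error", {
  st <- generate_kc(synth_config(n_labs = 12, mu_true = 20, tau_true = 1,
                                 effects_family = "gauss", seed = 8))
  shifted <- kc_study(tibble::tibble(lab = st$lab, value = 3 + 2 * st$value,
                                     u = 2 * st$u))
  f0 <- fit_hier(st, "gauss", control = test_mcmc(seed = 5))
  f1 <- fit_hier(shifted, "gauss", control = test_mcmc(seed = 5))
  expect_equal(f1$kcrv, 3 + 2 * f0$kcrv, tolerance = 0.3 * f0$std_unc)
  expect_equal(f1$tau$tau, 2 * f0$tau$tau, tolerance = 0.3 * f0$tau$tau + 0.05)
})

test_that("the skew-t fit collapses to the Gaussian fit in the symmetric limit", {
  st <- generate_kc(synth_config(n_labs = 10, mu_true = 5, tau_true = 2,
                                 effects_family = "gauss", seed = 31))
  fg <- fit_hier(st, "gauss", control = test_mcmc(seed = 3))
  # alpha pinned at ~0 and heavy prior mass on large nu: skew-t ~ Student-t
  # with many dof ~ Gaussian
  fs <- fit_hier(st, "skew_t",
                 spec = hier_model_spec(prior_alpha_sd = 1e-4,
                                        prior_nu_shape = 200,
                                        prior_nu_rate = 2),
                 control = test_mcmc(seed = 3))
  expect_equal(fs$kcrv, fg$kcrv, tolerance = 3 * fg$std_unc / sqrt(50))
  expect_equal(fs$std_unc, fg$std_unc, tolerance = 0.25 * fg$std_unc)
})

test_that("finite degrees of freedom widen the error-scale posterior", {
  st_inf <- toy_study(c(9, 10, 11, 10.5, 9.5, 10.2), u = 0.8)
  st_fin <- toy_study(c(9, 10, 11, 10.5, 9.5, 10.2), u = 0.8, dof = 4)
  f_inf <- fit_hier(st_inf, "gauss", control = test_mcmc(seed = 6))
  f_fin <- fit_hier(st_fin, "gauss", control = test_mcmc(seed = 6))
  expect_null(f_inf$posterior$sigma)
  expect_false(is.null(f_fin$posterior$sigma))
  # sigma posteriors have genuine spread, centred near the reported u
  sig_sd <- apply(f_fin$posterior$sigma, 2, sd)
  expect_true(all(sig_sd > 0.01))
  expect_gte(f_fin$std_unc, 0.8 * f_inf$std_unc)
})

test_that("posterior summaries are stable across seeds", {
  st <- kc_fixture("K145_Ni")
  f1 <- fit_hier(st, "gauss", control = mcmc_control(seed = 1))
  f2 <- fit_hier(st, "gauss", control = mcmc_control(seed = 2))
  expect_lt(abs(f1$kcrv - f2$kcrv), 0.1 * f1$std_unc)
  expect_lt(abs(f1$tau$tau - f2$tau$tau), 0.15 * f1$tau$sd)
})

test_that("mu is recovered with near-nominal coverage for every effects family", {
  n_sim <- 50
  for (family in c("gauss", "laplace", "skew_t")) {
    covered <- bias <- numeric(n_sim)
    taus <- numeric(n_sim)
    for (i in seq_len(n_sim)) {
      cfg <- synth_config(n_labs = 15, mu_true = 100, tau_true = 2,
                          effects_family = family, alpha_true = -4,
                          nu_df_true = 10, u_range = c(0.5, 2),
                          seed = 1000 + i)
      st <- generate_kc(cfg)
      fit <- suppressWarnings(
        fit_hier(st, family, control = test_mcmc(seed = i)))
      qs <- quantile(fit$draws$mu, c(0.025, 0.975))
      covered[i] <- qs[1] <= 100 && 100 <= qs[2]
      taus[i] <- fit$tau$tau
    }
    expect_gte(mean(covered), 0.90)
    expect_lt(abs(mean(taus) - 2) / 2, 0.25) # tau relative bias < 25 %
  }
})
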