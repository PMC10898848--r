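#' Prior specification for the hierarchical consensus models
#'
#' All three Bayesian leaves share the random-effects likelihood
#' \eqn{x_j = \mu + \lambda_j + \epsilon_j} with Gaussian errors
#' \eqn{\epsilon_j \sim N(0, \sigma_j)}; they differ in the distribution of
#' the lab effects \eqn{\lambda_j}, always parameterized so that \eqn{\tau}
#' is the effects' standard deviation (dark uncertainty). Default priors
#' are weakly informative and data-scaled:
#' \eqn{\mu \sim N(\mathrm{median}(x), (10^5 \mathrm{mad}(x))^2)},
#' \eqn{\tau \sim} half-Cauchy(mad(x)),
#' \eqn{\sigma_j \sim} half-Cauchy(median(u)) for labs with finite
#' \eqn{\nu_j} (with the data term
#' \eqn{\nu_j u_j^2 / \sigma_j^2 \sim \chi^2_{\nu_j}}), and for the
#' skew-Student effects \eqn{\alpha \sim N(0, 4^2)} and
#' \eqn{\nu \sim} Gamma(2, 0.2) truncated to \eqn{\nu \ge 3}.
#'
#' @param prior_mu Length-2 numeric `(center, scale)` or `NULL` to use the
#'   data-scaled default.
#' @param prior_tau_scale Half-Cauchy scale for tau, or `NULL` for mad(x).
#' @param prior_sigma_scale Half-Cauchy scale for the unknown error scales
#'   (finite-dof labs), or `NULL` for median(u).
#' @param prior_alpha_sd Gaussian prior sd for the skewness parameter.
#' @param prior_nu_shape,prior_nu_rate Gamma prior for the skew-t tail
#'   degrees of freedom, truncated below at `nu_min`.
#' @param nu_min Lower truncation for the tail degrees of freedom; must be
#'   > 2 so the effects' sd exists (default 3).
#' @return A list of class `kc_hier_spec`.
#' @export
hier_model_spec <- function(prior_mu = NULL,
                            prior_tau_scale = NULL,
                            prior_sigma_scale = NULL,
                            prior_alpha_sd = 4,
                            prior_nu_shape = 2,
                            prior_nu_rate = 0.2,
                            nu_min = 3) {
  stopifnot(prior_alpha_sd > 0, prior_nu_shape > 0, prior_nu_rate > 0)
  if (nu_min <= 2) stop("`nu_min` must exceed 2 for tau to be defined",
                        call. = FALSE)
  structure(list(prior_mu = prior_mu,
                 prior_tau_scale = prior_tau_scale,
                 prior_sigma_scale = prior_sigma_scale,
                 prior_alpha_sd = prior_alpha_sd,
                 prior_nu_shape = prior_nu_shape,
                 prior_nu_rate = prior_nu_rate,
                 nu_min = nu_min),
            class = "kc_hier_spec")
}

#' MCMC settings
#'
#' @param chains Number of chains (default 4).
#' @param warmup Adaptation plus burn-in iterations per chain (default 3000
#'   each).
#' @param samples Post-warmup draws retained per chain (default 2500).
#' @param thin Thinning interval (default 4): `samples * thin` iterations
#'   are run per chain, damping the autocorrelation between the location
#'   and the lab effects.
#' @param seed Integer seed; chain `i` uses `seed + i`.
#' @return A list of class `kc_mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, warmup = 3000, samples = 2500,
                         thin = 4, seed = 1) {
  stopifnot(chains >= 1, warmup >= 100, samples >= 100, thin >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 samples = as.integer(samples), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "kc_mcmc_control")
}

# Location offset that centres the Azzalini skew-t at mean zero:
# b(nu) = sqrt(nu/pi) * Gamma((nu-1)/2) / Gamma(nu/2)
skew_t_b <- function(nu_df) {
  sqrt(nu_df / pi) * exp(lgamma((nu_df - 1) / 2) - lgamma(nu_df / 2))
}

#' Mean-zero location offset of the Azzalini skew-t
#'
#' For a skew-t with scale `omega`, slant `alpha` and `nu_df` tail degrees
#' of freedom, the mean is \eqn{\xi + \omega\,\delta\,b(\nu)} with
#' \eqn{\delta = \alpha/\sqrt{1+\alpha^2}} and
#' \eqn{b(\nu) = \sqrt{\nu/\pi}\,\Gamma((\nu-1)/2)/\Gamma(\nu/2)}.
#' This returns the location \eqn{\xi = -\omega\,\delta\,b(\nu)} at which
#' the distribution has mean zero, as required of lab effects.
#'
#' @param omega Scale (> 0).
#' @param alpha Slant (real; 0 gives the symmetric Student-t, so offset 0).
#' @param nu_df Tail degrees of freedom (> 1, else the mean is undefined).
#' @return The location parameter xi.
#' @export
skew_t_mean_zero_offset <- function(omega, alpha, nu_df) {
  stopifnot(omega > 0)
  if (any(nu_df <= 1)) stop("`nu_df` must exceed 1 (mean undefined)",
                            call. = FALSE)
  delta <- alpha / sqrt(1 + alpha^2)
  -omega * delta * skew_t_b(nu_df)
}

# sd of the mean-zero skew-t with scale omega: omega * sd_factor(alpha, nu)
skew_t_sd_factor <- function(alpha, nu_df) {
  stopifnot(all(nu_df > 2))
  delta <- alpha / sqrt(1 + alpha^2)
  sqrt(nu_df / (nu_df - 2) - (delta * skew_t_b(nu_df))^2)
}

hier_jags_model <- function(family, any_finite) {
  sigma_block <- if (any_finite) "
    for (j in 1:n) {
      sigma[j] <- ifelse(nu[j] > 1.0E8, u[j], sigma_free[j])
      sigma_free[j] ~ dt(0, 1/(sigscale^2), 1) T(0,)
      u2[j] ~ dgamma(shp[j], rte[j])
      shp[j] <- ifelse(nu[j] > 1.0E8, 0.5, nu[j]/2)
      rte[j] <- ifelse(nu[j] > 1.0E8, 0.5/(u[j]^2), nu[j]/(2*sigma_free[j]^2))
    }" else "
    for (j in 1:n) { sigma[j] <- u[j] }"
  # effects are non-centred (lambda = tau * eta) so tau mixes well even
  # when the data only weakly separate lambda from epsilon
  effects_block <- switch(
    family,
    gauss = "
    for (j in 1:n) {
      eta[j] ~ dnorm(0, 1)
      lambda[j] <- tau*eta[j]
    }",
    laplace = "
    for (j in 1:n) { lambda[j] ~ ddexp(0, sqrt(2)/tau) }",
    skew_t = "
    alpha ~ dnorm(0, 1/(alphasd^2))
    nudf ~ dgamma(nushape, nurate) T(numin,)
    delta <- alpha/sqrt(1+alpha^2)
    bnu <- sqrt(nudf/3.14159265358979)*exp(loggam((nudf-1)/2) - loggam(nudf/2))
    omega <- tau/sqrt(nudf/(nudf-2) - (delta*bnu)^2)
    xi <- -omega*delta*bnu
    for (j in 1:n) {
      t0[j] ~ dnorm(0, 1) T(0,)
      z1[j] ~ dnorm(0, 1)
      g[j] ~ dgamma(nudf/2, 0.5)
      lambda[j] <- xi + omega*(delta*t0[j] + sqrt(1-delta^2)*z1[j])/sqrt(g[j]/nudf)
    }")
  paste0("
  model {
    for (j in 1:n) {
      x[j] ~ dnorm(mu + lambda[j], 1/(sigma[j]^2))
    }
    mu ~ dnorm(mu0, 1/(musd^2))
    tau ~ dt(0, 1/(tauscale^2), 1) T(0,)",
    sigma_block, effects_block, "
  }")
}

#' Fit a hierarchical random-effects consensus model
#'
#' Fits \eqn{x_j = \mu + \lambda_j + \epsilon_j} by MCMC (JAGS), with
#' Gaussian errors and the chosen lab-effects family:
#' `"gauss"` (\eqn{\lambda_j \sim N(0,\tau)}), `"laplace"` (Laplace with
#' sd \eqn{\tau}, i.e. scale \eqn{\tau/\sqrt 2}), or `"skew_t"`
#' (mean-zero Azzalini skew-Student with sd \eqn{\tau}, slant \eqn{\alpha}
#' and tail degrees of freedom \eqn{\nu}, both estimated). Error scales are
#' fixed at \eqn{\sigma_j = u_j} for labs reporting infinite degrees of
#' freedom and treated as unknown with the chi-squared data term
#' \eqn{\nu_j u_j^2/\sigma_j^2 \sim \chi^2_{\nu_j}} otherwise. The KCRV is
#' the posterior mean of \eqn{\mu} and its standard uncertainty the
#' posterior standard deviation.
#'
#' Convergence is gated on split-\eqn{\hat R \le 1.05} and effective sample
#' size \eqn{\ge 400} for \eqn{\mu} and \eqn{\tau}; failures raise a
#' warning carrying the diagnostics.
#'
#' @param study A [kc_study()] (at least 3 included results; 5 for
#'   `skew_t`, below which skewness is weakly identified).
#' @param family Effects family: `"gauss"`, `"laplace"`, or `"skew_t"`.
#' @param spec A [hier_model_spec()].
#' @param control A [mcmc_control()].
#' @return A `kc_consensus` object whose `posterior` element is a
#'   `kc_posterior`: parameter summary tibble, diagnostics, and retained
#'   joint draws.
#' @examples
#' \donttest{
#' fit_hier(kc_fixture("K145_Ni"), "gauss")
#' }
#' @export
fit_hier <- function(study, family = c("gauss", "laplace", "skew_t"),
                     spec = hier_model_spec(), control = mcmc_control()) {
  family <- match.arg(family)
  check_kc_study(study, n_min = if (family == "skew_t") 5L else 3L)
  stopifnot(inherits(spec, "kc_hier_spec"),
            inherits(control, "kc_mcmc_control"))
  inc <- kc_included(study)
  n <- nrow(inc)
  any_finite <- any(is.finite(inc$dof))

  mad_x <- stats::mad(inc$value)
  if (mad_x == 0) mad_x <- max(stats::sd(inc$value), max(inc$u))
  prior_mu <- spec$prior_mu %||% c(stats::median(inc$value), 1e5 * mad_x)
  data <- list(x = inc$value, u = inc$u, n = n,
               mu0 = prior_mu[1], musd = prior_mu[2],
               tauscale = spec$prior_tau_scale %||% mad_x)
  if (any_finite) {
    data$nu <- ifelse(is.finite(inc$dof), inc$dof, 1e9)
    data$u2 <- inc$u^2
    data$u <- NULL  # u enters via sigma / u2 when any dof is finite
    data$u <- inc$u
    data$sigscale <- spec$prior_sigma_scale %||% stats::median(inc$u)
  }
  if (family == "skew_t") {
    data$alphasd <- spec$prior_alpha_sd
    data$nushape <- spec$prior_nu_shape
    data$nurate <- spec$prior_nu_rate
    data$numin <- spec$nu_min
  }

  inits <- lapply(seq_len(control$chains), function(i) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = control$seed + i)
  })
  model <- rjags::jags.model(textConnection(hier_jags_model(family, any_finite)),
                             data = data, inits = inits,
                             n.chains = control$chains,
                             n.adapt = control$warmup, quiet = TRUE)
  update(model, control$warmup, progress.bar = "none")
  vars <- c("mu", "tau", "lambda",
            if (any_finite) "sigma",
            if (family == "skew_t") c("alpha", "nudf", "omega"))
  samp <- rjags::coda.samples(model, vars,
                              n.iter = control$samples * control$thin,
                              thin = control$thin, progress.bar = "none")

  diag_pars <- c("mu", "tau")
  gd <- try(coda::gelman.diag(samp[, diag_pars, drop = FALSE],
                              autoburnin = FALSE, multivariate = FALSE),
            silent = TRUE)
  rhat <- if (inherits(gd, "try-error")) rep(NA_real_, 2) else gd$psrf[, 1]
  ess <- coda::effectiveSize(samp[, diag_pars, drop = FALSE])
  if (any(rhat > 1.05, na.rm = TRUE) || any(ess < 400)) {
    warning(sprintf(
      "MCMC convergence gate failed (max Rhat %.3f, min ESS %.0f); ",
      max(rhat, na.rm = TRUE), min(ess)),
      "increase warmup/samples or check the data", call. = FALSE)
  }

  m <- as.matrix(samp)
  draws <- tibble::as_tibble(m[, c("mu", "tau"), drop = FALSE])
  if (family == "skew_t") {
    draws$alpha <- m[, "alpha"]
    draws$nu_df <- m[, "nudf"]
    draws$omega <- m[, "omega"]
  }
  lambda_cols <- grep("^lambda\\[", colnames(m))
  lambda <- m[, lambda_cols, drop = FALSE]
  colnames(lambda) <- inc$lab
  sigma <- if (any_finite) {
    s <- m[, grep("^sigma\\[", colnames(m)), drop = FALSE]
    colnames(s) <- inc$lab
    s
  }

  summarise_par <- function(v) {
    qs <- stats::quantile(v, c(0.025, 0.25, 0.5, 0.75, 0.975))
    tibble::tibble(mean = mean(v), sd = stats::sd(v),
                   q2.5 = qs[1], q25 = qs[2], median = qs[3],
                   q75 = qs[4], q97.5 = qs[5])
  }
  pars <- c("mu", "tau", if (family == "skew_t") c("alpha", "nudf"))
  summary <- dplyr::bind_cols(
    tibble::tibble(parameter = pars),
    dplyr::bind_rows(lapply(pars, function(p) summarise_par(m[, p]))))

  posterior <- structure(list(summary = summary,
                              lambda = lambda,
                              sigma = sigma,
                              diagnostics = tibble::tibble(
                                parameter = diag_pars,
                                rhat = unname(rhat),
                                ess = unname(ess)),
                              family = family,
                              control = control,
                              spec = spec),
                         class = "kc_posterior")

  tau_row <- summary[summary$parameter == "tau", ]
  method <- paste0("hier_", family, "_gauss")
  new_kc_consensus(
    kcrv = summary$mean[summary$parameter == "mu"],
    std_unc = summary$sd[summary$parameter == "mu"],
    method = method,
    tau = list(tau = tau_row$mean, sd = tau_row$sd, median = tau_row$median,
               method = "posterior"),
    draws = draws, seed = control$seed, study = study,
    extra = list(posterior = posterior, effects_family = family))
}

#' @export
print.kc_posterior <- function(x, ...) {
  cat(sprintf("<kc_posterior> %s effects, %d chains x %d draws\n",
              x$family, x$control$chains, x$control$samples))
  print(as.data.frame(x$summary), row.names = FALSE, digits = 4)
  cat("\ndiagnostics:\n")
  print(as.data.frame(x$diagnostics), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @rdname fit_hier
#' @param x A `kc_posterior`.
#' @param ... Unused.
#' @export
tidy.kc_posterior <- function(x, ...) x$summary
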