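# Random-variate generators for the effects families, all parameterized by
# the standard deviation so tau means the same thing everywhere.

rlaplace <- function(n, sd = 1) {
  b <- sd / sqrt(2)
  stats::rexp(n, 1 / b) * sample(c(-1, 1), n, replace = TRUE)
}

# Mean-zero Azzalini skew-t with sd tau, via the stochastic representation
# ST = xi + omega*(delta*|Z0| + sqrt(1-delta^2)*Z1)/sqrt(W/nu)
rskew_t_mean0 <- function(n, tau, alpha, nu_df) {
  stopifnot(all(nu_df > 2))
  delta <- alpha / sqrt(1 + alpha^2)
  omega <- tau / skew_t_sd_factor(alpha, nu_df)
  xi <- -omega * delta * skew_t_b(nu_df)
  z0 <- abs(stats::rnorm(n))
  z1 <- stats::rnorm(n)
  w <- stats::rchisq(n, nu_df)
  xi + omega * (delta * z0 + sqrt(1 - delta^2) * z1) / sqrt(w / nu_df)
}

#' Configuration for the synthetic key-comparison generator
#'
#' @param n_labs Number of laboratories (>= 2).
#' @param mu_true True measurand value.
#' @param tau_true Dark-uncertainty sd of the lab effects (0 required when
#'   `effects_family = "none"`).
#' @param effects_family `"none"` (common-mean data), `"gauss"`,
#'   `"laplace"`, or `"skew_t"`.
#' @param alpha_true,nu_df_true Skew-t slant and tail degrees of freedom
#'   (`nu_df_true` > 2), used only for `"skew_t"`.
#' @param u_range Range (low, high) of the reported standard uncertainties;
#'   drawn log-uniformly to mimic the order-of-magnitude spread seen in
#'   real comparisons.
#' @param dof_policy `"all_infinite"`, `"all_finite"`, or `"mixed"` (half
#'   the labs finite).
#' @param dof Degrees of freedom assigned under the finite policies
#'   (default 6).
#' @param seed Integer seed.
#' @return A list of class `kc_synth_config`.
#' @export
synth_config <- function(n_labs = 15, mu_true = 100, tau_true = 0,
                         effects_family = c("none", "gauss", "laplace",
                                            "skew_t"),
                         alpha_true = -4, nu_df_true = 10,
                         u_range = c(0.5, 2), dof_policy = c("all_infinite",
                                                             "all_finite",
                                                             "mixed"),
                         dof = 6, seed = 1) {
  effects_family <- match.arg(effects_family)
  dof_policy <- match.arg(dof_policy)
  stopifnot(n_labs >= 2, tau_true >= 0, all(u_range > 0),
            u_range[2] >= u_range[1], dof > 0)
  if (effects_family == "none" && tau_true != 0) {
    stop("`tau_true` must be 0 when `effects_family` is \"none\"",
         call. = FALSE)
  }
  if (effects_family == "skew_t" && nu_df_true <= 2) {
    stop("`nu_df_true` must exceed 2", call. = FALSE)
  }
  structure(list(n_labs = n_labs, mu_true = mu_true, tau_true = tau_true,
                 effects_family = effects_family, alpha_true = alpha_true,
                 nu_df_true = nu_df_true, u_range = u_range,
                 dof_policy = dof_policy, dof = dof, seed = seed),
            class = "kc_synth_config")
}

#' Generate a synthetic key comparison
#'
#' Simulates per-laboratory results from the random-effects model
#' \eqn{x_j = \mu + \lambda_j + \epsilon_j}: reported uncertainties
#' \eqn{u_j} log-uniform on `u_range`, lab effects \eqn{\lambda_j} from the
#' configured family scaled to sd `tau_true` (skew-t mean-centred via
#' [skew_t_mean_zero_offset()]), errors \eqn{\epsilon_j \sim N(0,
#' \sigma_j)} with \eqn{\sigma_j} equal to the drawn scale. Under a finite
#' `dof_policy`, the *reported* \eqn{u_j} is additionally redrawn as
#' \eqn{\sigma_j \sqrt{\chi^2_\nu/\nu}}, emulating uncertainty statements
#' estimated from \eqn{\nu} degrees of freedom.
#'
#' The generated study carries a `truth` attribute recording all latent
#' quantities for recovery tests.
#'
#' @param config A [synth_config()].
#' @return A [kc_study()] with attribute `truth` (list: `mu_true`,
#'   `tau_true`, `lambda`, `epsilon`, `sigma`, config).
#' @examples
#' generate_kc(synth_config(n_labs = 8, tau_true = 2,
#'                          effects_family = "laplace"))
#' @export
generate_kc <- function(config = synth_config()) {
  stopifnot(inherits(config, "kc_synth_config"))
  n <- config$n_labs
  with_rng_seed(config$seed, {
    sigma <- exp(stats::runif(n, log(config$u_range[1]),
                              log(config$u_range[2])))
    lambda <- switch(config$effects_family,
      none = rep(0, n),
      gauss = stats::rnorm(n, 0, config$tau_true),
      laplace = rlaplace(n, sd = config$tau_true),
      skew_t = rskew_t_mean0(n, tau = config$tau_true,
                             alpha = config$alpha_true,
                             nu_df = config$nu_df_true))
    if (config$tau_true == 0) lambda <- rep(0, n)
    eps <- stats::rnorm(n, 0, sigma)
    dof <- switch(config$dof_policy,
      all_infinite = rep(Inf, n),
      all_finite = rep(config$dof, n),
      mixed = rep(c(config$dof, Inf), length.out = n))
    u <- ifelse(is.finite(dof),
                sigma * sqrt(stats::rchisq(n, dof) / dof),
                sigma)
    study <- kc_study(tibble::tibble(
      lab = sprintf("L%02d", seq_len(n)),
      value = config$mu_true + lambda + eps,
      u = u, dof = dof),
      name = "synthetic", unit = "")
    attr(study, "truth") <- list(mu_true = config$mu_true,
                                 tau_true = config$tau_true,
                                 lambda = lambda, epsilon = eps,
                                 sigma = sigma, config = config)
    study
  })
}
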