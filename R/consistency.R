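#' Weighted mean of the included measurement results
#'
#' Computes the inverse-variance weighted mean with weights
#' \eqn{w_j \propto 1/(u_j^2 + \tau^2)}. With `tau = 0` this is the
#' classical fixed-effects weighted mean; a positive `tau` (dark
#' uncertainty) moderates the weights towards equality, and as
#' \eqn{\tau \to \infty} the estimate tends to the arithmetic mean. The
#' "internal" standard uncertainty \eqn{(\sum_j 1/(u_j^2+\tau^2))^{-1/2}}
#' ignores any dispersion of the values beyond their reported uncertainties.
#'
#' @param study A [kc_study()]; only included results are used.
#' @param tau Dark-uncertainty standard deviation (>= 0), default 0.
#' @return A list with `estimate`, `internal_std_unc`, and the normalized
#'   `weights` (named by lab).
#' @export
weighted_mean_est <- function(study, tau = 0) {
  check_kc_study(study, n_min = 2L)
  stopifnot(is.numeric(tau), length(tau) == 1, tau >= 0)
  inc <- kc_included(study)
  w <- 1 / (inc$u^2 + tau^2)
  list(
    estimate = sum(w * inc$value) / sum(w),
    internal_std_unc = 1 / sqrt(sum(w)),
    weights = stats::setNames(w / sum(w), inc$lab)
  )
}

new_kc_test <- function(test_name, statistic, dof, p_value, size,
                        details = list()) {
  out <- tibble::tibble(
    test = test_name,
    statistic = statistic,
    dof = dof,
    p_value = p_value,
    size = size,
    reject = p_value < size
  )
  attr(out, "details") <- details
  class(out) <- c("kc_test", class(out))
  out
}

#' Cochran's Q test of mutual consistency
#'
#' Tests whether the included measured values are more dispersed than their
#' reported standard uncertainties allow (homogeneity). The statistic
#' \eqn{Q = \sum_j w_j (x_j - \bar x_w)^2}, with \eqn{w_j = 1/u_j^2} and
#' \eqn{\bar x_w} the fixed-effects weighted mean, is referred to the upper
#' tail of the chi-squared distribution with \eqn{n - 1} degrees of freedom.
#' A generous test size (default 10 %) is used because failing to detect
#' dark uncertainty is more consequential than falsely declaring it.
#'
#' @param study A [kc_study()].
#' @param size Type-I error probability for the reject flag (default 0.10).
#' @return A one-row `kc_test` tibble: `test`, `statistic`, `dof`,
#'   `p_value`, `size`, `reject`.
#' @examples
#' cochran_q(kc_fixture("K45")) # Q = 3.92, p = 0.27
#' @export
cochran_q <- function(study, size = 0.10) {
  check_kc_study(study, n_min = 2L)
  inc <- kc_included(study)
  n <- nrow(inc)
  w <- 1 / inc$u^2
  xbar <- sum(w * inc$value) / sum(w)
  q <- sum(w * (inc$value - xbar)^2)
  p <- stats::pchisq(q, df = n - 1, lower.tail = FALSE)
  new_kc_test("cochran_q", q, n - 1L, p, size)
}

#' DerSimonian-Laird estimate of dark uncertainty
#'
#' Moment estimator of the between-laboratory standard deviation \eqn{\tau}:
#' \deqn{\hat\tau^2 = \max\{0,\; (Q - (n-1)) / (S_1 - S_2/S_1)\},}
#' with \eqn{S_r = \sum_j w_j^r}, \eqn{w_j = 1/u_j^2}, and Q the Cochran
#' statistic. The estimate is exactly 0 whenever \eqn{Q \le n - 1}, in which
#' case the adaptive weighted average reduces to the plain weighted mean.
#'
#' @param study A [kc_study()].
#' @return A one-row tibble of class `kc_tau`: `tau`, `ci_low`, `ci_high`
#'   (NA: no interval is attached to the moment estimate), `ci_level`,
#'   `method`.
#' @examples
#' dl_tau(kc_fixture("K45")) # tau = 0.601 mg/kg
#' @export
dl_tau <- function(study) {
  check_kc_study(study, n_min = 2L)
  inc <- kc_included(study)
  n <- nrow(inc)
  w <- 1 / inc$u^2
  xbar <- sum(w * inc$value) / sum(w)
  q <- sum(w * (inc$value - xbar)^2)
  s1 <- sum(w)
  s2 <- sum(w^2)
  tau2 <- max(0, (q - (n - 1)) / (s1 - s2 / s1))
  new_kc_tau(sqrt(tau2), NA_real_, NA_real_, NA_real_, "DL")
}

new_kc_tau <- function(tau, ci_low, ci_high, ci_level, method) {
  out <- tibble::tibble(tau = tau, ci_low = ci_low, ci_high = ci_high,
                        ci_level = ci_level, method = method)
  class(out) <- c("kc_tau", class(out))
  out
}

# Generalized Cochran statistic at a trial value of tau; strictly
# decreasing in tau whenever the included values are not all equal.
q_generalized <- function(value, u, tau) {
  w <- 1 / (u^2 + tau^2)
  xbar <- sum(w * value) / sum(w)
  sum(w * (value - xbar)^2)
}

#' Q-profile confidence interval for dark uncertainty
#'
#' Inverts the generalized Cochran statistic
#' \eqn{Q(\tau) = \sum_j (x_j - \bar x_w(\tau))^2 / (u_j^2 + \tau^2)},
#' which under the Gaussian random-effects model has a chi-squared
#' distribution with \eqn{n - 1} degrees of freedom, to obtain a
#' confidence interval for \eqn{\tau}. Because \eqn{Q(\tau)} decreases
#' monotonically in \eqn{\tau}, the bounds are the roots of
#' \eqn{Q(\tau) = \chi^2_{(1 \pm level)/2}}, found by bisection on
#' \eqn{[0, 100 \max_j u_j]}; the lower bound is truncated at 0. A wide
#' upper endpoint relative to the reported uncertainties is a warning sign
#' even when Cochran's test does not reject.
#'
#' @param study A [kc_study()].
#' @param level Confidence level (default 0.95).
#' @return A `kc_tau` tibble with the DerSimonian-Laird point estimate and
#'   the Q-profile bounds.
#' @examples
#' tau_qprofile(kc_fixture("K45")) # 95 % CI (0.0, 8.8) mg/kg
#' @export
tau_qprofile <- function(study, level = 0.95) {
  check_kc_study(study, n_min = 3L)
  stopifnot(level > 0, level < 1)
  inc <- kc_included(study)
  n <- nrow(inc)
  upper_q <- stats::qchisq((1 + level) / 2, df = n - 1)
  lower_q <- stats::qchisq((1 - level) / 2, df = n - 1)
  tau_max <- 100 * max(inc$u)

  solve_tau <- function(target) {
    f <- function(tau) q_generalized(inc$value, inc$u, tau) - target
    if (f(0) <= 0) return(0)       # even tau = 0 undershoots the quantile
    if (f(tau_max) > 0) {
      stop("Q-profile root finding failed: Q(", format(tau_max),
           ") = ", format(f(tau_max) + target),
           " still exceeds the chi-squared quantile ", format(target),
           call. = FALSE)
    }
    stats::uniroot(f, c(0, tau_max), tol = 1e-8 * max(1, tau_max))$root
  }

  new_kc_tau(dl_tau(study)$tau, solve_tau(upper_q), solve_tau(lower_q),
             level, "Q-profile")
}
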