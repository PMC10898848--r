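new_kc_consensus <- function(kcrv, std_unc, method, tau, draws, seed,
                             study, extra = list()) {
  structure(c(list(kcrv = kcrv,
                   std_unc = std_unc,
                   method = method,
                   tau = tau,
                   draws = draws,
                   n_draws = nrow(draws),
                   seed = seed,
                   study_name = attr(study, "kc_name"),
                   unit = attr(study, "kc_unit")),
              extra),
            class = "kc_consensus")
}

#' @export
print.kc_consensus <- function(x, ...) {
  cat(sprintf("<kc_consensus> %s\n", x$method))
  cat(sprintf("KCRV = %s +/- %s %s  (%d draws, seed %s)\n",
              format(signif(x$kcrv, 6)), format(signif(x$std_unc, 3)),
              x$unit %||% "", x$n_draws, format(x$seed)))
  if (!is.null(x$tau)) {
    cat("tau:", paste(sprintf("%s=%s", names(x$tau),
                              vapply(x$tau, function(v) {
                                if (is.numeric(v)) format(signif(v, 3))
                                else as.character(v)
                              }, "")), collapse = " "), "\n")
  }
  invisible(x)
}

#' @rdname kc_estimate
#' @export
tidy.kc_consensus <- function(x, ...) {
  tibble::tibble(term = c("kcrv", "tau"),
                 estimate = c(x$kcrv, x$tau$tau %||% NA_real_),
                 std.error = c(x$std_unc, x$tau$sd %||% NA_real_))
}

#' @rdname kc_estimate
#' @export
glance.kc_consensus <- function(x, ...) {
  tibble::tibble(method = x$method, kcrv = x$kcrv, std_unc = x$std_unc,
                 tau = x$tau$tau %||% NA_real_, n_draws = x$n_draws,
                 seed = x$seed)
}

# DerSimonian-Laird machinery on bare vectors (used in the bootstrap loop)
dl_fit_vec <- function(x, u) {
  n <- length(x)
  w <- 1 / u^2
  xbar <- sum(w * x) / sum(w)
  q <- sum(w * (x - xbar)^2)
  s1 <- sum(w)
  s2 <- sum(w^2)
  tau2 <- max(0, (q - (n - 1)) / (s1 - s2 / s1))
  wt <- 1 / (u^2 + tau2)
  c(mu = sum(wt * x) / sum(wt), tau = sqrt(tau2))
}

#' Adaptive (DerSimonian-Laird) weighted average
#'
#' The consensus value is the weighted mean with weights
#' \eqn{1/(u_j^2 + \hat\tau^2)}, where \eqn{\hat\tau} is the
#' DerSimonian-Laird estimate of dark uncertainty ([dl_tau()]); when
#' \eqn{\hat\tau = 0} this is exactly the plain weighted mean. Its standard
#' uncertainty is evaluated by a parametric bootstrap that honors finite
#' numbers of degrees of freedom: each replicate draws fresh lab effects
#' \eqn{\lambda_j^* \sim N(0, \hat\tau)} and errors
#' \eqn{\epsilon_j^* \sim N(0, \sigma_j^*)} with \eqn{\sigma_j^* = u_j} for
#' infinite \eqn{\nu_j} and \eqn{\sigma_j^* = u_j \sqrt{\nu_j/\chi^2_{\nu_j}}}
#' otherwise, re-estimates \eqn{\tau} and the weighted mean, and the
#' bootstrap standard deviation of the replicate means is compared against
#' the internal (fixed-effects) uncertainty; the larger of the two is
#' reported.
#'
#' @param study A [kc_study()] with at least 2 included results.
#' @param n_boot Bootstrap replicates (>= 100; default 5000).
#' @param seed Integer seed.
#' @return A `kc_consensus` object carrying the replicate draws for
#'   downstream degrees-of-equivalence computation.
#' @examples
#' \donttest{
#' adaptive_weighted_average(kc_fixture("K45"), seed = 1)
#' }
#' @export
adaptive_weighted_average <- function(study, n_boot = 5000, seed = 1) {
  check_kc_study(study, n_min = 2L)
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  inc <- kc_included(study)
  n <- nrow(inc)
  fit <- dl_fit_vec(inc$value, inc$u)
  kcrv <- unname(fit["mu"])
  tau_hat <- unname(fit["tau"])
  internal <- weighted_mean_est(study, tau = 0)$internal_std_unc

  finite <- is.finite(inc$dof)
  boot <- with_rng_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(b) {
      sig <- inc$u
      if (any(finite)) {
        sig[finite] <- inc$u[finite] *
          sqrt(inc$dof[finite] / stats::rchisq(sum(finite), inc$dof[finite]))
      }
      xs <- kcrv + stats::rnorm(n, 0, tau_hat) + stats::rnorm(n, 0, sig)
      c(dl_fit_vec(xs, inc$u), xs)
    }, numeric(2 + n))
    t(reps)
  })
  draws <- tibble::tibble(mu = boot[, 1], tau = boot[, 2])
  x_rep <- boot[, -(1:2), drop = FALSE]
  colnames(x_rep) <- inc$lab

  boot_sd <- stats::sd(draws$mu)
  new_kc_consensus(
    kcrv = kcrv,
    std_unc = max(boot_sd, internal),
    method = "adaptive_weighted_average",
    tau = list(tau = tau_hat, sd = stats::sd(draws$tau), method = "DL"),
    draws = draws, seed = seed, study = study,
    extra = list(internal_std_unc = internal, bootstrap_std_unc = boot_sd,
                 x_rep = x_rep, effects_family = "gauss"))
}

#' Weighted median of a sample
#'
#' The weighted median minimises \eqn{\sum_j w_j |x_j - m|}. Two
#' conventions are supported. `interpolate = TRUE` (default) inverts the
#' weighted empirical distribution function by linear interpolation
#' between the points \eqn{(F_k, x_k)}, \eqn{F_k = \sum_{i \le k} w_i}
#' (values sorted, weights normalized), evaluating it at 1/2: this smooths
#' the otherwise piecewise-constant estimator and is the convention under
#' which the worked examples reproduce. `interpolate = FALSE` returns the
#' order statistic at which the cumulative weight first reaches 1/2 (the
#' midpoint of the two adjacent values when it hits 1/2 exactly), the
#' textbook minimiser.
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @param interpolate Interpolate the weighted ECDF? (default `TRUE`).
#' @return The weighted median.
#' @examples
#' weighted_median(c(1, 2, 10), c(0.6, 0.2, 0.2), interpolate = FALSE) # 1
#' @export
weighted_median <- function(x, w, interpolate = TRUE) {
  if (!length(x)) stop("empty input", call. = FALSE)
  stopifnot(length(x) == length(w), all(is.finite(x)), all(is.finite(w)))
  if (any(w <= 0)) stop("weights must be positive", call. = FALSE)
  o <- order(x)
  x <- x[o]
  w <- w[o] / sum(w)
  cw <- cumsum(w)
  if (interpolate) {
    left <- which(cw <= 0.5)
    if (!length(left)) return(x[1])
    k <- max(left)
    if (cw[k] < 0.5 && k < length(x)) {
      lam <- (0.5 - cw[k]) / (cw[k + 1] - cw[k])
      return((1 - lam) * x[k] + lam * x[k + 1])
    }
    return(x[k])
  }
  k <- which(cw >= 0.5)[1]
  if (abs(cw[k] - 0.5) < sqrt(.Machine$double.eps) && k < length(x)) {
    (x[k] + x[k + 1]) / 2
  } else {
    x[k]
  }
}

#' Weighted-median consensus with bootstrap uncertainty
#'
#' The robust consensus for mutually consistent but non-Gaussian results:
#' the weighted median with weights \eqn{w_j \propto 1/u_j^2}. Uncertainty
#' and bias are evaluated by the bootstrap. The nonparametric version
#' resamples the \eqn{(x_j, u_j)} pairs with replacement; the parametric
#' version redraws \eqn{x_j^* \sim} Gaussian (Student-t with \eqn{\nu_j}
#' degrees of freedom when finite) around the point estimate with scale
#' \eqn{u_j}. `bootstrap = "auto"` chooses nonparametric for 15 or more
#' included labs and parametric below that. The reported KCRV is the
#' bootstrap-smoothed (bagged) estimate — the mean of the replicate
#' weighted medians — which removes the jumpiness of the raw weighted
#' median; the reported standard uncertainty is the standard deviation of
#' the replicates.
#'
#' @param study A [kc_study()]; nonparametric resampling requires at least
#'   5 included results, otherwise 2 suffice.
#' @param n_boot Bootstrap replicates (default 5000).
#' @param seed Integer seed.
#' @param bootstrap `"auto"`, `"parametric"`, or `"nonparametric"`.
#' @return A `kc_consensus` object.
#' @examples
#' \donttest{
#' weighted_median_consensus(kc_fixture("K145_Zn"), seed = 1)
#' }
#' @export
weighted_median_consensus <- function(study, n_boot = 5000, seed = 1,
                                      bootstrap = c("auto", "parametric",
                                                    "nonparametric")) {
  bootstrap <- match.arg(bootstrap)
  check_kc_study(study, n_min = 2L)
  if (n_boot < 100) stop("`n_boot` must be at least 100", call. = FALSE)
  inc <- kc_included(study)
  n <- nrow(inc)
  if (bootstrap == "auto") {
    bootstrap <- if (n >= 15) "nonparametric" else "parametric"
  }
  if (bootstrap == "nonparametric" && n < 5) {
    stop("nonparametric bootstrap needs at least 5 included results",
         call. = FALSE)
  }
  w <- 1 / inc$u^2
  m_hat <- weighted_median(inc$value, w)

  x_rep <- NULL
  if (bootstrap == "nonparametric") {
    meds <- with_rng_seed(seed, {
      vapply(seq_len(n_boot), function(b) {
        i <- sample.int(n, n, replace = TRUE)
        weighted_median(inc$value[i], w[i])
      }, 0)
    })
  } else {
    finite <- is.finite(inc$dof)
    boot <- with_rng_seed(seed, {
      reps <- vapply(seq_len(n_boot), function(b) {
        t_draw <- stats::rnorm(n)
        if (any(finite)) {
          t_draw[finite] <- stats::rt(sum(finite), df = inc$dof[finite])
        }
        xs <- m_hat + inc$u * t_draw
        c(weighted_median(xs, w), xs)
      }, numeric(1 + n))
      t(reps)
    })
    meds <- boot[, 1]
    x_rep <- boot[, -1, drop = FALSE]
    colnames(x_rep) <- inc$lab
  }

  if (stats::sd(meds) == 0) {
    warning("bootstrap replicates are all identical; reported std_unc is 0")
  }
  kcrv <- mean(meds)  # bagged estimate; raw point estimate kept alongside
  new_kc_consensus(
    kcrv = kcrv,
    std_unc = stats::sd(meds),
    method = "weighted_median",
    tau = list(tau = 0, sd = NA_real_, method = "none"),
    draws = tibble::tibble(mu = meds, tau = 0),
    seed = seed, study = study,
    extra = list(point_estimate = m_hat, bootstrap = bootstrap,
                 bias = mean(meds) - m_hat, x_rep = x_rep,
                 effects_family = "none"))
}
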