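#' Unilateral degrees of equivalence
#'
#' For every laboratory in the study — included in the KCRV or not — the
#' degree of equivalence is \eqn{D_j = x_j - \mathrm{KCRV}} together with
#' an expanded uncertainty \eqn{U_{95}(D_j)} at 95 % coverage. Following
#' the predictive ("fresh effect") construction, \eqn{U_{95}} is the
#' half-width of the central 95 % interval of replicate differences
#' \eqn{d_j^* = x_j^* - \mu^*}: a lab is flagged only when its value lies
#' beyond the range the fitted model allows for a lab like it, which
#' propagates dark uncertainty into the DoEs.
#'
#' Per retained draw (bootstrap replicate or posterior draw) \eqn{b}:
#' * For labs whose replicate data were retained by a parametric bootstrap
#'   leaf, \eqn{d_j^* = x_{jb}^* - \mu_b^*} uses the very replicate datum
#'   that entered the replicate consensus, so the estimator-datum
#'   correlation is inherited automatically.
#' * Otherwise \eqn{x_{jb}^* = \mu_b^* + \lambda_{jb}^* + \epsilon_{jb}^*}
#'   is generated fresh — \eqn{\lambda^*} from the fitted effects family
#'   with that draw's \eqn{\tau_b^*} (Gaussian, Laplace, or mean-zero
#'   skew-t; none for the common-mean weighted-median leaf) and
#'   \eqn{\epsilon^*} Gaussian with scale \eqn{u_j} (redrawn via
#'   \eqn{u_j\sqrt{\nu_j/\chi^2_{\nu_j}}} when \eqn{\nu_j} is finite) —
#'   and compared against the reported KCRV:
#'   \eqn{d_j^* = x_{jb}^* - \mathrm{KCRV}}, so the spread combines the
#'   lab's predictive dispersion with the consensus uncertainty, with no
#'   correlation credit.
#'
#' @param study The full [kc_study()] (all N labs receive a DoE).
#' @param consensus A `kc_consensus` from any leaf, with draws retained.
#' @param n_draws Number of predictive replicates (default 10000); draws
#'   are recycled by resampling when fewer were retained.
#' @param seed Integer seed for the fresh predictive draws.
#' @return A tibble of class `kc_doe`: `lab`, `value`, `u`, `D`, `U95`,
#'   `included`, `significant` (`|D| > U95`).
#' @examples
#' \donttest{
#' st <- kc_fixture("K45")
#' compute_does(st, adaptive_weighted_average(st, seed = 1))
#' }
#' @export
compute_does <- function(study, consensus, n_draws = 10000, seed = 1) {
  check_kc_study(study)
  if (!inherits(consensus, "kc_consensus")) {
    stop("`consensus` must be a kc_consensus", call. = FALSE)
  }
  if (is.null(consensus$draws) || !nrow(consensus$draws)) {
    stop("consensus carries no draws; re-run the estimator with draws ",
         "retained", call. = FALSE)
  }
  draws <- consensus$draws
  x_rep <- consensus$x_rep
  family <- consensus$effects_family %||% "gauss"
  kcrv <- consensus$kcrv

  with_rng_seed(seed, {
    idx <- if (nrow(draws) >= n_draws) {
      sample.int(nrow(draws), n_draws)
    } else {
      sample.int(nrow(draws), n_draws, replace = TRUE)
    }
    mu_s <- draws$mu[idx]
    tau_s <- draws$tau[idx]

    entries <- lapply(seq_len(nrow(study)), function(j) {
      lab <- study$lab[j]
      d_obs <- study$value[j] - kcrv
      if (!is.null(x_rep) && lab %in% colnames(x_rep) && study$include[j]) {
        d_star <- x_rep[idx, lab] - mu_s
      } else {
        lam <- switch(family,
          none = rep(0, n_draws),
          gauss = stats::rnorm(n_draws, 0, tau_s),
          laplace = rlaplace(n_draws, sd = tau_s),
          skew_t = rskew_t_mean0(n_draws, tau = tau_s,
                                 alpha = draws$alpha[idx],
                                 nu_df = draws$nu_df[idx]))
        scale_j <- if (is.finite(study$dof[j])) {
          study$u[j] * sqrt(study$dof[j] / stats::rchisq(n_draws, study$dof[j]))
        } else {
          study$u[j]
        }
        eps <- if (family == "none") {
          rlaplace(n_draws, sd = scale_j)
        } else {
          stats::rnorm(n_draws, 0, scale_j)
        }
        d_star <- (mu_s + lam + eps) - kcrv
      }
      qs <- stats::quantile(d_star, c(0.025, 0.975), names = FALSE)
      u95 <- (qs[2] - qs[1]) / 2
      tibble::tibble(lab = lab, value = study$value[j], u = study$u[j],
                     D = d_obs, U95 = u95,
                     included = study$include[j],
                     significant = abs(d_obs) > u95)
    })
    out <- dplyr::bind_rows(entries)
    attr(out, "method") <- consensus$method
    attr(out, "n_draws") <- n_draws
    attr(out, "kc_unit") <- consensus$unit
    class(out) <- c("kc_doe", class(out))
    out
  })
}

#' Plot-ready records for a DoE table
#'
#' @param table A `kc_doe` tibble.
#' @return A tibble with `lab`, `D`, `lower`, `upper`, `included`,
#'   `significant`, preserving input order.
#' @export
doe_plot_data <- function(table) {
  if (!inherits(table, "kc_doe") || !nrow(table)) {
    stop("`table` must be a non-empty kc_doe", call. = FALSE)
  }
  tibble::tibble(lab = factor(table$lab, levels = table$lab),
                 D = table$D,
                 lower = table$D - table$U95,
                 upper = table$D + table$U95,
                 included = table$included,
                 significant = table$significant)
}

#' @rdname compute_does
#' @param object A `kc_doe`.
#' @param ... Unused.
#' @export
autoplot.kc_doe <- function(object, ...) {
  pd <- doe_plot_data(object)
  ggplot2::ggplot(pd, ggplot2::aes(x = .data$lab, y = .data$D)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower,
                                         ymax = .data$upper,
                                         colour = .data$included)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$significant), size = 2) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = NULL,
                  y = paste0("D = x - KCRV",
                             if (nzchar(attr(object, "kc_unit") %||% ""))
                               paste0(" [", attr(object, "kc_unit"), "]")),
                  colour = "in KCRV", shape = "|D| > U95") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
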