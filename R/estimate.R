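#' Estimate the consensus value with a chosen (or recommended) leaf
#'
#' Dispatches to one of the five consensus estimators. With
#' `method = "auto"` the decision tree is traversed first
#' ([kc_decide()]) and its recommended leaf is used; the tree is advisory,
#' so any leaf can also be requested directly.
#'
#' @param study A [kc_study()].
#' @param method `"auto"` or one of `"adaptive_weighted_average"`,
#'   `"weighted_median"`, `"hier_gauss_gauss"`, `"hier_laplace_gauss"`,
#'   `"hier_skew_t_gauss"`.
#' @param n_boot Bootstrap replicates for the frequentist leaves.
#' @param seed Integer seed (bootstrap and MCMC).
#' @param config [decision_config()] used when `method = "auto"`.
#' @param spec [hier_model_spec()] for the Bayesian leaves.
#' @param control [mcmc_control()] for the Bayesian leaves; its seed is
#'   overridden by `seed`.
#' @param bootstrap Bootstrap mode for the weighted median.
#' @return A `kc_consensus` object (with the `kc_decision` attached as
#'   attribute `decision` when `method = "auto"`).
#' @examples
#' \donttest{
#' kc_estimate(kc_fixture("K45"), "adaptive_weighted_average", seed = 1)
#' }
#' @export
kc_estimate <- function(study,
                        method = c("auto", "adaptive_weighted_average",
                                   "weighted_median", "hier_gauss_gauss",
                                   "hier_laplace_gauss",
                                   "hier_skew_t_gauss"),
                        n_boot = 5000, seed = 1,
                        config = decision_config(seed = seed),
                        spec = hier_model_spec(),
                        control = mcmc_control(seed = seed),
                        bootstrap = "auto") {
  method <- match.arg(method)
  decision <- NULL
  if (method == "auto") {
    decision <- kc_decide(study, config)
    method <- decision$leaf
  }
  control$seed <- as.integer(seed)
  out <- switch(method,
    adaptive_weighted_average =
      adaptive_weighted_average(study, n_boot = n_boot, seed = seed),
    weighted_median =
      weighted_median_consensus(study, n_boot = n_boot, seed = seed,
                                bootstrap = bootstrap),
    hier_gauss_gauss = fit_hier(study, "gauss", spec, control),
    hier_laplace_gauss = fit_hier(study, "laplace", spec, control),
    hier_skew_t_gauss = fit_hier(study, "skew_t", spec, control))
  attr(out, "decision") <- decision
  out
}

#' Run the full decision-tree pipeline
#'
#' Traverses the tree, fits the recommended estimator, and computes
#' degrees of equivalence for all laboratories — the complete per-study
#' analysis. The returned report prints as a compact summary (gating
#' tests, leaf, KCRV with uncertainty, dark-uncertainty interval, DoE
#' table) and can be serialized to JSON with [write_kc_report()].
#'
#' @inheritParams kc_estimate
#' @param n_doe_draws Predictive replicates for the DoEs.
#' @param force_leaf Optional leaf name overriding the recommendation
#'   (the tree is a guide, not the sole determinant).
#' @return A list of class `kc_report`: `study`, `decision`, `consensus`,
#'   `doe`, `tau_profile`, `seed`.
#' @examples
#' \donttest{
#' kc_run(kc_fixture("K45"), seed = 1)
#' }
#' @export
kc_run <- function(study, seed = 1, n_boot = 5000,
                   config = decision_config(seed = seed),
                   spec = hier_model_spec(),
                   control = mcmc_control(seed = seed),
                   n_doe_draws = 10000,
                   force_leaf = NULL) {
  check_kc_study(study, n_min = 3L)
  decision <- kc_decide(study, config)
  leaf <- force_leaf %||% decision$leaf
  consensus <- kc_estimate(study, method = leaf, n_boot = n_boot,
                           seed = seed, spec = spec, control = control)
  doe <- compute_does(study, consensus, n_draws = n_doe_draws, seed = seed)
  tau_ci <- tryCatch(tau_qprofile(study), error = function(e) NULL)
  structure(list(study = study, decision = decision, consensus = consensus,
                 doe = doe, tau_profile = tau_ci, seed = seed,
                 forced = !is.null(force_leaf)),
            class = "kc_report")
}

#' @export
print.kc_report <- function(x, ...) {
  nm <- attr(x$study, "kc_name")
  un <- attr(x$study, "kc_unit")
  cat("== key comparison analysis ==\n")
  if (nzchar(nm %||% "")) cat("study:", nm,
                              if (nzchar(un %||% "")) paste0("[", un, "]"),
                              "\n")
  cat(sprintf("labs: %d total, %d included in KCRV; seed %d\n",
              nrow(x$study), sum(x$study$include), x$seed))
  cat("\n-- gating tests --\n")
  print(as.data.frame(x$decision$nodes), row.names = FALSE, digits = 4)
  cat("\nleaf:", x$consensus$method,
      if (x$forced) "(forced by user)" else "(recommended)", "\n")
  cat(sprintf("\nKCRV = %s +/- %s %s\n",
              format(signif(x$consensus$kcrv, 6)),
              format(signif(x$consensus$std_unc, 3)), un %||% ""))
  if (!is.null(x$tau_profile)) {
    cat(sprintf("dark uncertainty: tau_DL = %s, Q-profile %g %% CI (%s, %s)\n",
                format(signif(x$tau_profile$tau, 3)),
                100 * x$tau_profile$ci_level,
                format(signif(x$tau_profile$ci_low, 3)),
                format(signif(x$tau_profile$ci_high, 3))))
  }
  cat("\n-- degrees of equivalence --\n")
  print(as.data.frame(x$doe), row.names = FALSE, digits = 4)
  if (length(x$decision$warnings)) {
    cat("\nwarnings:\n")
    for (w in x$decision$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the decision trace, consensus summary, and DoE table (plus all
#' seeds and settings) as a single JSON document, the machine-readable
#' companion of the printed report.
#'
#' @param report A `kc_report` from [kc_run()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_kc_report <- function(report, path) {
  stopifnot(inherits(report, "kc_report"))
  payload <- list(
    study = list(name = attr(report$study, "kc_name"),
                 unit = attr(report$study, "kc_unit"),
                 results = as.data.frame(report$study)),
    decision = list(leaf = report$decision$leaf,
                    nodes = as.data.frame(report$decision$nodes),
                    warnings = report$decision$warnings,
                    sizes = report$decision$config[
                      c("size_homogeneity", "size_symmetry",
                        "size_gaussian", "bonferroni")]),
    consensus = list(method = report$consensus$method,
                     kcrv = report$consensus$kcrv,
                     std_unc = report$consensus$std_unc,
                     tau = report$consensus$tau,
                     n_draws = report$consensus$n_draws,
                     seed = report$consensus$seed),
    tau_profile = if (!is.null(report$tau_profile))
      as.data.frame(report$tau_profile),
    doe = as.data.frame(report$doe),
    seed = report$seed)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname kc_run
#' @param object A `kc_study`.
#' @param ... Unused.
#' @export
autoplot.kc_study <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$lab <- factor(df$lab, levels = df$lab)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lab, y = .data$value)) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$value - .data$u,
                                         ymax = .data$value + .data$u,
                                         colour = .data$include)) +
    ggplot2::geom_point(colour = "firebrick", shape = 18, size = 2.5) +
    ggplot2::labs(x = NULL,
                  y = paste0("measured value",
                             if (nzchar(attr(object, "kc_unit") %||% ""))
                               paste0(" [", attr(object, "kc_unit"), "]")),
                  colour = "in KCRV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom rlang .data
NULL
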