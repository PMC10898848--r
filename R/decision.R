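#' Configuration for traversing the decision tree
#'
#' The three gating tests each have a size (Type-I error probability).
#' Cochran's Q defaults to a generous 10 % because failing to detect dark
#' uncertainty is the costlier mistake; the symmetry and Gaussian-shape
#' tests default to 5 %. Setting `bonferroni = TRUE` replaces all three by
#' `overall_alpha / 3`, a conservative multiplicity correction over the at
#' most three tests a traversal can visit.
#'
#' @param size_homogeneity Size of Cochran's Q test (default 0.10).
#' @param size_symmetry Size of the symmetry test (default 0.05).
#' @param size_gaussian Size of the Gaussian-shape test (default 0.05).
#' @param bonferroni Apply the Bonferroni correction? (default `FALSE`).
#' @param overall_alpha Overall Type-I error when `bonferroni = TRUE`
#'   (default 0.05).
#' @param n_boot Bootstrap replicates for the symmetry test.
#' @param seed Seed forwarded to the symmetry test.
#' @return A list of class `kc_decision_config`.
#' @export
decision_config <- function(size_homogeneity = 0.10,
                            size_symmetry = 0.05,
                            size_gaussian = 0.05,
                            bonferroni = FALSE,
                            overall_alpha = 0.05,
                            n_boot = 10000,
                            seed = 1) {
  sizes <- c(size_homogeneity, size_symmetry, size_gaussian, overall_alpha)
  if (any(sizes <= 0 | sizes >= 1)) {
    stop("all test sizes must lie strictly between 0 and 1", call. = FALSE)
  }
  if (bonferroni) {
    per_test <- bonferroni_sizes(overall_alpha, 3L)
    size_homogeneity <- size_symmetry <- size_gaussian <- per_test[1]
  }
  structure(list(size_homogeneity = size_homogeneity,
                 size_symmetry = size_symmetry,
                 size_gaussian = size_gaussian,
                 bonferroni = bonferroni,
                 overall_alpha = overall_alpha,
                 n_boot = n_boot,
                 seed = seed),
            class = "kc_decision_config")
}

#' Equal Bonferroni split of an overall test size
#'
#' @param overall_alpha Overall Type-I error probability in (0, 1).
#' @param n_tests Number of tests (2 or 3 along a traversal).
#' @return Vector of `n_tests` equal per-test sizes summing to
#'   `overall_alpha`.
#' @export
bonferroni_sizes <- function(overall_alpha, n_tests) {
  stopifnot(overall_alpha > 0, overall_alpha < 1, n_tests >= 1)
  rep(overall_alpha / n_tests, n_tests)
}

#' Traverse the decision tree for a key comparison
#'
#' Runs the gating tests and returns the recommended consensus estimator
#' (leaf) together with a full audit trail. The topology is:
#'
#' 1. **Mutual consistency** (Cochran's Q). Consistent results go to node 2,
#'    inconsistent ones to node 3.
#' 2. **Gaussian shape** of the standardized values: Gaussian shape selects
#'    the *adaptive weighted average*, otherwise the *weighted median*.
#' 3. **Symmetry** of the measured values: asymmetry selects the
#'    *hierarchical skew-Student + Gauss* model; symmetric samples go to
#'    node 4.
#' 4. **Gaussian shape** again: Gaussian selects *hierarchical Gauss +
#'    Gauss*, otherwise *hierarchical Laplace + Gauss*.
#'
#' A test rejects only when its p-value is strictly below its size. The
#' recommendation is advisory: estimation is a separate call
#' ([kc_estimate()]), so the analyst may override it. Warnings are attached
#' when the number of included labs is below the ranges over which the
#' tests are reliable (fewer than 5 labs overall, 30 for symmetry, 10 for
#' Gaussian shape), and when the Q-profile interval for \eqn{\tau} reaches
#' far above the reported uncertainties despite a non-significant Q.
#'
#' @param study A [kc_study()] with at least 3 included results.
#' @param config A [decision_config()].
#' @return A `kc_decision` object: list with `leaf`, `nodes` (tibble of
#'   node label, test name, statistic, p-value, size, branch), `warnings`,
#'   `tau` (Q-profile summary), and `config`.
#' @examples
#' kc_decide(kc_fixture("K45"))$leaf # adaptive weighted average
#' @export
kc_decide <- function(study, config = decision_config()) {
  check_kc_study(study, n_min = 3L)
  stopifnot(inherits(config, "kc_decision_config"))
  n <- sum(study$include)

  nodes <- list()
  note <- function(label, outcome, branch) {
    nodes[[length(nodes) + 1L]] <<-
      tibble::tibble(node = label,
                     test = outcome$test,
                     statistic = outcome$statistic,
                     p_value = outcome$p_value,
                     size = outcome$size,
                     reject = outcome$reject,
                     branch = branch)
  }

  warnings <- character()
  if (n < 5) {
    warnings <- c(warnings, paste0(
      "only ", n, " results are included; the gating tests are unreliable ",
      "for fewer than 5 participants - professional judgment should ",
      "complement this recommendation"))
  }

  q_test <- cochran_q(study, size = config$size_homogeneity)
  tau_ci <- tryCatch(tau_qprofile(study), error = function(e) NULL)
  if (!q_test$reject && !is.null(tau_ci) && is.finite(tau_ci$ci_high) &&
      tau_ci$ci_high > 2 * stats::median(kc_included(study)$u)) {
    warnings <- c(warnings, paste0(
      "Cochran's Q does not reject homogeneity, but the Q-profile 95 % ",
      "interval for tau reaches ", format(signif(tau_ci$ci_high, 3)),
      ", well above the reported uncertainties; dark uncertainty may be ",
      "present but undetected"))
  }

  if (!q_test$reject) {
    note("homogeneity", q_test, "consistent")
    g_test <- gaussian_shape_test(study, "auto", size = config$size_gaussian)
    if (n < 10) {
      warnings <- c(warnings,
        "Gaussian-shape tests have low power below 10 participants")
    }
    if (!g_test$reject) {
      note("gaussian_shape", g_test, "gaussian")
      leaf <- "adaptive_weighted_average"
    } else {
      note("gaussian_shape", g_test, "non_gaussian")
      leaf <- "weighted_median"
    }
  } else {
    note("homogeneity", q_test, "inconsistent")
    s_test <- symmetry_test(study, size = config$size_symmetry,
                            n_boot = config$n_boot, seed = config$seed)
    if (n < 30) {
      warnings <- c(warnings,
        "the symmetry test was validated for 30 or more participants; below that its conclusions carry low power")
    }
    if (s_test$reject) {
      note("symmetry", s_test, "asymmetric")
      leaf <- "hier_skew_t_gauss"
    } else {
      note("symmetry", s_test, "symmetric")
      g_test <- gaussian_shape_test(study, "auto", size = config$size_gaussian)
      if (n < 10) {
        warnings <- c(warnings,
          "Gaussian-shape tests have low power below 10 participants")
      }
      if (!g_test$reject) {
        note("gaussian_shape", g_test, "gaussian")
        leaf <- "hier_gauss_gauss"
      } else {
        note("gaussian_shape", g_test, "non_gaussian")
        leaf <- "hier_laplace_gauss"
      }
    }
  }

  structure(list(leaf = leaf,
                 nodes = dplyr::bind_rows(nodes),
                 warnings = warnings,
                 tau = tau_ci,
                 config = config,
                 study_name = attr(study, "kc_name")),
            class = "kc_decision")
}

#' @export
print.kc_decision <- function(x, ...) {
  cat("<kc_decision>", if (nzchar(x$study_name %||% "")) x$study_name else "",
      "\n")
  cat("recommended leaf:", x$leaf, "\n\n")
  print(as.data.frame(x$nodes), row.names = FALSE, digits = 4)
  if (length(x$warnings)) {
    cat("\nwarnings:\n")
    for (w in x$warnings) cat(" -", w, "\n")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname kc_decide
#' @param x A `kc_decision`.
#' @param ... Unused.
#' @export
tidy.kc_decision <- function(x, ...) x$nodes

#' @rdname kc_decide
#' @export
glance.kc_decision <- function(x, ...) {
  tibble::tibble(leaf = x$leaf,
                 n_nodes = nrow(x$nodes),
                 n_warnings = length(x$warnings),
                 tau_dl = if (!is.null(x$tau)) x$tau$tau else NA_real_,
                 tau_ci_high = if (!is.null(x$tau)) x$tau$ci_high else NA_real_)
}
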