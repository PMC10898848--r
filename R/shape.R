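#' Roughly standardized measured values
#'
#' Centers the included measured values at their median and scales each by
#' its own reported standard uncertainty:
#' \eqn{z_j = (x_j - m)/u_j}, \eqn{m = \mathrm{median}(x)}. These are the
#' values to which the Gaussian-shape tests are applied: under the common
#' mean model with Gaussian errors they are roughly standard Gaussian.
#'
#' @param study A [kc_study()] with at least 3 included results.
#' @return A tibble with columns `lab` and `z`.
#' @export
standardize_values <- function(study) {
  check_kc_study(study, n_min = 3L)
  inc <- kc_included(study)
  tibble::tibble(lab = inc$lab,
                 z = (inc$value - stats::median(inc$value)) / inc$u)
}

#' Miao-Gel-Gastwirth statistic for symmetry about an unknown median
#'
#' \deqn{T = \frac{\bar x - m}{J}, \qquad
#'       J = \sqrt{\pi/2}\; \frac{1}{n}\sum_j |x_j - m|,}
#' where \eqn{m} is the sample median. Positive values indicate right skew.
#' Degenerate samples (all values equal) return 0.
#'
#' @param x Numeric vector, length >= 3.
#' @return The signed statistic.
#' @export
mgg_statistic <- function(x) {
  stopifnot(is.numeric(x), length(x) >= 3, all(is.finite(x)))
  m <- stats::median(x)
  j <- sqrt(pi / 2) * mean(abs(x - m))
  if (j == 0) return(0)
  (mean(x) - m) / j
}

# MGG statistic row-wise over a matrix of samples (bootstrap replicates)
mgg_statistic_rows <- function(mat) {
  med <- apply(mat, 1L, stats::median)
  dev <- abs(mat - med)
  j <- sqrt(pi / 2) * rowMeans(dev)
  t <- (rowMeans(mat) - med) / j
  t[j == 0] <- 0
  t
}

#' Bootstrap test of symmetry about an unknown median
#'
#' Applies the Miao-Gel-Gastwirth statistic to the included *measured
#' values* (not the standardized ones) and computes a two-sided p-value
#' from a bootstrap null distribution: the sample is symmetrized about its
#' median into the 2n-point set \eqn{\{x_j - m\} \cup \{-(x_j - m)\}}, a
#' full bootstrap sample (of size 2n) is drawn from that set in each
#' replicate, and the p-value is the proportion of replicate \eqn{|T^*|}
#' at least as large as the observed \eqn{|T|}.
#'
#' @param study A [kc_study()] with at least 4 included results.
#' @param size Type-I error probability for the reject flag (default 0.05).
#' @param n_boot Number of bootstrap replicates (>= 100; default 10000,
#'   which stabilises the p-value to about ±0.005).
#' @param seed Integer seed making the p-value reproducible.
#' @return A one-row `kc_test` tibble; the observed statistic is signed.
#' @examples
#' symmetry_test(kc_fixture("K30_1"), seed = 1) # rejects symmetry
#' @export
symmetry_test <- function(study, size = 0.05, n_boot = 10000, seed = 1) {
  check_kc_study(study, n_min = 4L)
  if (n_boot < 100) stop("`n_boot` below 100 gives unstable p-values",
                         call. = FALSE)
  inc <- kc_included(study)
  x <- inc$value
  n <- length(x)
  t_obs <- mgg_statistic(x)
  d <- x - stats::median(x)
  pool <- c(d, -d)
  boot <- with_rng_seed(seed, {
    idx <- matrix(sample.int(2L * n, n_boot * 2L * n, replace = TRUE),
                  nrow = n_boot)
    mgg_statistic_rows(matrix(pool[idx], nrow = n_boot))
  })
  p <- mean(abs(boot) >= abs(t_obs))
  new_kc_test("symmetry_mgg", t_obs, NA_integer_, p, size,
              details = list(n_boot = n_boot, seed = seed))
}

#' Tests of Gaussian shape on standardized values
#'
#' Applies the Shapiro-Wilk and/or Anderson-Darling test to the roughly
#' standardized values of [standardize_values()]. The Anderson-Darling
#' implementation requires at least 8 observations; `method = "auto"`
#' therefore uses Shapiro-Wilk alone below 8 and otherwise runs both,
#' deciding on (and reporting) the smaller of the two p-values, with both
#' recorded in the `details` attribute.
#'
#' @param study A [kc_study()] with at least 3 included results (8 for
#'   `anderson_darling`).
#' @param method `"shapiro_wilk"`, `"anderson_darling"`, or `"auto"`.
#' @param size Type-I error probability for the reject flag (default 0.05).
#' @return A one-row `kc_test` tibble.
#' @examples
#' gaussian_shape_test(kc_fixture("K45")) # Shapiro-Wilk, p = 0.92
#' @export
gaussian_shape_test <- function(study,
                                method = c("auto", "shapiro_wilk",
                                           "anderson_darling"),
                                size = 0.05) {
  method <- match.arg(method)
  check_kc_study(study, n_min = 3L)
  z <- standardize_values(study)$z
  n <- length(z)
  if (method == "anderson_darling" && n < 8) {
    stop("the Anderson-Darling test cannot handle samples with fewer than ",
         "eight observations (n = ", n, ")", call. = FALSE)
  }
  run_sw <- method %in% c("shapiro_wilk", "auto")
  run_ad <- method == "anderson_darling" || (method == "auto" && n >= 8)

  sw <- if (run_sw) stats::shapiro.test(z)
  ad <- if (run_ad) nortest::ad.test(z)

  if (run_sw && run_ad && ad$p.value < sw$p.value) {
    pick <- ad
    name <- "anderson_darling"
  } else if (run_sw) {
    pick <- sw
    name <- "shapiro_wilk"
  } else {
    pick <- ad
    name <- "anderson_darling"
  }
  new_kc_test(name, unname(pick$statistic), NA_integer_, pick$p.value, size,
              details = list(
                shapiro_wilk_p = if (run_sw) sw$p.value else NA_real_,
                anderson_darling_p = if (run_ad) ad$p.value else NA_real_))
}

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG afterwards.
with_rng_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}
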