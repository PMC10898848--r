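#' Assemble a key-comparison study from per-laboratory measurement results
#'
#' A key comparison (KC) summarises each participating laboratory by a
#' triplet: the measured value \eqn{x_j}, its standard uncertainty
#' \eqn{u_j = u_c(x_j)}, and the number of degrees of freedom \eqn{\nu_j}
#' supporting that uncertainty. `kc_study()` validates a data frame of such
#' results and returns a `kc_study` tibble, the input to every test and
#' estimator in the package.
#'
#' Either `u` (standard uncertainty) or the pair `U` (expanded uncertainty)
#' and `k` (coverage factor) must be present for every row; when `u` is
#' missing it is filled as `U / k`. A finite `dof` marks the reported
#' uncertainty as an *estimate* of the underlying error scale; an infinite
#' `dof` (the default) treats it as known exactly. `include` flags the labs
#' whose results contribute to the consensus value (KCRV); excluded labs
#' still receive degrees of equivalence.
#'
#' @param data Data frame with columns `lab`, `value`, and `u` or
#'   (`U`, `k`); optional `dof` and `include`.
#' @param name Optional study label carried through outputs.
#' @param unit Measurand unit, carried as an opaque string.
#' @return A tibble of class `kc_study` with columns
#'   `lab`, `value`, `u`, `dof`, `include`.
#' @examples
#' kc_study(data.frame(lab = c("A", "B"), value = c(10, 11), u = c(1, 2)))
#' @export
kc_study <- function(data, name = NULL, unit = NULL) {
  stopifnot(is.data.frame(data))
  data <- tibble::as_tibble(data)
  need <- c("lab", "value")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!"u" %in% names(data)) data$u <- NA_real_
  fill <- is.na(data$u)
  if (any(fill)) {
    if (!all(c("U", "k") %in% names(data))) {
      stop("rows without `u` need both `U` and `k`", call. = FALSE)
    }
    bad <- fill & (is.na(data$U) | is.na(data$k))
    if (any(bad)) {
      stop("row(s) ", paste(which(bad), collapse = ", "),
           " have neither `u` nor a complete (`U`, `k`) pair", call. = FALSE)
    }
    data$u[fill] <- data$U[fill] / data$k[fill]
  }
  if (!"dof" %in% names(data)) data$dof <- Inf
  data$dof[is.na(data$dof)] <- Inf
  if (!"include" %in% names(data)) data$include <- TRUE
  data$include[is.na(data$include)] <- TRUE

  data$lab <- as.character(data$lab)
  data$value <- as.numeric(data$value)
  data$u <- as.numeric(data$u)
  data$dof <- as.numeric(data$dof)
  data$include <- as.logical(data$include)

  bad_u <- which(!is.finite(data$u) | data$u <= 0)
  if (length(bad_u)) {
    stop("non-positive or missing standard uncertainty in row(s) ",
         paste(bad_u, collapse = ", "), " (lab ",
         paste(data$lab[bad_u], collapse = ", "), ")", call. = FALSE)
  }
  bad_nu <- which(!(data$dof > 0))
  if (length(bad_nu)) {
    stop("degrees of freedom must be positive in row(s) ",
         paste(bad_nu, collapse = ", "), call. = FALSE)
  }
  dup <- data$lab[duplicated(data$lab)]
  if (length(dup)) {
    stop("duplicate lab label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }

  out <- data[, c("lab", "value", "u", "dof", "include")]
  class(out) <- c("kc_study", class(out))
  attr(out, "kc_name") <- name %||% attr(data, "kc_name") %||% ""
  attr(out, "kc_unit") <- unit %||% attr(data, "kc_unit") %||% ""
  out
}

#' @export
print.kc_study <- function(x, ...) {
  nm <- attr(x, "kc_name")
  un <- attr(x, "kc_unit")
  cat(sprintf("<kc_study> %s%s: %d labs, %d included in KCRV\n",
              if (nzchar(nm)) nm else "(unnamed)",
              if (nzchar(un)) paste0(" [", un, "]") else "",
              nrow(x), sum(x$include)))
  NextMethod()
}

#' Included subset of a study
#'
#' @param study A `kc_study`.
#' @return The rows with `include == TRUE`, as a `kc_study`.
#' @export
kc_included <- function(study) {
  check_kc_study(study)
  out <- study[study$include, , drop = FALSE]
  attributes(out)[c("kc_name", "kc_unit")] <-
    attributes(study)[c("kc_name", "kc_unit")]
  out
}

#' Mark every laboratory as included in the KCRV
#'
#' Inclusion is a substantive choice made upstream of any statistics; this
#' helper supports re-analyses that deliberately retain all results.
#'
#' @param study A `kc_study`.
#' @return The study with all `include` flags set to `TRUE`.
#' @export
kc_include_all <- function(study) {
  check_kc_study(study)
  study$include <- TRUE
  study
}

check_kc_study <- function(study, n_min = 0L) {
  if (!inherits(study, "kc_study")) {
    stop("expected a `kc_study`; see ?kc_study", call. = FALSE)
  }
  n_inc <- sum(study$include)
  if (n_inc < n_min) {
    stop("needs at least ", n_min, " included results; study has ", n_inc,
         call. = FALSE)
  }
  invisible(study)
}

#' Read a key-comparison study from CSV
#'
#' Expects one row per laboratory. Column names are configurable through
#' `dialect`, a named character vector mapping the canonical names
#' `lab`, `value`, `u`, `U`, `k`, `dof`, `include` to the names used in the
#' file. `u` may be omitted where (`U`, `k`) are present (the loader stores
#' `U / k`); a missing `dof` column means all uncertainties are treated as
#' exact (infinite degrees of freedom); a missing `include` column includes
#' every laboratory.
#'
#' @param path CSV file path.
#' @param dialect Named character vector of column-name overrides, e.g.
#'   `c(value = "x", u = "u_std")`.
#' @inheritParams kc_study
#' @return A `kc_study`.
#' @export
read_kc_csv <- function(path, dialect = character(), name = NULL, unit = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  canonical <- c("lab", "value", "u", "U", "k", "dof", "include")
  map <- stats::setNames(canonical, canonical)
  map[names(dialect)] <- dialect
  present <- map[map %in% names(raw)]
  dat <- raw[, present, drop = FALSE]
  names(dat) <- names(present)
  kc_study(dat, name = name %||% sub("\\.csv$", "", basename(path)),
           unit = unit)
}

#' Write a key-comparison study to CSV
#'
#' @param study A `kc_study`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_kc_csv <- function(study, path) {
  check_kc_study(study)
  out <- as.data.frame(study)
  # Inf does not round-trip through all CSV readers; encode as empty
  out$dof <- ifelse(is.finite(out$dof), out$dof, NA_real_)
  readr::write_csv(out, path)
  invisible(path)
}

#' Effective degrees of freedom implied by a coverage factor
#'
#' Laboratories report expanded uncertainties \eqn{U = k\,u} for a stated
#' coverage probability (usually 95 %). A coverage factor larger than the
#' Gaussian two-sided quantile signals that the lab based its interval on a
#' Student-t distribution with few effective degrees of freedom; inverting
#' the t quantile recovers them. For example \eqn{k = 2.45} at 95 % coverage
#' corresponds to 6 degrees of freedom.
#'
#' @param k Coverage factor (> 0).
#' @param p Coverage probability (default 0.95).
#' @param tol `k` within `tol` of (or below) the Gaussian quantile returns
#'   `Inf`.
#' @return Effective degrees of freedom, rounded to the nearest integer, or
#'   `Inf`.
#' @examples
#' dof_from_coverage_factor(2.45) # 6
#' dof_from_coverage_factor(1.96) # Inf
#' @export
dof_from_coverage_factor <- function(k, p = 0.95, tol = 0.005) {
  stopifnot(length(k) == 1, length(p) == 1)
  if (!is.finite(k) || k <= 0) stop("`k` must be a positive number", call. = FALSE)
  if (p <= 0 || p >= 1) stop("`p` must be in (0, 1)", call. = FALSE)
  q <- (1 + p) / 2
  z <- stats::qnorm(q)
  if (k <= z + tol) return(Inf)
  # qt(q, nu) decreases monotonically in nu from +Inf (nu -> 0) to z
  root <- stats::uniroot(function(nu) stats::qt(q, nu) - k,
                         lower = 0.1, upper = 1e6, tol = 1e-10)$root
  round(root)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
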