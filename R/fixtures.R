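#' Worked key-comparison datasets
#'
#' Eight published key-comparison datasets, stored to full printed precision,
#' with the inclusion flags used in the corresponding consensus analyses:
#'
#' * `K45` — CCQM-K45, mass fraction of tin in tomato paste (mg/kg), 5 labs;
#'   UME excluded. KRISS reported `k = 2.45`, i.e. 6 effective degrees of
#'   freedom, stored in `dof`.
#' * `K145_Zn` — CCQM-K145, zinc in bovine liver (mg/kg), 25 labs, 19
#'   included.
#' * `K145_Ni` — CCQM-K145, nickel in bovine liver (mg/kg), 23 labs, 17
#'   included.
#' * `K88` — CCQM-K88, lead in lead-free solder (mg/kg), 10 labs; the final
#'   report's 5 inclusion flags are stored, but the decision-tree re-analysis
#'   retains all 10 (see [kc_include_all()]).
#' * `K30_1` — CCQM-K30.1, lead in wine (ng/g), 10 labs, all included.
#' * `Zn65` — equivalent activity of Zn-65 (kBq) from linked comparisons
#'   BIPM.RI(II)-K1.Zn-65 + CCRI(II)-K2.Zn-65, 21 labs; BEV, ENEA and SMU
#'   excluded.
#' * `Sr90` — half-life of Sr-90 (days), 11 independent studies, all
#'   included.
#' * `CCEM_RF_K25W` — CCEM.RF-K25.W, effective efficiency of the PTB-1
#'   thermistor power sensor at 36 GHz (dimensionless), 8 labs, all included.
#'
#' Uncertainties printed as expanded (`U`, `k`) pairs are converted to
#' standard uncertainties `U / k` at load time; degrees of freedom are
#' infinite except where a finite value is documented (KRISS in `K45`).
#'
#' @param name Fixture name, one of `"K45"`, `"K145_Zn"`, `"K145_Ni"`,
#'   `"K88"`, `"K30_1"`, `"Zn65"`, `"Sr90"`, `"CCEM_RF_K25W"`.
#' @return A [kc_study()].
#' @examples
#' kc_fixture("K45")
#' @export
kc_fixture <- function(name) {
  tables <- kc_fixture_tables()
  if (!name %in% names(tables)) {
    stop("unknown fixture '", name, "'; valid names: ",
         paste(names(tables), collapse = ", "), call. = FALSE)
  }
  tables[[name]]()
}

kc_fixture_tables <- function() {
  list(
    K45 = function() kc_study(tibble::tibble(
      lab = c("KRISS", "LGC", "LNE", "PTB", "UME"),
      value = c(226.26, 224.6, 230.42, 227.0, 209.8),
      U = c(1.94, 3.0, 5.97, 1.4, 7.6),
      k = c(2.45, 2, 2, 2, 2),
      dof = c(6, Inf, Inf, Inf, Inf),
      include = c(TRUE, TRUE, TRUE, TRUE, FALSE)
    ), name = "CCQM-K45", unit = "mg/kg"),

    K145_Zn = function() kc_study(tibble::tibble(
      lab = c("EXHM", "INRAP", "UNIIM", "LATU", "INACAL", "GLHK", "NMIA",
              "NIM", "KRISS", "LGC", "NMISA", "JSI", "NIST", "UME", "HSA",
              "PTB", "RISE", "SYKE", "INMC", "NRC", "NIMT", "NMIJ", "KEBS",
              "INRIM", "VNIIFTRI"),
      value = c(420.6, 429.71, 436, 453, 453.1, 453.6, 454.1, 454.5, 454.5,
                454.5, 454.5, 455, 456.2, 457, 459, 459.4, 460.5, 460.9, 461,
                462, 462, 462, 474.22, 491.7, 524),
      u = c(11.5, 9.48, 9, 5.6, 8.8, 7.7, 4.2, 5.5, 6.7, 3.9, 6.1, 14, 2.0,
            4, 7.1, 1.7, 3.2, 11.5, 6.5, 5, 13.2, 3, 16.46, 10.0, 16),
      include = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
    ), name = "CCQM-K145 Zn", unit = "mg/kg"),

    K145_Ni = function() kc_study(tibble::tibble(
      lab = c("UNIIM", "NMISA", "EXHM", "NIMT", "JSI", "INMC", "GLHK", "LNE",
              "VNIIFTRI", "NIST", "KRISS", "INACAL", "NMIA", "NIM", "NMIJ",
              "RISE", "NRC", "PTB", "LATU", "LGC", "UME", "HSA", "KEBS"),
      value = c(0.147, 0.902, 1.017, 1.65, 1.93, 1.94, 1.942, 1.958, 1.96,
                1.984, 1.993, 2.01, 2.02, 2.022, 2.05, 2.055, 2.07, 2.077,
                2.08, 2.131, 2.15, 2.18, 4.63),
      u = c(0.016, 0.038, 0.05, 0.06, 0.11, 0.06387, 0.092, 0.075, 0.09,
            0.020, 0.033, 0.06, 0.05, 0.023, 0.02, 0.052, 0.05, 0.035, 0.059,
            0.042, 0.03, 0.08, 0.94),
      include = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE,
                  TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE,
                  TRUE, TRUE, TRUE, FALSE)
    ), name = "CCQM-K145 Ni", unit = "mg/kg"),

    K88 = function() kc_study(tibble::tibble(
      lab = c("INMETRO", "VNIIM", "NIM", "NMIJ", "KRISS", "PTB", "BAM",
              "INTI", "NIST", "NRC"),
      value = c(179, 194.2, 195.8, 196.7, 197.2, 197.9, 198.29, 199, 199.43,
                202.4),
      U = c(4, 10, 2.6, 1.52, 2, 1.9, 0.5, 4, 0.7, 18.6),
      k = rep(2, 10),
      include = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE,
                  FALSE)
    ), name = "CCQM-K88", unit = "mg/kg"),

    K30_1 = function() kc_study(tibble::tibble(
      lab = c("HSA", "NMIA", "LGC", "NMISA", "INMETRO", "CMQ", "INDECOPI",
              "UME", "EXHM", "IJS"),
      value = c(12.3, 12.14, 12.12, 12.08, 11.8, 12.31, 12.16, 11.88, 11.424,
                10.45),
      u = c(0.25, 0.12, 0.155, 0.16, 0.14, 0.06, 0.3, 0.32, 0.153, 0.13)
    ), name = "CCQM-K30.1", unit = "ng/g"),

    Zn65 = function() kc_study(tibble::tibble(
      lab = c("ANSTO", "ASMW", "NIST", "BARC", "BEV", "CMI-IIR", "CNEA",
              "ENEA", "IFIN-HH", "IRA", "IRMM", "KRISS", "LNE-LNHB",
              "LNMRI/IRD", "MKEH", "NMIJ", "NMISA", "NPL", "PTB", "SMU",
              "VNIIM"),
      value = c(29610, 29480, 29840, 29130, 29670, 29850, 30030, 29660,
                29550, 29720, 29661, 29780, 29810, 30040, 29590, 29700,
                29870, 29990, 29710, 29200, 29727),
      u = c(100, 130, 190, 310, 330, 170, 130, 120, 150, 140, 68, 130, 130,
            160, 120, 150, 110, 110, 130, 670, 87),
      include = !(c("ANSTO", "ASMW", "NIST", "BARC", "BEV", "CMI-IIR",
                    "CNEA", "ENEA", "IFIN-HH", "IRA", "IRMM", "KRISS",
                    "LNE-LNHB", "LNMRI/IRD", "MKEH", "NMIJ", "NMISA", "NPL",
                    "PTB", "SMU", "VNIIM") %in% c("BEV", "ENEA", "SMU"))
    ), name = "Zn-65 equivalent activity", unit = "kBq"),

    Sr90 = function() kc_study(tibble::tibble(
      lab = c("WT55", "An58", "Fl65a", "Fl65b", "Ho77", "La78", "Ra83",
              "Ko89", "Ma94", "WL96", "Sc04"),
      value = c(10120, 10700, 10230, 10410, 10636, 10282, 10588, 10665,
                10561, 10495, 10557),
      u = c(150, 580, 150, 330, 88, 12, 91, 37, 14, 4, 11)
    ), name = "Sr-90 half-life", unit = "d"),

    CCEM_RF_K25W = function() kc_study(tibble::tibble(
      lab = c("KRISS", "LNE", "NIST", "NPL", "PTB", "VNIIFTRI", "NIM", "NRC"),
      value = c(0.9143, 0.9157, 0.9184, 0.9167, 0.9153, 0.9160, 0.8360,
                0.9375),
      u = c(0.0104, 0.0018, 0.0064, 0.0060, 0.0031, 0.0079, 0.0072, 0.0130)
    ), name = "CCEM.RF-K25.W 36 GHz", unit = "")
  )
}

#' The late P3KRBiN Zn-65 result
#'
#' A 1993 measurement of the equivalent activity of Zn-65 (28540 ± 89 kBq)
#' originally considered for, then excluded from, the Zn-65 KCRV. Appending
#' it to the included labs of [kc_fixture("Zn65")][kc_fixture] reproduces
#' the re-analysis in which the decision tree switches from Gaussian to
#' Laplace lab effects. Degrees of freedom were not published; the
#' uncertainty is treated as exact.
#'
#' @return A one-row tibble suitable for `rbind`ing onto the `Zn65` fixture.
#' @export
kc_zn65_p3krbin <- function() {
  tibble::tibble(lab = "P3KRBiN", value = 28540, u = 89, dof = Inf,
                 include = TRUE)
}
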