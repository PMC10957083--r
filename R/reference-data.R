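#' Chromium-nickel ostracod acute-toxicity reference data
#'
#' Published single-toxicant acute-toxicity results for chromium and nickel
#' salts against the ostracod *Heterocypris* sp., distributed with the
#' package for examples and validation. `crni_single_mortality()` gives the
#' pooled mortality fraction (three replicates of ten animals per group,
#' blank-control mortality zero) at each of five design concentrations and
#' four census times. Concentrations are as dosed — mg/L of
#' K2Cr2O7 respectively Ni(NO3)2 — with no conversion to elemental metal.
#'
#' @return `crni_single_mortality()`: data.frame with columns `element`
#'   ("Cr"/"Ni"), `time_h`, `conc` (mg/L) and `mortality` (fraction).
#' @examples
#' d <- subset(crni_single_mortality(), element == "Cr" & time_h == 96)
#' fit_crc(d, "Weibull")
#' @export
crni_single_mortality <- function() {
  conc_cr <- c(0.2, 0.59, 1.73, 5.1, 15)
  conc_ni <- c(3, 5.87, 11.49, 22.48, 44)
  mort <- rbind(
    # Cr: rows = group 1..5, cols = 24/48/72/96 h (%)
    Cr = c(3, 13, 20, 23,
           10, 23, 37, 47,
           20, 33, 43, 53,
           37, 50, 63, 77,
           67, 83, 100, 100),
    Ni = c(7, 13, 23, 37,
           23, 30, 40, 57,
           30, 43, 67, 90,
           43, 67, 87, 93,
           67, 83, 100, 100)
  )
  out <- do.call(rbind, lapply(c("Cr", "Ni"), function(el) {
    m <- matrix(mort[el, ], ncol = 4, byrow = TRUE)
    conc <- if (el == "Cr") conc_cr else conc_ni
    do.call(rbind, lapply(1:4, function(j) {
      data.frame(element = el, time_h = c(24, 48, 72, 96)[j],
                 conc = conc, mortality = m[, j] / 100)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @rdname crni_single_mortality
#' @details `crni_reference_fits()` gives the published CRC fits for the
#'   same data: selected family, parameters, fit quality and the LC10, LC30
#'   and LC50 point estimates (mg/L). Parameters are printed to two decimals,
#'   so quantities recomputed from them can differ from the tabulated values
#'   in the last digit; the BCW rows are most affected because their LCx are
#'   very sensitive to the rounded gamma.
#' @return `crni_reference_fits()`: data.frame with columns `element`,
#'   `time_h`, `family`, `alpha`, `beta`, `gamma`, `r2`, `mae`, `lc10`,
#'   `lc30`, `lc50`.
#' @export
crni_reference_fits <- function() {
  out <- data.frame(
    element = rep(c("Cr", "Ni"), each = 4),
    time_h = rep(c(24, 48, 72, 96), 2),
    family = c("GL", "Weibull", "Weibull", "Weibull",
               "BCW", "BCW", "Weibull", "GL"),
    alpha = c(-5.91, -1.18, -0.72, -0.4, -3.13, -3.17, -2.48, -9.44),
    beta = c(4.31, 1.38, 1.3, 1.21, 0.88, 1.31, 2.39, 8.94),
    gamma = c(0.34, NA, NA, NA, -0.03, -0.16, NA, 0.2),
    r2 = c(0.99, 0.98, 0.94, 0.96, 0.98, 0.99, 0.99, 0.98),
    mae = c(0.01, 0.03, 0.06, 0.05, 0.03, 0.01, 0.01, 0.023),
    lc10 = c(0.63, 0.17, 0.07, 0.03, 2.74, 2.1, 1.25, 0.59),
    lc30 = c(3.59, 1.29, 0.58, 0.3, 11.57, 6.54, 4.03, 2.42),
    lc50 = c(8.5, 3.92, 1.86, 1.07, 25.94, 13.37, 7.65, 4.7)
  )
  out
}

#' @rdname crni_single_mortality
#' @details `crni_mixture_results()` gives the measured 96-h mixture LC30
#'   and LC50 (mg/L total concentration) for the eight chromium-nickel
#'   design ratios, together with the published synergistic ratios relative
#'   to each single metal.
#' @return `crni_mixture_results()`: data.frame with columns `combination`,
#'   `lc30`, `lc50`, `sr_cr`, `sr_ni`.
#' @export
crni_mixture_results <- function() {
  data.frame(
    combination = c("EECR 10", "EECR 30", "EECR 50",
                    paste("EquRay", 1:5)),
    lc30 = c(0.46, 0.24, 0.16, 0.46, 0.36, 0.24, 0.24, 0.22),
    lc50 = c(1.07, 0.66, 0.56, 1.48, 1.25, 1.03, 0.97, 0.74),
    sr_cr = c(1.01, 1.63, 1.93, 0.73, 0.86, 1.04, 1.1, 1.45),
    sr_ni = c(4.41, 7.16, 8.45, 3.19, 3.75, 4.57, 4.84, 6.37)
  )
}
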