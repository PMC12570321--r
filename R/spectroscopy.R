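#' Relative quantum yield from fluorescence-vs-absorbance slopes
#'
#' Integrated fluorescence is regressed on integrated absorbance for a
#' dilution series of the unknown and of a standard of known quantum yield
#' (ordinary least squares, free intercept). The unknown's quantum yield is
#' \code{phi_standard * m_unknown / m_standard}, the ratio of the two fitted
#' slopes. Absorbances above 0.1 leave the linear (inner-filter-free) regime
#' and trigger a warning.
#'
#' @param unknown,standard data frames (or 2-column matrices) with columns
#'   \code{A} (integrated absorbance) and \code{F} (integrated fluorescence),
#'   one row per dilution; at least 2 dilutions each.
#' @param phi_standard quantum yield of the standard (e.g. 0.95 for
#'   fluorescein in 0.1 M NaOH).
#' @return list with \code{phi_unknown}, \code{phi_standard},
#'   \code{slope_unknown}, \code{slope_standard}, and the two intercepts.
#' @export
quantum_yield <- function(unknown, standard, phi_standard) {
  as_af <- function(x, what) {
    x <- as.data.frame(x)
    if (!all(c("A", "F") %in% names(x))) names(x)[1:2] <- c("A", "F")
    if (nrow(x) < 2) stop("need >= 2 dilutions for the ", what, " series")
    x
  }
  u <- as_af(unknown, "unknown"); s <- as_af(standard, "standard")
  if (any(c(u$A, s$A) > 0.1))
    warning("absorbance > 0.1: outside the linear regime, slopes may be biased")
  fu <- stats::lm(F ~ A, data = u)
  fs <- stats::lm(F ~ A, data = s)
  m_u <- unname(coef(fu)[["A"]]); m_s <- unname(coef(fs)[["A"]])
  if (!is.finite(m_s) || m_s <= 0)
    stop("standard slope is zero or negative; cannot form slope ratio")
  list(phi_unknown = phi_standard * m_u / m_s,
       phi_standard = phi_standard,
       slope_unknown = m_u, slope_standard = m_s,
       intercept_unknown = unname(coef(fu)[[1]]),
       intercept_standard = unname(coef(fs)[[1]]))
}

#' Molar extinction coefficient by Beer's law
#'
#' Fits \code{A = epsilon * b * c} by ordinary least squares of absorbance on
#' concentration (free intercept, reported so blank errors are visible);
#' \code{epsilon} is the fitted slope divided by the path length.
#'
#' @param points data frame (or 2-column matrix) with columns
#'   \code{concentration} (molar) and \code{absorbance} (a.u.); >= 2 rows.
#' @param path_length cuvette path length b in cm (> 0).
#' @return list with \code{epsilon} (M^-1 cm^-1), \code{path_length},
#'   \code{intercept} and \code{r_squared}.
#' @export
extinction_coefficient <- function(points, path_length = 1) {
  if (path_length <= 0) stop("path_length must be > 0")
  x <- as.data.frame(points)
  if (!all(c("concentration", "absorbance") %in% names(x)))
    names(x)[1:2] <- c("concentration", "absorbance")
  if (nrow(x) < 2) stop("need >= 2 concentrations")
  fit <- stats::lm(absorbance ~ concentration, data = x)
  eps <- unname(coef(fit)[["concentration"]]) / path_length
  if (!is.finite(eps) || eps <= 0)
    stop("fitted extinction coefficient is not positive")
  list(epsilon = eps, path_length = path_length,
       intercept = unname(coef(fit)[[1]]),
       r_squared = suppressWarnings(summary(fit)$r.squared))
}

#' Dye:dextran labeling ratio from absorbance
#'
#' Dye molarity is \code{A / (epsilon * b)} (Beer's law); dextran molarity is
#' mass concentration over molecular weight. Their quotient is the average
#' number of dye molecules per dextran polymer.
#'
#' @param absorbance blank-corrected absorbance at the dye maximum (a.u.).
#' @param epsilon molar extinction coefficient (M^-1 cm^-1).
#' @param path path length in cm.
#' @param dextran_mass_conc dextran concentration in mg/mL.
#' @param dextran_mw dextran molecular weight in kDa.
#' @return dye:dextran molar ratio (dimensionless).
#' @export
labeling_ratio <- function(absorbance, epsilon, path, dextran_mass_conc,
                           dextran_mw) {
  args <- c(absorbance, epsilon, path, dextran_mass_conc, dextran_mw)
  if (any(!is.finite(args)) || any(args <= 0))
    stop("all arguments must be positive and finite")
  dye_molar <- absorbance / (epsilon * path)
  dextran_molar <- dextran_mass_conc / (dextran_mw * 1000)  # g/L over g/mol
  dye_molar / dextran_molar
}
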