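#' Ratio-to-pH calibration curve
#'
#' A four-parameter logistic on the ratio scale, with provenance: either
#' fitted to a full multi-pH ratio titration (\code{mode = "full"}) or
#' constructed by the single-anchor procedure (\code{mode = "anchored"}):
#' one fixed-cell ratio measured at a known anchor pH is used to rescale a
#' solution ratio titration of the same probes across pH 3.5-7.4.
#'
#' @name calibration_curve
#' @keywords internal
new_calibration_curve <- function(bottom, top, pka, slope, mode,
                                  valid_ph_range, anchor = NULL,
                                  guard_frac = 0.01, source = list()) {
  structure(list(bottom = bottom, top = top, pka = pka, slope = slope,
                 mode = mode, anchor = anchor,
                 valid_ph_range = as.numeric(valid_ph_range),
                 valid_ratio_range = sort(c(bottom, top)),
                 guard_frac = guard_frac, source = source),
            class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> mode=%s\n", x$mode))
  cat(sprintf("  bottom %.5g  top %.5g  pKa %.4f  slope %.4f\n",
              x$bottom, x$top, x$pka, x$slope))
  cat(sprintf("  valid pH [%.2f, %.2f], valid ratio (%.4g, %.4g)\n",
              x$valid_ph_range[1], x$valid_ph_range[2],
              x$valid_ratio_range[1], x$valid_ratio_range[2]))
  if (!is.null(x$anchor))
    cat(sprintf("  anchor: ratio %.5g at pH %.2f\n",
                x$anchor$ratio, x$anchor$ph))
  invisible(x)
}

#' Build a calibration curve from a full ratio titration
#'
#' Fits the four-parameter logistic to fixed-cell (or solution) ratios
#' measured across at least 4 pH buffers; the valid pH range is the span of
#' the input buffers.
#'
#' @param ratios \code{titration_series} with \code{assay = "ratio"} (or any
#'   data frame with \code{ph}, \code{signal} on the ratio scale).
#' @param guard_frac near-asymptote guard band as a fraction of top - bottom
#'   used by \code{\link{interpolate_ph}}.
#' @return a \code{calibration_curve} with \code{mode = "full"}.
#' @export
build_calibration_full <- function(ratios, guard_frac = 0.01) {
  fit <- fit_sigmoid(ratios)
  if (!isTRUE(fit$converged))
    stop("calibration fit did not converge: ", fit$message)
  df <- as.data.frame(ratios)
  new_calibration_curve(fit$bottom, fit$top, fit$pka, fit$slope,
                        mode = "full", valid_ph_range = range(df$ph),
                        guard_frac = guard_frac,
                        source = list(n_points = nrow(df), fit = fit))
}

#' Build a calibration curve from a single anchor measurement
#'
#' The simplified calibration: ratios across the full pH range are generated
#' from one fixed-cell ratio at a known anchor pH (default 5.0) by scaling a
#' solution ratio titration of the same probe pair:
#' \code{R(p) = anchor_ratio * R_sol(p) / R_sol(anchor_ph)} on a 0.1-pH grid
#' over 3.5-7.4. The generated points are refit to the four-parameter
#' logistic and the plateaus rescaled so the curve passes through the anchor
#' exactly; under exact scaling the refit reproduces the scaled solution
#' curve.
#'
#' @param anchor_ratio fixed-cell ratio measured at \code{anchor_ph} (> 0).
#' @param anchor_ph anchor buffer pH (default 5.0).
#' @param solution a solution ratio titration: \code{titration_series}
#'   (\code{assay = "ratio"}), a \code{sigmoid_fit}, or a
#'   \code{probe_model}-like parameter set on the ratio scale.
#' @param ph_grid pH grid for the generated ratios.
#' @param guard_frac see \code{\link{build_calibration_full}}.
#' @return a \code{calibration_curve} with \code{mode = "anchored"}.
#' @export
build_calibration_anchored <- function(anchor_ratio, anchor_ph = 5.0,
                                       solution,
                                       ph_grid = seq(3.5, 7.4, by = 0.1),
                                       guard_frac = 0.01) {
  if (!is.finite(anchor_ratio) || anchor_ratio <= 0)
    stop("anchor_ratio must be positive")
  sol_fit <- if (inherits(solution, "data.frame")) {
    df <- as.data.frame(solution)
    if (anchor_ph < min(df$ph) || anchor_ph > max(df$ph))
      stop("anchor_ph ", anchor_ph, " is outside the solution titration range [",
           min(df$ph), ", ", max(df$ph), "]")
    fit_sigmoid(solution)
  } else sigmoid_params(solution)
  r_anchor <- sigmoid_value(sol_fit, anchor_ph)
  if (!is.finite(r_anchor) || r_anchor <= 0)
    stop("solution ratio at the anchor pH is <= 0; cannot scale")

  k <- anchor_ratio / r_anchor
  gen <- titration_series(ph_grid, k * sigmoid_value(sol_fit, ph_grid),
                          assay = "ratio")
  fit <- fit_sigmoid(gen)
  if (!isTRUE(fit$converged))
    stop("anchored calibration refit did not converge: ", fit$message)
  # exact pass through the anchor, independent of optimizer tolerance
  adj <- anchor_ratio / sigmoid_value(fit, anchor_ph)
  new_calibration_curve(fit$bottom * adj, fit$top * adj, fit$pka, fit$slope,
                        mode = "anchored", valid_ph_range = range(ph_grid),
                        anchor = list(ph = anchor_ph, ratio = anchor_ratio),
                        guard_frac = guard_frac,
                        source = list(scale_factor = k, fit = fit))
}

#' Interpolate measured ratios to pH
#'
#' Closed-form inversion of the calibration sigmoid:
#' \code{pH = pKa + (1/slope) * log10((top - r) / (r - bottom))}. Ratios at
#' or beyond the asymptotes - within a guard band of
#' \code{guard_frac * (top - bottom)} - are flagged non-interpolatable with
#' the side recorded; interpolations landing outside the calibration's valid
#' pH range are returned but flagged extrapolated. Flags are data, not
#' errors.
#'
#' @param ratio numeric vector of measured ratios.
#' @param curve a \code{calibration_curve}.
#' @return data frame with columns \code{ratio}, \code{ph}, \code{flag}
#'   (one of \code{ok}, \code{extrapolated}, \code{above_range},
#'   \code{below_range}).
#' @export
interpolate_ph <- function(ratio, curve) {
  stopifnot(inherits(curve, "calibration_curve"))
  span <- curve$top - curve$bottom
  guard <- curve$guard_frac * span
  ph <- rep(NA_real_, length(ratio))
  flag <- rep("ok", length(ratio))

  above <- ratio >= curve$top - guard
  below <- ratio <= curve$bottom + guard
  ok <- !above & !below & is.finite(ratio)
  ph[ok] <- curve$pka + (1 / curve$slope) *
    log10((curve$top - ratio[ok]) / (ratio[ok] - curve$bottom))
  flag[above] <- "above_range"
  flag[below] <- "below_range"
  flag[!above & !below & !is.finite(ratio)] <- "above_range"
  out_of_ph <- ok & (ph < curve$valid_ph_range[1] |
                       ph > curve$valid_ph_range[2])
  flag[out_of_ph] <- "extrapolated"
  data.frame(ratio = ratio, ph = ph, flag = flag,
             stringsAsFactors = FALSE)
}

#' Persist / load a calibration curve as JSON
#'
#' @param curve a \code{calibration_curve}.
#' @param path JSON file path.
#' @return \code{read_calibration}: the restored \code{calibration_curve}.
#' @export
write_calibration <- function(curve, path) {
  stopifnot(inherits(curve, "calibration_curve"))
  obj <- list(bottom = curve$bottom, top = curve$top, pka = curve$pka,
              slope = curve$slope, mode = curve$mode, anchor = curve$anchor,
              valid_ph_range = curve$valid_ph_range,
              guard_frac = curve$guard_frac,
              package_version = as.character(utils::packageVersion("lysoratio")))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_calibration_curve(obj$bottom, obj$top, obj$pka, obj$slope,
                        mode = obj$mode,
                        valid_ph_range = obj$valid_ph_range,
                        anchor = if (!is.null(obj$anchor))
                          list(ph = obj$anchor$ph, ratio = obj$anchor$ratio),
                        guard_frac = obj$guard_frac)
}
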