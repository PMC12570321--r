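#' Evaluate the four-parameter logistic pH response
#'
#' \code{bottom + (top - bottom) / (1 + 10^(slope * (ph - pka)))}. With
#' \code{slope > 0} the curve is acid-bright: it tends to \code{top} as pH
#' decreases and to \code{bottom} as pH increases.
#'
#' @param object a \code{probe_model}, \code{sigmoid_fit},
#'   \code{calibration_curve}, or any list with fields \code{bottom},
#'   \code{top}, \code{pka}, \code{slope}.
#' @param ph numeric vector of pH values.
#' @return numeric vector of signals (same length as \code{ph}).
#' @export
sigmoid_value <- function(object, ph) {
  p <- sigmoid_params(object)
  stopifnot(is.numeric(ph))
  p$bottom + (p$top - p$bottom) / (1 + 10^(p$slope * (ph - p$pka)))
}

#' Fit a pH titration to the four-parameter logistic
#'
#' Least-squares fit of \code{signal ~ bottom + (top - bottom) /
#' (1 + 10^(slope * (ph - pka)))} by Levenberg-Marquardt. Replicates enter as
#' individual points so parameter standard errors reflect replicate scatter.
#' Starting values are deterministic: \code{bottom = min(signal)},
#' \code{top = max(signal)}, \code{pka} = pH of the point nearest mid-range,
#' slope sign from the rank correlation of signal with pH. The fit is
#' canonicalized to \code{top >= bottom} (swapping plateaus and negating the
#' slope leaves the curve unchanged).
#'
#' @param series a \code{titration_series} or data frame with columns
#'   \code{ph} and \code{signal}.
#' @param weights optional per-point weights passed to the least-squares fit.
#' @return A \code{sigmoid_fit}: list with \code{bottom}, \code{top},
#'   \code{pka}, \code{slope}, per-parameter standard errors \code{se},
#'   residual standard deviation \code{sigma}, \code{converged},
#'   \code{extrapolated} (pKa outside the fitted pH range by more than 1
#'   unit), and \code{message}.
#' @export
fit_sigmoid <- function(series, weights = NULL) {
  df <- as.data.frame(series)
  if (!all(c("ph", "signal") %in% names(df)))
    stop("series must have columns 'ph' and 'signal'")
  df <- df[is.finite(df$ph) & is.finite(df$signal), , drop = FALSE]
  if (length(unique(df$ph)) < 4)
    stop("need >= 4 distinct pH values to fit the 4-parameter sigmoid")
  if (diff(range(df$signal)) == 0)
    stop("degenerate input: signal is constant, sigmoid fit is undefined")

  lo <- min(df$signal); hi <- max(df$signal)
  mid <- (lo + hi) / 2
  pka0 <- df$ph[which.min(abs(df$signal - mid))]
  slope0 <- if (cor(df$ph, df$signal, method = "spearman") < 0) 1 else -1
  start <- list(bottom = lo, top = hi, pka = pka0, slope = slope0)

  args <- list(
    signal ~ bottom + (top - bottom) / (1 + 10^(slope * (ph - pka))),
    data = df, start = start,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  if (!is.null(weights)) args$weights <- weights
  fit <- tryCatch(do.call(minpack.lm::nlsLM, args), error = function(e) e)

  if (inherits(fit, "error")) {
    out <- c(start, list(
      se = c(bottom = NA_real_, top = NA_real_, pka = NA_real_,
             slope = NA_real_),
      sigma = NA_real_, converged = FALSE, extrapolated = NA,
      n = nrow(df), ph_range = range(df$ph),
      message = conditionMessage(fit)))
    class(out) <- "sigmoid_fit"
    return(out)
  }

  cf <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) setNames(rep(NA_real_, 4), names(cf)))
  if (cf[["top"]] < cf[["bottom"]]) {   # canonical form
    cf[c("bottom", "top")] <- cf[c("top", "bottom")]
    se[c("bottom", "top")] <- se[c("top", "bottom")]
    cf[["slope"]] <- -cf[["slope"]]
  }
  rng <- range(df$ph)
  out <- list(
    bottom = cf[["bottom"]], top = cf[["top"]], pka = cf[["pka"]],
    slope = cf[["slope"]],
    se = se[c("bottom", "top", "pka", "slope")],
    sigma = summary(fit)$sigma,
    converged = fit$convInfo$isConv %||% TRUE,
    extrapolated = cf[["pka"]] < rng[1] - 1 || cf[["pka"]] > rng[2] + 1,
    n = nrow(df), ph_range = rng, message = "ok")
  class(out) <- "sigmoid_fit"
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("<sigmoid_fit>",
      if (isTRUE(x$converged)) "converged" else "NOT CONVERGED", "\n")
  cat(sprintf("  bottom %.5g (se %.2g)  top %.5g (se %.2g)\n",
              x$bottom, x$se[["bottom"]], x$top, x$se[["top"]]))
  cat(sprintf("  pKa %.4f (se %.2g)  slope %.4f (se %.2g)\n",
              x$pka, x$se[["pka"]], x$slope, x$se[["slope"]]))
  if (isTRUE(x$extrapolated)) cat("  warning: pKa extrapolated beyond data\n")
  invisible(x)
}

#' Fold-change of probe signal between two pH values
#'
#' Evaluates the fitted sigmoid at \code{ph_lo} and \code{ph_hi} and returns
#' \code{max/min} of the two values together with which pH is brighter.
#'
#' @param fit a \code{sigmoid_fit} or \code{probe_model}.
#' @param ph_lo,ph_hi the two pH values to compare (\code{ph_lo < ph_hi}).
#' @return list with \code{fold} (>= 1, or NA when a value is <= 0),
#'   \code{brighter} ("lo", "hi" or "equal"), the two signal values, and
#'   \code{undefined} flag.
#' @export
dynamic_range <- function(fit, ph_lo, ph_hi) {
  if (!(ph_lo < ph_hi)) stop("ph_lo must be < ph_hi")
  v_lo <- sigmoid_value(fit, ph_lo)
  v_hi <- sigmoid_value(fit, ph_hi)
  if (min(v_lo, v_hi) <= 0)
    return(list(fold = NA_real_, brighter = NA_character_,
                value_lo = v_lo, value_hi = v_hi, undefined = TRUE))
  list(fold = max(v_lo, v_hi) / min(v_lo, v_hi),
       brighter = if (v_lo > v_hi) "lo" else if (v_hi > v_lo) "hi" else "equal",
       value_lo = v_lo, value_hi = v_hi, undefined = FALSE)
}
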