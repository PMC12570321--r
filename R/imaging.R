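#' Background-correct a stack by per-plane 5th-percentile subtraction
#'
#' For each channel and each plane independently, the 5th-percentile pixel
#' value of that plane is subtracted and negatives are clipped to 0. The
#' subtracted values are recorded in \code{meta$background_subtracted}
#' (channel x plane matrix). Idempotent on planes whose 5th percentile is
#' already 0.
#'
#' @param stack an \code{image_stack}.
#' @param probs percentile to subtract (default 0.05).
#' @return the corrected \code{image_stack} with
#'   \code{meta$background_corrected = TRUE}.
#' @export
background_correct <- function(stack, probs = 0.05) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels[[1]])
  log_mat <- matrix(NA_real_, length(stack$channels), d[1],
                    dimnames = list(names(stack$channels), NULL))
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    for (p in seq_len(d[1])) {
      q <- stats::quantile(a[p, , ], probs, names = FALSE)
      a[p, , ] <- pmax(a[p, , ] - q, 0)
      log_mat[ch, p] <- q
    }
    stack$channels[[ch]] <- a
  }
  stack$meta$background_corrected <- TRUE
  stack$meta$background_subtracted <- log_mat
  stack
}

#' Sum projection of a z-stack
#'
#' Pixel-wise sum of all planes per channel, accumulated in doubles so no
#' 16-bit overflow can occur. Warns when the stack has not been
#' background-corrected.
#'
#' @param stack an \code{image_stack}.
#' @return named list of (rows x cols) matrices, one per channel, with
#'   attributes \code{pixel_size} and \code{z_spacing}.
#' @export
sum_project <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (!isTRUE(stack$meta$background_corrected))
    warning("projecting a stack that has not been background-corrected")
  out <- lapply(stack$channels, function(a) {
    apply(a, c(2, 3), sum)
  })
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "z_spacing") <- stack$z_spacing
  out
}

# Otsu threshold over the exact empirical value set: candidate thresholds
# are the observed values; the one maximizing between-class variance wins
# (lowest such value on ties). Mask convention is pixels >= threshold, so
# the returned threshold is the smallest value of the upper class.
otsu_threshold <- function(x) {
  v <- sort(unique(as.numeric(x)))
  if (length(v) < 2) return(v[1])
  cnt <- as.numeric(tabulate(match(as.numeric(x), v)))
  n <- sum(cnt)
  w <- cumsum(cnt)
  s <- cumsum(cnt * v)
  tot <- s[length(s)]
  k <- seq_len(length(v) - 1)       # split after value k
  mu1 <- s[k] / w[k]
  mu2 <- (tot - s[k]) / (n - w[k])
  bcv <- w[k] * (n - w[k]) * (mu1 - mu2)^2
  v[which.max(bcv) + 1]
}

#' Build a binary mask from the pH-independent channel
#'
#' @param reference_image matrix (typically a sum projection or plane of the
#'   pH-independent channel).
#' @param method "otsu" (default; between-class-variance threshold on the
#'   empirical histogram), "fixed" (use \code{value}), or "percentile"
#'   (threshold at the \code{value}-th percentile, 0-100).
#' @param value threshold value (fixed) or percentile (percentile method).
#' @return logical matrix of pixels >= threshold, with attributes
#'   \code{threshold} and \code{method}. An empty mask triggers a warning;
#'   downstream results on it are flagged, not errors.
#' @export
make_mask <- function(reference_image,
                      method = c("otsu", "fixed", "percentile"),
                      value = NULL) {
  method <- match.arg(method)
  thr <- switch(method,
    otsu = otsu_threshold(reference_image),
    fixed = {
      if (is.null(value)) stop("method 'fixed' requires a threshold value")
      value
    },
    percentile = {
      if (is.null(value)) stop("method 'percentile' requires a percentile")
      stats::quantile(reference_image, value / 100, names = FALSE)
    })
  mask <- reference_image >= thr
  if (!any(mask)) warning("mask is empty at threshold ", thr)
  attr(mask, "threshold") <- thr
  attr(mask, "method") <- method
  mask
}

#' Per-field ratio and pH
#'
#' Integrated masked intensity of the pH-dependent channel divided by that
#' of the pH-independent channel, on the sum projection (a stack input is
#' projected first). With a calibration the ratio is interpolated to pH.
#'
#' @param x an \code{image_stack} or a projection list from
#'   \code{\link{sum_project}}.
#' @param mask logical matrix congruent with the projection; when NULL an
#'   Otsu mask is built from the pH-independent projection.
#' @param calibration optional \code{calibration_curve}.
#' @return one-row data frame: \code{ratio}, \code{ph}, \code{flag},
#'   \code{n_pixels}, \code{threshold}. Empty mask gives NA ratio with flag
#'   \code{empty_mask}.
#' @export
field_ratio <- function(x, mask = NULL, calibration = NULL) {
  proj <- if (inherits(x, "image_stack")) sum_project(x) else x
  if (!all(c("ph_dependent", "ph_independent") %in% names(proj)))
    stop("projection must carry channels 'ph_dependent' and 'ph_independent'")
  if (is.null(mask)) mask <- make_mask(proj$ph_independent)
  thr <- attr(mask, "threshold") %||% NA_real_
  if (!any(mask))
    return(data.frame(ratio = NA_real_, ph = NA_real_, flag = "empty_mask",
                      n_pixels = 0L, threshold = thr))
  num <- sum(proj$ph_dependent[mask])
  den <- sum(proj$ph_independent[mask])
  if (den <= 0)
    return(data.frame(ratio = NA_real_, ph = NA_real_, flag = "zero_reference",
                      n_pixels = sum(mask), threshold = thr))
  ratio <- num / den
  ph <- NA_real_; flag <- "ok"
  if (!is.null(calibration)) {
    ip <- interpolate_ph(ratio, calibration)
    ph <- ip$ph; flag <- ip$flag
  }
  data.frame(ratio = ratio, ph = ph, flag = flag, n_pixels = sum(mask),
             threshold = thr)
}

#' Per-object integrated intensities, ratios and pH
#'
#' For each segmented object, integrates both channels over the object's
#' pixels (in the object's plane), computes the pH-sensitive /
#' pH-independent ratio and, with a calibration, interpolates it to pH;
#' interpolation flags are propagated.
#'
#' @param records output of \code{\link{segment_objects}} (its \code{labels}
#'   attribute identifies the pixels).
#' @param dep_plane,indep_plane matching background-corrected planes of the
#'   two channels.
#' @param calibration optional \code{calibration_curve}.
#' @return \code{records} with added columns \code{intensity_dep},
#'   \code{intensity_indep}, \code{ratio}, \code{ph}, \code{flag}.
#' @export
object_ratios <- function(records, dep_plane, indep_plane,
                          calibration = NULL) {
  labels <- attr(records, "labels")
  if (is.null(labels)) stop("records must carry a 'labels' attribute")
  n <- nrow(records)
  records$intensity_dep <- numeric(n)
  records$intensity_indep <- numeric(n)
  for (i in seq_len(n)) {
    w <- labels == records$id[i]
    records$intensity_dep[i] <- sum(dep_plane[w])
    records$intensity_indep[i] <- sum(indep_plane[w])
  }
  records$ratio <- ifelse(records$intensity_indep > 0,
                          records$intensity_dep / records$intensity_indep,
                          NA_real_)
  if (!is.null(calibration) && n > 0) {
    ip <- interpolate_ph(records$ratio, calibration)
    records$ph <- ip$ph
    records$flag <- ip$flag
    records$flag[is.na(records$ratio)] <- "zero_reference"
  } else {
    records$ph <- rep(NA_real_, n)
    records$flag <- ifelse(is.na(records$ratio), "zero_reference", "ok")
  }
  records
}

#' Quantify every plane of a stack per object
#'
#' Runs \code{\link{segment_objects}} on each plane of the pH-independent
#' channel and \code{\link{object_ratios}} against the matching pH-dependent
#' plane, binding records across planes (objects are per-plane; no 3-D
#' merging, matching the per-plane quantification protocol).
#'
#' @param stack background-corrected \code{image_stack}.
#' @param calibration optional \code{calibration_curve}.
#' @param threshold_method,threshold_value threshold choice; the threshold
#'   is computed once from all planes of the pH-independent channel and
#'   applied to every plane (one threshold per experiment, as in manual
#'   thresholding practice; per-plane automatic thresholds collapse to the
#'   background level on planes without puncta).
#' @param ... passed to \code{\link{segment_objects}} (split rule, filters,
#'   units).
#' @return data frame of per-object records across planes; attribute
#'   \code{discarded} binds the per-plane discard tables; attribute
#'   \code{threshold} the stack-wide threshold used.
#' @export
quantify_objects <- function(stack, calibration = NULL,
                             threshold_method = "otsu",
                             threshold_value = NULL, ...) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$channels$ph_independent)
  thr <- switch(threshold_method,
    otsu = otsu_threshold(stack$channels$ph_independent),
    fixed = threshold_value %||%
      stop("threshold_method 'fixed' needs threshold_value"),
    percentile = stats::quantile(stack$channels$ph_independent,
                                 threshold_value / 100, names = FALSE),
    stop("unknown threshold_method: ", threshold_method))
  out <- vector("list", d[1])
  disc <- vector("list", d[1])
  for (p in seq_len(d[1])) {
    indep <- stack$channels$ph_independent[p, , ]
    dep <- stack$channels$ph_dependent[p, , ]
    recs <- segment_objects(indep, pixel_size = stack$pixel_size,
                            plane_index = p, threshold_method = "fixed",
                            threshold_value = thr, ...)
    disc[[p]] <- attr(recs, "discarded")
    out[[p]] <- object_ratios(recs, dep, indep, calibration)
  }
  res <- do.call(rbind, out)
  attr(res, "discarded") <- do.call(rbind, disc)
  attr(res, "threshold") <- thr
  rownames(res) <- NULL
  res
}

# Fixed blue -> green -> red lookup table (256 RGB rows in [0, 1]); blue is
# the least-acidic end of the displayed ratio range.
ratio_lut <- function(n = 256) {
  half <- n %/% 2
  t1 <- seq(0, 1, length.out = half)
  t2 <- seq(0, 1, length.out = n - half)
  rbind(cbind(r = 0, g = t1, b = 1 - t1),
        cbind(r = t2, g = 1 - t2, b = 0))
}

#' Color-coded pixel-by-pixel ratio image
#'
#' A mask from the pH-independent channel is applied to both channels, a
#' 7x7 Gaussian filter (sigma = 7/6 px, kernel truncated to exactly 7x7) is
#' applied, and the pixel-wise ratio inside the mask is clipped to
#' [min_ratio, max_ratio] and mapped linearly onto a fixed blue-green-red
#' lookup table (blue = mildly acidic end, red = most acidic for an
#' acid-bright probe). Pixels outside the mask are black.
#'
#' @param x \code{image_stack} (sum-projected internally) or projection
#'   list.
#' @param min_ratio,max_ratio display range, e.g. the fixed-cell ratios at
#'   the two calibration buffer pHs bracketing the expected range.
#' @param mask optional logical matrix; Otsu on the pH-independent channel
#'   by default.
#' @return (rows x cols x 3) array of RGB values in [0, 1]; attributes
#'   \code{lut} (the 256 x 3 table) and \code{lut_index} (integer matrix of
#'   assigned LUT bins, 0 outside the mask).
#' @export
ratio_image <- function(x, min_ratio, max_ratio, mask = NULL) {
  if (!(min_ratio < max_ratio)) stop("min_ratio must be < max_ratio")
  proj <- if (inherits(x, "image_stack")) sum_project(x) else x
  dep <- proj$ph_dependent; indep <- proj$ph_independent
  if (is.null(mask)) mask <- make_mask(indep)
  dep[!mask] <- 0; indep[!mask] <- 0
  brush <- EBImage::makeBrush(7, shape = "gaussian", sigma = 7 / 6)
  dep_f <- EBImage::filter2(dep, brush, boundary = 0)
  indep_f <- EBImage::filter2(indep, brush, boundary = 0)
  ratio <- matrix(NA_real_, nrow(dep), ncol(dep))
  valid <- mask & indep_f > 0
  ratio[valid] <- dep_f[valid] / indep_f[valid]
  ratio[valid] <- pmin(pmax(ratio[valid], min_ratio), max_ratio)
  lut <- ratio_lut()
  idx <- matrix(0L, nrow(dep), ncol(dep))
  idx[valid] <- 1L + as.integer(
    round((ratio[valid] - min_ratio) / (max_ratio - min_ratio) * 255))
  rgb <- array(0, dim = c(nrow(dep), ncol(dep), 3))
  for (k in 1:3) {
    chan <- matrix(0, nrow(dep), ncol(dep))
    chan[valid] <- lut[idx[valid], k]
    rgb[, , k] <- chan
  }
  attr(rgb, "lut") <- lut
  attr(rgb, "lut_index") <- idx
  rgb
}

#' Photobleaching F/F0 curve
#'
#' Normalizes per-cycle integrated field intensities to the first
#' irradiation cycle (F0) and summarizes the fraction of signal lost by the
#' final cycle.
#'
#' @param intensities numeric vector of per-cycle integrated intensities, or
#'   a data frame with columns \code{cycle} and \code{intensity} (e.g. from
#'   \code{\link{simulate_photobleach}}).
#' @return data frame with columns \code{cycle}, \code{intensity},
#'   \code{f_over_f0} (exactly 1 at cycle 1); attribute
#'   \code{fraction_lost} = 1 - final F/F0.
#' @export
photobleach_curve <- function(intensities) {
  df <- if (is.data.frame(intensities)) {
    stopifnot(all(c("cycle", "intensity") %in% names(intensities)))
    intensities[order(intensities$cycle), ]
  } else {
    data.frame(cycle = seq_along(intensities), intensity = intensities)
  }
  if (nrow(df) < 2) stop("need >= 2 irradiation cycles")
  f0 <- df$intensity[1]
  if (!is.finite(f0) || f0 <= 0) stop("first-cycle intensity must be > 0")
  df$f_over_f0 <- df$intensity / f0
  attr(df, "fraction_lost") <- 1 - df$f_over_f0[nrow(df)]
  df
}

#' Count stained nuclei in a field
#'
#' Thresholds the nuclear-channel sum projection at local background plus
#' \code{local_threshold} gray levels (local background estimated as the
#' image median, adequate for flat synthetic backgrounds), labels connected
#' blobs and counts those whose equivalent diameter
#' \code{2 * sqrt(area / pi)} falls within [min_width, max_width]
#' micrometres.
#'
#' @param nuclear_image matrix (sum projection of the nuclear channel) or an
#'   \code{image_stack} with a \code{nuclear} channel.
#' @param pixel_size micrometres per pixel (taken from the stack when
#'   given one).
#' @param min_width,max_width nucleus equivalent-diameter limits in
#'   micrometres (defaults 5 and 30).
#' @param local_threshold gray levels above local background (default 100,
#'   inside the 50-200 working range).
#' @return integer count; attribute \code{diameters} holds all candidate
#'   blob diameters.
#' @export
count_nuclei <- function(nuclear_image, pixel_size = NULL, min_width = 5,
                         max_width = 30, local_threshold = 100) {
  if (inherits(nuclear_image, "image_stack")) {
    if (is.null(nuclear_image$channels$nuclear))
      stop("stack has no 'nuclear' channel")
    pixel_size <- nuclear_image$pixel_size
    nuclear_image <- apply(nuclear_image$channels$nuclear, c(2, 3), sum)
  }
  if (is.null(pixel_size))
    stop("pixel_size is required: nucleus width filters are in micrometres")
  bg <- stats::median(nuclear_image)
  mask <- nuclear_image >= bg + local_threshold
  if (!any(mask))
    return(structure(0L, diameters = numeric(0)))
  labels <- segment_labels(nuclear_image, mask, saddle_frac = 0,
                           rule = "saddle")   # frac 0: plain components
  sizes <- tabulate(labels[labels > 0])
  diam <- 2 * sqrt(sizes / pi) * pixel_size
  structure(sum(diam >= min_width & diam <= max_width), diameters = diam)
}
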