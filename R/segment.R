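# Connected-component labeling with intensity-guided splitting of touching
# puncta. Pixels above threshold are flooded in order of decreasing intensity
# (union-find): each new pixel joins the adjacent region with the highest
# peak. A pixel touching two regions is their saddle; the regions stay
# separate objects when the saddle is <= saddle_frac (default 50%) of the
# lower peak, and are merged into one object otherwise. rule = "peak"
# switches to the literal peak-comparison reading: two touching regions stay
# separate when the lower peak is <= saddle_frac of the higher peak,
# regardless of saddle depth. 8-connectivity; ties broken by pixel index so
# labeling is deterministic; equal-valued plateaus merge into one maximum.

segment_labels <- function(img, mask, saddle_frac = 0.5,
                           rule = c("saddle", "peak")) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(img), is.logical(mask), all(dim(img) == dim(mask)))
  nr <- nrow(img); nc <- ncol(img)
  idx <- which(mask)
  labels <- matrix(0L, nr, nc)
  if (!length(idx)) return(structure(labels, peaks = numeric(0)))

  ord <- idx[order(img[idx], idx, decreasing = c(TRUE, FALSE), method = "radix")]
  parent <- integer(nr * nc)        # 0 = unprocessed
  peak <- numeric(nr * nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  off_r <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
  off_c <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)

  for (p in ord) {
    v <- img[p]
    r <- ((p - 1L) %% nr) + 1L
    cc <- ((p - 1L) %/% nr) + 1L
    roots <- integer(0)
    for (k in 1:8) {
      rr <- r + off_r[k]; ck <- cc + off_c[k]
      if (rr >= 1L && rr <= nr && ck >= 1L && ck <= nc) {
        q <- (ck - 1L) * nr + rr
        if (parent[q] != 0L) roots <- c(roots, find(q))
      }
    }
    roots <- unique(roots)
    if (!length(roots)) {
      parent[p] <- p
      peak[p] <- v
      next
    }
    roots <- roots[order(peak[roots], decreasing = TRUE)]
    target <- roots[1]
    parent[p] <- target
    if (length(roots) > 1) {
      for (rt in roots[-1]) {
        merge_it <- if (rule == "saddle") v > saddle_frac * peak[rt]
                    else peak[rt] > saddle_frac * peak[target]
        if (merge_it) parent[rt] <- target
      }
    }
  }

  roots_all <- vapply(idx, find, integer(1))
  uniq <- unique(roots_all)
  labels[idx] <- match(roots_all, uniq)
  structure(labels, peaks = peak[uniq])
}

#' Segment punctate organelles in one image plane
#'
#' Thresholds the pH-independent channel plane, labels connected components
#' (8-connectivity) and splits touching puncta by the saddle rule: two local
#' maxima are separate objects when the saddle between them is at most 50\%
#' of the lower peak (\code{split_rule = "peak"} selects the literal
#' peak-comparison variant instead). Morphometry is computed in calibrated
#' units - area as pixel count times pixel_size^2 (micrometre^2) and outer
#' radius as the maximal centroid-to-pixel distance (micrometre) - or in
#' pixel units with \code{units = "pixel"}. Objects outside the area or
#' outer-radius filters are moved to a discard table (attribute
#' \code{discarded}) with the reason.
#'
#' @param plane numeric matrix: one background-corrected plane of the
#'   pH-independent channel.
#' @param mask optional logical matrix; when NULL a mask is built with
#'   \code{\link{make_mask}(plane, method = threshold_method, ...)}.
#' @param threshold_method,threshold_value passed to \code{make_mask} when
#'   \code{mask} is NULL.
#' @param split_rule "saddle" (default) or "peak".
#' @param saddle_frac splitting fraction (default 0.5).
#' @param area_filter retained object area range in calibrated units
#'   (default c(10, 1500)).
#' @param radius_filter retained outer-radius range (default c(0, 1000)).
#' @param pixel_size micrometres per pixel; required when
#'   \code{units = "um"}.
#' @param units "um" for micrometre-calibrated morphometry, "pixel" for
#'   pixel units.
#' @param plane_index stored in the records (per-object quantification is
#'   per-plane).
#' @return data frame with one row per retained object: \code{id},
#'   \code{plane}, \code{n_pixels}, \code{area}, \code{outer_radius},
#'   \code{centroid_y}, \code{centroid_x} (0-based pixel centers),
#'   \code{peak}. Attributes: \code{labels} (label matrix), \code{discarded}
#'   (discard table with \code{reason}), \code{threshold}.
#' @export
segment_objects <- function(plane, mask = NULL, threshold_method = "otsu",
                            threshold_value = NULL,
                            split_rule = c("saddle", "peak"),
                            saddle_frac = 0.5,
                            area_filter = c(10, 1500),
                            radius_filter = c(0, 1000),
                            pixel_size = NULL,
                            units = c("um", "pixel"),
                            plane_index = 1L) {
  split_rule <- match.arg(split_rule)
  units <- match.arg(units)
  if (units == "um" && is.null(pixel_size))
    stop("pixel_size is required for micrometre-calibrated filters ",
         "(use units = \"pixel\" for uncalibrated images)")
  px <- if (units == "um") pixel_size else 1
  if (is.null(mask)) {
    # empty masks are a valid per-plane outcome, not worth a warning here
    mask <- suppressWarnings(
      make_mask(plane, method = threshold_method, value = threshold_value))
  }
  thr <- attr(mask, "threshold")
  labels <- segment_labels(plane, mask, saddle_frac = saddle_frac,
                           rule = split_rule)
  n_lab <- max(labels)
  empty <- data.frame(id = integer(0), plane = integer(0),
                      n_pixels = integer(0), area = numeric(0),
                      outer_radius = numeric(0), centroid_y = numeric(0),
                      centroid_x = numeric(0), peak = numeric(0))
  if (n_lab == 0) {
    attr(empty, "labels") <- labels
    attr(empty, "discarded") <- cbind(empty, reason = character(0))
    attr(empty, "threshold") <- thr
    return(empty)
  }
  recs <- do.call(rbind, lapply(seq_len(n_lab), function(l) {
    w <- which(labels == l, arr.ind = TRUE)
    cy <- mean(w[, 1] - 1); cx <- mean(w[, 2] - 1)
    d <- sqrt((w[, 1] - 1 - cy)^2 + (w[, 2] - 1 - cx)^2)
    data.frame(id = l, plane = plane_index, n_pixels = nrow(w),
               area = nrow(w) * px^2, outer_radius = max(d) * px,
               centroid_y = cy, centroid_x = cx,
               peak = max(plane[labels == l]))
  }))
  reason <- rep(NA_character_, n_lab)
  reason[recs$area < area_filter[1] | recs$area > area_filter[2]] <- "area"
  bad_r <- recs$outer_radius < radius_filter[1] |
    recs$outer_radius > radius_filter[2]
  reason[is.na(reason) & bad_r] <- "outer_radius"
  keep <- is.na(reason)
  out <- recs[keep, , drop = FALSE]
  rownames(out) <- NULL
  disc <- recs[!keep, , drop = FALSE]
  disc$reason <- reason[!keep]
  rownames(disc) <- NULL
  attr(out, "labels") <- labels
  attr(out, "discarded") <- disc
  attr(out, "threshold") <- thr
  out
}
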