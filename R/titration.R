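#' Construct a titration series
#'
#' A titration series is a data frame with one row per measurement: columns
#' \code{ph}, \code{signal}, \code{replicate}, plus attributes recording the
#' probe label, assay kind and whether blanks were subtracted. This is the
#' table read from / written to the CSV schema
#' \code{ph, signal, replicate, probe, assay}.
#'
#' @param ph numeric pH values (within [0, 14]).
#' @param signal numeric signals (a.u.).
#' @param replicate replicate identifiers (recycled).
#' @param probe probe/channel label.
#' @param assay one of "absorbance", "fluorescence", "ratio".
#' @param blank_corrected logical.
#' @return data frame of class \code{titration_series}.
#' @export
titration_series <- function(ph, signal, replicate = 1L, probe = "probe",
                             assay = c("fluorescence", "absorbance", "ratio"),
                             blank_corrected = FALSE) {
  assay <- match.arg(assay)
  if (!all(is.finite(ph)) || any(ph < 0 | ph > 14))
    stop("pH values must be finite and within [0, 14]")
  if (!all(is.finite(signal))) stop("signals must be finite")
  df <- data.frame(ph = ph, signal = signal,
                   replicate = rep_len(replicate, length(ph)))
  attr(df, "probe") <- probe
  attr(df, "assay") <- assay
  attr(df, "blank_corrected") <- blank_corrected
  class(df) <- c("titration_series", "data.frame")
  df
}

#' Subtract buffer-only blanks from a titration series
#'
#' Blank signals measured in buffers alone are averaged per pH and subtracted
#' from the series at the matching pH (exact match or nearest within 0.05 pH
#' units). Negative corrected signals are retained, not clipped, and flagged
#' in a logical \code{negative} column.
#'
#' @param series,blanks \code{titration_series} objects on the same buffers.
#' @return the corrected series with \code{blank_corrected = TRUE}.
#' @export
blank_subtract <- function(series, blanks) {
  s <- as.data.frame(series); b <- as.data.frame(blanks)
  blank_ph <- sort(unique(b$ph))
  blank_mean <- vapply(blank_ph,
                       function(p) mean(b$signal[b$ph == p]), numeric(1))
  idx <- vapply(s$ph, function(p) {
    i <- which.min(abs(blank_ph - p))
    if (abs(blank_ph[i] - p) > 0.05) NA_integer_ else i
  }, integer(1))
  if (anyNA(idx))
    stop("no blank within 0.05 pH units for pH value(s): ",
         paste(sort(unique(s$ph[is.na(idx)])), collapse = ", "))
  out <- titration_series(s$ph, s$signal - blank_mean[idx], s$replicate,
                          probe = attr(series, "probe") %||% "probe",
                          assay = attr(series, "assay") %||% "fluorescence",
                          blank_corrected = TRUE)
  out$negative <- out$signal < 0
  out
}

#' Point-wise ratio titration from two per-channel titrations
#'
#' Builds the pH-sensitive / pH-independent ratio series from two solution
#' titrations measured on the same pH buffers (replicate means are ratioed
#' per matched pH). Used when a ratio titration was not measured directly.
#'
#' @param dep_series pH-dependent channel titration.
#' @param indep_series pH-independent channel titration.
#' @return \code{titration_series} with \code{assay = "ratio"}.
#' @export
ratio_titration <- function(dep_series, indep_series) {
  d <- as.data.frame(dep_series); i <- as.data.frame(indep_series)
  ph <- sort(intersect(unique(d$ph), unique(i$ph)))
  if (length(ph) < 4)
    stop("need >= 4 matched pH values across the two channels")
  num <- vapply(ph, function(p) mean(d$signal[d$ph == p]), numeric(1))
  den <- vapply(ph, function(p) mean(i$signal[i$ph == p]), numeric(1))
  if (any(den <= 0))
    stop("pH-independent channel mean is <= 0 at pH: ",
         paste(ph[den <= 0], collapse = ", "))
  titration_series(ph, num / den, probe = attr(dep_series, "probe") %||% "probe",
                   assay = "ratio",
                   blank_corrected = isTRUE(attr(dep_series, "blank_corrected")))
}

#' Read / write the titration CSV schema
#'
#' Columns: \code{ph, signal, replicate, probe, assay}.
#' @param path CSV file path.
#' @return \code{read_titration}: a \code{titration_series}.
#' @export
read_titration <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("ph", "signal")
  if (!all(need %in% names(df)))
    stop("titration CSV must have columns 'ph' and 'signal'")
  titration_series(df$ph, df$signal,
                   replicate = df$replicate %||% 1L,
                   probe = if ("probe" %in% names(df)) df$probe[1] else "probe",
                   assay = if ("assay" %in% names(df)) df$assay[1]
                           else "fluorescence")
}

#' @rdname read_titration
#' @param series a \code{titration_series}.
#' @export
write_titration <- function(series, path) {
  df <- as.data.frame(series)
  df$probe <- attr(series, "probe") %||% "probe"
  df$assay <- attr(series, "assay") %||% "fluorescence"
  utils::write.csv(df[c("ph", "signal", "replicate", "probe", "assay")],
                   path, row.names = FALSE)
  invisible(path)
}
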