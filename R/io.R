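#' Write a two-channel stack as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel (\code{<base>_<role>.tif}),
#' intensities rounded and clipped to [0, 65535], plus a JSON metadata
#' sidecar \code{<base>_meta.json} carrying pixel size, z-spacing, channel
#' roles and free-form metadata (the TIFF writer has no OME tag support).
#'
#' @param stack an \code{image_stack}.
#' @param base output path prefix (no extension).
#' @return invisibly, the vector of files written.
#' @export
write_stack <- function(stack, base) {
  stopifnot(inherits(stack, "image_stack"))
  files <- character(0)
  for (ch in names(stack$channels)) {
    a <- stack$channels[[ch]]
    pages <- lapply(seq_len(dim(a)[1]), function(p) {
      round(pmin(pmax(a[p, , ], 0), 65535)) / 65535
    })
    f <- paste0(base, "_", ch, ".tif")
    tiff::writeTIFF(pages, f, bits.per.sample = 16L)
    files <- c(files, f)
  }
  meta_file <- paste0(base, "_meta.json")
  meta <- list(pixel_size = stack$pixel_size, z_spacing = stack$z_spacing,
               bit_depth = 16L, channels = names(stack$channels))
  extra <- stack$meta[vapply(stack$meta, function(x)
    is.atomic(x) && length(x) < 100, logical(1))]
  jsonlite::write_json(c(meta, list(extra = extra)), meta_file,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(files, meta_file))
}

#' Read a two-channel stack from per-channel multi-page TIFFs
#'
#' Reads the files written by \code{\link{write_stack}}, or any per-channel
#' multi-page TIFFs named in \code{channel_map}. Pixel size and z-spacing
#' come from the JSON sidecar when present and can be overridden; without
#' either source an error is raised (calibrated morphometry needs them)
#' unless \code{pixels_mode = TRUE}.
#'
#' @param base path prefix used by \code{write_stack}, or NULL when
#'   \code{channel_map} holds full paths.
#' @param channel_map named character vector role -> file path; defaults to
#'   the \code{write_stack} layout for roles \code{ph_dependent} and
#'   \code{ph_independent}.
#' @param pixel_size,z_spacing overrides in micrometres.
#' @param pixels_mode allow missing spatial calibration (pixel units).
#' @return an \code{image_stack} with integer-valued intensities.
#' @export
read_stack <- function(base = NULL, channel_map = NULL, pixel_size = NULL,
                       z_spacing = NULL, pixels_mode = FALSE) {
  if (is.null(channel_map)) {
    if (is.null(base)) stop("give either 'base' or 'channel_map'")
    channel_map <- c(ph_dependent = paste0(base, "_ph_dependent.tif"),
                     ph_independent = paste0(base, "_ph_independent.tif"))
  }
  need <- c("ph_dependent", "ph_independent")
  if (!all(need %in% names(channel_map)))
    stop("channel_map must name roles: ",
         paste(setdiff(need, names(channel_map)), collapse = ", "))
  missing <- !file.exists(channel_map)
  if (any(missing))
    stop("stack file(s) not found: ",
         paste(channel_map[missing], collapse = ", "))
  channels <- lapply(channel_map, function(f) {
    pages <- tiff::readTIFF(f, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    arr <- array(0, dim = c(length(pages), dim(pages[[1]])))
    for (p in seq_along(pages)) arr[p, , ] <- round(pages[[p]] * 65535)
    arr
  })
  meta <- list()
  if (!is.null(base) && file.exists(paste0(base, "_meta.json")))
    meta <- jsonlite::read_json(paste0(base, "_meta.json"),
                                simplifyVector = TRUE)
  px <- pixel_size %||% meta$pixel_size
  zs <- z_spacing %||% meta$z_spacing
  if (is.null(px)) {
    if (!pixels_mode)
      stop("pixel size unknown: supply pixel_size, a metadata sidecar, ",
           "or pixels_mode = TRUE")
    px <- 1; zs <- zs %||% 1
  }
  image_stack(channels, pixel_size = px, z_spacing = zs %||% px,
              meta = list(source = unname(channel_map)))
}

file_md5 <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

#' Write a result table with a provenance sidecar
#'
#' Writes the records as CSV (floats at 9 significant digits, stable column
#' order) and a JSON sidecar \code{<path>.provenance.json} with the
#' parameters, package version, seed and input-file hashes, so any artifact
#' can be reproduced from its sidecar.
#'
#' @param records data frame.
#' @param path CSV output path.
#' @param parameters named list of run parameters to record.
#' @param inputs character vector of input file paths to hash.
#' @return invisibly, \code{path}.
#' @export
write_results <- function(records, path, parameters = list(),
                          inputs = character(0)) {
  df <- as.data.frame(records)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], signif, digits = 9)
  utils::write.csv(df, path, row.names = FALSE)
  prov <- list(
    columns = names(df), n_rows = nrow(df),
    parameters = parameters,
    inputs = file_md5(inputs),
    package = "lysoratio",
    package_version = as.character(utils::packageVersion("lysoratio")))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
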