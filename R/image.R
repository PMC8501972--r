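#' Multi-channel fluorescence image container
#'
#' A single field of view with one 2D intensity matrix per channel role.
#' rF3H images carry three roles: the nuclear stain (DAPI-like), the green
#' trap channel (EGFP-tagged RNA trap) and the red protein-of-interest
#' channel (mCherry-tagged candidate binder). Intensities are arbitrary
#' gray-level units; the enrichment statistic downstream is invariant to
#' additive offsets and, after control normalization, to channel gain, so no
#' bit-depth rescaling is ever applied.
#'
#' @param channels named list of numeric matrices with names
#'   `nuclear_stain`, `trap_green`, `poi_red`; all the same dimensions,
#'   finite and non-negative.
#' @param source_id image identifier string (defaults to `"image"`).
#' @param pixel_size_um optional physical pixel size in micrometres.
#'
#' @return An object of class `rf3h_image`: a list with elements
#'   `channels`, `source_id`, `pixel_size_um`.
#' @export
#' @examples
#' m <- matrix(100, 16, 16)
#' img <- multichannel_image(
#'   list(nuclear_stain = m, trap_green = m, poi_red = m),
#'   source_id = "demo"
#' )
multichannel_image <- function(channels, source_id = "image",
                               pixel_size_um = NULL) {
  roles <- c("nuclear_stain", "trap_green", "poi_red")
  if (!is.list(channels) || !setequal(names(channels), roles)) {
    abort("`channels` must be a named list with roles nuclear_stain, trap_green, poi_red.")
  }
  channels <- channels[roles]
  dims <- lapply(channels, dim)
  if (!all(vapply(channels, is.matrix, logical(1))) ||
      !all(vapply(dims, identical, logical(1), dims[[1]]))) {
    abort("All channels must be matrices of identical dimensions.")
  }
  for (role in roles) {
    v <- channels[[role]]
    if (!all(is.finite(v)) || any(v < 0)) {
      abort(sprintf("Channel '%s' must be finite and non-negative.", role))
    }
  }
  structure(
    list(channels = channels, source_id = as.character(source_id),
         pixel_size_um = pixel_size_um),
    class = "rf3h_image"
  )
}

#' @export
print.rf3h_image <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<rf3h_image '%s'> %d x %d px, channels: %s\n",
              x$source_id, d[1], d[2],
              paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

#' Extract one channel of a multi-channel image
#'
#' @param image an [multichannel_image()] object.
#' @param role one of `"nuclear_stain"`, `"trap_green"`, `"poi_red"`.
#' @return The channel's intensity matrix.
#' @export
get_channel <- function(image, role) {
  stopifnot(inherits(image, "rf3h_image"))
  role <- match.arg(role, c("nuclear_stain", "trap_green", "poi_red"))
  image$channels[[role]]
}

# gray levels are stored as 16-bit TIFF samples; this is the integer ceiling
.TIFF_MAX <- 65535

#' Read a multi-page TIFF as an rF3H image
#'
#' Expects a plain multi-page grayscale TIFF, one page per channel, with the
#' channel-role assignment supplied from the run configuration (a sidecar
#' mapping, not embedded metadata). Pixel values are returned on the
#' integer gray-level scale they were written with (16-bit, 0–65535);
#' no rescaling is applied beyond undoing the TIFF library's unit-interval
#' encoding.
#'
#' @param path path to a multi-page TIFF file.
#' @param role_map named integer vector mapping the three roles
#'   (`nuclear_stain`, `trap_green`, `poi_red`) to 1-based page indices.
#' @param source_id identifier recorded on the image; defaults to the file
#'   name without extension.
#' @return An [multichannel_image()] object.
#' @export
read_image <- function(path,
                       role_map = c(nuclear_stain = 1, trap_green = 2, poi_red = 3),
                       source_id = NULL) {
  if (!file.exists(path)) abort(sprintf("Image file not found: %s", path), class = "rf3h_io_error")
  roles <- c("nuclear_stain", "trap_green", "poi_red")
  if (!setequal(names(role_map), roles)) {
    abort("`role_map` must name exactly nuclear_stain, trap_green, poi_red.")
  }
  role_map <- vapply(role_map[roles], as.integer, integer(1))
  if (anyDuplicated(role_map)) abort("Channel roles must map to distinct pages.")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 3) {
    abort(sprintf("Expected at least 3 channels, found %d in %s.",
                  length(pages), path))
  }
  if (any(role_map < 1 | role_map > length(pages))) {
    abort(sprintf("role_map indices out of range for %d-channel file.",
                  length(pages)))
  }
  chans <- lapply(role_map, function(i) {
    p <- pages[[i]]
    if (length(dim(p)) == 3) p <- p[, , 1]  # tolerate RGB pages: first plane
    round(p * .TIFF_MAX)
  })
  if (is.null(source_id)) source_id <- sub("\\.[^.]*$", "", basename(path))
  multichannel_image(chans, source_id = source_id)
}

#' Write an rF3H image as a multi-page 16-bit TIFF
#'
#' Pages are written in role order nuclear_stain, trap_green, poi_red, so the
#' default `role_map` of [read_image()] round-trips. Values are clamped to
#' the 16-bit range and rounded to integers; integer inputs within range
#' round-trip exactly.
#'
#' @param image an [multichannel_image()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rf3h_image"))
  pages <- lapply(image$channels, function(m) {
    pmin(pmax(round(m), 0), .TIFF_MAX) / .TIFF_MAX
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}
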