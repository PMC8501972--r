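#' Anchor geometry: the structural model of the RNA-anchoring region
#'
#' rF3H traps tether the test RNA at one of three kinds of nuclear
#' structures, and the enrichment region is defined accordingly:
#'
#' * `single_spot` — one dominant punctum (a lacO repeat array bound by a
#'   LacI-fused trap). The single brightest blob in the green channel wins.
#' * `multi_puncta` — many puncta (chromocenters targeted by dCas9, or
#'   Cajal bodies via Coilin). All detected blobs are pooled into one
#'   anchor region per nucleus, since enrichment is reported per cell.
#' * `nuclear_rim` — a band along the inner nuclear membrane (Lamin
#'   B1-fused trap), constructed as the nucleus minus its morphological
#'   erosion by the band width.
#'
#' @param kind one of `"single_spot"`, `"multi_puncta"`, `"nuclear_rim"`.
#' @param spot_sigma_px blob-detection scale in pixels (Laplacian-of-Gaussian
#'   sigma, roughly structure radius / sqrt(2)); must be >= 1. Used by the
#'   spot and puncta geometries.
#' @param detect_threshold relative intensity excess a candidate blob must
#'   show over the nuclear median green level to count as detected
#'   (0.5 means 50% brighter). Used by the spot and puncta geometries.
#' @param rim_band_px rim band width in pixels (>= 1); used by
#'   `nuclear_rim` only. Parameters not used by `kind` are ignored.
#' @return An object of class `rf3h_geometry`.
#' @export
anchor_geometry <- function(kind = c("single_spot", "multi_puncta", "nuclear_rim"),
                            spot_sigma_px = 3, detect_threshold = 0.5,
                            rim_band_px = 4) {
  kind <- match.arg(kind)
  if (spot_sigma_px < 1) abort("spot_sigma_px must be >= 1 px.")
  if (rim_band_px < 1) abort("rim_band_px must be >= 1 px.")
  if (detect_threshold < 0) abort("detect_threshold must be non-negative.")
  structure(
    list(kind = kind, spot_sigma_px = spot_sigma_px,
         detect_threshold = detect_threshold, rim_band_px = rim_band_px),
    class = "rf3h_geometry"
  )
}

#' @export
print.rf3h_geometry <- function(x, ...) {
  cat(sprintf("<rf3h_geometry> %s (sigma %.3g px, threshold %.3g, rim band %d px)\n",
              x$kind, x$spot_sigma_px, x$detect_threshold, as.integer(x$rim_band_px)))
  invisible(x)
}

#' Partition nuclei from the nuclear-stain channel
#'
#' Deterministic nucleus segmentation: Gaussian smoothing, Otsu threshold on
#' the range-normalized image (so the partition is invariant to affine
#' intensity transforms a*I + b with a > 0), hole filling,
#' connected-component labelling, then area and border filters. Touching
#' nuclei are not split; merged blobs are expected to fail the area bound.
#'
#' @param nuclear_stain 2D intensity matrix (finite, non-negative).
#' @param min_area,max_area admissible nucleus area in px^2.
#' @param blur_sigma smoothing sigma in px before thresholding.
#' @return An object of class `rf3h_nuclei`: list with `labels` (integer
#'   matrix, 0 = background, 1..K = nuclei) and `cells` (tibble of per-
#'   nucleus `cell`, `area`, `centroid_r`, `centroid_c`). A blank or
#'   constant image yields zero nuclei, not an error.
#' @export
segment_nuclei <- function(nuclear_stain, min_area = 300, max_area = 8000,
                           blur_sigma = 2) {
  stopifnot(is.matrix(nuclear_stain))
  if (!all(is.finite(nuclear_stain)) || any(nuclear_stain < 0)) {
    abort("nuclear_stain must be finite and non-negative.")
  }
  empty <- function() {
    structure(list(labels = matrix(0L, nrow(nuclear_stain), ncol(nuclear_stain)),
                   cells = tibble(cell = integer(), area = integer(),
                                  centroid_r = double(), centroid_c = double())),
              class = "rf3h_nuclei")
  }
  rng <- range(nuclear_stain)
  if (diff(rng) == 0) return(empty())
  xn <- (nuclear_stain - rng[1]) / diff(rng)
  sm <- .sep_blur(xn, blur_sigma)
  th <- EBImage::otsu(sm, range = c(0, 1))
  mask <- sm > th
  mask <- EBImage::fillHull(mask)
  labels <- EBImage::bwlabel(mask)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  k <- max(labels)
  if (k == 0) return(empty())
  nr <- nrow(labels); nc <- ncol(labels)
  border <- unique(c(labels[1, ], labels[nr, ], labels[, 1], labels[, nc]))
  keep <- integer(0)
  areas <- tabulate(labels, nbins = k)
  for (lab in seq_len(k)) {
    if (areas[lab] >= min_area && areas[lab] <= max_area && !(lab %in% border)) {
      keep <- c(keep, lab)
    }
  }
  if (length(keep) == 0) return(empty())
  relab <- integer(k); relab[keep] <- seq_along(keep)
  out <- matrix(0L, nr, nc)
  nz <- labels > 0
  out[nz] <- relab[labels[nz]]
  cells <- purrr::map_dfr(seq_along(keep), function(i) {
    idx <- which(out == i, arr.ind = TRUE)
    tibble(cell = i, area = nrow(idx),
           centroid_r = mean(idx[, 1]), centroid_c = mean(idx[, 2]))
  })
  structure(list(labels = out, cells = cells), class = "rf3h_nuclei")
}

#' @export
print.rf3h_nuclei <- function(x, ...) {
  cat(sprintf("<rf3h_nuclei> %d nuclei in %d x %d px image\n",
              nrow(x$cells), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Extract the mask of one segmented nucleus
#'
#' @param nuclei an `rf3h_nuclei` object from [segment_nuclei()].
#' @param cell integer nucleus label.
#' @return Logical mask matrix.
#' @export
nucleus_mask <- function(nuclei, cell) {
  stopifnot(inherits(nuclei, "rf3h_nuclei"))
  nuclei$labels == as.integer(cell)
}

#' Detect the anchor structure inside one nucleus
#'
#' Finds the enrichment region in the green trap channel under the
#' configured [anchor_geometry()]. Spot and puncta detection use a
#' scale-normalized Laplacian-of-Gaussian filter at `spot_sigma_px`; a blob
#' is accepted only when its smoothed intensity exceeds the nuclear median
#' green level by the configured relative threshold, so a uniform nucleus
#' yields an empty anchor (the cell is later QC-failed). For `single_spot`
#' the maximum-response blob wins, with ties broken by disk-integrated
#' intensity and then by lowest (row, col). The background reference region
#' is always the whole nucleus, anchor pixels included.
#'
#' @param trap_green 2D green-channel intensity matrix.
#' @param nucleus_mask logical nucleus mask (non-empty).
#' @param geometry an [anchor_geometry()].
#' @return List with `anchor` and `reference` logical masks (both subsets of
#'   the nucleus; `anchor` may be empty when nothing is detected).
#' @export
detect_anchor <- function(trap_green, nucleus_mask, geometry) {
  stopifnot(is.matrix(trap_green), is.logical(nucleus_mask),
            inherits(geometry, "rf3h_geometry"))
  if (!any(nucleus_mask)) abort("nucleus_mask must be non-empty.")
  anchor <- switch(
    geometry$kind,
    single_spot  = .detect_blobs(trap_green, nucleus_mask, geometry, single = TRUE),
    multi_puncta = .detect_blobs(trap_green, nucleus_mask, geometry, single = FALSE),
    nuclear_rim  = .rim_band(nucleus_mask, geometry$rim_band_px)
  )
  list(anchor = anchor & nucleus_mask, reference = nucleus_mask)
}

.disk_mask <- function(dims, center, radius) {
  g <- .coord_grids(dims)
  (g$rr - center[1])^2 + (g$cc - center[2])^2 <= radius^2
}

.detect_blobs <- function(green, nucleus, geom, single) {
  sigma <- geom$spot_sigma_px
  dims <- dim(green)
  resp <- .log_response(green, sigma)
  sm <- .sep_blur(green, sigma)
  bg <- median(green[nucleus])
  accept_level <- (1 + geom$detect_threshold) * bg
  radius <- sqrt(2) * sigma
  none <- matrix(FALSE, dims[1], dims[2])

  if (single) {
    rmax <- max(resp[nucleus])
    if (rmax <= 0) return(none)
    cand <- which(nucleus & resp == rmax, arr.ind = TRUE)
    if (nrow(cand) > 1) {
      integ <- apply(cand, 1, function(p) {
        sum(green[.disk_mask(dims, p, radius) & nucleus])
      })
      cand <- cand[integ == max(integ), , drop = FALSE]
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    }
    peak <- cand[1, ]
    if (sm[peak[1], peak[2]] <= accept_level) return(none)
    return(.disk_mask(dims, peak, radius))
  }

  # multi_puncta: all local maxima of the LoG response above threshold
  w <- 2L * ceiling(sigma) + 1L
  local_max <- .max_filter(resp, w)
  peaks <- which(nucleus & resp > 0 & resp >= local_max - 1e-12 & sm > accept_level,
                 arr.ind = TRUE)
  if (nrow(peaks) == 0) return(none)
  anchor <- none
  for (i in seq_len(nrow(peaks))) {
    anchor <- anchor | .disk_mask(dims, peaks[i, ], radius)
  }
  anchor
}

# sliding-window maximum via shifted comparisons (window w must be odd)
.max_filter <- function(m, w) {
  half <- (w - 1L) / 2L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(-Inf, nr + 2L * half, nc + 2L * half)
  pad[half + seq_len(nr), half + seq_len(nc)] <- m
  out <- matrix(-Inf, nr, nc)
  for (dr in -half:half) {
    for (dc in -half:half) {
      out <- pmax(out, pad[half + dr + seq_len(nr), half + dc + seq_len(nc)])
    }
  }
  out
}

.rim_band <- function(nucleus, band) {
  band <- as.integer(band)
  brush <- EBImage::makeBrush(2L * band + 1L, shape = "disc")
  eroded <- EBImage::erode(nucleus * 1, brush) > 0
  nucleus & !eroded
}

#' Intersection-over-union of two masks
#'
#' @param a,b logical mask matrices of identical dimensions.
#' @return IoU in \[0, 1\]; 1 when both masks are empty.
#' @export
mask_iou <- function(a, b) {
  stopifnot(identical(dim(a), dim(b)))
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}
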