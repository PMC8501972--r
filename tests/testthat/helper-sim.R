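# Small, fast simulation designs used by the unit and property tests.
# These are deliberately smaller than the figure presets (fewer cells,
# smaller fields) so the property suites stay quick; the acceptance tests
# run the full presets.

small_config <- function(kind = "single_spot", n = 6, fold = 2, seed = 42,
                         noise = list(), ...) {
  simulation_config(
    conditions = tibble::tibble(
      label = c("ctrl", "test"), n_cells = c(n, n),
      fold = c(1, fold), is_control = c(TRUE, FALSE)
    ),
    geometry = anchor_geometry(kind),
    image_size = 72,
    nucleus = list(semi_axis_range = c(14, 18)),
    noise = noise,
    seed = seed,
    ...
  )
}

# a filled ellipse test pattern on constant background
ellipse_image <- function(size = 96, center = c(48, 48), axes = c(20, 14),
                          fg = 200, bg = 10) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  img <- matrix(bg, size, size)
  inside <- ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
  img[inside] <- fg
  img
}

disk <- function(size, center, radius) {
  rr <- matrix(seq_len(size), size, size)
  cc <- t(rr)
  (rr - center[1])^2 + (cc - center[2])^2 <= radius^2
}

mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}
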