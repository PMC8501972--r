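test_that("a single bright ellipse yields exactly one nucleus", {
  img <- ellipse_image(fg = 200, bg = 10)
  seg <- segment_nuclei(img, min_area = 300, max_area = 8000)
  expect_equal(nrow(seg$cells), 1L)
  expect_equal(seg$cells$centroid_r, 48, tolerance = 0.05)
  expect_equal(seg$cells$centroid_c, 48, tolerance = 0.05)
})

test_that("constant images yield zero nuclei without error", {
  seg <- segment_nuclei(matrix(37, 64, 64))
  expect_equal(nrow(seg$cells), 0L)
  expect_true(all(seg$labels == 0L))
})

test_that("border-clipped nuclei are excluded", {
  size <- 128
  rr <- matrix(seq_len(size), size, size); cc <- t(rr)
  img <- matrix(10, size, size)
  put <- function(center, axes) {
    inside <- ((rr - center[1]) / axes[1])^2 + ((cc - center[2]) / axes[2])^2 <= 1
    img[inside] <<- 220
  }
  put(c(35, 35), c(16, 12))
  put(c(90, 90), c(14, 15))
  put(c(4, 90), c(15, 13))  # clipped by the top border
  seg <- segment_nuclei(img, min_area = 300, max_area = 8000)
  expect_equal(nrow(seg$cells), 2L)
})

test_that("nucleus partition is invariant to affine intensity transforms", {
  img <- ellipse_image(fg = 180, bg = 25)
  a <- segment_nuclei(img)
  b <- segment_nuclei(3.7 * img + 120)
  expect_identical(a$labels, b$labels)
})

test_that("single-spot detection localizes a bright punctum to within 1 px", {
  size <- 96
  nucleus <- disk(size, c(48, 48), 25)
  rr <- matrix(seq_len(size), size, size); cc <- t(rr)
  true_center <- c(40, 55)
  green <- matrix(20, size, size)
  green[nucleus] <- 100
  green <- green + 400 * exp(-((rr - true_center[1])^2 +
                               (cc - true_center[2])^2) / (2 * 3^2))
  det <- detect_anchor(green, nucleus, anchor_geometry("single_spot"))
  expect_true(any(det$anchor))
  expect_true(all(det$anchor[!nucleus] == FALSE))
  expect_lt(sqrt(sum((mask_centroid(det$anchor) - true_center)^2)), 1)
  expect_identical(det$reference, nucleus)
})

test_that("a uniform green nucleus yields an empty anchor mask", {
  size <- 96
  nucleus <- disk(size, c(48, 48), 25)
  green <- matrix(20, size, size)
  green[nucleus] <- 100
  det <- detect_anchor(green, nucleus, anchor_geometry("single_spot"))
  expect_false(any(det$anchor))
})

test_that("rim band area matches the analytic annulus and excludes the eroded core", {
  size <- 96
  nucleus <- disk(size, c(48, 48), 30)
  green <- matrix(100, size, size)
  geom <- anchor_geometry("nuclear_rim", rim_band_px = 4)
  det <- detect_anchor(green, nucleus, geom)
  analytic <- pi * (30^2 - 26^2)
  expect_lt(abs(sum(det$anchor) - analytic) / analytic, 0.10)
  core <- nucleus & !det$anchor
  expect_false(any(det$anchor & core))
  expect_true(all(det$anchor[!nucleus] == FALSE))
})

test_that("multi-puncta detection pools puncta into one anchor inside the nucleus", {
  size <- 96
  nucleus <- disk(size, c(48, 48), 28)
  green <- matrix(20, size, size)
  green[nucleus] <- 100
  centers <- rbind(c(38, 40), c(55, 60), c(60, 38))
  for (i in 1:3) green[disk(size, centers[i, ], 2.5)] <- 500
  det <- detect_anchor(green, nucleus,
                       anchor_geometry("multi_puncta", spot_sigma_px = 2))
  expect_true(all(det$anchor[!nucleus] == FALSE))
  for (i in 1:3) {
    expect_true(det$anchor[centers[i, 1], centers[i, 2]])
  }
})

test_that("segmentation recovers simulator ground truth masks and spot centers", {
  sim <- simulate_experiment(small_config(n = 4, seed = 9))
  geom <- sim$config$geometry
  ious <- c(); errs <- c()
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    img <- purrr::detect(sim$images[[tr$condition]],
                         function(im) im$source_id == tr$source_id)
    seg <- segment_nuclei(get_channel(img, "nuclear_stain"))
    expect_equal(nrow(seg$cells), 1L)
    nm <- nucleus_mask(seg, 1)
    ious <- c(ious, mask_iou(nm, tr$nucleus_mask[[1]]))
    det <- detect_anchor(get_channel(img, "trap_green"), nm, geom)
    errs <- c(errs, sqrt(sum((mask_centroid(det$anchor) -
                              tr$spot_center[[1]][1, ])^2)))
  }
  expect_true(all(ious >= 0.9))
  expect_true(all(errs <= 2))
})
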