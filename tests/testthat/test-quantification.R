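test_that("mask means reproduce a hand-computed arithmetic oracle", {
  # anchor: 2 px with red {14,16}, green {28,32}; 8 more reference px with
  # red 2.5 and green 5 -> reference means: red (30+20)/10 = 5,
  # green (60+40)/10 = 10; raw ratio (15-5)/(30-10) = 0.5
  size <- 8
  anchor <- matrix(FALSE, size, size); anchor[4, 4:5] <- TRUE
  reference <- matrix(FALSE, size, size); reference[4:5, 2:6] <- TRUE
  stopifnot(sum(reference) == 10, all(reference[anchor]))
  red <- matrix(0, size, size); green <- matrix(0, size, size)
  red[reference] <- 2.5; green[reference] <- 5
  red[4, 4] <- 14; red[4, 5] <- 16
  green[4, 4] <- 28; green[4, 5] <- 32
  img <- multichannel_image(list(nuclear_stain = matrix(1, size, size),
                                 trap_green = green, poi_red = red))
  m <- measure_masks(img, anchor, reference)
  expect_equal(m$red_anchor, 15)
  expect_equal(m$red_nucleus, 5)
  expect_equal(m$green_anchor, 30)
  expect_equal(m$green_nucleus, 10)
  expect_equal(m$raw_ratio, 0.5)
  expect_true(m$qc_pass)
})

test_that("uniform channels give equal anchor and nucleus means and fail weak-trap QC", {
  size <- 8
  anchor <- matrix(FALSE, size, size); anchor[3, 3] <- TRUE
  reference <- matrix(FALSE, size, size); reference[2:6, 2:6] <- TRUE
  img <- multichannel_image(list(nuclear_stain = matrix(1, size, size),
                                 trap_green = matrix(50, size, size),
                                 poi_red = matrix(80, size, size)))
  m <- measure_masks(img, anchor, reference)
  expect_equal(m$red_anchor, m$red_nucleus)
  expect_equal(m$green_anchor, m$green_nucleus)
  expect_true(is.na(m$raw_ratio))
  expect_identical(m$qc_reason, "weak_trap")
})

test_that("single-pixel masks return the pixel values themselves", {
  size <- 4
  anchor <- matrix(FALSE, size, size); anchor[2, 3] <- TRUE
  green <- matrix(0, size, size); green[2, 3] <- 123.25
  red <- matrix(0, size, size); red[2, 3] <- 45.5
  img <- multichannel_image(list(nuclear_stain = matrix(1, size, size),
                                 trap_green = green, poi_red = red))
  m <- measure_masks(img, anchor, anchor)
  expect_equal(m$green_anchor, 123.25)
  expect_equal(m$red_anchor, 45.5)
})

test_that("empty anchor is flagged no_anchor but reference means are recorded", {
  size <- 6
  reference <- matrix(FALSE, size, size); reference[2:5, 2:5] <- TRUE
  img <- multichannel_image(list(nuclear_stain = matrix(1, size, size),
                                 trap_green = matrix(10, size, size),
                                 poi_red = matrix(20, size, size)))
  m <- measure_masks(img, matrix(FALSE, size, size), reference)
  expect_identical(m$qc_reason, "no_anchor")
  expect_equal(m$green_nucleus, 10)
  expect_equal(m$red_nucleus, 20)
  expect_true(is.na(m$raw_ratio))
})

test_that("relative fluorescence follows the printed formula and its invariances", {
  expect_equal(relative_fluorescence(15, 5, 30, 10), 0.5)
  # no red enrichment -> 0 regardless of green values
  expect_equal(relative_fluorescence(7, 7, 90, 10), 0)
  # offset invariance: adding any constant to all four means changes nothing
  expect_equal(relative_fluorescence(15 + 7, 5 + 7, 30 + 7, 10 + 7), 0.5)
  expect_equal(relative_fluorescence(15 - 3, 5 - 3, 30 + 100, 10 + 100), 0.5)
  # red-channel scale equivariance
  expect_equal(relative_fluorescence(15 * 3, 5 * 3, 30, 10), 0.5 * 3)
  # denominator floor
  expect_true(is.na(relative_fluorescence(15, 5, 10.4, 10, denom_floor = 0.5)))
  # negative ratios are kept
  expect_equal(relative_fluorescence(5, 15, 30, 10), -0.5)
})

test_that("normalization divides by the control mean and errors on degenerate controls", {
  recs <- tibble::tibble(
    source_id = "s", cell = 1:4, condition = c("ctrl", "ctrl", "ctrl", "test"),
    area = 100, anchor_area = 4, green_anchor = 30, green_nucleus = 10,
    red_anchor = 15, red_nucleus = 5,
    raw_ratio = c(0.4, 0.5, 0.6, 1.0), normalized_value = NA_real_,
    qc_pass = TRUE, qc_reason = NA_character_
  )
  out <- normalize_by_control(recs, "ctrl")
  expect_equal(out$normalized_value[4], 2.0)
  expect_equal(mean(out$normalized_value[1:3]), 1.0)  # self-normalization

  neg <- recs; neg$raw_ratio[1:3] <- c(-0.2, 0, 0.2)
  expect_error(normalize_by_control(neg, "ctrl"), "undefined",
               class = "rf3h_control_error")
  few <- recs[c(1, 2, 4), ]
  expect_error(normalize_by_control(few, "ctrl"), "at least 3",
               class = "rf3h_control_error")
})

test_that("QC partition rejects exactly the constructed violations with reasons", {
  recs <- tibble::tibble(
    source_id = "s", cell = 1:5, condition = "test",
    area = c(1000, 1000, 1000, 90, 1000),
    anchor_area = c(10, 0, 10, 10, 10),
    green_anchor = c(30, NA, 10.2, 30, 30), green_nucleus = 10,
    red_anchor = c(15, NA, 11, 15, 15), red_nucleus = 5,
    raw_ratio = NA_real_, normalized_value = NA_real_,
    qc_pass = NA, qc_reason = NA_character_
  )
  parts <- qc_filter(recs, denom_floor_frac = 0.05, min_area = 300,
                     max_area = 8000)
  expect_equal(nrow(parts$kept) + nrow(parts$rejected), 5L)
  expect_setequal(parts$rejected$cell, c(2, 3, 4))
  expect_identical(parts$rejected$qc_reason[parts$rejected$cell == 2], "no_anchor")
  expect_identical(parts$rejected$qc_reason[parts$rejected$cell == 3], "weak_trap")
  expect_identical(parts$rejected$qc_reason[parts$rejected$cell == 4],
                   "area_out_of_bounds")
  expect_true(all(parts$kept$qc_pass))
})

test_that("scale and offset transforms act on group results as the statistic predicts", {
  sim <- simulate_experiment(small_config(n = 5, seed = 21,
                                          noise = list(enabled = FALSE)))
  base <- measure_with_truth_masks(sim)
  scaled <- purrr::map(sim$images, function(imgs) {
    purrr::map(imgs, function(img) {
      multichannel_image(list(
        nuclear_stain = get_channel(img, "nuclear_stain"),
        trap_green = get_channel(img, "trap_green") + 55,
        poi_red = get_channel(img, "poi_red") * 2.5
      ), source_id = img$source_id)
    })
  })
  sim2 <- sim
  sim2$images <- scaled
  tr <- measure_with_truth_masks(sim2)
  # red scaling multiplies raw ratios by the factor; green offset is inert
  expect_equal(tr$raw_ratio, base$raw_ratio * 2.5, tolerance = 1e-12)
  # shared scaling cancels after control normalization
  n1 <- normalize_by_control(base, "ctrl")
  n2 <- normalize_by_control(tr, "ctrl")
  expect_equal(n2$normalized_value, n1$normalized_value, tolerance = 1e-12)
})
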