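test_that("simulation is bit-identical under a fixed seed and differs across seeds", {
  a <- simulate_experiment(small_config(n = 2, seed = 17))
  b <- simulate_experiment(small_config(n = 2, seed = 17))
  expect_identical(a$truth$raw_ratio, b$truth$raw_ratio)
  expect_identical(get_channel(a$images[["test"]][[1]], "poi_red"),
                   get_channel(b$images[["test"]][[1]], "poi_red"))
  c <- simulate_experiment(small_config(n = 2, seed = 18))
  expect_false(identical(a$truth$raw_ratio, c$truth$raw_ratio))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_experiment(small_config(n = 1, seed = 4)))
  expect_identical(.Random.seed, before)
})

test_that("noise-free measurement with true masks matches ground truth to 1e-9", {
  for (kind in c("single_spot", "multi_puncta", "nuclear_rim")) {
    sim <- simulate_experiment(small_config(kind, n = 3, seed = 33,
                                            noise = list(enabled = FALSE)))
    m <- measure_with_truth_masks(sim)
    expect_lt(max(abs(m$raw_ratio - sim$truth$raw_ratio) /
                  abs(sim$truth$raw_ratio)), 1e-9)
  }
})

test_that("per-cell noise-free truth ratios scale with the condition fold", {
  sim <- simulate_experiment(small_config(n = 4, fold = 3, seed = 12,
                                          noise = list(enabled = FALSE)))
  cfg <- sim$config
  # each cell's truth ratio equals the closed form with its own drawn levels
  per_cell <- with(sim$truth, diffuse_red * (gain - 1) /
                              (diffuse_green * cfg$green$trap_gain))
  expect_equal(sim$truth$raw_ratio, per_cell, tolerance = 1e-9)
})

test_that("the closed-form expected ratio is linear in fold and ignores anchor fraction", {
  cfg2 <- small_config(fold = 2)
  cfg4 <- small_config(fold = 4)
  r1 <- expected_raw_ratio(cfg2, "ctrl")
  r2 <- expected_raw_ratio(cfg2, "test")
  r4 <- expected_raw_ratio(cfg4, "test")
  # control fold 1: the expected normalized value of a fold-G condition is G
  expect_equal(r2 / r1, 2)
  expect_equal(r4 / r2, 2)  # doubling the fold doubles the expectation
  # the anchor-area fraction cancels between numerator and denominator
  expect_equal(expected_raw_ratio(cfg2, "test", anchor_fraction = 0.3), r2)
  expect_equal(expected_raw_ratio(cfg2, "test", anchor_fraction = 1e-9), r2)
  expect_error(expected_raw_ratio(cfg2, "test", anchor_fraction = 1), "anchor")
  expect_error(expected_raw_ratio(cfg2, "nope"), "Unknown condition")
})

test_that("a null experiment (fold 1) recovers normalized means near 1 in both groups", {
  sim <- simulate_experiment(small_config(n = 10, fold = 1, seed = 71))
  m <- measure_with_truth_masks(sim)
  norm <- normalize_by_control(m, "ctrl")
  s <- summarize_groups(norm, control = "ctrl")
  expect_equal(s$mean[s$is_control], 1, tolerance = 1e-12)
  expect_equal(s$mean[!s$is_control], 1, tolerance = 0.35)
})

test_that("estimated enrichment is insensitive to the expression-variability spread", {
  means <- vapply(c(0.1, 0.5), function(sdlog) {
    cfg <- small_config(n = 12, fold = 2, seed = 55,
                        red = list(expr_sdlog = sdlog))
    m <- measure_with_truth_masks(simulate_experiment(cfg))
    norm <- normalize_by_control(m, "ctrl")
    mean(norm$normalized_value[norm$condition == "test" & norm$qc_pass])
  }, double(1))
  expect_equal(means[1], 2, tolerance = 0.25)
  expect_equal(means[2], 2, tolerance = 0.35)
})

test_that("different seeds draw from the same distribution (KS sanity check)", {
  vals <- lapply(c(101, 202), function(s) {
    sim <- simulate_experiment(small_config(n = 15, seed = s))
    m <- normalize_by_control(measure_with_truth_masks(sim), "ctrl")
    m$normalized_value[m$condition == "test" & m$qc_pass]
  })
  ks <- suppressWarnings(stats::ks.test(vals[[1]], vals[[2]]))
  expect_gt(ks$p.value, 0.01)
})

test_that("figure presets freeze the published designs", {
  f1 <- figure_preset("F1_pp7_PCP")
  expect_identical(f1$geometry$kind, "single_spot")
  expect_equal(f1$conditions$n_cells[f1$conditions$label == "+ms2-pp7"], 24L)
  expect_equal(f1$conditions$fold[f1$conditions$label == "+ms2-pp7"], 2)

  f5 <- figure_preset("F5_chromocenter_MCP")
  expect_identical(f5$geometry$kind, "multi_puncta")
  expect_equal(f5$conditions$n_cells[!f5$conditions$is_control], 26L)
  expect_equal(f5$conditions$fold[!f5$conditions$is_control], 3)

  rim <- figure_preset("F5_laminB1_rim")
  expect_identical(rim$geometry$kind, "nuclear_rim")

  null <- figure_preset("F6_dCas13a_MCP", null = TRUE)
  expect_true(all(null$conditions$fold == 1))
  expect_error(figure_preset("F9_unknown"))
})

test_that("degenerate simulation configurations are rejected", {
  conds <- tibble::tibble(label = c("c", "t"), n_cells = c(3L, 3L),
                          fold = c(1, 2), is_control = c(TRUE, FALSE))
  expect_error(simulation_config(conds, red = list(g0 = 1)), "g0")
  expect_error(simulation_config(conds, red = list(g0 = 0.8)), "g0")
  expect_error(
    simulation_config(conds, geometry = anchor_geometry("nuclear_rim",
                                                        rim_band_px = 20),
                      nucleus = list(semi_axis_range = c(14, 18))),
    "rim band"
  )
  two_ctrl <- conds; two_ctrl$is_control <- c(TRUE, TRUE)
  expect_error(simulation_config(two_ctrl), "Exactly one")
  ctrl_fold <- conds; ctrl_fold$fold <- c(2, 2)
  expect_error(simulation_config(ctrl_fold), "fold = 1")
})
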