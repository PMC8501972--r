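#' Configuration of a synthetic rF3H experiment
#'
#' Full generative specification of a simulated experiment: per-condition
#' cell counts and binding fold-changes, nucleus and anchor-structure
#' geometry, the green trap and red protein intensity models, and the
#' camera noise model. One nucleus is rendered per field of view.
#'
#' The red recruitment model is multiplicative on the nonspecific excess:
#' inside the anchor the red level is `diffuse * (1 + (g0 - 1) * fold)`,
#' where `g0 > 1` is the nonspecific-recruitment gain every condition shows
#' (default 1.15, a 15% red excess at the anchor in controls, so control
#' raw ratios are small but positive and control normalization is defined)
#' and `fold` is the condition's specific binding fold-change (1 for
#' controls). Under this model the expected normalized enrichment of a
#' condition equals its `fold` exactly, and doubling `fold` doubles it.
#' Per-cell red and green diffuse levels are log-normal with fixed mean
#' (mean-preserving spread), emulating cell-to-cell expression variability
#' that the nucleus-normalized ratio is designed to cancel.
#'
#' @param conditions tibble with columns `label`, `n_cells`, `fold`,
#'   `is_control` (exactly one control, whose `fold` must be 1).
#' @param geometry an [anchor_geometry()] used both to render the anchor
#'   structure and to detect it downstream.
#' @param image_size side of the square field of view, px.
#' @param nucleus list: `semi_axis_range` (px, ellipse semi-axes drawn
#'   uniformly), `stain_level`, `background` (a.u.).
#' @param structure list: `spot_radius_px` (single-spot disk radius),
#'   `n_puncta_range`, `puncta_radius_px`, `margin_px` (clearance of anchor
#'   placements from the nuclear boundary).
#' @param green list: `diffuse_mean` (a.u.), `diffuse_sdlog` (log-normal
#'   spread of the per-cell trap expression), `trap_gain` (green excess at
#'   the anchor as a multiple of the diffuse level), `background`.
#' @param red list: `diffuse_mean`, `expr_sdlog` (per-cell expression
#'   spread), `g0` (nonspecific recruitment gain, > 1), `background`.
#' @param noise list: `enabled`, `poisson_slope` (signal-dependent variance
#'   per intensity unit, Gaussian approximation of shot noise), `read_sd`
#'   (additive read noise sd, a.u.), `offset` (constant camera offset),
#'   `blur_sigma` (optional optical blur, px; 0 by default, so the rendered
#'   structures keep the piecewise-constant profiles whose region means the
#'   closed-form expectation describes — a nonzero blur bleeds intensity
#'   across the nuclear boundary and biases the whole-nucleus reference
#'   means, which the analytic oracle deliberately does not model).
#'   Disabling noise also disables the blur and offset.
#' @param seed RNG seed giving bit-identical output.
#' @return An object of class `rf3h_sim_config`.
#' @export
simulation_config <- function(conditions,
                              geometry = anchor_geometry("single_spot"),
                              image_size = 96,
                              nucleus = list(),
                              structure = list(),
                              green = list(),
                              red = list(),
                              noise = list(),
                              seed = 1L) {
  nucleus <- modifyList(list(semi_axis_range = c(20, 28), stain_level = 500,
                             background = 40), nucleus)
  structure_ <- modifyList(list(spot_radius_px = 4, n_puncta_range = c(10, 40),
                                puncta_radius_px = 2.5, margin_px = 6), structure)
  green <- modifyList(list(diffuse_mean = 400, diffuse_sdlog = 0.2,
                           trap_gain = 4, background = 20), green)
  red <- modifyList(list(diffuse_mean = 300, expr_sdlog = 0.3, g0 = 1.15,
                         background = 20), red)
  noise <- modifyList(list(enabled = TRUE, poisson_slope = 0.5, read_sd = 8,
                           offset = 100, blur_sigma = 0), noise)
  conditions <- as_tibble(conditions)
  stopifnot(all(c("label", "n_cells", "fold", "is_control") %in% names(conditions)))
  if (sum(conditions$is_control) != 1) {
    abort("Exactly one simulated condition must be the control.")
  }
  if (conditions$fold[conditions$is_control] != 1) {
    abort("The control condition must have fold = 1 (no specific binding).")
  }
  if (red$g0 <= 1) {
    abort("g0 must exceed 1: controls need nonzero nonspecific recruitment.")
  }
  if (green$trap_gain <= 0) abort("trap_gain must be positive.")
  if (geometry$kind == "nuclear_rim" &&
      geometry$rim_band_px >= min(nucleus$semi_axis_range)) {
    abort("rim band width must be smaller than the nucleus minor semi-axis.")
  }
  structure(
    list(conditions = conditions, geometry = geometry,
         image_size = as.integer(image_size), nucleus = nucleus,
         structure = structure_, green = green, red = red, noise = noise,
         seed = as.integer(seed)),
    class = "rf3h_sim_config"
  )
}

#' @export
print.rf3h_sim_config <- function(x, ...) {
  cat(sprintf("<rf3h_sim_config> %s, %d x %d px, seed %d\n", x$geometry$kind,
              x$image_size, x$image_size, x$seed))
  print(x$conditions)
  invisible(x)
}

# run code under a fixed seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

.ellipse_mask <- function(size, center, semi_axes) {
  g <- .coord_grids(c(size, size))
  ((g$rr - center[1]) / semi_axes[1])^2 +
    ((g$cc - center[2]) / semi_axes[2])^2 <= 1
}

# uniform point inside the ellipse shrunk by margin (anchor placement region)
.sample_in_ellipse <- function(center, semi_axes, margin) {
  ax <- pmax(semi_axes - margin, 1)
  repeat {
    u <- runif(2, -1, 1)
    if (sum(u^2) <= 1) {
      return(center + u * ax)
    }
  }
}

.render_anchor <- function(cfg, nucleus, center, semi_axes) {
  size <- cfg$image_size
  st <- cfg$structure
  switch(
    cfg$geometry$kind,
    single_spot = {
      p <- round(.sample_in_ellipse(center, semi_axes, st$margin_px))
      list(mask = .disk_mask(c(size, size), p, st$spot_radius_px) & nucleus,
           centers = matrix(p, 1, 2))
    },
    multi_puncta = {
      n <- sample(seq(st$n_puncta_range[1], st$n_puncta_range[2]), 1)
      sep <- 2 * st$puncta_radius_px + 1
      centers <- matrix(NA_real_, 0, 2)
      tries <- 0
      while (nrow(centers) < n && tries < 200 * n) {
        tries <- tries + 1
        p <- .sample_in_ellipse(center, semi_axes, st$margin_px)
        if (nrow(centers) == 0 ||
            min(sqrt(rowSums(sweep(centers, 2, p)^2))) >= sep) {
          centers <- rbind(centers, p)
        }
      }
      mask <- matrix(FALSE, size, size)
      for (i in seq_len(nrow(centers))) {
        mask <- mask | .disk_mask(c(size, size), round(centers[i, ]),
                                  st$puncta_radius_px)
      }
      list(mask = mask & nucleus, centers = centers)
    },
    nuclear_rim = list(mask = .rim_band(nucleus, cfg$geometry$rim_band_px),
                       centers = matrix(center, 1, 2))
  )
}

.apply_noise <- function(clean, noise) {
  out <- clean
  out <- .sep_blur(out, noise$blur_sigma)
  out <- out + noise$offset
  v <- noise$poisson_slope * pmax(out, 0) + noise$read_sd^2
  out <- out + rnorm(length(out), sd = sqrt(v))
  pmax(out, 0)
}

# mean-preserving log-normal draw: E[X] = mean for every sdlog
.rlnorm_mean <- function(n, mean, sdlog) {
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate a complete rF3H experiment with ground truth
#'
#' Renders one multi-channel field of view per cell: a nuclear-stain
#' ellipse, a green channel with diffuse trap signal plus the anchor
#' structure, and a red channel with per-cell diffuse expression plus
#' recruitment at the anchor (nonspecific in controls, fold-scaled in
#' specific conditions); optics blur, camera offset and Poisson–Gaussian
#' noise are then applied. Ground truth records the true masks and the
#' noise-free channel means over them, from which each cell's expected raw
#' enrichment ratio follows.
#'
#' @param config an [simulation_config()].
#' @param seed optional seed overriding `config$seed`.
#' @return An object of class `rf3h_simulation`: list with `config`,
#'   `images` (list per condition of [multichannel_image()]s) and `truth`
#'   (tibble with per-cell generative levels, noise-free means, expected
#'   `raw_ratio` and list-columns `nucleus_mask`, `anchor_mask`,
#'   `spot_center`).
#' @export
simulate_experiment <- function(config, seed = NULL) {
  stopifnot(inherits(config, "rf3h_sim_config"))
  seed <- seed %||% config$seed
  .with_seed(seed, {
    size <- config$image_size
    images <- list()
    truth <- list()
    for (ci in seq_len(nrow(config$conditions))) {
      cond <- config$conditions[ci, ]
      imgs <- vector("list", cond$n_cells)
      for (i in seq_len(cond$n_cells)) {
        axes <- runif(2, config$nucleus$semi_axis_range[1],
                      config$nucleus$semi_axis_range[2])
        center <- size / 2 + runif(2, -4, 4)
        nucleus <- .ellipse_mask(size, center, axes)
        anc <- .render_anchor(config, nucleus, center, axes)
        d_g <- .rlnorm_mean(1, config$green$diffuse_mean,
                            config$green$diffuse_sdlog)
        r_lvl <- .rlnorm_mean(1, config$red$diffuse_mean, config$red$expr_sdlog)
        gain <- 1 + (config$red$g0 - 1) * cond$fold

        stain <- matrix(config$nucleus$background, size, size)
        stain[nucleus] <- stain[nucleus] + config$nucleus$stain_level
        green <- matrix(config$green$background, size, size)
        green[nucleus] <- green[nucleus] + d_g
        green[anc$mask] <- green[anc$mask] + d_g * config$green$trap_gain
        red <- matrix(config$red$background, size, size)
        red[nucleus] <- red[nucleus] + r_lvl
        red[anc$mask] <- red[anc$mask] + r_lvl * (gain - 1)

        ga <- if (any(anc$mask)) mean(green[anc$mask]) else NA_real_
        gn <- mean(green[nucleus])
        ra <- if (any(anc$mask)) mean(red[anc$mask]) else NA_real_
        rn <- mean(red[nucleus])
        sid <- sprintf("%s_cell%03d", gsub("[^A-Za-z0-9]+", "-", cond$label), i)
        truth[[length(truth) + 1]] <- tibble(
          condition = cond$label, source_id = sid, fold = cond$fold,
          diffuse_green = d_g, diffuse_red = r_lvl, gain = gain,
          green_anchor = ga, green_nucleus = gn,
          red_anchor = ra, red_nucleus = rn,
          raw_ratio = (ra - rn) / (ga - gn),
          nucleus_mask = list(nucleus), anchor_mask = list(anc$mask),
          spot_center = list(anc$centers)
        )
        if (config$noise$enabled) {
          stain <- .apply_noise(stain, config$noise)
          green <- .apply_noise(green, config$noise)
          red <- .apply_noise(red, config$noise)
        }
        imgs[[i]] <- multichannel_image(
          list(nuclear_stain = stain, trap_green = green, poi_red = red),
          source_id = sid
        )
      }
      images[[cond$label]] <- imgs
    }
    structure(list(config = config, images = images,
                   truth = bind_rows(truth)),
              class = "rf3h_simulation")
  })
}

#' @export
print.rf3h_simulation <- function(x, ...) {
  cat(sprintf("<rf3h_simulation> %s; %d cells over %d conditions\n",
              x$config$geometry$kind, nrow(x$truth), length(x$images)))
  invisible(x)
}

#' Closed-form expected raw enrichment ratio of a simulated condition
#'
#' From the noise-free generative means, with anchor-area fraction `f` of
#' the whole-nucleus reference accounted for: the red excess at the anchor
#' over the nucleus mean is `r * (gain - 1) * (1 - f)` and the green excess
#' is `d_g * trap_gain * (1 - f)`, so the `(1 - f)` factors cancel and the
#' expected raw ratio is
#' `red_diffuse_mean * (gain - 1) / (green_diffuse_mean * trap_gain)` for
#' every admissible anchor fraction. Dividing by the control's expectation,
#' the expected normalized enrichment of a condition is exactly its `fold`.
#'
#' @param config an [simulation_config()].
#' @param condition condition label.
#' @param anchor_fraction anchor area as a fraction of nucleus area, in
#'   \[0, 1); enters both excesses and cancels, kept explicit to document
#'   the accounting. `anchor_fraction >= 1` (or a non-positive green
#'   excess) is degenerate and errors.
#' @return The expected raw ratio (dimensionless).
#' @export
expected_raw_ratio <- function(config, condition, anchor_fraction = 0) {
  stopifnot(inherits(config, "rf3h_sim_config"))
  row <- config$conditions[config$conditions$label == condition, ]
  if (nrow(row) != 1) abort(sprintf("Unknown condition '%s'.", condition))
  if (anchor_fraction < 0 || anchor_fraction >= 1) {
    abort("anchor_fraction must lie in [0, 1): the anchor cannot fill the nucleus.")
  }
  gain <- 1 + (config$red$g0 - 1) * row$fold
  num <- config$red$diffuse_mean * (gain - 1) * (1 - anchor_fraction)
  den <- config$green$diffuse_mean * config$green$trap_gain * (1 - anchor_fraction)
  if (den <= 0) abort("Degenerate geometry: non-positive expected green excess.")
  num / den
}

#' Frozen simulation presets matching the assay's figure designs
#'
#' Each preset reproduces the design of one quantified figure panel:
#' geometry, per-group cell counts from the figure legends, and a binding
#' fold equal to the reported enrichment, so the expected normalized mean
#' of the specific condition equals the published fold.
#'
#' * `F1_pp7_PCP` — pp7 RNA vs PCP at a lacO array (single spot); control
#'   n = 23, specific n = 24, fold 2.
#' * `F2_polyA_PABPC1` — polyadenylated mRNA mimic vs PABPC1 at a lacO
#'   array (single spot); n = 27 / 27, fold 2.
#' * `F5_laminB1_rim` — ms2 RNA vs MCP at the inner nuclear membrane
#'   (nuclear rim); n = 21 / 24, fold 2.
#' * `F5_chromocenter_MCP` — ms2 RNA vs MCP at chromocenters
#'   (multi-puncta, ~20 puncta); n = 23 / 26, fold 3.
#' * `F6_dCas13a_MCP` — ms2 RNA trapped by dCas13a vs MCP at a lacO array
#'   (single spot); n = 21 / 26, fold 2.
#'
#' @param name preset name.
#' @param null if `TRUE`, return the matched null design: identical in
#'   every respect but with all folds set to 1 (no specific binding).
#' @param seed RNG seed stored in the config.
#' @return An [simulation_config()].
#' @export
figure_preset <- function(name = c("F1_pp7_PCP", "F2_polyA_PABPC1",
                                   "F5_laminB1_rim", "F5_chromocenter_MCP",
                                   "F6_dCas13a_MCP"),
                          null = FALSE, seed = 1L) {
  name <- match.arg(name)
  design <- switch(
    name,
    F1_pp7_PCP = list(
      geometry = anchor_geometry("single_spot"),
      conditions = tibble(label = c("-RNA", "+ms2-pp7"), n_cells = c(23L, 24L),
                          fold = c(1, 2), is_control = c(TRUE, FALSE))
    ),
    F2_polyA_PABPC1 = list(
      geometry = anchor_geometry("single_spot"),
      conditions = tibble(label = c("-RNA", "+ms2-polyA"), n_cells = c(27L, 27L),
                          fold = c(1, 2), is_control = c(TRUE, FALSE))
    ),
    F5_laminB1_rim = list(
      geometry = anchor_geometry("nuclear_rim"),
      conditions = tibble(label = c("-RNA", "+ms2"), n_cells = c(21L, 24L),
                          fold = c(1, 2), is_control = c(TRUE, FALSE))
    ),
    F5_chromocenter_MCP = list(
      geometry = anchor_geometry("multi_puncta", spot_sigma_px = 2),
      conditions = tibble(label = c("-RNA", "+ms2"), n_cells = c(23L, 26L),
                          fold = c(1, 3), is_control = c(TRUE, FALSE)),
      structure = list(n_puncta_range = c(15, 25))
    ),
    F6_dCas13a_MCP = list(
      geometry = anchor_geometry("single_spot"),
      conditions = tibble(label = c("-RNA", "+ms2+gRNA"), n_cells = c(21L, 26L),
                          fold = c(1, 2), is_control = c(TRUE, FALSE))
    )
  )
  if (null) design$conditions$fold[] <- 1
  simulation_config(conditions = design$conditions, geometry = design$geometry,
                    structure = design$structure %||% list(), seed = seed)
}

#' Measure simulated cells with ground-truth masks injected
#'
#' Bypasses segmentation and anchor detection entirely: each simulated
#' cell's true nucleus and anchor masks are fed straight into the
#' intensity measurement, producing the same measurement table as
#' [measure_cells()]. This isolates the quantification arithmetic from the
#' detection stages (the noise-free oracle check) and gives a fast
#' measurement path for statistical calibration studies.
#'
#' @param sim an `rf3h_simulation`.
#' @param denom_floor_frac see [measure_masks()].
#' @return Measurement tibble in the [measure_cells()] schema.
#' @export
measure_with_truth_masks <- function(sim, denom_floor_frac = 0.05) {
  stopifnot(inherits(sim, "rf3h_simulation"))
  purrr::map_dfr(seq_len(nrow(sim$truth)), function(i) {
    tr <- sim$truth[i, ]
    img <- purrr::detect(sim$images[[tr$condition]],
                         function(im) im$source_id == tr$source_id)
    measure_masks(img, tr$anchor_mask[[1]], tr$nucleus_mask[[1]],
                  denom_floor_frac = denom_floor_frac) %>%
      mutate(source_id = tr$source_id, cell = 1L, condition = tr$condition,
             normalized_value = NA_real_) %>%
      select(dplyr::all_of(.MEASUREMENT_COLS))
  })
}
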