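#' Analyze a set of in-memory images grouped by condition
#'
#' The pipeline core shared by [rf3h_analyze()] (file-based) and
#' [analyze_simulation()] (in-memory): segment nuclei from the stain
#' channel, detect the anchor in the green channel, measure every cell,
#' apply QC, normalize by the control group and compute the group
#' comparisons.
#'
#' @param images named list (by condition label) of lists of
#'   [multichannel_image()]s.
#' @param control control condition label.
#' @param geometry an [anchor_geometry()].
#' @param segmentation list of `blur_sigma`, `min_area`, `max_area`.
#' @param qc list of `denom_floor_frac`.
#' @return An object of class `rf3h_results`: list with `cells` (per-cell
#'   tibble, QC-annotated and normalized), `groups` (per-condition summary),
#'   `stats` (comparisons vs control), `control`, and `counts` (per-stage
#'   accounting: segmented = kept + rejected).
#' @export
analyze_images <- function(images, control, geometry,
                           segmentation = list(blur_sigma = 2, min_area = 300,
                                               max_area = 8000),
                           qc = list(denom_floor_frac = 0.05)) {
  if (!control %in% names(images)) {
    abort(sprintf("Control condition '%s' not among the image groups.", control),
          class = "rf3h_config_error")
  }
  cells <- purrr::imap_dfr(images, function(imgs, label) {
    purrr::map_dfr(imgs, function(img) {
      nuc <- segment_nuclei(get_channel(img, "nuclear_stain"),
                            min_area = segmentation$min_area,
                            max_area = segmentation$max_area,
                            blur_sigma = segmentation$blur_sigma)
      measure_cells(img, nuc, geometry, condition = label,
                    denom_floor_frac = qc$denom_floor_frac)
    })
  })
  parts <- qc_filter(cells, denom_floor_frac = qc$denom_floor_frac,
                     min_area = segmentation$min_area,
                     max_area = segmentation$max_area)
  cells <- bind_rows(parts$kept, parts$rejected) %>%
    arrange(.data$condition, .data$source_id, .data$cell)
  cells <- normalize_by_control(cells, control)
  groups <- summarize_groups(cells, control = control)
  stats <- compare_to_control(cells, control)
  counts <- list(
    segmented = nrow(cells),
    kept = nrow(parts$kept),
    rejected = nrow(parts$rejected),
    rejected_by_reason = table(parts$rejected$qc_reason)
  )
  stopifnot(counts$segmented == counts$kept + counts$rejected)
  structure(list(cells = cells, groups = groups, stats = stats,
                 control = control, counts = counts),
            class = "rf3h_results")
}

#' @export
print.rf3h_results <- function(x, ...) {
  cat(sprintf("<rf3h_results> %d cells (%d kept, %d rejected), control '%s'\n",
              x$counts$segmented, x$counts$kept, x$counts$rejected, x$control))
  print(x$groups)
  invisible(x)
}

#' Run the full pipeline on a simulated experiment in memory
#'
#' @param sim an `rf3h_simulation` from [simulate_experiment()].
#' @param segmentation,qc see [analyze_images()].
#' @return An `rf3h_results` object.
#' @export
analyze_simulation <- function(sim,
                               segmentation = list(blur_sigma = 2,
                                                   min_area = 300,
                                                   max_area = 8000),
                               qc = list(denom_floor_frac = 0.05)) {
  stopifnot(inherits(sim, "rf3h_simulation"))
  ctrl <- sim$config$conditions$label[sim$config$conditions$is_control]
  analyze_images(sim$images, control = ctrl, geometry = sim$config$geometry,
                 segmentation = segmentation, qc = qc)
}

#' Write a synthetic rF3H dataset to disk
#'
#' Simulates an experiment and writes everything [rf3h_analyze()] needs to
#' re-analyze it from files: one multi-page TIFF per field of view under
#' `images/`, a `manifest.yaml` naming the conditions, control group and
#' analysis parameters, and a `ground_truth.csv` with the generative
#' per-cell levels and expected raw ratios.
#'
#' @param config a preset name accepted by [figure_preset()] or an
#'   [simulation_config()].
#' @param out_dir output directory, created if absent.
#' @param seed RNG seed (overrides the config's).
#' @return Invisibly, a list with `dir`, `manifest` (path), `truth` (path)
#'   and the `rf3h_simulation` object.
#' @export
rf3h_simulate_dataset <- function(config, out_dir, seed = NULL) {
  if (is.character(config)) config <- figure_preset(config, seed = seed %||% 1L)
  stopifnot(inherits(config, "rf3h_sim_config"))
  sim <- simulate_experiment(config, seed = seed)
  img_dir <- file.path(out_dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  cond_list <- lapply(seq_len(nrow(config$conditions)), function(ci) {
    cond <- config$conditions[ci, ]
    paths <- vapply(sim$images[[cond$label]], function(img) {
      p <- file.path("images", paste0(img$source_id, ".tif"))
      write_image(img, file.path(out_dir, p))
      p
    }, character(1))
    list(label = cond$label, is_control = cond$is_control, images = paths)
  })
  manifest <- experiment_manifest(conditions = cond_list,
                                  geometry = config$geometry)
  manifest_path <- file.path(out_dir, "manifest.yaml")
  write_manifest(manifest, manifest_path)
  truth <- sim$truth %>%
    mutate(spot_r = vapply(.data$spot_center, function(m) m[1, 1], double(1)),
           spot_c = vapply(.data$spot_center, function(m) m[1, 2], double(1))) %>%
    select(-"nucleus_mask", -"anchor_mask", -"spot_center")
  truth_path <- file.path(out_dir, "ground_truth.csv")
  readr::write_csv(truth, truth_path, progress = FALSE)
  invisible(list(dir = out_dir, manifest = manifest_path, truth = truth_path,
                 sim = sim))
}

#' Run the file-based analysis pipeline
#'
#' Reads a manifest, analyzes every image, and writes `cells.csv` (per-cell
#' measurements), `groups.csv` (per-condition summaries), `stats.csv`
#' (comparisons vs control) and `run.log` (all parameters echoed, per-stage
#' cell counts and the QC rejection tally) into `out_dir`. Re-running on the
#' same inputs reproduces the outputs byte for byte: no stage is stochastic.
#'
#' @param manifest_path path to a manifest YAML (see [read_manifest()]).
#' @param out_dir output directory, created if absent.
#' @param plots also write `enrichment.png` (scatter with mean ± SD bars and
#'   significance stars); cosmetic, never load-bearing.
#' @return Invisibly, the `rf3h_results` object with an `paths` attribute
#'   naming the written artifacts.
#' @export
rf3h_analyze <- function(manifest_path, out_dir, plots = FALSE) {
  m <- read_manifest(manifest_path)
  ctrl <- purrr::detect(m$conditions, function(c) isTRUE(c$is_control))$label
  images <- setNames(
    lapply(m$conditions, function(cond) {
      lapply(cond$images, function(p) {
        if (!file.exists(p)) {
          abort(sprintf("Image not readable: %s", p), class = "rf3h_io_error")
        }
        read_image(p)
      })
    }),
    vapply(m$conditions, function(c) c$label, character(1))
  )
  res <- analyze_images(images, control = ctrl, geometry = m$geometry,
                        segmentation = m$segmentation, qc = m$qc)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(cells = file.path(out_dir, "cells.csv"),
                groups = file.path(out_dir, "groups.csv"),
                stats = file.path(out_dir, "stats.csv"),
                log = file.path(out_dir, "run.log"))
  write_measurements(res$cells, paths$cells)
  readr::write_csv(res$groups, paths$groups, progress = FALSE)
  readr::write_csv(res$stats, paths$stats, progress = FALSE)
  writeLines(.run_log_lines(m, res), paths$log)
  if (plots) {
    paths$plot <- file.path(out_dir, "enrichment.png")
    ggplot2::ggsave(paths$plot, plot_enrichment(res), width = 4, height = 4,
                    dpi = 150)
  }
  attr(res, "paths") <- paths
  invisible(res)
}

.run_log_lines <- function(manifest, res) {
  rej <- res$counts$rejected_by_reason
  c(
    "rf3h analysis run",
    sprintf("control: %s", res$control),
    sprintf("geometry: kind=%s spot_sigma_px=%g detect_threshold=%g rim_band_px=%g",
            manifest$geometry$kind, manifest$geometry$spot_sigma_px,
            manifest$geometry$detect_threshold, manifest$geometry$rim_band_px),
    sprintf("segmentation: blur_sigma=%g min_area=%g max_area=%g",
            manifest$segmentation$blur_sigma, manifest$segmentation$min_area,
            manifest$segmentation$max_area),
    sprintf("qc: denom_floor_frac=%g", manifest$qc$denom_floor_frac),
    vapply(manifest$conditions, function(c) {
      sprintf("condition: %s%s images=%d", c$label,
              if (isTRUE(c$is_control)) " (control)" else "", length(c$images))
    }, character(1)),
    sprintf("cells segmented: %d", res$counts$segmented),
    sprintf("cells kept: %d", res$counts$kept),
    sprintf("cells rejected: %d", res$counts$rejected),
    if (length(rej)) paste0("  rejected ", names(rej), ": ", as.integer(rej))
    else character(0),
    "accounting: kept + rejected == segmented (asserted)"
  )
}
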