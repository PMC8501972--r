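#' Per-cell relative-fluorescence enrichment ratio
#'
#' The core per-cell statistic of the rF3H assay:
#' \deqn{(Red_{anchor} - Red_{nucleus}) / (Green_{anchor} - Green_{nucleus})}
#' where each term is the mean gray value over the anchor region or the
#' whole nucleus in the red (protein) or green (trap) channel. The
#' nucleus-wide means normalize cell-to-cell variation in expression level;
#' subtracting them makes the ratio invariant to any additive intensity
#' offset, and dividing by the green excess makes it independent of how much
#' trap accumulated at the anchor. Negative ratios (a red dip at the anchor)
#' are kept, not clipped.
#'
#' @param red_anchor,red_nucleus,green_anchor,green_nucleus mean intensities
#'   (vectorized; arbitrary units).
#' @param denom_floor minimum green excess (same units) below which the
#'   ratio is undefined (`NA`) — a trap spot too weak to measure against.
#' @return Numeric vector of raw ratios, `NA` where the denominator does not
#'   clear the floor.
#' @export
#' @examples
#' relative_fluorescence(15, 5, 30, 10)  # (15-5)/(30-10) = 0.5
relative_fluorescence <- function(red_anchor, red_nucleus,
                                  green_anchor, green_nucleus,
                                  denom_floor = 0) {
  denom <- green_anchor - green_nucleus
  ratio <- (red_anchor - red_nucleus) / denom
  ratio[denom <= denom_floor] <- NA_real_
  ratio
}

#' Measure one cell from explicit masks
#'
#' Computes the four mean intensities of the enrichment ratio over given
#' anchor and reference masks. Used internally by [measure_cells()] and
#' directly when ground-truth masks from the simulator are injected to
#' bypass segmentation.
#'
#' @param image an [multichannel_image()].
#' @param anchor_mask,reference_mask logical masks; the reference is the
#'   whole nucleus (anchor pixels included). An empty anchor yields `NA`
#'   anchor means and a `no_anchor` QC failure; reference means are still
#'   recorded.
#' @param denom_floor_frac denominator floor as a fraction of the nuclear
#'   green mean (default 0.05: the green excess at the anchor must exceed
#'   5% of the nucleus-wide green level).
#' @return One-row tibble with the four means, `anchor_area`, `area`,
#'   `raw_ratio`, `qc_pass`, `qc_reason`.
#' @export
measure_masks <- function(image, anchor_mask, reference_mask,
                          denom_floor_frac = 0.05) {
  stopifnot(inherits(image, "rf3h_image"))
  if (!any(reference_mask)) abort("reference_mask must be non-empty.")
  green <- get_channel(image, "trap_green")
  red <- get_channel(image, "poi_red")
  gn <- mean(green[reference_mask])
  rn <- mean(red[reference_mask])
  if (any(anchor_mask)) {
    ga <- mean(green[anchor_mask])
    ra <- mean(red[anchor_mask])
    floor_au <- denom_floor_frac * gn
    ratio <- relative_fluorescence(ra, rn, ga, gn, denom_floor = floor_au)
    pass <- !is.na(ratio)
    reason <- if (pass) NA_character_ else "weak_trap"
  } else {
    ga <- NA_real_; ra <- NA_real_; ratio <- NA_real_
    pass <- FALSE; reason <- "no_anchor"
  }
  tibble(
    area = sum(reference_mask), anchor_area = sum(anchor_mask),
    green_anchor = ga, green_nucleus = gn,
    red_anchor = ra, red_nucleus = rn,
    raw_ratio = ratio, qc_pass = pass, qc_reason = reason
  )
}

#' Measure every segmented cell in an image
#'
#' For each nucleus, detects the anchor structure in the green channel under
#' the given geometry and computes the four mean intensities and the raw
#' enrichment ratio. One row per cell; cells whose anchor is undetectable or
#' whose trap signal is too weak are flagged rather than dropped, so every
#' segmented nucleus is accounted for.
#'
#' @param image an [multichannel_image()].
#' @param nuclei an `rf3h_nuclei` segmentation of the image.
#' @param geometry an [anchor_geometry()].
#' @param condition condition label recorded on each row.
#' @param denom_floor_frac see [measure_masks()].
#' @return Tibble with columns `source_id`, `cell`, `condition`, `area`,
#'   `anchor_area`, the four means, `raw_ratio`, `normalized_value` (`NA`
#'   until [normalize_by_control()]), `qc_pass`, `qc_reason`.
#' @export
measure_cells <- function(image, nuclei, geometry, condition = NA_character_,
                          denom_floor_frac = 0.05) {
  stopifnot(inherits(nuclei, "rf3h_nuclei"))
  green <- get_channel(image, "trap_green")
  rows <- purrr::map_dfr(nuclei$cells$cell, function(lab) {
    nm <- nucleus_mask(nuclei, lab)
    det <- detect_anchor(green, nm, geometry)
    measure_masks(image, det$anchor, det$reference,
                  denom_floor_frac = denom_floor_frac) %>%
      mutate(cell = lab, .before = 1)
  })
  if (nrow(rows) == 0) {
    rows <- measure_masks(
      multichannel_image(list(nuclear_stain = matrix(0, 1, 1),
                              trap_green = matrix(0, 1, 1),
                              poi_red = matrix(0, 1, 1))),
      matrix(FALSE, 1, 1), matrix(TRUE, 1, 1)
    )[0, ] %>% mutate(cell = integer(0), .before = 1)
  }
  rows %>%
    mutate(source_id = image$source_id, condition = condition,
           normalized_value = NA_real_) %>%
    select("source_id", "cell", "condition", "area", "anchor_area",
           "green_anchor", "green_nucleus", "red_anchor", "red_nucleus",
           "raw_ratio", "normalized_value", "qc_pass", "qc_reason")
}

#' Split measurements into QC-passing and rejected cells
#'
#' Re-applies the quality rules to a measurement table: a cell is rejected
#' when its anchor is empty (`no_anchor`), its green excess does not clear
#' the denominator floor (`weak_trap`), or its nucleus area falls outside
#' the admissible range (`area_out_of_bounds`). Every rejection carries a
#' reason code; the two parts partition the input.
#'
#' @param records measurement tibble from [measure_cells()].
#' @param denom_floor_frac denominator floor as a fraction of the nuclear
#'   green mean.
#' @param min_area,max_area admissible nucleus area (px^2).
#' @return List with tibbles `kept` and `rejected`.
#' @export
qc_filter <- function(records, denom_floor_frac = 0.05,
                      min_area = 0, max_area = Inf) {
  records <- records %>%
    mutate(
      qc_reason = dplyr::case_when(
        .data$anchor_area == 0 ~ "no_anchor",
        is.na(.data$green_anchor) |
          (.data$green_anchor - .data$green_nucleus) <=
            denom_floor_frac * .data$green_nucleus ~ "weak_trap",
        .data$area < min_area | .data$area > max_area ~ "area_out_of_bounds",
        TRUE ~ NA_character_
      ),
      qc_pass = is.na(.data$qc_reason)
    )
  list(kept = filter(records, .data$qc_pass),
       rejected = filter(records, !.data$qc_pass))
}

#' Normalize raw ratios by the no-RNA control group
#'
#' Divides every cell's raw enrichment ratio by the arithmetic mean raw
#' ratio of the QC-passing control cells, so the control group's normalized
#' mean is exactly 1 by construction and other groups read as fold
#' enrichment over background (nonspecific) recruitment.
#'
#' @param records measurement tibble with `condition`, `raw_ratio`,
#'   `qc_pass` columns.
#' @param control label of the control condition.
#' @return The tibble with `normalized_value` filled in (`NA` for QC-failed
#'   cells).
#' @export
normalize_by_control <- function(records, control) {
  if (!control %in% records$condition) {
    abort(sprintf("Control condition '%s' not present in the records.", control))
  }
  ctrl <- records %>%
    filter(.data$condition == control, .data$qc_pass, !is.na(.data$raw_ratio))
  if (nrow(ctrl) < 3) {
    abort(sprintf(
      "Control group '%s' has %d QC-passing cells; at least 3 are required for normalization.",
      control, nrow(ctrl)), class = "rf3h_control_error")
  }
  ctrl_mean <- mean(ctrl$raw_ratio)
  if (ctrl_mean <= 0) {
    abort(sprintf(
      "Control group mean raw ratio is %.4g (<= 0); normalization is undefined.",
      ctrl_mean), class = "rf3h_control_error")
  }
  records %>%
    mutate(normalized_value = ifelse(.data$qc_pass,
                                     .data$raw_ratio / ctrl_mean, NA_real_))
}

#' Per-condition summary of normalized enrichment
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of the
#' normalized values over QC-passing cells, the presentation the assay uses
#' for its scatter plots. `sd` is `NA` for a single-cell group.
#'
#' @param records normalized measurement tibble.
#' @param control optional control label, recorded as `is_control`.
#' @return Tibble with `condition`, `is_control`, `n`, `mean`, `sd`.
#' @export
summarize_groups <- function(records, control = NULL) {
  records %>%
    filter(.data$qc_pass, !is.na(.data$normalized_value)) %>%
    group_by(.data$condition) %>%
    summarise(n = dplyr::n(),
              mean = mean(.data$normalized_value),
              sd = sd(.data$normalized_value), .groups = "drop") %>%
    mutate(is_control = if (is.null(control)) NA else .data$condition == control,
           .after = "condition")
}

# fixed per-cell CSV schema, documented in write_measurements()
.MEASUREMENT_COLS <- c("source_id", "cell", "condition", "area", "anchor_area",
                       "green_anchor", "green_nucleus", "red_anchor",
                       "red_nucleus", "raw_ratio", "normalized_value",
                       "qc_pass", "qc_reason")

#' Write per-cell measurements to CSV
#'
#' One row per cell with the fixed header `source_id, cell, condition, area,
#' anchor_area, green_anchor, green_nucleus, red_anchor, red_nucleus,
#' raw_ratio, normalized_value, qc_pass, qc_reason`. An empty record set
#' writes the header only. Doubles are written at full precision, so a
#' write–read round trip reproduces them to at least 12 significant digits.
#'
#' @param records measurement tibble (possibly empty).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  missing_cols <- setdiff(.MEASUREMENT_COLS, names(records))
  if (length(missing_cols)) {
    abort(sprintf("records is missing columns: %s",
                  paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(records[, .MEASUREMENT_COLS], path, progress = FALSE)
  invisible(path)
}

#' Read a per-cell measurement CSV written by [write_measurements()]
#'
#' @param path CSV path.
#' @return Measurement tibble with the documented column types.
#' @export
read_measurements <- function(path) {
  readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(
      source_id = readr::col_character(), cell = readr::col_integer(),
      condition = readr::col_character(), area = readr::col_double(),
      anchor_area = readr::col_double(), green_anchor = readr::col_double(),
      green_nucleus = readr::col_double(), red_anchor = readr::col_double(),
      red_nucleus = readr::col_double(), raw_ratio = readr::col_double(),
      normalized_value = readr::col_double(), qc_pass = readr::col_logical(),
      qc_reason = readr::col_character()
    )
  )
}
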