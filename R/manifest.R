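#' Experiment manifest: conditions, control group and analysis parameters
#'
#' The manifest is the run configuration of an rF3H analysis. It names the
#' experimental conditions, lists the image files belonging to each, flags
#' exactly one condition as the no-RNA control (the normalization reference),
#' and carries the anchor geometry, segmentation and QC parameters. It is
#' stored as YAML; unknown keys are rejected so that typos never silently
#' fall back to defaults.
#'
#' @param conditions a data frame (or list of lists) with columns/fields
#'   `label`, `is_control`, `images` (list of image paths per condition).
#' @param geometry an [anchor_geometry()] object.
#' @param segmentation list of nucleus-partitioning parameters:
#'   `blur_sigma` (px), `min_area` (px^2), `max_area` (px^2).
#' @param qc list of quality-control parameters: `denom_floor_frac`, the
#'   green-enrichment denominator floor as a fraction of the nuclear green
#'   mean.
#' @return An object of class `rf3h_manifest`.
#' @export
experiment_manifest <- function(conditions,
                                geometry = anchor_geometry("single_spot"),
                                segmentation = list(blur_sigma = 2,
                                                    min_area = 300,
                                                    max_area = 8000),
                                qc = list(denom_floor_frac = 0.05)) {
  if (is.data.frame(conditions)) {
    conditions <- purrr::pmap(conditions, function(label, is_control, images, ...) {
      list(label = label, is_control = is_control,
           images = unlist(images, use.names = FALSE))
    })
  }
  m <- structure(
    list(conditions = conditions, geometry = geometry,
         segmentation = segmentation, qc = qc),
    class = "rf3h_manifest"
  )
  validate_manifest(m)
}

#' Validate an experiment manifest
#'
#' Checks the invariants every downstream stage relies on: unique non-empty
#' condition labels, exactly one control condition, well-formed geometry and
#' complete parameter lists.
#'
#' @param m an `rf3h_manifest` object or the equivalent plain list.
#' @return The validated manifest, invisibly classed `rf3h_manifest`.
#' @export
validate_manifest <- function(m) {
  known <- c("conditions", "segmentation", "qc", "geometry")
  extra <- setdiff(names(m), known)
  if (length(extra)) {
    abort(sprintf("Unknown manifest keys: %s", paste(extra, collapse = ", ")), class = "rf3h_config_error")
  }
  missing <- setdiff(known, names(m))
  if (length(missing)) {
    abort(sprintf("Manifest is missing keys: %s", paste(missing, collapse = ", ")), class = "rf3h_config_error")
  }
  conds <- m$conditions
  if (length(conds) == 0) abort("Manifest must list at least one condition.", class = "rf3h_config_error")
  labels <- vapply(conds, function(x) as.character(x$label %||% ""), character(1))
  if (any(!nzchar(labels)) || anyDuplicated(labels)) {
    abort("Condition labels must be unique and non-empty.", class = "rf3h_config_error")
  }
  ctrl <- vapply(conds, function(x) isTRUE(x$is_control), logical(1))
  if (sum(ctrl) != 1) {
    abort(sprintf("Exactly one condition must have is_control = true (found %d).",
                  sum(ctrl)), class = "rf3h_config_error")
  }
  if (!inherits(m$geometry, "rf3h_geometry")) {
    m$geometry <- do.call(anchor_geometry, m$geometry)
  }
  seg_known <- c("blur_sigma", "min_area", "max_area")
  if (length(setdiff(names(m$segmentation), seg_known)) ||
      length(setdiff(seg_known, names(m$segmentation)))) {
    abort(sprintf("segmentation must define exactly: %s",
                  paste(seg_known, collapse = ", ")), class = "rf3h_config_error")
  }
  if (!identical(names(m$qc), "denom_floor_frac")) {
    abort("qc must define exactly: denom_floor_frac", class = "rf3h_config_error")
  }
  class(m) <- "rf3h_manifest"
  invisible(m)
}

#' @export
print.rf3h_manifest <- function(x, ...) {
  labs <- vapply(x$conditions, function(c) {
    sprintf("%s%s (%d images)", c$label, if (isTRUE(c$is_control)) "*" else "",
            length(c$images))
  }, character(1))
  cat(sprintf("<rf3h_manifest> geometry: %s; conditions: %s (* = control)\n",
              x$geometry$kind, paste(labs, collapse = ", ")))
  invisible(x)
}

#' Read and validate a YAML experiment manifest
#'
#' @param path path to a manifest YAML file. Relative image paths are
#'   resolved against the manifest's directory.
#' @return A validated `rf3h_manifest`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) abort(sprintf("Manifest not found: %s", path))
  raw <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  raw$conditions <- lapply(raw$conditions, function(cond) {
    cond$images <- vapply(cond$images, function(p) {
      if (file.exists(p)) p else file.path(base, p)
    }, character(1))
    cond
  })
  validate_manifest(raw)
}

#' Write an experiment manifest to YAML
#'
#' @param m a validated `rf3h_manifest`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(m, path) {
  m <- validate_manifest(m)
  out <- list(
    conditions = lapply(m$conditions, function(c) {
      list(label = c$label, is_control = isTRUE(c$is_control),
           images = as.list(c$images))
    }),
    geometry = unclass(m$geometry),
    segmentation = m$segmentation,
    qc = m$qc
  )
  out$geometry <- out$geometry[!vapply(out$geometry, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
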