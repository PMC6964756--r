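#' Read and write plan files
#'
#' Plans are stored as versioned JSON:
#' ```
#' {
#'   "schema_version": "1.0",
#'   "gamma_deg": 90,
#'   "calibration": {"dose_rate_Gy_per_min": 3.0, "date": "2026-01-01"},
#'   "shots": [
#'     {"isocenter_mm": [100,100,100], "sectors": ["16", ... 8 states ...],
#'      "duration_min": 1.0}
#'   ],
#'   "skull": {"mode": "threshold", "path": "image.nii.gz", "threshold": -400}
#' }
#' ```
#' The optional `skull` block records how the skull used for the check was
#' rendered (`mode` is `"threshold"` or `"scalar"`); dosimetric parameter
#' overrides may be supplied under `"params"`.
#'
#' @param path JSON file path.
#' @param geometry unit geometry attached to the plan on read.
#' @return `read_plan()` returns a [gk_plan()] (with the `skull` block, if
#'   any, in attribute `skull_ref`); `write_plan()` returns `path`
#'   invisibly.
#' @export
read_plan <- function(path, geometry = gk_geometry()) {
  if (!file.exists(path)) abort(sprintf("plan file not found: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (field in c("gamma_deg", "shots", "calibration")) {
    if (is.null(j[[field]])) {
      abort(sprintf("plan schema error: missing field `%s` in %s", field, path))
    }
  }
  if (is.null(j$calibration$dose_rate_Gy_per_min)) {
    abort("plan schema error: missing field `calibration.dose_rate_Gy_per_min`")
  }
  shots <- purrr::imap(j$shots, function(s, i) {
    for (field in c("isocenter_mm", "sectors", "duration_min")) {
      if (is.null(s[[field]])) {
        abort(sprintf("plan schema error: shot %d is missing field `%s`", i, field))
      }
    }
    if (length(s$sectors) != 8L) {
      abort(sprintf("plan schema error: shot %d `sectors` must have 8 entries", i))
    }
    gk_shot(unlist(s$isocenter_mm), sectors = unlist(s$sectors),
            duration_min = s$duration_min)
  })
  pj <- j$params
  params <- gk_dose_params(
    dose_rate = j$calibration$dose_rate_Gy_per_min,
    mu = pj$mu_per_mm %||% 0.0063,
    d_ref = pj$d_ref_mm %||% 80,
    output_factors = unlist(pj$output_factors) %||%
      c("4" = 0.814, "8" = 0.900, "16" = 1.000),
    field_radius = unlist(pj$field_radius_mm) %||% c("4" = 2, "8" = 4, "16" = 8),
    penumbra = unlist(pj$penumbra_mm) %||% c("4" = 0.6, "8" = 0.8, "16" = 1.1),
    calibration_date = if (is.character(j$calibration$date) &&
                           length(j$calibration$date) == 1L) {
      as.Date(j$calibration$date)
    }
  )
  plan <- gk_plan(shots, gamma_deg = j$gamma_deg, params = params,
                  geometry = geometry)
  attr(plan, "skull_ref") <- j$skull
  plan
}

#' @rdname read_plan
#' @param plan a [gk_plan()].
#' @param skull_ref optional list describing the skull source (stored
#'   verbatim under `"skull"`).
#' @export
write_plan <- function(plan, path, skull_ref = attr(plan, "skull_ref")) {
  stopifnot(inherits(plan, "gk_plan"))
  p <- plan$params
  out <- list(
    schema_version = "1.0",
    gamma_deg = plan$gamma_deg,
    calibration = list(
      dose_rate_Gy_per_min = p$dose_rate,
      date = if (!is.null(p$calibration_date)) format(p$calibration_date)
    ),
    params = list(
      mu_per_mm = p$mu, d_ref_mm = p$d_ref,
      output_factors = as.list(p$output_factors),
      field_radius_mm = as.list(p$field_radius),
      penumbra_mm = as.list(p$penumbra)
    ),
    shots = purrr::map(seq_len(nrow(plan$shots)), function(i) {
      s <- plan$shots[i, ]
      list(isocenter_mm = c(s$iso_x, s$iso_y, s$iso_z),
           sectors = as.list(s$sectors[[1]]),
           duration_min = s$duration_min)
    }),
    skull = skull_ref
  )
  out <- out[!vapply(out, is.null, TRUE)]
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Build a skull model from a run configuration
#'
#' Resolves exactly one skull source — a voxel image to threshold, or a
#' 24-measurement CSV — into a queryable skull model. Used by the
#' command-line interface.
#'
#' @param image_path NIfTI path (threshold mode), or `NULL`.
#' @param measurements_path 24-row measurement CSV (scalar mode), or `NULL`.
#' @param threshold image-scale threshold for CT thresholding.
#' @param z_base base plane for the scalar realization, mm.
#' @return A skull model.
#' @export
resolve_skull <- function(image_path = NULL, measurements_path = NULL,
                          threshold = -400, z_base = 0) {
  if (is.null(image_path) == is.null(measurements_path)) {
    abort("exactly one of `image_path` or `measurements_path` must be given")
  }
  if (!is.null(image_path)) {
    if (!file.exists(image_path)) abort(sprintf("image not found: %s", image_path))
    threshold_skull(read_gk_image(image_path), threshold = threshold)
  } else {
    if (!file.exists(measurements_path)) {
      abort(sprintf("measurements not found: %s", measurements_path))
    }
    skull_from_measurements(read_measurements(measurements_path), z_base = z_base)
  }
}
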