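#' Build the 192-source unit geometry
#'
#' Constructs explicit source coordinates for a Gamma Knife-style unit:
#' 192 Co-60 sources arranged in 8 azimuthal sectors of 24 sources each,
#' grouped in rings at fixed polar angles from the superior axis, every
#' source focused on a single point (the focus). Coordinates are expressed
#' in a right-handed Leksell-style stereotactic frame in millimetres with
#' the focus at (100, 100, 100): x runs patient left-right (the gamma
#' rotation axis), y posterior-anterior, z inferior-superior.
#'
#' The vendor's exact source map is proprietary, so the default layout
#' (shipped as `extdata/icon_like_default.json`) is an approximation that
#' preserves the 8 x 24 topology, polar angles of roughly 36-72 degrees and
#' focal distances of 370-435 mm; every number can be overridden through
#' `config`.
#'
#' @param config `NULL` for the shipped default, a path to a geometry JSON
#'   file, or an equivalent named list with elements `frame$focus_mm`,
#'   `n_sectors`, `sector_span_deg` and `rings` (each ring: `polar_deg`,
#'   `focal_mm`, `sources_per_sector`).
#'
#' @return An object of class `gk_geometry`: a list with `sources` (a tibble
#'   with one row per source: `source_id`, `ring`, `sector`, `polar_deg`,
#'   `azimuth_deg`, `focal_mm` and unit-frame coordinates `x`, `y`, `z`),
#'   `focus` (length-3 mm) and the parsed `config`.
#' @examples
#' geom <- gk_geometry()
#' nrow(geom$sources) # 192
#' @export
gk_geometry <- function(config = NULL) {
  cfg <- load_geometry_config(config)
  n_sectors <- as.integer(cfg$n_sectors)
  span <- as.numeric(cfg$sector_span_deg)
  rings <- cfg$rings
  if (is.data.frame(rings)) rings <- split(rings, seq_len(nrow(rings)))
  per_sector <- vapply(rings, function(r) as.integer(r$sources_per_sector), 1L)
  if (n_sectors * sum(per_sector) != 192L) {
    abort(sprintf(
      "geometry configuration invalid: %d sectors x %d sources per sector != 192",
      n_sectors, sum(per_sector)
    ))
  }
  focal <- vapply(rings, function(r) as.numeric(r$focal_mm), 1.0)
  if (any(focal <= 0)) abort("all ring focal distances must be > 0")
  focus <- as_point(cfg$frame$focus_mm, "frame$focus_mm")

  src <- purrr::imap(rings, function(r, i) {
    i <- as.integer(i)
    k <- as.integer(r$sources_per_sector)
    sector <- rep(seq_len(n_sectors) - 1L, each = k)
    az <- (sector * span) + (rep(seq_len(k), n_sectors) - 0.5) * span / k
    tibble(
      ring = i, sector = sector,
      polar_deg = as.numeric(r$polar_deg), azimuth_deg = az,
      focal_mm = as.numeric(r$focal_mm)
    )
  })
  src <- dplyr::bind_rows(src)
  th <- src$polar_deg * pi / 180
  ph <- src$azimuth_deg * pi / 180
  src <- src |>
    mutate(
      x = focus[1] + .data$focal_mm * sin(th) * cos(ph),
      y = focus[2] + .data$focal_mm * sin(th) * sin(ph),
      z = focus[3] + .data$focal_mm * cos(th)
    ) |>
    arrange(.data$sector, .data$ring, .data$azimuth_deg) |>
    mutate(source_id = dplyr::row_number(), .before = 1)

  structure(list(sources = src, focus = focus, config = cfg),
            class = "gk_geometry")
}

load_geometry_config <- function(config) {
  if (is.null(config)) {
    config <- system.file("extdata", "icon_like_default.json",
                          package = "icondose", mustWork = TRUE)
  }
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  }
  if (!is.list(config)) abort("`config` must be NULL, a file path, or a list")
  config
}

#' @export
print.gk_geometry <- function(x, ...) {
  cat(sprintf(
    "<gk_geometry> %d sources, %d sectors, %d rings; focus (%g, %g, %g) mm\n",
    nrow(x$sources), length(unique(x$sources$sector)),
    length(unique(x$sources$ring)), x$focus[1], x$focus[2], x$focus[3]
  ))
  invisible(x)
}

#' Validate a gamma angle
#'
#' The gamma angle describes the tilt of the patient's head relative to the
#' unit: 90 degrees is the standard setup, 70 and 110 degrees the
#' nonstandard ones. Values outside \[70, 110\] are rejected.
#'
#' @param gamma_deg scalar gamma angle in degrees.
#' @return The validated numeric angle.
#' @export
validate_gamma <- function(gamma_deg) {
  g <- as.numeric(gamma_deg)
  if (length(g) != 1L || !is.finite(g) || g < 70 || g > 110) {
    abort("`gamma_deg` must be a single value in [70, 110] degrees.")
  }
  g
}

#' Rotation matrix for a gamma angle
#'
#' Returns the proper 3x3 rotation about the patient left-right axis (+x)
#' through the focus that places beamlets for a nonstandard gamma angle.
#' By the package's sign convention, gamma 110 rotates beamlet positions by
#' +20 degrees and gamma 70 by -20 degrees; gamma 90 is the identity.
#'
#' @inheritParams validate_gamma
#' @return A 3x3 orthonormal matrix with determinant +1.
#' @examples
#' gamma_rotation(90) # identity
#' @export
gamma_rotation <- function(gamma_deg) {
  g <- validate_gamma(gamma_deg)
  a <- (g - 90) * pi / 180
  matrix(c(
    1, 0, 0,
    0, cos(a), -sin(a),
    0, sin(a), cos(a)
  ), nrow = 3L, byrow = TRUE)
}

#' Normalize an 8-sector collimator state vector
#'
#' @param sectors length-8 vector; each entry one of `4`, `8`, `16`
#'   (numeric or character) or `"blocked"`. A single value is recycled to
#'   all 8 sectors.
#' @return Character vector of length 8 with values `"4"`, `"8"`, `"16"`,
#'   `"blocked"`.
#' @export
sector_states <- function(sectors) {
  if (length(sectors) == 1L) sectors <- rep(sectors, 8L)
  if (length(sectors) != 8L) abort("`sectors` must have exactly 8 entries.")
  s <- tolower(as.character(sectors))
  s[s %in% c("b", "block", "off")] <- "blocked"
  ok <- s %in% c("4", "8", "16", "blocked")
  if (!all(ok)) {
    abort(sprintf("invalid sector state(s): %s (allowed: 4, 8, 16, blocked)",
                  paste(unique(s[!ok]), collapse = ", ")))
  }
  s
}

#' Place beamlets for a shot
#'
#' A beamlet is the ray from one source through the shot isocenter. Sources
#' are first rotated about the x-axis through the focus according to the
#' gamma angle, then translated so the unit focus coincides with the shot
#' isocenter; blocked sectors contribute no beamlets. Each active beamlet's
#' direction points exactly at the isocenter and its source-to-isocenter
#' distance equals the ring focal distance.
#'
#' @param geometry a [gk_geometry()] object.
#' @param isocenter length-3 shot isocenter, mm, patient frame.
#' @param sectors per-sector collimator states, see [sector_states()].
#' @param gamma_deg gamma angle in degrees (default 90, the standard setup).
#' @return A tibble with one row per active beamlet: `source_id`, `ring`,
#'   `sector`, `collimator` ("4"/"8"/"16"), `focal_mm`, source position
#'   `x`,`y`,`z` and unit direction `dx`,`dy`,`dz` (toward the isocenter).
#' @examples
#' bl <- place_beamlets(gk_geometry(), c(100, 100, 100), "16")
#' nrow(bl) # 192
#' @export
place_beamlets <- function(geometry, isocenter, sectors, gamma_deg = 90) {
  stopifnot(inherits(geometry, "gk_geometry"))
  iso <- as_point(isocenter, "isocenter")
  states <- sector_states(sectors)
  R <- gamma_rotation(gamma_deg)

  src <- geometry$sources
  coll <- states[src$sector + 1L]
  active <- coll != "blocked"
  src <- src[active, , drop = FALSE]
  if (nrow(src) == 0L) {
    return(tibble(
      source_id = integer(), ring = integer(), sector = integer(),
      collimator = character(), focal_mm = numeric(),
      x = numeric(), y = numeric(), z = numeric(),
      dx = numeric(), dy = numeric(), dz = numeric()
    ))
  }
  pos <- cbind(src$x, src$y, src$z)
  pos <- sweep(pos, 2, geometry$focus) %*% t(R)
  pos <- sweep(pos, 2, iso, `+`)
  dir <- unitize(matrix(iso, nrow(pos), 3, byrow = TRUE) - pos)

  tibble(
    source_id = src$source_id, ring = src$ring, sector = src$sector,
    collimator = coll[active], focal_mm = src$focal_mm,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    dx = dir[, 1], dy = dir[, 2], dz = dir[, 3]
  )
}
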