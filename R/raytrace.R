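#' Radiological depth of a point along source rays
#'
#' For each source position, casts the ray from the source toward `point`,
#' finds the first skull crossing and reports the path length from that
#' entry point to `point` — the attenuation depth used by the dose model.
#' The interior is treated as homogeneous: internal cavities and re-entrant
#' crossings after the first are ignored. Rays for which `point` lies
#' outside the skull (the ray misses, or enters beyond the point) are
#' flagged `missed` with zero depth.
#'
#' @param model a skull model (see [first_intersection()]).
#' @param sources n x 3 matrix (or length-3 vector) of source positions, mm.
#' @param point length-3 calculation point, mm.
#' @param quiet suppress the missed-ray warning.
#' @return A tibble with one row per source: `depth` (mm), `distance`
#'   (source-to-point, mm), `entry_distance` (mm along the ray; `NA` on a
#'   miss), `missed`.
#' @export
depth_to_point <- function(model, sources, point, quiet = FALSE) {
  src <- as_point_matrix(sources, "sources")
  pt <- as_point(point)
  diff <- matrix(pt, nrow(src), 3, byrow = TRUE) - src
  L <- vnorm(diff)
  if (any(L == 0)) abort("calculation point coincides with a source position")
  dirs <- diff / L

  fi <- first_intersection(model, src, dirs, t_max = max(L) + 1)
  entry <- ifelse(fi$inside_start, 0, fi$distance)
  missed <- !fi$hit & !fi$inside_start
  # the point must lie inside, i.e. past the entry but before the source-point end
  missed <- missed | (!is.na(entry) & entry > L)
  depth <- ifelse(missed, 0, L - entry)
  if (any(missed) && !quiet) {
    warn(sprintf("%d of %d ray(s) do not place the point inside the skull; depth set to 0",
                 sum(missed), length(missed)))
  }
  tibble(depth = depth, distance = L, entry_distance = ifelse(missed, NA_real_, entry),
         missed = missed)
}

#' Average calculation depth over a beamlet set
#'
#' The arithmetic mean of per-beamlet radiological depth over the active
#' beamlets that intersect the skull; beamlets that miss are excluded from
#' the mean and counted. This is the per-target "average calculation depth"
#' covariate used in the cohort evaluation.
#'
#' @param model a skull model.
#' @param beamlets a beamlet tibble from [place_beamlets()] (columns
#'   `x`,`y`,`z` are used as source positions).
#' @param point length-3 calculation point, mm.
#' @return A list with `average_depth_mm`, `n_used`, `n_missed`, and the
#'   per-beamlet `depths` tibble.
#' @export
average_depth <- function(model, beamlets, point) {
  if (nrow(beamlets) == 0L) abort("no active beamlets")
  d <- depth_to_point(model, cbind(beamlets$x, beamlets$y, beamlets$z), point,
                      quiet = TRUE)
  used <- !d$missed
  if (!any(used)) abort("all beamlets miss the skull at this point")
  list(
    average_depth_mm = mean(d$depth[used]),
    n_used = sum(used), n_missed = sum(!used),
    depths = d
  )
}
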