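#' Dosimetric parameters of the point-dose engine
#'
#' Parameters of the exponential-attenuation (TMR-style) beamlet model
#'
#' \deqn{\dot D_b = \frac{\dot D_{cal}}{192}\, OF_c\,
#'   e^{-\mu (d - d_{ref})}\, (f/r)^2\, P_c(\rho)}
#'
#' where \eqn{d} is the radiological depth of the calculation point along
#' beamlet \eqn{b}, \eqn{f} the ring focal distance, \eqn{r} the
#' source-to-point distance and \eqn{P_c} the off-axis profile
#' \eqn{P_c(\rho) = \frac{1}{2}\left[\mathrm{erf}((R_c-\rho)/s_c) +
#' \mathrm{erf}((R_c+\rho)/s_c)\right] / \mathrm{erf}(R_c/s_c)},
#' normalized to 1 on-axis, with \eqn{\rho} the perpendicular distance from
#' the beamlet axis scaled to the focal plane by \eqn{f/r}.
#'
#' @param dose_rate calibration dose rate, Gy/min, for the 16 mm collimator
#'   at the reference depth with all sectors open.
#' @param mu effective linear attenuation coefficient, mm^-1 (default
#'   0.0063, Co-60 in water).
#' @param d_ref reference calibration depth, mm (default 80, the centre of
#'   the standard 160 mm calibration sphere).
#' @param output_factors named unitless factors for collimators "4", "8",
#'   "16"; the 16 mm factor must be 1 (it is the normalization reference).
#' @param field_radius named nominal focal-plane field radii R_c, mm.
#' @param penumbra named penumbra widths s_c, mm.
#' @param calibration_date optional `Date` of the dose-rate calibration.
#' @param decay_correct apply Co-60 decay (half-life 5.2711 y) between
#'   `calibration_date` and `calc_date` at calculation time; off by default
#'   since paired secondary checks are same-day comparisons.
#' @return An object of class `gk_dose_params`.
#' @export
gk_dose_params <- function(dose_rate = 3.0, mu = 0.0063, d_ref = 80,
                           output_factors = c("4" = 0.814, "8" = 0.900, "16" = 1.000),
                           field_radius = c("4" = 2, "8" = 4, "16" = 8),
                           penumbra = c("4" = 0.6, "8" = 0.8, "16" = 1.1),
                           calibration_date = NULL, decay_correct = FALSE) {
  if (mu <= 0) abort("`mu` must be > 0")
  if (dose_rate <= 0) abort("`dose_rate` must be > 0")
  cs <- c("4", "8", "16")
  if (!all(cs %in% names(output_factors)) || abs(output_factors[["16"]] - 1) > 1e-12) {
    abort("`output_factors` must name collimators 4/8/16 with OF(16) = 1")
  }
  if (!all(cs %in% names(field_radius)) || is.unsorted(field_radius[cs])) {
    abort("`field_radius` must name 4/8/16 and increase with collimator size")
  }
  if (!all(cs %in% names(penumbra)) || any(penumbra <= 0)) {
    abort("`penumbra` must name 4/8/16 with positive widths")
  }
  structure(
    list(dose_rate = dose_rate, mu = mu, d_ref = d_ref,
         output_factors = output_factors[cs], field_radius = field_radius[cs],
         penumbra = penumbra[cs], calibration_date = calibration_date,
         decay_correct = isTRUE(decay_correct)),
    class = "gk_dose_params"
  )
}

#' @export
print.gk_dose_params <- function(x, ...) {
  cat(sprintf(
    "<gk_dose_params> %.4g Gy/min @ d_ref %g mm; mu %.4g /mm; OF 4/8/16 = %s\n",
    x$dose_rate, x$d_ref, x$mu, paste(x$output_factors, collapse = "/")
  ))
  invisible(x)
}

co60_decay_factor <- function(calibration_date, calc_date) {
  dy <- as.numeric(difftime(calc_date, calibration_date, units = "days")) / 365.25
  0.5^(dy / 5.2711)
}

#' Treatment plan container
#'
#' A plan is one or more shots (isocenter, 8 per-sector collimator states,
#' duration in minutes) delivered at a single gamma angle, together with the
#' dosimetric parameters and the unit geometry used to place beamlets.
#'
#' @param shots a tibble/data.frame with columns `iso_x`, `iso_y`, `iso_z`
#'   (mm), `duration_min`, and `sectors` (a list column of length-8 state
#'   vectors, see [sector_states()]); or a list of shots created by
#'   [gk_shot()].
#' @param gamma_deg plan gamma angle, degrees.
#' @param params a [gk_dose_params()].
#' @param geometry a [gk_geometry()]; defaults to the shipped unit model.
#' @return An object of class `gk_plan`.
#' @examples
#' plan <- gk_plan(gk_shot(c(100, 100, 100), "16", 1))
#' @export
gk_plan <- function(shots, gamma_deg = 90, params = gk_dose_params(),
                    geometry = gk_geometry()) {
  if (inherits(shots, "gk_shot")) shots <- list(shots)
  if (is.list(shots) && !is.data.frame(shots) && all(purrr::map_lgl(shots, inherits, "gk_shot"))) {
    shots <- purrr::map_dfr(shots, function(s) tibble::as_tibble_row(unclass(s)))
  }
  shots <- as_tibble(shots)
  need <- c("iso_x", "iso_y", "iso_z", "duration_min", "sectors")
  miss <- setdiff(need, names(shots))
  if (length(miss)) abort(sprintf("`shots` is missing column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(shots) < 1L) abort("a plan needs at least one shot")
  if (any(shots$duration_min < 0)) abort("shot durations must be >= 0 min")
  shots$sectors <- purrr::map(shots$sectors, sector_states)
  shots$shot_id <- seq_len(nrow(shots))
  structure(
    list(shots = shots, gamma_deg = validate_gamma(gamma_deg),
         params = params, geometry = geometry),
    class = "gk_plan"
  )
}

#' @rdname gk_plan
#' @param isocenter length-3 shot isocenter, mm.
#' @param sectors sector states for this shot (see [sector_states()]).
#' @param duration_min shot duration, minutes.
#' @export
gk_shot <- function(isocenter, sectors = "16", duration_min = 1) {
  iso <- as_point(isocenter, "isocenter")
  structure(
    list(iso_x = iso[1], iso_y = iso[2], iso_z = iso[3],
         duration_min = as.numeric(duration_min),
         sectors = list(sector_states(sectors))),
    class = c("gk_shot", "list")
  )
}

#' @export
print.gk_plan <- function(x, ...) {
  cat(sprintf("<gk_plan> %d shot(s), gamma %g deg, %.4g Gy/min calibration\n",
              nrow(x$shots), x$gamma_deg, x$params$dose_rate))
  invisible(x)
}

plan_beamlets <- function(plan) {
  purrr::map(seq_len(nrow(plan$shots)), function(i) {
    s <- plan$shots[i, ]
    place_beamlets(plan$geometry, c(s$iso_x, s$iso_y, s$iso_z),
                   s$sectors[[1]], plan$gamma_deg)
  })
}

# Per-beamlet dose rates at one point given precomputed depths.
beamlet_rates <- function(beamlets, point, depths, params, calc_date = NULL) {
  if (nrow(beamlets) == 0L) return(numeric(0))
  pt <- as_point(point)
  src <- cbind(beamlets$x, beamlets$y, beamlets$z)
  vec <- matrix(pt, nrow(src), 3, byrow = TRUE) - src
  r <- vnorm(vec)
  if (any(r < 1e-9)) abort("calculation point coincides with a source position")
  dir <- cbind(beamlets$dx, beamlets$dy, beamlets$dz)
  along <- rowSums(vec * dir)
  perp <- sqrt(pmax(0, r^2 - along^2))
  f <- beamlets$focal_mm
  rho <- perp * f / r

  cid <- as.character(beamlets$collimator)
  OF <- params$output_factors[cid]
  Rc <- params$field_radius[cid]
  sc <- params$penumbra[cid]
  P <- 0.5 * (erf((Rc - rho) / sc) + erf((Rc + rho) / sc)) / erf(Rc / sc)

  rate <- params$dose_rate / 192 * OF * exp(-params$mu * (depths - params$d_ref)) *
    (f / r)^2 * P
  if (params$decay_correct && !is.null(params$calibration_date)) {
    rate <- rate * co60_decay_factor(params$calibration_date,
                                     calc_date %||% Sys.Date())
  }
  unname(rate)
}

#' Dose rate of a single beamlet at a point
#'
#' Evaluates the beamlet model of [gk_dose_params()] for each row of a
#' beamlet tibble, given the radiological depth of the point along each
#' beamlet. Missed beamlets (depth result flagged `missed`) contribute 0.
#'
#' @param beamlets a beamlet tibble from [place_beamlets()].
#' @param point length-3 calculation point, mm.
#' @param depth a tibble from [depth_to_point()] (or a numeric depth vector,
#'   mm, with no misses).
#' @param params a [gk_dose_params()].
#' @return Numeric vector of dose rates, Gy/min, one per beamlet.
#' @export
beamlet_dose_rate <- function(beamlets, point, depth, params = gk_dose_params()) {
  if (is.data.frame(depth)) {
    d <- depth$depth
    missed <- depth$missed
  } else {
    d <- as.numeric(depth)
    missed <- rep(FALSE, length(d))
  }
  rate <- beamlet_rates(beamlets, point, d, params)
  rate[missed] <- 0
  rate
}

# Doses at many points; returns list(dose = numeric(npts), and for
# diagnostics the total missed-ray count and mean depth over used rays).
point_dose_batch <- function(plan, skull, points, chunk_rays = 500000L) {
  pts <- as_point_matrix(points)
  npts <- nrow(pts)
  bl_by_shot <- plan_beamlets(plan)
  dose <- matrix(0, npts, nrow(plan$shots))
  depth_sum <- 0; depth_n <- 0L; missed <- 0L

  for (s in seq_along(bl_by_shot)) {
    bl <- bl_by_shot[[s]]
    dur <- plan$shots$duration_min[s]
    if (nrow(bl) == 0L) next
    nb <- nrow(bl)
    chunk <- max(1L, chunk_rays %/% nb)
    for (start in seq(1L, npts, by = chunk)) {
      ii <- start:min(npts, start + chunk - 1L)
      bi <- rep(seq_len(nb), length(ii))
      pi <- rep(ii, each = nb)
      src <- cbind(bl$x, bl$y, bl$z)[bi, , drop = FALSE]
      ptm <- pts[pi, , drop = FALSE]
      vec <- ptm - src
      L <- vnorm(vec)
      dirs <- vec / L
      fi <- first_intersection(skull, src, dirs, t_max = max(L) + 1)
      entry <- ifelse(fi$inside_start, 0, fi$distance)
      miss <- (!fi$hit & !fi$inside_start) | (!is.na(entry) & entry > L)
      dpt <- ifelse(miss, 0, L - entry)
      blc <- bl[bi, , drop = FALSE]
      # rate evaluated pairwise; geometry terms recomputed from blc vs ptm
      r <- L
      dir_b <- cbind(blc$dx, blc$dy, blc$dz)
      along <- rowSums(vec * dir_b)
      perp <- sqrt(pmax(0, r^2 - along^2))
      f <- blc$focal_mm
      rho <- perp * f / r
      cid <- as.character(blc$collimator)
      OF <- plan$params$output_factors[cid]
      Rc <- plan$params$field_radius[cid]
      sc <- plan$params$penumbra[cid]
      P <- 0.5 * (erf((Rc - rho) / sc) + erf((Rc + rho) / sc)) / erf(Rc / sc)
      rate <- plan$params$dose_rate / 192 * OF *
        exp(-plan$params$mu * (dpt - plan$params$d_ref)) * (f / r)^2 * P
      rate[miss] <- 0
      dose[ii, s] <- dose[ii, s] + rowsum(rate * dur, pi)[, 1]
      depth_sum <- depth_sum + sum(dpt[!miss]); depth_n <- depth_n + sum(!miss)
      missed <- missed + sum(miss)
    }
  }
  list(dose = rowSums(dose), per_shot = dose,
       average_depth_mm = if (depth_n > 0) depth_sum / depth_n else NA_real_,
       n_missed = missed)
}

#' Point dose for a plan
#'
#' Sums duration-weighted beamlet dose rates over every shot of a plan at a
#' single calculation point: each active beamlet is ray traced through the
#' skull model for its radiological depth and evaluated with the
#' exponential-attenuation model of [gk_dose_params()].
#'
#' @param plan a [gk_plan()].
#' @param point length-3 calculation point, mm.
#' @param skull a skull model (mask, scalar or analytic realization).
#' @return An object of class `gk_dose`: total `dose` (Gy), per-shot
#'   breakdown, `average_depth_mm` over contributing beamlets, and the
#'   missed-beamlet count. `tidy()` gives the per-shot table, `glance()` a
#'   one-row summary.
#' @examples
#' \donttest{
#' ph <- make_phantom()
#' plan <- gk_plan(gk_shot(c(100, 100, 100), "16", 1))
#' point_dose(plan, c(100, 100, 100), ph$surface)
#' }
#' @export
point_dose <- function(plan, point, skull) {
  stopifnot(inherits(plan, "gk_plan"))
  pt <- as_point(point)
  res <- point_dose_batch(plan, skull, matrix(pt, 1))
  if (res$n_missed > 0 && res$dose == 0) {
    warn("every beamlet missed the skull at this point; dose is 0")
  }
  structure(
    list(point = pt, dose = res$dose,
         per_shot = tibble(shot_id = plan$shots$shot_id,
                           duration_min = plan$shots$duration_min,
                           dose_gy = drop(res$per_shot)),
         average_depth_mm = res$average_depth_mm,
         n_missed = res$n_missed, gamma_deg = plan$gamma_deg),
    class = "gk_dose"
  )
}

#' @export
print.gk_dose <- function(x, ...) {
  cat(sprintf("<gk_dose> %.6g Gy at (%s) mm; average depth %.2f cm; %d missed beamlet(s)\n",
              x$dose, paste(signif(x$point, 5), collapse = ", "),
              x$average_depth_mm / 10, x$n_missed))
  invisible(x)
}

#' @export
tidy.gk_dose <- function(x, ...) x$per_shot

#' @export
glance.gk_dose <- function(x, ...) {
  tibble(dose_gy = x$dose, average_depth_cm = x$average_depth_mm / 10,
         n_shots = nrow(x$per_shot), n_missed_beamlets = x$n_missed,
         gamma_deg = x$gamma_deg)
}

#' One-dimensional dose profile
#'
#' Samples the point dose along a patient-frame axis through a centre point,
#' the geometry used to compare engine behaviour for a single shot at
#' standard and nonstandard gamma angles.
#'
#' @param plan a [gk_plan()].
#' @param skull a skull model.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param center length-3 centre, mm; defaults to the first shot isocenter.
#' @param half_extent profile half-length, mm.
#' @param step sample spacing, mm (> 0).
#' @return A tibble of class `gk_profile` with columns `offset_mm`, `dose_gy`
#'   and the sampled `x`,`y`,`z`; plot with [autoplot()].
#' @export
dose_profile <- function(plan, skull, axis = c("x", "y", "z"), center = NULL,
                         half_extent = 30, step = 0.5) {
  axis <- match.arg(axis)
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    abort("`step` must be a positive sampling interval in mm")
  }
  if (is.null(center)) {
    center <- c(plan$shots$iso_x[1], plan$shots$iso_y[1], plan$shots$iso_z[1])
  }
  center <- as_point(center, "center")
  off <- seq(-half_extent, half_extent, by = step)
  ax <- match(axis, c("x", "y", "z"))
  pts <- matrix(center, length(off), 3, byrow = TRUE)
  pts[, ax] <- pts[, ax] + off
  res <- point_dose_batch(plan, skull, pts)
  out <- tibble(offset_mm = off, dose_gy = res$dose,
                x = pts[, 1], y = pts[, 2], z = pts[, 3])
  attr(out, "axis") <- axis
  attr(out, "center") <- center
  class(out) <- c("gk_profile", class(out))
  out
}

#' @export
autoplot.gk_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_mm, y = .data$dose_gy)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = sprintf("offset along %s (mm)", toupper(attr(object, "axis"))),
      y = "dose (Gy)"
    ) +
    ggplot2::theme_minimal()
}

#' Locate the maximum dose point
#'
#' Coarse grid search over the bounding box of the shot isocenters (padded
#' by twice the largest field radius) followed by local grid refinement to
#' 0.1 mm.
#'
#' @param plan a [gk_plan()].
#' @param skull a skull model.
#' @param grid_spacing coarse grid spacing, mm (> 0).
#' @return A list with `point` (mm) and `dose` (Gy).
#' @export
find_max_dose_point <- function(plan, skull, grid_spacing = 2) {
  if (grid_spacing <= 0) abort("`grid_spacing` must be > 0")
  iso <- cbind(plan$shots$iso_x, plan$shots$iso_y, plan$shots$iso_z)
  pad <- 2 * max(plan$params$field_radius)
  lo <- apply(iso, 2, min) - pad
  hi <- apply(iso, 2, max) + pad
  gx <- seq(lo[1], hi[1], by = grid_spacing)
  gy <- seq(lo[2], hi[2], by = grid_spacing)
  gz <- seq(lo[3], hi[3], by = grid_spacing)
  pts <- as.matrix(expand.grid(x = gx, y = gy, z = gz))
  d <- point_dose_batch(plan, skull, pts)$dose
  best <- pts[which.max(d), ]
  best_dose <- max(d)

  h <- grid_spacing / 2
  while (h >= 0.05) {
    offs <- as.matrix(expand.grid(x = c(-h, 0, h), y = c(-h, 0, h), z = c(-h, 0, h)))
    cand <- sweep(offs, 2, best, `+`)
    dd <- point_dose_batch(plan, skull, cand)$dose
    if (max(dd) > best_dose) {
      best <- cand[which.max(dd), ]
      best_dose <- max(dd)
    } else {
      h <- h / 2
    }
  }
  list(point = unname(best), dose = best_dose)
}

#' Scale a plan to a prescribed maximum dose
#'
#' Multiplies every shot duration by `target / max-dose` so the recomputed
#' maximum equals `target` (dose is linear in duration). This mirrors the
#' phantom workflow of scaling a patient plan to a 4 Gy maximum before
#' delivery and measurement.
#'
#' @inheritParams find_max_dose_point
#' @param target desired maximum dose, Gy.
#' @return The rescaled `gk_plan`, with the located maximum in attributes
#'   `max_point` and `max_dose`.
#' @export
scale_plan_to_max_dose <- function(plan, skull, target = 4, grid_spacing = 2) {
  mx <- find_max_dose_point(plan, skull, grid_spacing)
  if (mx$dose <= 0) abort("plan maximum dose is zero; cannot scale")
  plan$shots$duration_min <- plan$shots$duration_min * target / mx$dose
  attr(plan, "max_point") <- mx$point
  attr(plan, "max_dose") <- target
  plan
}
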