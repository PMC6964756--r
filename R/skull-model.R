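#' Scalar skull measurements
#'
#' The scalar-measurement skull realization describes the head as 24 radial
#' distances from a dome centre, taken on a fixed angular grid of 3 polar
#' rings (30, 55, 80 degrees from the vertex axis) by 8 azimuths (every 45
#' degrees) — the instrument-style description that some planning and
#' verification systems use instead of an image dataset.
#'
#' @param radii numeric vector of 24 positive radii in mm, ordered ring-major
#'   (ring 1 azimuth 0..315, ring 2 ..., ring 3 ...), or a 3 x 8 matrix.
#' @param center length-3 dome centre, mm, patient frame.
#' @param polar_deg polar angles of the three rings, degrees from vertex.
#' @param azimuth_deg the 8 azimuth nodes, degrees.
#' @return A tibble of class `gk_measurements` with columns `ring`,
#'   `polar_deg`, `azimuth_deg`, `radius_mm`; the centre is kept as an
#'   attribute.
#' @export
gk_measurements <- function(radii, center,
                            polar_deg = c(30, 55, 80),
                            azimuth_deg = seq(0, 315, by = 45)) {
  radii <- as.numeric(radii)
  if (length(radii) != 24L) abort("exactly 24 radii are required")
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    abort("all 24 radii must be positive and finite")
  }
  stopifnot(length(polar_deg) == 3L, length(azimuth_deg) == 8L)
  out <- tibble(
    ring = rep(1:3, each = 8L),
    polar_deg = rep(as.numeric(polar_deg), each = 8L),
    azimuth_deg = rep(as.numeric(azimuth_deg), 3L),
    radius_mm = radii
  )
  attr(out, "center") <- as_point(center, "center")
  class(out) <- c("gk_measurements", class(out))
  out
}

#' Read / write scalar skull measurements as CSV
#'
#' The on-disk form is a 24-row CSV with columns `ring`, `azimuth_deg`,
#' `radius_mm` (plus `polar_deg`), and the dome centre in a `center_x/y/z`
#' triple repeated on each row.
#'
#' @param path CSV file path.
#' @param m a [gk_measurements()] object.
#' @return `read_measurements()` returns a [gk_measurements()];
#'   `write_measurements()` returns `path` invisibly.
#' @export
read_measurements <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  d <- d[order(d$ring, d$azimuth_deg), ]
  gk_measurements(d$radius_mm,
                  center = c(d$center_x[1], d$center_y[1], d$center_z[1]),
                  polar_deg = unique(d$polar_deg),
                  azimuth_deg = unique(d$azimuth_deg))
}

#' @rdname read_measurements
#' @export
write_measurements <- function(m, path) {
  stopifnot(inherits(m, "gk_measurements"))
  ctr <- attr(m, "center")
  d <- as_tibble(m) |>
    mutate(center_x = ctr[1], center_y = ctr[2], center_z = ctr[3])
  readr::write_csv(d, path)
  invisible(path)
}

#' Build a skull model from 24 scalar measurements
#'
#' The 24 radii are interpolated bilinearly in angle: linearly along each
#' polar ring (periodic in azimuth) and linearly between rings. Above the
#' 30-degree ring the radius tapers to the vertex value (the ring-1 azimuth
#' mean); below the 80-degree ring it is held constant in polar angle. The
#' dome is closed below by a horizontal base plane at `z_base`, the frame's
#' inferior limit.
#'
#' @param m a [gk_measurements()] object.
#' @param z_base mm height of the closing base plane (default 0, the frame
#'   inferior limit).
#' @return An object of class `gk_skull_scalar` usable with
#'   [first_intersection()] and [skull_inside()].
#' @export
skull_from_measurements <- function(m, z_base = 0) {
  stopifnot(inherits(m, "gk_measurements"))
  rmat <- matrix(m$radius_mm, nrow = 3L, byrow = TRUE) # ring x azimuth
  structure(
    list(center = attr(m, "center"), radii = rmat,
         polar_deg = unique(m$polar_deg), azimuth_deg = unique(m$azimuth_deg),
         z_base = as.numeric(z_base)),
    class = c("gk_skull_scalar", "gk_skull")
  )
}

#' @export
print.gk_skull_scalar <- function(x, ...) {
  cat(sprintf(
    "<gk_skull_scalar> 24 radii %.1f-%.1f mm, centre (%s) mm, base plane z = %g mm\n",
    min(x$radii), max(x$radii), paste(signif(x$center, 5), collapse = ", "),
    x$z_base
  ))
  invisible(x)
}

# interpolated radius r(theta, phi) of a scalar skull (vectorized, degrees)
scalar_radius <- function(model, theta_deg, phi_deg) {
  az <- model$azimuth_deg
  pol <- model$polar_deg
  span <- 360 / length(az)
  phi <- phi_deg %% 360
  j0 <- floor(phi / span)
  w <- (phi - j0 * span) / span
  j0 <- (as.integer(j0) %% length(az)) + 1L
  j1 <- (j0 %% length(az)) + 1L

  ring_at <- function(i) (1 - w) * model$radii[i, j0] + w * model$radii[i, j1]
  r_vertex <- mean(model$radii[1L, ])

  th <- pmax(theta_deg, 0)
  out <- numeric(length(th))
  lo <- th <= pol[1]
  out[lo] <- {
    u <- th[lo] / pol[1]
    (1 - u) * r_vertex + u * ring_at(1L)[lo]
  }
  mid1 <- th > pol[1] & th <= pol[2]
  out[mid1] <- {
    u <- (th[mid1] - pol[1]) / (pol[2] - pol[1])
    (1 - u) * ring_at(1L)[mid1] + u * ring_at(2L)[mid1]
  }
  mid2 <- th > pol[2] & th <= pol[3]
  out[mid2] <- {
    u <- (th[mid2] - pol[2]) / (pol[3] - pol[2])
    (1 - u) * ring_at(2L)[mid2] + u * ring_at(3L)[mid2]
  }
  hi <- th > pol[3]
  out[hi] <- ring_at(3L)[hi]
  out
}

#' Analytic skull realization
#'
#' A closed-form sphere or axis-aligned ellipsoid used as the exact-oracle
#' skull: inside/outside and ray first-intersections are solved from the
#' line-quadric quadratic, with no voxelization error. Synthetic phantoms
#' built by [make_phantom()] carry one of these as their ground-truth
#' surface descriptor.
#'
#' @param center length-3 centre, mm.
#' @param radii scalar radius (sphere) or length-3 semi-axes (ellipsoid), mm.
#' @return An object of class `gk_skull_analytic`.
#' @export
gk_skull_analytic <- function(center, radii) {
  radii <- as.numeric(radii)
  if (length(radii) == 1L) radii <- rep(radii, 3L)
  if (length(radii) != 3L || any(radii <= 0)) {
    abort("`radii` must be one or three positive semi-axes (mm)")
  }
  structure(list(center = as_point(center, "center"), radii = radii),
            class = c("gk_skull_analytic", "gk_skull"))
}

#' @export
print.gk_skull_analytic <- function(x, ...) {
  cat(sprintf("<gk_skull_analytic> semi-axes (%s) mm at (%s) mm\n",
              paste(x$radii, collapse = ", "),
              paste(signif(x$center, 5), collapse = ", ")))
  invisible(x)
}

#' Point-in-skull test
#'
#' @param model a skull model (`gk_skull_mask`, `gk_skull_scalar` or
#'   `gk_skull_analytic`).
#' @param points n x 3 matrix (or length-3 vector) of mm points.
#' @return Logical vector: is each point inside the skull?
#' @export
skull_inside <- function(model, points) UseMethod("skull_inside")

#' @export
skull_inside.gk_skull_mask <- function(model, points) {
  p <- as_point_matrix(points)
  dm <- dim(model$inside)
  idx <- sweep(sweep(p, 2, model$origin), 2, model$spacing, `/`)
  iv <- floor(idx + 0.5) + 1 # nearest voxel under half-open convention
  ok <- iv[, 1] >= 1 & iv[, 1] <= dm[1] &
    iv[, 2] >= 1 & iv[, 2] <= dm[2] &
    iv[, 3] >= 1 & iv[, 3] <= dm[3]
  out <- logical(nrow(p))
  if (any(ok)) {
    out[ok] <- model$inside[cbind(iv[ok, 1], iv[ok, 2], iv[ok, 3])]
  }
  out
}

#' @export
skull_inside.gk_skull_scalar <- function(model, points) {
  p <- as_point_matrix(points)
  rel <- sweep(p, 2, model$center)
  rr <- vnorm(rel)
  theta <- acos(pmin(1, pmax(-1, ifelse(rr > 0, rel[, 3] / rr, 1))))
  phi <- atan2(rel[, 2], rel[, 1]) * 180 / pi
  r <- scalar_radius(model, theta * 180 / pi, phi)
  p[, 3] >= model$z_base & rr <= r
}

#' @export
skull_inside.gk_skull_analytic <- function(model, points) {
  p <- as_point_matrix(points)
  rel <- sweep(sweep(p, 2, model$center), 2, model$radii, `/`)
  rowSums(rel^2) <= 1
}

#' First skull intersection along rays
#'
#' Finds, for each ray, the first outside-to-inside crossing of the skull
#' surface. For the mask realization the crossing is located by parametric
#' voxel traversal; for the scalar realization by marching along the ray and
#' bisecting the bracketing interval on the interpolated surface; for the
#' analytic realization from the closed-form quadratic. Rays starting inside
#' the skull are flagged `inside_start` with entry distance 0.
#'
#' @param model a skull model.
#' @param origins n x 3 ray origins, mm.
#' @param directions n x 3 unit direction vectors.
#' @param t_max maximum search distance, mm (default 1000).
#' @return A tibble with columns `hit`, `inside_start`, `distance` (mm from
#'   origin to the entry point; `NA` on a miss) and `entry_x/y/z`.
#' @export
first_intersection <- function(model, origins, directions, t_max = 1000) {
  UseMethod("first_intersection")
}

fi_result <- function(status, dist, entry) {
  hit <- status > 0
  dist[!hit] <- NA_real_
  entry[!hit, ] <- NA_real_
  tibble(
    hit = hit, inside_start = status == 2, distance = dist,
    entry_x = entry[, 1], entry_y = entry[, 2], entry_z = entry[, 3]
  )
}

check_rays <- function(origins, directions) {
  o <- as_point_matrix(origins, "origins")
  d <- as_point_matrix(directions, "directions")
  if (nrow(o) != nrow(d)) abort("`origins` and `directions` must have equal rows")
  nd <- vnorm(d)
  if (any(abs(nd - 1) > 1e-6)) abort("`directions` must be unit vectors")
  list(o = o, d = d / nd)
}

#' @export
first_intersection.gk_skull_mask <- function(model, origins, directions, t_max = 1000) {
  r <- check_rays(origins, directions)
  res <- cpp_ray_first_hit(r$o, r$d, model$inside, dim(model$inside),
                           model$spacing, model$origin, t_max)
  fi_result(res[, 1], res[, 2], res[, 3:5, drop = FALSE])
}

#' @export
first_intersection.gk_skull_scalar <- function(model, origins, directions, t_max = 1000) {
  r <- check_rays(origins, directions)
  n <- nrow(r$o)
  status <- numeric(n); dist <- numeric(n); entry <- matrix(0, n, 3)
  step <- 1.0 # mm marching step; crossings thinner than this can be skipped
  for (k in seq_len(n)) {
    o <- r$o[k, ]; d <- r$d[k, ]
    if (skull_inside(model, o)) { status[k] <- 2; next }
    reach <- min(t_max, vnorm(matrix(o - model$center, 1)) + max(model$radii) + 10)
    ts <- seq(0, reach, by = step)
    pts <- cbind(o[1] + ts * d[1], o[2] + ts * d[2], o[3] + ts * d[3])
    ins <- skull_inside(model, pts)
    i <- which(ins)[1]
    if (is.na(i)) next
    lo <- ts[i - 1L]; hi <- ts[i]
    for (j in 1:60) {
      mid <- (lo + hi) / 2
      if (skull_inside(model, o + mid * d)) hi <- mid else lo <- mid
    }
    status[k] <- 1; dist[k] <- hi; entry[k, ] <- o + hi * d
  }
  fi_result(status, dist, entry)
}

#' @export
first_intersection.gk_skull_analytic <- function(model, origins, directions, t_max = 1000) {
  r <- check_rays(origins, directions)
  op <- sweep(sweep(r$o, 2, model$center), 2, model$radii, `/`)
  dp <- sweep(r$d, 2, model$radii, `/`)
  A <- rowSums(dp^2)
  B <- 2 * rowSums(op * dp)
  C <- rowSums(op^2) - 1
  disc <- B^2 - 4 * A * C
  n <- nrow(r$o)
  status <- numeric(n); dist <- numeric(n); entry <- matrix(0, n, 3)
  real <- disc >= 0
  t1 <- (-B - sqrt(pmax(disc, 0))) / (2 * A)
  t2 <- (-B + sqrt(pmax(disc, 0))) / (2 * A)
  inside0 <- C <= 0
  status[real & inside0] <- 2
  hit <- real & !inside0 & t1 > 0 & t1 <= t_max
  status[hit] <- 1
  dist[hit] <- t1[hit]
  entry[hit, ] <- r$o[hit, , drop = FALSE] + t1[hit] * r$d[hit, , drop = FALSE]
  fi_result(status, dist, entry)
}

#' Infer scalar skull measurements from a mask
#'
#' Emulates deriving the 24 instrument-style radii from an image dataset:
#' rays are cast from `center` along the fixed 3-ring x 8-azimuth angular
#' grid and the distance to the mask surface (the inside-to-outside
#' crossing, refined by bisection to sub-voxel precision) is recorded.
#'
#' @param mask a `gk_skull_mask`.
#' @param center length-3 mm point; must lie inside the mask.
#' @param polar_deg,azimuth_deg the angular grid, as in [gk_measurements()].
#' @return A [gk_measurements()] object.
#' @export
sample_measurements_from_mask <- function(mask, center,
                                          polar_deg = c(30, 55, 80),
                                          azimuth_deg = seq(0, 315, by = 45)) {
  stopifnot(inherits(mask, "gk_skull_mask"))
  ctr <- as_point(center, "center")
  if (!skull_inside(mask, ctr)) {
    abort("`center` must lie inside the skull mask")
  }
  grid <- expand.grid(azimuth_deg = azimuth_deg, polar_deg = polar_deg)
  th <- grid$polar_deg * pi / 180
  ph <- grid$azimuth_deg * pi / 180
  dirs <- cbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  reach <- sum(dim(mask$inside) * mask$spacing) # generous upper bound
  step <- min(mask$spacing) / 4
  radii <- vapply(seq_len(nrow(dirs)), function(k) {
    d <- dirs[k, ]
    ts <- seq(0, reach, by = step)
    pts <- cbind(ctr[1] + ts * d[1], ctr[2] + ts * d[2], ctr[3] + ts * d[3])
    ins <- skull_inside(mask, pts)
    i <- which(!ins)[1]
    if (is.na(i)) {
      abort(sprintf("ray at polar %g / azimuth %g never exits the mask",
                    grid$polar_deg[k], grid$azimuth_deg[k]))
    }
    lo <- ts[i - 1L]; hi <- ts[i]
    for (j in 1:40) {
      mid <- (lo + hi) / 2
      if (skull_inside(mask, ctr + mid * d)) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 1.0)
  gk_measurements(radii, center = ctr,
                  polar_deg = polar_deg, azimuth_deg = azimuth_deg)
}
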