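test_that("reference conditions give exactly the per-source calibration rate", {
  params <- gk_dose_params()
  # a synthetic beamlet at focal distance with the point on-axis at d_ref
  bl <- tibble::tibble(
    source_id = 1L, ring = 1L, sector = 0L, collimator = "16",
    focal_mm = 400, x = 100, y = 100 - 400, z = 100,
    dx = 0, dy = 1, dz = 0
  )
  rate <- beamlet_dose_rate(bl, FOCUS, depth = params$d_ref, params = params)
  expect_equal(rate, params$dose_rate / 192, tolerance = 1e-12)
})

test_that("depth increments scale the rate by the exponential factor", {
  params <- gk_dose_params()
  bl <- full_beamlets()[1, ]
  r0 <- beamlet_dose_rate(bl, FOCUS, depth = 80, params = params)
  r10 <- beamlet_dose_rate(bl, FOCUS, depth = 90, params = params)
  expect_equal(r10 / r0, exp(-10 * params$mu), tolerance = 1e-12)

  # monotone attenuation: deeper is strictly weaker
  depths <- seq(20, 120, by = 5)
  rates <- vapply(depths, function(d) beamlet_dose_rate(bl, FOCUS, d, params), 1.0)
  expect_true(all(diff(rates) < 0))
})

test_that("missed beamlets and blocked sectors contribute zero dose", {
  params <- gk_dose_params()
  bl <- full_beamlets()[1:2, ]
  dep <- tibble::tibble(depth = c(80, 0), distance = c(400, 400),
                        entry_distance = c(320, NA), missed = c(FALSE, TRUE))
  rates <- beamlet_dose_rate(bl, FOCUS, dep, params)
  expect_gt(rates[1], 0)
  expect_equal(rates[2], 0)
  # all sectors blocked: no beamlets, zero profile
  plan0 <- gk_plan(gk_shot(FOCUS, "blocked", 1), geometry = default_geometry())
  prof <- dose_profile(plan0, sphere_phantom()$surface, "x",
                       half_extent = 5, step = 2.5)
  expect_true(all(prof$dose_gy == 0))
})

test_that("point dose is linear in duration and additive over shots", {
  sk <- sphere_phantom()$surface
  p1 <- gk_plan(gk_shot(FOCUS, "16", 0.7), geometry = default_geometry())
  p2 <- gk_plan(gk_shot(FOCUS, "16", 1.4), geometry = default_geometry())
  d1 <- point_dose(p1, FOCUS, sk)$dose
  d2 <- point_dose(p2, FOCUS, sk)$dose
  expect_equal(d2, 2 * d1, tolerance = 1e-12)

  shots <- list(gk_shot(FOCUS + c(5, 0, 0), "16", 0.4),
                gk_shot(FOCUS - c(5, 0, 0), c("8", "8", "8", "8", "blocked", "16", "4", "16"), 0.8))
  both <- gk_plan(shots, geometry = default_geometry())
  da <- point_dose(both, FOCUS, sk)
  ia <- point_dose(gk_plan(shots[1], geometry = default_geometry()), FOCUS, sk)$dose
  ib <- point_dose(gk_plan(shots[2], geometry = default_geometry()), FOCUS, sk)$dose
  expect_equal(da$dose, ia + ib, tolerance = 1e-9)
  expect_equal(sum(da$per_shot$dose_gy), da$dose, tolerance = 1e-12)

  # zero-duration plan delivers nothing
  z <- gk_plan(gk_shot(FOCUS, "16", 0), geometry = default_geometry())
  expect_equal(point_dose(z, FOCUS, sk)$dose, 0)
})

test_that("point dose equals an independently hand-rolled beamlet summation", {
  params <- gk_dose_params()
  geom <- default_geometry()
  states <- c("16", "blocked", "8", "blocked", "blocked", "4", "blocked", "blocked")
  plan <- gk_plan(gk_shot(FOCUS + c(4, -2, 6), states, 0.9),
                  params = params, geometry = geom)
  sk <- ellipsoid_phantom()$surface
  pt <- FOCUS + c(1, 5, -3)
  got <- point_dose(plan, pt, sk)$dose
  bl <- place_beamlets(geom, FOCUS + c(4, -2, 6), states)
  want <- oracle_point_dose(bl, pt, FOCUS, c(90, 75, 70), params, 0.9)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("mirror-symmetric points about a centred shot receive equal dose", {
  sk <- sphere_phantom()$surface
  plan <- single_shot_plan()
  for (offset in list(c(6, 0, 0), c(0, 4.5, 0))) {
    da <- point_dose(plan, FOCUS + offset, sk)$dose
    db <- point_dose(plan, FOCUS - offset, sk)$dose
    expect_equal(da, db, tolerance = 1e-6)
  }
})

test_that("dose with rotated beamlets equals dose with a counter-rotated skull", {
  ctr <- c(100, 108, 94)
  sk <- gk_skull_analytic(ctr, 75)
  set.seed(51)
  pts <- sweep(matrix(runif(24, -8, 8), 8, 3), 2, FOCUS, `+`)
  for (g in c(70, 110)) {
    plan_g <- single_shot_plan(gamma = g)
    plan_90 <- single_shot_plan(gamma = 90)
    Rinv <- t(gamma_rotation(g))
    sk_c <- gk_skull_analytic(as.numeric(Rinv %*% (ctr - FOCUS)) + FOCUS, 75)
    for (i in seq_len(nrow(pts))) {
      d_g <- point_dose(plan_g, pts[i, ], sk)$dose
      p_r <- as.numeric(Rinv %*% (pts[i, ] - FOCUS)) + FOCUS
      d_90 <- point_dose(plan_90, p_r, sk_c)$dose
      expect_equal(d_g, d_90, tolerance = 1e-9)
    }
  }
})

test_that("profile sampling is ordered, symmetric for x, and validates step", {
  sk <- sphere_phantom()$surface
  plan <- single_shot_plan()
  prof <- dose_profile(plan, sk, "x", half_extent = 12, step = 3)
  expect_equal(prof$offset_mm, seq(-12, 12, by = 3))
  D0 <- prof$dose_gy[prof$offset_mm == 0]
  expect_lt(max(abs(prof$dose_gy - rev(prof$dose_gy)) / D0), 1e-3)
  expect_error(dose_profile(plan, sk, "x", step = 0), "positive")
})

test_that("nonstandard gamma alters the z-profile as a pure rotation of the field", {
  sk <- sphere_phantom()$surface # centred sphere: rotating the skull is a no-op
  plan70 <- single_shot_plan(gamma = 70)
  plan90 <- single_shot_plan(gamma = 90)
  p70 <- dose_profile(plan70, sk, "z", half_extent = 12, step = 3)
  p90 <- dose_profile(plan90, sk, "z", half_extent = 12, step = 3)
  # differs beyond tolerance in the penumbra/tail region
  D0 <- p90$dose_gy[p90$offset_mm == 0]
  expect_gt(max(abs(p70$dose_gy - p90$dose_gy)) / D0, 1e-3)
  # and equals the gamma-90 field sampled at counter-rotated points
  Rinv <- t(gamma_rotation(70))
  for (i in seq_along(p70$offset_mm)) {
    p <- c(p70$x[i], p70$y[i], p70$z[i])
    pr <- as.numeric(Rinv %*% (p - FOCUS)) + FOCUS
    expect_equal(p70$dose_gy[i], point_dose(plan90, pr, sk)$dose,
                 tolerance = 1e-9)
  }
})

test_that("maximum dose point search matches a dense-grid oracle", {
  sk <- sphere_phantom()$surface
  plan <- single_shot_plan()
  mx <- find_max_dose_point(plan, sk, grid_spacing = 4)
  expect_equal(mx$dose, point_dose(plan, mx$point, sk)$dose, tolerance = 1e-12)
  # x/y reflection symmetry pins the optimum to the isocenter's vertical axis
  # (along z the superior source array pulls the maximum above the isocenter)
  expect_lt(max(abs(mx$point[1:2] - FOCUS[1:2])), 0.5)
  dense <- vapply(seq(-10, 10, by = 0.5), function(t) {
    point_dose(plan, FOCUS + c(0, 0, t), sk)$dose
  }, 1.0)
  expect_gte(mx$dose, max(dense) - 1e-9)

  # two identical shots 40 mm apart: the maximum hugs one shot, never midway
  plan2 <- gk_plan(list(gk_shot(FOCUS + c(20, 0, 0), "16", 1),
                        gk_shot(FOCUS - c(20, 0, 0), "16", 1)),
                   geometry = default_geometry())
  mx2 <- find_max_dose_point(plan2, sk, grid_spacing = 4)
  expect_lt(min(abs(mx2$point[1] - (FOCUS[1] + 20)),
                abs(mx2$point[1] - (FOCUS[1] - 20))), 2)
  expect_gt(mx2$dose, point_dose(plan2, FOCUS, sk)$dose)
})

test_that("scaling a plan to a target maximum is an exact fixed point", {
  sk <- sphere_phantom()$surface
  plan <- single_shot_plan(duration = 0.37)
  scaled <- scale_plan_to_max_dose(plan, sk, target = 4, grid_spacing = 4)
  mx <- find_max_dose_point(scaled, sk, grid_spacing = 4)
  expect_equal(mx$dose, 4, tolerance = 1e-6)
  # scaling to the current max is the identity on durations
  again <- scale_plan_to_max_dose(scaled, sk, target = mx$dose, grid_spacing = 4)
  expect_equal(again$shots$duration_min, scaled$shots$duration_min,
               tolerance = 1e-9)
  # zero plans cannot be scaled
  z <- gk_plan(gk_shot(FOCUS, "16", 0), geometry = default_geometry())
  expect_error(scale_plan_to_max_dose(z, sk, 4, grid_spacing = 8), "zero")
})
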