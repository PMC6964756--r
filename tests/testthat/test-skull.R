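test_that("threshold mask volume matches the analytic sphere volume", {
  mask <- sphere_mask()
  vol <- mask_volume(mask)
  analytic <- 4 / 3 * pi * 80^3
  # one voxel-shell bound: surface area x voxel size
  shell <- 4 * pi * 80^2 * max(mask$spacing)
  expect_lt(abs(vol - analytic), shell)
  expect_equal(icondose:::cpp_n_components(mask$inside, dim(mask$inside)), 1L)
})

test_that("degenerate thresholds behave as specified", {
  ph <- sphere_phantom()
  expect_error(threshold_skull(ph$image, threshold = 2000), "empty mask")
  full <- threshold_skull(ph$image, threshold = -2000)
  expect_true(all(full$inside))
  expect_equal(icondose:::cpp_n_components(full$inside, dim(full$inside)), 1L)
})

test_that("MR mode thresholds within a band and requires one", {
  ph <- sphere_phantom()
  img <- gk_image(ph$image$values, ph$image$spacing, ph$image$origin, modality = "MR")
  expect_error(threshold_skull(img), "band")
  msk <- threshold_skull(img, band = c(500, 1500))
  expect_equal(sum(msk$inside), sum(sphere_mask()$inside))
})

test_that("constant scalar measurements give a spherical dome", {
  m <- gk_measurements(rep(80, 24), center = FOCUS)
  sk <- skull_from_measurements(m)
  th <- runif(20, 0, 120)
  ph <- runif(20, 0, 360)
  expect_equal(icondose:::scalar_radius(sk, th, ph), rep(80, 20))
})

test_that("scalar interpolation reproduces node radii exactly and is bounded", {
  semi <- c(90, 75, 70)
  grid <- expand.grid(az = seq(0, 315, 45), pol = c(30, 55, 80))
  u <- cbind(sin(grid$pol * pi / 180) * cos(grid$az * pi / 180),
             sin(grid$pol * pi / 180) * sin(grid$az * pi / 180),
             cos(grid$pol * pi / 180))
  radii <- apply(u, 1, oracle_radius, semi = semi)
  m <- gk_measurements(radii, center = FOCUS)
  sk <- skull_from_measurements(m)
  # nodes reproduced exactly
  expect_equal(icondose:::scalar_radius(sk, grid$pol, grid$az), radii,
               tolerance = 1e-12)
  # interpolated values bounded by the surrounding node values
  set.seed(7)
  for (i in 1:50) {
    pol <- runif(1, 30, 80)
    az <- runif(1, 0, 360)
    ring_lo <- max(which(c(30, 55, 80) <= pol))
    az_lo <- floor(az / 45) %% 8
    nodes <- c(
      sk$radii[ring_lo, az_lo + 1], sk$radii[ring_lo, (az_lo + 1) %% 8 + 1],
      sk$radii[min(ring_lo + 1, 3), az_lo + 1],
      sk$radii[min(ring_lo + 1, 3), (az_lo + 1) %% 8 + 1]
    )
    r <- icondose:::scalar_radius(sk, pol, az)
    expect_gte(r, min(nodes) - 1e-9)
    expect_lte(r, max(nodes) + 1e-9)
  }
})

test_that("measurements sampled from a mask recover the analytic radii", {
  radii <- sample_measurements_from_mask(sphere_mask(), FOCUS)
  halfdiag <- sqrt(3) / 2 * max(sphere_mask()$spacing)
  expect_lt(max(abs(radii$radius_mm - 80)), halfdiag)

  emask <- ellipsoid_mask()
  em <- sample_measurements_from_mask(emask, FOCUS)
  th <- em$polar_deg * pi / 180
  az <- em$azimuth_deg * pi / 180
  u <- cbind(sin(th) * cos(az), sin(th) * sin(az), cos(th))
  expected <- apply(u, 1, oracle_radius, semi = c(90, 75, 70))
  expect_lt(max(abs(em$radius_mm - expected)), sqrt(3) / 2 * max(emask$spacing))

  expect_error(sample_measurements_from_mask(sphere_mask(), c(300, 300, 300)),
               "inside")
})

test_that("measurement validation rejects bad inputs", {
  expect_error(gk_measurements(rep(80, 23), FOCUS), "24")
  expect_error(gk_measurements(c(rep(80, 23), -1), FOCUS), "positive")
})

test_that("first_intersection matches analytic entry on all realizations", {
  realizations <- list(
    mask = sphere_mask(),
    scalar = skull_from_measurements(gk_measurements(rep(80, 24), FOCUS)),
    analytic = sphere_phantom()$surface
  )
  tol <- c(mask = sqrt(3) * 2 / 2, scalar = 1e-6, analytic = 1e-9)
  for (nm in names(realizations)) {
    sk <- realizations[[nm]]
    # head-on ray from 250 mm: entry at 250 - 80
    fi <- first_intersection(sk, FOCUS + c(0, -250, 0), rbind(c(0, 1, 0)))
    expect_true(fi$hit)
    expect_equal(fi$distance, 170, tolerance = tol[[nm]])
    # tangent-beyond ray misses
    miss <- first_intersection(sk, FOCUS + c(0, -250, 90), rbind(c(0, 1, 0)))
    expect_false(miss$hit)
    # origin inside is flagged with zero entry
    ins <- first_intersection(sk, FOCUS, rbind(c(0, 0, 1)))
    expect_true(ins$inside_start)
    expect_equal(ins$distance, 0)
  }
})

test_that("oblique rays agree with the line-sphere quadratic oracle", {
  set.seed(21)
  sk <- sphere_mask_1mm()
  n <- 200
  src <- matrix(rnorm(n * 3), n, 3)
  src <- 300 * src / sqrt(rowSums(src^2))
  src <- sweep(src, 2, FOCUS, `+`)
  tgt <- matrix(runif(n * 3, -50, 50), n, 3)
  tgt <- sweep(tgt, 2, FOCUS, `+`)
  dirs <- tgt - src
  dirs <- dirs / sqrt(rowSums(dirs^2))
  fi <- first_intersection(sk, src, dirs)
  oracle <- vapply(seq_len(n), function(i) {
    oracle_entry(src[i, ], dirs[i, ], FOCUS, 80)
  }, 1.0)
  expect_true(all(fi$hit))
  expect_lt(max(abs(fi$distance - oracle)), sqrt(3) / 2)
})

test_that("mask and scalar realizations of one sphere agree on random rays", {
  mask <- sphere_mask()
  scal <- skull_from_measurements(gk_measurements(rep(80, 24), FOCUS))
  set.seed(31)
  n <- 300
  src <- matrix(rnorm(n * 3), n, 3)
  src <- sweep(280 * src / sqrt(rowSums(src^2)), 2, FOCUS, `+`)
  # keep rays on the dome side so the base-plane closure is never queried
  src[, 3] <- abs(src[, 3] - FOCUS[3]) / 2 + FOCUS[3]
  tgt <- sweep(matrix(runif(n * 3, -30, 30), n, 3), 2, FOCUS, `+`)
  dirs <- tgt - src
  dirs <- dirs / sqrt(rowSums(dirs^2))
  fm <- first_intersection(mask, src, dirs)
  fs <- first_intersection(scal, src, dirs)
  expect_true(all(fm$hit & fs$hit))
  expect_lt(max(abs(fm$distance - fs$distance)), sqrt(3) * max(mask$spacing))
})

test_that("entry distance is monotone under forward origin shifts", {
  shift <- 7.5
  dir <- rbind(c(0, 1, 0))
  models <- list(sphere_mask(),
                 skull_from_measurements(gk_measurements(rep(80, 24), FOCUS)),
                 sphere_phantom()$surface)
  for (sk in models) {
    d0 <- first_intersection(sk, FOCUS + c(0, -250, 0), dir)$distance
    d1 <- first_intersection(sk, FOCUS + c(0, -250 + shift, 0), dir)$distance
    expect_equal(d0 - d1, shift, tolerance = 1e-6)
  }
})
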