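# Shared fixtures, built once per test session (phantom voxelization and
# mask cleanup are the slow parts).

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

FOCUS <- c(100, 100, 100)

# 80 mm sphere at the focus, 2 mm voxels (fast unit-test grid)
sphere_phantom <- function() fixture("sphere2", function() make_phantom(spacing = 2))
sphere_mask <- function() fixture("sphere2m", function() phantom_mask(sphere_phantom()))

# ellipsoid (90, 75, 70) mm, 2 mm voxels
ellipsoid_phantom <- function() {
  fixture("ellip2", function() {
    make_phantom("ellipsoid", radii = c(90, 75, 70), spacing = 2)
  })
}
ellipsoid_mask <- function() fixture("ellip2m", function() phantom_mask(ellipsoid_phantom()))

# 80 mm sphere at the focus, 1 mm voxels (accuracy-sensitive checks)
sphere_phantom_1mm <- function() fixture("sphere1", function() make_phantom(spacing = 1))
sphere_mask_1mm <- function() fixture("sphere1m", function() phantom_mask(sphere_phantom_1mm()))

default_geometry <- function() fixture("geom", gk_geometry)

full_beamlets <- function(iso = FOCUS, gamma = 90) {
  place_beamlets(default_geometry(), iso, "16", gamma)
}

single_shot_plan <- function(gamma = 90, duration = 1, iso = FOCUS) {
  gk_plan(gk_shot(iso, "16", duration), gamma_deg = gamma,
          geometry = default_geometry())
}
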