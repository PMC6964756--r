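#' Construct a voxel image
#'
#' A minimal axis-aligned 3-D scalar image in patient-frame millimetres.
#' `origin` is the mm position of the *centre* of voxel (1,1,1); voxel `i`
#' along an axis covers the half-open interval
#' `origin + (i - 1.5) * spacing` to `origin + (i - 0.5) * spacing`.
#'
#' @param values 3-D numeric array of intensities (CT numbers or MR a.u.).
#' @param spacing length-3 voxel spacing in mm (or scalar, recycled).
#' @param origin length-3 mm position of the first voxel centre.
#' @param modality `"CT"` or `"MR"`.
#' @return An object of class `gk_image`.
#' @export
gk_image <- function(values, spacing, origin = c(0, 0, 0), modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  if (length(dim(values)) != 3L || any(dim(values) < 1L)) {
    abort("`values` must be a non-empty 3-D array.")
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be 3 positive mm values.")
  }
  structure(
    list(values = values, spacing = spacing, origin = as_point(origin, "origin"),
         modality = modality),
    class = "gk_image"
  )
}

#' @export
print.gk_image <- function(x, ...) {
  cat(sprintf("<gk_image %s> %s voxels, %s mm spacing, origin (%s) mm\n",
              x$modality, paste(dim(x$values), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x"),
              paste(signif(x$origin, 5), collapse = ", ")))
  invisible(x)
}

#' Read / write voxel images as NIfTI
#'
#' Thin wrappers around the RNifti reader/writer restricted to axis-aligned
#' volumes (the only orientation the dose engine consumes). The voxel
#' spacing is carried in `pixdim` and the patient-frame origin in the sform
#' translation.
#'
#' @param path file path (`.nii` / `.nii.gz`).
#' @param image a [gk_image()].
#' @param modality stored modality tag for the re-read image.
#' @return `read_gk_image()` returns a [gk_image()]; `write_gk_image()`
#'   returns `path` invisibly.
#' @export
read_gk_image <- function(path, modality = c("CT", "MR")) {
  modality <- match.arg(modality)
  nii <- RNifti::readNifti(path)
  arr <- as.array(nii)
  if (length(dim(arr)) != 3L) abort("expected a 3-D NIfTI volume")
  sp <- attr(nii, "pixdim")
  if (is.null(sp)) sp <- RNifti::pixdim(nii)
  xf <- RNifti::xform(nii)
  gk_image(arr, spacing = as.numeric(sp[1:3]),
           origin = as.numeric(xf[1:3, 4]), modality = modality)
}

#' @rdname read_gk_image
#' @export
write_gk_image <- function(image, path) {
  stopifnot(inherits(image, "gk_image"))
  nii <- RNifti::asNifti(image$values)
  xf <- diag(4)
  diag(xf)[1:3] <- image$spacing
  xf[1:3, 4] <- image$origin
  nii <- RNifti::`sform<-`(nii, structure(xf, code = 2L))
  nii <- RNifti::`qform<-`(nii, structure(xf, code = 2L))
  RNifti::pixdim(nii) <- image$spacing
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Render the skull by image thresholding
#'
#' Binarily assigns every voxel to inside/outside the skull from a single
#' image-scale threshold: a CT voxel is inside when its value is at least
#' `threshold`; an MR voxel when its value falls inside `band` (MR
#' intensities are not calibrated, so a two-sided band replaces the single
#' cut). Speckle and small holes are then suppressed with a one-voxel
#' binary closing, and the largest 6-connected component is kept so the
#' surface seen by the ray tracer is a single solid.
#'
#' @param image a [gk_image()].
#' @param threshold image-scale cut (CT mode). The clinical default for CT
#'   is about -400 HU, midway between air (-1000) and soft tissue (~0).
#' @param band optional `c(low, high)` used when `image$modality == "MR"`.
#' @param clean logical; apply closing + largest-component selection
#'   (default `TRUE`).
#' @return An object of class `gk_skull_mask`: binary array `inside` plus
#'   grid metadata, usable with [first_intersection()].
#' @export
threshold_skull <- function(image, threshold = -400, band = NULL, clean = TRUE) {
  stopifnot(inherits(image, "gk_image"))
  v <- image$values
  if (identical(image$modality, "MR")) {
    if (is.null(band)) abort("MR thresholding requires `band = c(low, high)`.")
    m <- v >= band[1] & v <= band[2]
  } else {
    rng <- range(v)
    if (threshold > rng[2]) {
      abort(sprintf(
        "skull rendering failed: threshold %g exceeds the image maximum %g (empty mask)",
        threshold, rng[2]
      ))
    }
    m <- v >= threshold
  }
  if (!any(m)) {
    abort(sprintf("skull rendering failed: threshold %g yields an empty mask", threshold))
  }
  dim3 <- dim(v)
  storage.mode(m) <- "logical"
  if (clean) {
    m <- cpp_binary_close(m, dim3)
    m <- cpp_largest_component(m, dim3)
  }
  dim(m) <- dim3
  structure(
    list(inside = m, spacing = image$spacing, origin = image$origin,
         modality = image$modality),
    class = c("gk_skull_mask", "gk_skull")
  )
}

#' @export
print.gk_skull_mask <- function(x, ...) {
  cat(sprintf("<gk_skull_mask> %s voxels, %.0f cm^3 inside\n",
              paste(dim(x$inside), collapse = "x"),
              sum(x$inside) * prod(x$spacing) / 1000))
  invisible(x)
}

#' Mask volume in mm^3
#' @param mask a `gk_skull_mask`.
#' @return Scalar volume (voxel count times voxel volume), mm^3.
#' @export
mask_volume <- function(mask) {
  stopifnot(inherits(mask, "gk_skull_mask"))
  sum(mask$inside) * prod(mask$spacing)
}
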