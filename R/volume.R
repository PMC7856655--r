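#' Volume image container
#'
#' A `volume_image` is a 3D scalar field (gray-matter probability in \[0, 1\],
#' or integer atlas labels) on a voxel grid, together with a 4x4 affine
#' mapping 0-based voxel indices (i, j, k) to world millimetre coordinates.
#'
#' @param data Numeric 3D array.
#' @param affine 4x4 voxel-to-mm matrix; must be invertible. Defaults to a
#'   diagonal affine with `voxel_mm` spacing.
#' @param voxel_mm Isotropic voxel size in mm used when `affine` is missing.
#' @return An object of class `volume_image` with elements `data`, `affine`
#'   and `voxel_size` (mm per axis, derived from the affine column norms).
#' @export
volume_image <- function(data, affine = NULL, voxel_mm = 1.5) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("volume data must be a 3D array; got ", length(dim(data)), " dims")
  if (any(dim(data) < 1L)) stop("all three dims must be >= 1")
  if (is.null(affine)) {
    affine <- diag(c(rep(voxel_mm, 3), 1))
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("affine must be 4x4")
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("affine must be invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(data = data, affine = affine, voxel_size = vs),
            class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat("<volume_image> ", paste(dim(x$data), collapse = " x "),
      " voxels, ", paste(signif(x$voxel_size, 4), collapse = " x "),
      " mm\n", sep = "")
  invisible(x)
}

#' Read a NIfTI volume
#'
#' @param path Path to a NIfTI-1/2 file (`.nii` or `.nii.gz`).
#' @return A [volume_image].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- as.array(img)
  nd <- length(dim(d))
  if (nd != 3L)
    stop("expected a 3D volume, got ", nd, " dims (",
         paste(dim(d), collapse = " x "), ")")
  attributes(d) <- list(dim = dim(d))
  volume_image(d, affine = unclass(RNifti::xform(img))[1:4, 1:4])
}

#' Write a NIfTI volume
#'
#' Data are stored as float32 (or int16 for integer label volumes).
#'
#' @param vol A [volume_image].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume_image"))
  img <- RNifti::asNifti(vol$data)
  aff <- vol$affine
  RNifti::sform(img) <- structure(aff, code = 2L)
  dtype <- if (is.integer(vol$data) ||
               all(vol$data == round(vol$data))) "int16" else "float"
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

# Gaussian 1D kernel in voxel units, truncated at 4 sigma and renormalised.
.gauss_kernel <- function(sigma_vox) {
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- stats::dnorm(seq(-r, r), sd = sigma_vox)
  k / sum(k)
}

# Zero-padded convolution of a 3D array along one axis via a banded matrix.
.conv_axis <- function(a, k, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (off in -r:r) {
    idx <- seq_len(n - abs(off))
    if (off >= 0) K[cbind(idx, idx + off)] <- k[off + r + 1L]
    else K[cbind(idx - off, idx)] <- k[off + r + 1L]
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  m <- K %*% matrix(ap, nrow = n)
  out <- array(m, dim = d[perm])
  aperm(out, order(perm))
}

#' Gaussian smoothing of a volume
#'
#' Smooths with an isotropic Gaussian of the given full width at half maximum,
#' sigma_mm = fwhm / (2 sqrt(2 ln 2)), converted to voxel units per axis by the
#' voxel size. Boundary handling is zero-padding, matching the convention that
#' outside-brain voxels carry zero gray matter; mass is lost at the array edge.
#'
#' @param vol A [volume_image] on an axis-aligned grid (no shear in the
#'   affine).
#' @param fwhm_mm Positive kernel FWHM in mm.
#' @return A smoothed [volume_image] on the same grid.
#' @export
smooth_volume <- function(vol, fwhm_mm) {
  stopifnot(inherits(vol, "volume_image"))
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || fwhm_mm <= 0)
    stop("fwhm_mm must be a positive scalar")
  R <- vol$affine[1:3, 1:3]
  if (any(abs(R[row(R) != col(R)]) > 1e-8 * max(abs(diag(R)))))
    stop("smoothing requires an axis-aligned grid (affine has shear/rotation)")
  sig_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- vol$data
  for (ax in 1:3) {
    sig_vox <- sig_mm / vol$voxel_size[ax]
    out <- .conv_axis(out, .gauss_kernel(sig_vox), ax)
  }
  volume_image(out, affine = vol$affine)
}

#' FWHM to Gaussian sigma
#'
#' @param fwhm_mm Kernel FWHM in mm.
#' @param voxel_mm Voxel size in mm (default 1: result in mm).
#' @return Sigma in voxel units (or mm when `voxel_mm = 1`).
#' @export
fwhm_to_sigma <- function(fwhm_mm, voxel_mm = 1) {
  fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
}
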