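#' 3-D scalar volume with physical geometry
#'
#' A `hab_volume` couples a 3-D intensity array with its voxel spacing and
#' physical origin (both in mm). All geometric operations in the package
#' (rings, resampling, shape features) are computed in physical units through
#' these fields. Voxel indices are 0-based in physical formulas: the center of
#' voxel `(i, j, k)` sits at `origin + c(i, j, k) * spacing`.
#'
#' @param array numeric 3-D array of intensities.
#' @param spacing numeric length-3 voxel size in mm, strictly positive.
#' @param origin numeric length-3 physical offset in mm.
#' @return A `hab_volume` object.
#' @export
volume <- function(array, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  stopifnot(length(dim(array)) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  if (!all(is.finite(array))) stop("volume intensities must be finite")
  structure(list(array = array, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "hab_volume")
}

#' Binary region mask on a volume's grid
#'
#' @param array logical (or 0/1) 3-D array.
#' @param spacing,origin grid geometry, as in [volume()].
#' @param role free-form tag: `"tumor"`, `"ring_2mm"`, `"habitat_h1"`, ...
#' @return A `hab_mask` object.
#' @export
region_mask <- function(array, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        role = "tumor") {
  stopifnot(length(dim(array)) == 3L)
  if (any(spacing <= 0)) stop("voxel spacing must be strictly positive")
  arr <- array(as.logical(array), dim = dim(array))
  structure(list(array = arr, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), role = role),
            class = "hab_mask")
}

#' @export
print.hab_volume <- function(x, ...) {
  cat("<hab_volume> ", paste(dim(x$array), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "x"),
      " mm\n", sep = "")
  invisible(x)
}

#' @export
print.hab_mask <- function(x, ...) {
  cat("<hab_mask role=", x$role, "> ", sum(x$array), " foreground voxels of ",
      length(x$array), "\n", sep = "")
  invisible(x)
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$array), dim(b$array)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

voxel_volume_mm3 <- function(x) prod(x$spacing)

mask_count <- function(mask) sum(mask$array)

#' Read / write volumes as NIfTI
#'
#' Thin wrappers around RNifti. Spacing is carried through `pixdim`; the
#' physical origin through the quaternion offset.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param x a [volume()] or [region_mask()].
#' @return `read_volume` returns a `hab_volume`; `read_mask` a `hab_mask`.
#' @export
write_volume <- function(x, path) {
  img <- RNifti::asNifti(x$array)
  RNifti::pixdim(img) <- x$spacing
  aff <- diag(4)
  diag(aff)[1:3] <- x$spacing
  aff[1:3, 4] <- x$origin
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  sp <- RNifti::pixdim(img)[1:3]
  or <- tryCatch(as.numeric(RNifti::xform(img)[1:3, 4]),
                 error = function(e) c(0, 0, 0))
  volume(arr, spacing = sp, origin = or)
}

#' @rdname write_volume
#' @param role mask role tag assigned on read.
#' @export
read_mask <- function(path, role = "tumor") {
  v <- read_volume(path)
  region_mask(v$array > 0.5, spacing = v$spacing, origin = v$origin, role = role)
}
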