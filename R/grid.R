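#' @useDynLib adrenomorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats sd quantile median shapiro.test oneway.test var
#'   kruskal.test wilcox.test t.test cor.test rnorm qtukey lm coef
#'   complete.cases setNames p.adjust
#' @importFrom utils write.csv read.csv combn
#' @importFrom tools file_ext
NULL

ANATOMICAL_AXES <- c("CC", "DV", "ML")

#' Construct a CT image grid
#'
#' An `image_grid` couples a 3D array of Hounsfield-unit intensities with its
#' voxel geometry: spacing in mm per axis, an explicit mapping of the three
#' grid axes onto the anatomical directions, and an origin offset. Anatomical
#' labels are `"CC"` (craniocaudal), `"DV"` (dorsoventral) and `"ML"`
#' (mediolateral); they are never inferred from the data, because the
#' height/width conventions downstream are anatomical.
#'
#' Coordinates are voxel-center based: the center of voxel `i` (1-based)
#' along an axis with spacing `s` lies at `origin + (i - 1) * s` mm, and the
#' voxel spans `[center - s/2, center + s/2)`.
#'
#' @param intensities numeric 3D array of HU values; must be finite.
#' @param spacing numeric length-3, mm per axis; all positive.
#' @param axes character length-3, a permutation of `c("CC","DV","ML")`
#'   giving the anatomical direction of each grid axis.
#' @param origin numeric length-3 mm offset of the first voxel center.
#' @return an object of class `image_grid`.
#' @export
image_grid <- function(intensities, spacing,
                       axes = c("CC", "DV", "ML"),
                       origin = c(0, 0, 0)) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (!all(is.finite(intensities)))
    stop("intensities must be finite")
  spacing <- check_spacing(spacing)
  axes <- check_axes(axes)
  stopifnot(is.numeric(origin), length(origin) == 3L, all(is.finite(origin)))
  structure(
    list(intensities = intensities, spacing = spacing,
         axes = axes, origin = as.numeric(origin)),
    class = "image_grid"
  )
}

#' Construct a binary label mask aligned to an image grid
#'
#' A `label_mask` stores 0/1 voxel occupancy (here: the manually segmented
#' adrenal gland) on the same lattice as a companion [image_grid()]. Any
#' nonzero value is coerced to 1.
#'
#' @param occupancy numeric/logical 3D array; nonzero means occupied.
#' @inheritParams image_grid
#' @return an object of class `label_mask`.
#' @export
label_mask <- function(occupancy, spacing,
                       axes = c("CC", "DV", "ML"),
                       origin = c(0, 0, 0)) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L)
    stop("occupancy must be a 3D array")
  if (anyNA(occupancy)) stop("occupancy must not contain NA")
  occ <- array(as.integer(occupancy != 0), dim(occupancy))
  spacing <- check_spacing(spacing)
  axes <- check_axes(axes)
  structure(
    list(occupancy = occ, spacing = spacing,
         axes = axes, origin = as.numeric(origin)),
    class = "label_mask"
  )
}

check_spacing <- function(spacing) {
  if (!is.numeric(spacing) || length(spacing) != 3L || anyNA(spacing))
    stop("spacing must be a numeric vector of 3 values (mm)")
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  as.numeric(spacing)
}

check_axes <- function(axes) {
  if (!is.character(axes) || length(axes) != 3L ||
      !setequal(axes, ANATOMICAL_AXES))
    stop("axes must be a permutation of c(\"CC\", \"DV\", \"ML\")")
  axes
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(dim(x$intensities), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm, axes", paste(x$axes, collapse = "/"), "\n")
  invisible(x)
}

#' @export
print.label_mask <- function(x, ...) {
  cat("label_mask:", paste(dim(x$occupancy), collapse = " x "),
      "voxels,", sum(x$occupancy), "occupied, spacing",
      paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  invisible(x)
}

# grids are compatible when shapes match and spacing agrees to `tol` mm
check_compatible <- function(a, b, tol = 1e-4) {
  da <- dim(if (inherits(a, "image_grid")) a$intensities else a$occupancy)
  db <- dim(if (inherits(b, "image_grid")) b$intensities else b$occupancy)
  if (!identical(da, db))
    stop(sprintf("shape mismatch: %s vs %s",
                 paste(da, collapse = "x"), paste(db, collapse = "x")))
  if (any(abs(a$spacing - b$spacing) > tol))
    stop(sprintf("spacing mismatch beyond %g mm tolerance", tol))
  if (!identical(a$axes, b$axes))
    stop("axes labels differ between grid and mask")
  invisible(TRUE)
}

#' Read a CT volume from a NIfTI file
#'
#' Spacing is taken from the file's `pixdim` metadata; a file without
#' positive pixel spacing is rejected. Because NIfTI orientation codes are
#' frequently absent or untrustworthy in exported veterinary CT, the
#' anatomical axis labels must be supplied explicitly; they are never
#' guessed from the data.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param axes anatomical labels of the three grid axes (see [image_grid()]).
#' @return an [image_grid()].
#' @export
read_volume <- function(path, axes) {
  if (dir.exists(path))
    stop("directory input (DICOM series) is not supported; supply a NIfTI file")
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop("input is not a 3D volume: ", path)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0))
    stop("missing or invalid pixel spacing (pixdim) in ", path)
  image_grid(array(as.numeric(arr), dim(arr)), spacing = sp[1:3], axes = axes)
}

#' Write a CT volume to NIfTI
#' @param grid an [image_grid()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "image_grid"))
  img <- RNifti::asNifti(grid$intensities)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a segmentation mask aligned to a grid
#'
#' Any nonzero stored label maps to occupancy 1. The mask must match the
#' companion grid's shape exactly and its spacing to within `tol` mm.
#'
#' @param path NIfTI mask path.
#' @param grid the companion [image_grid()].
#' @param tol spacing agreement tolerance in mm.
#' @return a [label_mask()].
#' @export
read_mask <- function(path, grid, tol = 1e-4) {
  stopifnot(inherits(grid, "image_grid"))
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) != 3L) stop("mask is not a 3D volume: ", path)
  sp <- RNifti::pixdim(img)
  m <- label_mask(arr != 0, spacing = sp[1:3], axes = grid$axes,
                  origin = grid$origin)
  check_compatible(grid, m, tol = tol)
  m
}

#' Write a mask to NIfTI
#' @param mask a [label_mask()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  img <- RNifti::asNifti(mask$occupancy)
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Convert stored CT values to Hounsfield units
#'
#' The linear rescale `HU = slope * stored + intercept` applied by CT
#' readers to raw stored values (DICOM RescaleSlope / RescaleIntercept).
#'
#' @param stored numeric stored pixel values.
#' @param slope,intercept rescale parameters.
#' @return numeric HU values.
#' @examples
#' hu_rescale(1104, 1, -1024)  # 80 HU
#' @export
hu_rescale <- function(stored, slope = 1, intercept = 0) {
  stopifnot(is.numeric(stored), is.finite(slope), is.finite(intercept))
  slope * stored + intercept
}

#' Resample a volume (and mask) to a uniform in-plane resolution
#'
#' Reproduces the acquisition-side harmonization step in which in-plane
#' pixel size is interpolated to a common value (0.2 x 0.2 mm by default
#' elsewhere in the package) while the slice thickness is preserved.
#' Intensities are interpolated bilinearly within each slice (trilinear
#' interpolation restricted to the plane, since through-plane sampling is
#' unchanged); the mask is interpolated as a real-valued field and
#' thresholded at 0.5.
#'
#' @param grid an [image_grid()].
#' @param mask optional companion [label_mask()].
#' @param target target in-plane spacing, mm (> 0).
#' @param slice_axis index (1-3) of the through-plane axis; its spacing is
#'   kept.
#' @return if `mask` is `NULL` the resampled grid, else
#'   `list(grid = , mask = )`.
#' @export
resample_inplane <- function(grid, mask = NULL, target, slice_axis = 3L) {
  stopifnot(inherits(grid, "image_grid"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0)
    stop("target spacing must be a single positive value (mm)")
  slice_axis <- as.integer(slice_axis)
  stopifnot(slice_axis %in% 1:3)
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "label_mask"))
    check_compatible(grid, mask)
  }
  inplane <- setdiff(1:3, slice_axis)
  extent <- (dim(grid$intensities)[inplane] - 1) * grid$spacing[inplane]
  if (all(target > extent))
    warning("target spacing exceeds the in-plane extent; output collapses to one sample per axis")

  if (all(abs(grid$spacing[inplane] - target) < 1e-12)) {
    out_grid <- grid
    out_mask <- mask
  } else {
    new_arr <- resample_inplane_array(grid$intensities, grid$spacing,
                                      target, slice_axis)
    new_spacing <- grid$spacing
    new_spacing[inplane] <- target
    out_grid <- image_grid(new_arr, new_spacing, grid$axes, grid$origin)
    out_mask <- NULL
    if (!is.null(mask)) {
      mres <- resample_inplane_array(array(as.numeric(mask$occupancy),
                                           dim(mask$occupancy)),
                                     mask$spacing, target, slice_axis)
      out_mask <- label_mask(mres >= 0.5, new_spacing, mask$axes, mask$origin)
    }
  }
  if (is.null(mask)) out_grid else list(grid = out_grid, mask = out_mask)
}

# bilinear in-plane resampling of a 3D array, through-plane axis untouched.
# Sample positions are voxel centers of the new lattice laid over [0, L] mm.
resample_inplane_array <- function(arr, spacing, target, slice_axis) {
  perm <- c(setdiff(1:3, slice_axis), slice_axis)
  a <- aperm(arr, perm)
  d <- dim(a)
  sp <- spacing[perm]

  # new samples are edge-aligned with the old field of view [-s/2, n*s - s/2]
  # so that refining a lattice never places samples exactly on occupancy
  # midpoints (which would bias thresholded masks), and target == s is the
  # identity
  coords <- function(n, s) {
    n_new <- max(1L, floor(n * s / target + 1e-9))
    -s / 2 + (seq_len(n_new) - 0.5) * target
  }
  x_new <- coords(d[1], sp[1])
  y_new <- coords(d[2], sp[2])

  # fractional source indices (1-based), clamped to the lattice
  fx <- pmin(pmax(x_new / sp[1], 0), d[1] - 1)
  fy <- pmin(pmax(y_new / sp[2], 0), d[2] - 1)
  ix0 <- pmin(floor(fx) + 1L, d[1] - 1L); ix0[d[1] == 1L] <- 1L
  iy0 <- pmin(floor(fy) + 1L, d[2] - 1L); iy0[d[2] == 1L] <- 1L
  wx <- fx - (ix0 - 1L)
  wy <- fy - (iy0 - 1L)
  ix1 <- pmin(ix0 + 1L, d[1])
  iy1 <- pmin(iy0 + 1L, d[2])

  nx <- length(x_new); ny <- length(y_new)
  out <- array(0, c(nx, ny, d[3]))
  WX <- matrix(wx, nx, ny)
  WY <- matrix(wy, nx, ny, byrow = TRUE)
  for (k in seq_len(d[3])) {
    s <- a[, , k, drop = FALSE]
    dim(s) <- d[1:2]
    v00 <- s[ix0, iy0, drop = FALSE]
    v10 <- s[ix1, iy0, drop = FALSE]
    v01 <- s[ix0, iy1, drop = FALSE]
    v11 <- s[ix1, iy1, drop = FALSE]
    out[, , k] <- (1 - WX) * (1 - WY) * v00 + WX * (1 - WY) * v10 +
      (1 - WX) * WY * v01 + WX * WY * v11
  }
  aperm(out, order(perm))
}
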