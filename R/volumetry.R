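#' Slice-addition volumetry of a segmented gland
#'
#' Implements the slice-addition technique (SAT): within each slice the
#' number of segmented voxels is multiplied by the single-voxel volume to
#' give a partial volume, and the partial volumes are summed over slices to
#' give the total. Because every voxel contributes exactly its own volume,
#' the total is identical to `voxel count x voxel volume` and is exactly
#' independent of the slicing axis; the per-slice decomposition is retained
#' for reporting.
#'
#' @param mask a nonempty [label_mask()].
#' @param slice_axis axis (1-3) along which per-slice partial volumes are
#'   reported.
#' @return a list of class `volumetry_result` with `total_volume_cm3`,
#'   `per_slice_volumes_cm3` (one entry per slice along `slice_axis`),
#'   `voxel_count`, `voxel_volume_mm3` and `slice_axis`.
#' @export
compute_volume <- function(mask, slice_axis = 3L) {
  stopifnot(inherits(mask, "label_mask"))
  slice_axis <- as.integer(slice_axis)
  stopifnot(slice_axis %in% 1:3)
  counts <- slice_counts(mask$occupancy, slice_axis)
  nvox <- sum(counts)
  if (nvox == 0L) stop("empty segmentation")
  vox_mm3 <- prod(mask$spacing)
  structure(
    list(total_volume_cm3 = nvox * vox_mm3 / 1000,
         per_slice_volumes_cm3 = counts * vox_mm3 / 1000,
         per_slice_counts = as.integer(counts),
         voxel_count = as.integer(nvox),
         voxel_volume_mm3 = vox_mm3,
         slice_axis = slice_axis),
    class = "volumetry_result"
  )
}

slice_counts <- function(occ, axis) {
  apply(occ, axis, sum)
}

#' @export
print.volumetry_result <- function(x, ...) {
  cat(sprintf("SAT volume: %.4f cm^3 (%d voxels x %.4f mm^3, %d slices along axis %d)\n",
              x$total_volume_cm3, x$voxel_count, x$voxel_volume_mm3,
              length(x$per_slice_volumes_cm3), x$slice_axis))
  invisible(x)
}

#' Mean attenuation over a 3D ROI
#'
#' Mean and SD of the Hounsfield-unit intensities over exactly the voxels
#' selected for volumetry — the entire organ including its boundary voxels,
#' mirroring a whole-gland 3D ROI. A simple homogeneity screen flags the
#' ROI as homogeneous when the HU standard deviation does not exceed
#' `sd_threshold`; this operationalizes the qualitative requirement of
#' homogeneous contrast distribution and is a configurable stand-in, not a
#' validated criterion.
#'
#' @param grid an [image_grid()].
#' @param mask a nonempty [label_mask()] compatible with `grid`.
#' @param sd_threshold HU standard deviation above which the ROI is flagged
#'   non-homogeneous (default 25 HU).
#' @return a list of class `attenuation_result` with `mean_hu`, `sd_hu`,
#'   `n_voxels`, `homogeneous`.
#' @export
mean_attenuation <- function(grid, mask, sd_threshold = 25) {
  stopifnot(inherits(grid, "image_grid"), inherits(mask, "label_mask"))
  check_compatible(grid, mask)
  sel <- mask$occupancy == 1L
  n <- sum(sel)
  if (n == 0L) stop("empty segmentation")
  vals <- grid$intensities[sel]
  s <- if (n > 1L) stats::sd(vals) else 0
  structure(
    list(mean_hu = mean(vals), sd_hu = s, n_voxels = n,
         homogeneous = s <= sd_threshold),
    class = "attenuation_result"
  )
}

#' @export
print.attenuation_result <- function(x, ...) {
  cat(sprintf("attenuation: %.1f +/- %.1f HU over %d voxels (%s)\n",
              x$mean_hu, x$sd_hu, x$n_voxels,
              if (x$homogeneous) "homogeneous" else "non-homogeneous"))
  invisible(x)
}

#' Extract the boundary surface of a mask as a triangle mesh
#'
#' Builds the exact boundary of the voxel solid: every face of an occupied
#' voxel whose 6-neighbour is background contributes an outward-oriented
#' quad, split into two triangles. The mesh is closed and watertight by
#' construction, and the volume it encloses equals the voxel-counting (SAT)
#' volume exactly.
#'
#' @param mask a nonempty [label_mask()].
#' @return list of class `surface_mesh` with `vertices` (n x 3, mm) and
#'   `faces` (m x 3, 1-based, counter-clockwise seen from outside).
#' @export
extract_surface <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  occ <- mask$occupancy
  if (sum(occ) == 0L) stop("empty segmentation")
  ncomp <- max(label_components_cpp(occ, dim(occ)))
  if (ncomp > 1L)
    warning(sprintf("mask has %d connected components; surface will be disjoint", ncomp))

  d <- dim(occ)
  sp <- mask$spacing
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ

  # voxel corner offsets (units of one voxel), corners of the unit cube
  corner <- rbind(c(0,0,0), c(1,0,0), c(0,1,0), c(1,1,0),
                  c(0,0,1), c(1,0,1), c(0,1,1), c(1,1,1))
  # for each face direction: corner indices of the exposed quad, ordered CCW
  # when viewed from outside (outward normal = the direction)
  face_corners <- list(
    `+x` = c(2, 4, 8, 6), `-x` = c(1, 5, 7, 3),
    `+y` = c(3, 7, 8, 4), `-y` = c(1, 2, 6, 5),
    `+z` = c(5, 6, 8, 7), `-z` = c(1, 3, 4, 2)
  )
  shifts <- list(`+x` = c(1,0,0), `-x` = c(-1,0,0),
                 `+y` = c(0,1,0), `-y` = c(0,-1,0),
                 `+z` = c(0,0,1), `-z` = c(0,0,-1))

  idx <- which(occ == 1L, arr.ind = TRUE)
  quads_v <- list(); qi <- 0L
  for (dir in names(shifts)) {
    s <- shifts[[dir]]
    nb <- pad[cbind(idx[, 1] + 1L + s[1], idx[, 2] + 1L + s[2],
                    idx[, 3] + 1L + s[3])]
    exposed <- idx[nb == 0L, , drop = FALSE]
    if (nrow(exposed) == 0L) next
    cc <- face_corners[[dir]]
    # corner coordinates in voxel units: (index - 1) + corner offset - 1/2
    for (k in 1:4) {
      qi <- qi + 1L
      quads_v[[qi]] <- sweep(exposed - 1.5, 2, corner[cc[k], ], "+")
    }
  }
  # quads_v holds, per direction block, 4 matrices (one per quad corner)
  nblocks <- qi / 4L
  verts_all <- do.call(rbind, lapply(seq_len(nblocks), function(b) {
    m <- lapply(1:4, function(k) quads_v[[(b - 1L) * 4L + k]])
    nq <- nrow(m[[1]])
    out <- matrix(0, 4L * nq, 3)
    for (k in 1:4) out[seq(k, by = 4L, length.out = nq), ] <- m[[k]]
    out
  }))
  nq_total <- nrow(verts_all) / 4L

  key <- paste(verts_all[, 1], verts_all[, 2], verts_all[, 3], sep = "/")
  uk <- unique(key)
  vid <- match(key, uk)
  first <- match(uk, key)
  vertices <- sweep(verts_all[first, , drop = FALSE], 2, sp, "*")
  q <- matrix(vid, ncol = 4, byrow = TRUE)
  faces <- rbind(q[, c(1, 2, 3), drop = FALSE], q[, c(1, 3, 4), drop = FALSE])

  structure(list(vertices = vertices, faces = faces,
                 n_quads = nq_total, n_components = ncomp),
            class = "surface_mesh")
}

#' Volume enclosed by a triangle mesh
#'
#' Signed volume via the divergence theorem (sum of signed tetrahedra
#' against the origin); positive for outward-oriented closed meshes.
#'
#' @param mesh a `surface_mesh`.
#' @return enclosed volume in mm^3.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
      a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
      a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
}

#' Euler characteristic of a triangle mesh
#'
#' `V - E + F` with edges counted once regardless of orientation; equals 2
#' for a closed surface of genus 0.
#'
#' @param mesh a `surface_mesh`.
#' @return integer Euler characteristic.
#' @export
mesh_euler <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- t(apply(e, 1, sort))
  nE <- nrow(unique(e))
  nrow(mesh$vertices) - nE + nrow(f)
}

#' Write a mesh as ASCII PLY or OBJ
#' @param mesh a `surface_mesh`.
#' @param path output path; format chosen from the `.ply`/`.obj` extension.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  ext <- tolower(tools::file_ext(path))
  if (ext == "ply") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 sprintf("element vertex %d", nrow(v)),
                 "property float x", "property float y", "property float z",
                 sprintf("element face %d", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    writeLines(sprintf("%g %g %g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("3 %d %d %d", f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  } else if (ext == "obj") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("v %g %g %g", v[, 1], v[, 2], v[, 3]), con)
    writeLines(sprintf("f %d %d %d", f[, 1], f[, 2], f[, 3]), con)
  } else stop("unsupported mesh format: ", ext)
  invisible(path)
}
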