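#' Voxel-center coordinates (mm) of occupied boundary voxels
#'
#' A boundary voxel is an occupied voxel with at least one background
#' 6-neighbour (or lying on the array edge). The farthest pair of occupied
#' voxel centers is always attained on this set.
#' @param mask a [label_mask()].
#' @return matrix (n x 3) of mm coordinates.
#' @keywords internal
boundary_voxel_centers <- function(mask) {
  occ <- mask$occupancy
  d <- dim(occ)
  pad <- array(0L, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)]
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(core == 1L & nb < 6L, arr.ind = TRUE)
  sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
}

#' Maximal craniocaudal length of a segmented gland
#'
#' The gland length is formalized as the maximum Euclidean distance between
#' any two occupied voxel centers (the 3D farthest pair), computed exactly
#' over the boundary voxels. This is the rotation-invariant counterpart of
#' seeding a 3D length tool on the gland surface in a sagittal view.
#'
#' The returned endpoints are ordered so that the first is the cranial one
#' (smaller coordinate along the grid axis labelled `"CC"`).
#'
#' @param mask a nonempty [label_mask()].
#' @return list with `length_mm` and `endpoints` (2 x 3 matrix, mm).
#' @export
craniocaudal_length <- function(mask) {
  stopifnot(inherits(mask, "label_mask"))
  if (sum(mask$occupancy) == 0L) stop("empty segmentation")
  pts <- boundary_voxel_centers(mask)
  if (nrow(pts) == 1L) {
    warning("single-voxel mask: length is 0")
    return(list(length_mm = 0,
                endpoints = rbind(pts[1, ], pts[1, ])))
  }
  fp <- farthest_pair_cpp(pts)
  p1 <- pts[fp$i, ]; p2 <- pts[fp$j, ]
  cc <- which(mask$axes == "CC")
  if (p2[cc] < p1[cc]) { tmp <- p1; p1 <- p2; p2 <- tmp }
  list(length_mm = fp$d, endpoints = rbind(cranial = p1, caudal = p2))
}

#' Construct a gland measurement frame
#'
#' An orthonormal, proper (det +1) rotation from grid coordinates into the
#' gland frame: first axis along the craniocaudal length axis, second and
#' third axes the in-plane dorsoventral and mediolateral directions of the
#' adjusted transverse plane.
#'
#' @param rotation 3 x 3 matrix whose rows are the frame axes expressed in
#'   grid mm coordinates (length axis, DV, ML).
#' @param center mm point about which the rotation pivots.
#' @return object of class `gland_frame`.
#' @export
gland_frame <- function(rotation, center = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(is.numeric(rotation), all(dim(rotation) == c(3L, 3L)),
            length(center) == 3L)
  if (max(abs(rotation %*% t(rotation) - diag(3))) > 1e-8)
    stop("degenerate frame: rows are not orthonormal")
  if (det(rotation) < 0.99)
    stop("degenerate frame: rotation must be proper (det +1)")
  structure(list(rotation = rotation, center = as.numeric(center)),
            class = "gland_frame")
}

#' Derive the gland frame from a mask
#'
#' The length axis is the unit vector between the farthest-pair endpoints,
#' oriented cranial-to-caudal. The in-plane dorsoventral axis is the
#' anatomical DV direction projected onto the plane orthogonal to the
#' length axis and renormalized (minimal-rotation convention); the
#' mediolateral axis completes the right-handed triad.
#'
#' @param mask a nonempty [label_mask()].
#' @return a [gland_frame()].
#' @export
compute_gland_frame <- function(mask) {
  len <- craniocaudal_length(mask)
  if (len$length_mm <= 0) stop("degenerate frame: zero-length gland")
  u <- len$endpoints[2, ] - len$endpoints[1, ]
  u <- u / sqrt(sum(u^2))
  e_dv <- as.numeric(mask$axes == "DV")
  v <- e_dv - sum(e_dv * u) * u
  nv <- sqrt(sum(v^2))
  if (nv < 1e-8)
    stop("degenerate frame: length axis is parallel to the DV direction")
  v <- v / nv
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  gland_frame(rbind(u, v, w), center = colMeans(len$endpoints))
}

# trilinear interpolation of a 3D array at arbitrary mm points
# (voxel-center convention; points outside the lattice read as `outside`)
trilinear_sample <- function(arr, spacing, origin, pts, outside = 0) {
  d <- dim(arr)
  f <- sweep(sweep(pts, 2, origin, "-"), 2, spacing, "/")  # 0-based index
  inside <- f[, 1] >= 0 & f[, 1] <= d[1] - 1 &
    f[, 2] >= 0 & f[, 2] <= d[2] - 1 &
    f[, 3] >= 0 & f[, 3] <= d[3] - 1
  out <- rep(outside, nrow(pts))
  if (!any(inside)) return(out)
  f <- f[inside, , drop = FALSE]
  i0 <- pmin(floor(f) + 1, pmax(d - 1, 1))
  i0 <- pmax(i0, 1)
  w <- f - (i0 - 1)
  i1 <- pmin(i0 + 1, d[1] * 0 + d)  # clamp per axis
  i1 <- cbind(pmin(i0[, 1] + 1, d[1]), pmin(i0[, 2] + 1, d[2]),
              pmin(i0[, 3] + 1, d[3]))
  g <- function(ix, iy, iz) arr[cbind(ix, iy, iz)]
  v <- (1 - w[, 1]) * (1 - w[, 2]) * (1 - w[, 3]) * g(i0[, 1], i0[, 2], i0[, 3]) +
    w[, 1] * (1 - w[, 2]) * (1 - w[, 3]) * g(i1[, 1], i0[, 2], i0[, 3]) +
    (1 - w[, 1]) * w[, 2] * (1 - w[, 3]) * g(i0[, 1], i1[, 2], i0[, 3]) +
    (1 - w[, 1]) * (1 - w[, 2]) * w[, 3] * g(i0[, 1], i0[, 2], i1[, 3]) +
    w[, 1] * w[, 2] * (1 - w[, 3]) * g(i1[, 1], i1[, 2], i0[, 3]) +
    w[, 1] * (1 - w[, 2]) * w[, 3] * g(i1[, 1], i0[, 2], i1[, 3]) +
    (1 - w[, 1]) * w[, 2] * w[, 3] * g(i0[, 1], i1[, 2], i1[, 3]) +
    w[, 1] * w[, 2] * w[, 3] * g(i1[, 1], i1[, 2], i1[, 3])
  out[inside] <- v
  out
}

#' Resample a mask into its gland frame
#'
#' Rotates the mask so that the first axis runs along the craniocaudal
#' length axis and the in-plane axes are the adjusted-plane DV and ML
#' directions — the standardized sectional view in which pole and isthmus
#' calipers are taken. The mask is resampled isotropically at the smallest
#' original spacing; occupancy is interpolated trilinearly and thresholded
#' at 0.5.
#'
#' @param mask a nonempty [label_mask()].
#' @param frame a [gland_frame()]; computed from the mask when omitted.
#' @return a [label_mask()] with axes `c("CC","DV","ML")` in frame order.
#' @export
reorient_to_gland_frame <- function(mask, frame = NULL) {
  stopifnot(inherits(mask, "label_mask"))
  if (is.null(frame)) frame <- compute_gland_frame(mask)
  stopifnot(inherits(frame, "gland_frame"))
  R <- frame$rotation
  ctr <- frame$center
  s <- min(mask$spacing)

  idx <- which(mask$occupancy == 1L, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty segmentation")
  pts <- sweep(sweep(idx - 1, 2, mask$spacing, "*"), 2, mask$origin, "+")
  fpts <- t(R %*% (t(pts) - ctr))
  lo <- apply(fpts, 2, min) - 2 * s
  hi <- apply(fpts, 2, max) + 2 * s
  nn <- pmax(2L, floor((hi - lo) / s) + 1L)

  gx <- lo[1] + (seq_len(nn[1]) - 1) * s
  gy <- lo[2] + (seq_len(nn[2]) - 1) * s
  gz <- lo[3] + (seq_len(nn[3]) - 1) * s
  tgt <- cbind(rep(gx, times = nn[2] * nn[3]),
               rep(rep(gy, each = nn[1]), times = nn[3]),
               rep(gz, each = nn[1] * nn[2]))
  src <- t(t(R) %*% t(tgt) + ctr)
  occ_real <- trilinear_sample(array(as.numeric(mask$occupancy),
                                     dim(mask$occupancy)),
                               mask$spacing, mask$origin, src)
  occ_new <- array(occ_real >= 0.5, nn)
  label_mask(occ_new, spacing = c(s, s, s), axes = c("CC", "DV", "ML"),
             origin = lo)
}

#' Locate pole and isthmus stations along the length axis
#'
#' Works on a reoriented mask (first axis = length axis). Cross-sectional
#' areas are scanned station by station: the cranial pole is the maximal
#' area within the cranial `pole_window` fraction of the occupied length
#' (ties toward the cranial end), the caudal pole the maximal area within
#' the caudal window (ties toward the caudal end), and the isthmus the
#' minimal area strictly between the two pole stations (ties toward the
#' midpoint between the poles). This operationalizes pole/isthmus placement,
#' which clinical protocols leave to the observer.
#'
#' @param rmask a reoriented [label_mask()] (see
#'   [reorient_to_gland_frame()]).
#' @param pole_window fraction of the occupied length searched from each
#'   end for the pole stations (default 0.5).
#' @return list with `cranial`, `caudal`, `isthmus` (station indices along
#'   axis 1; `isthmus` may be `NA` if no interior station exists) and
#'   `areas_mm2` (per-station cross-sectional area).
#' @export
locate_poles_and_isthmus <- function(rmask, pole_window = 0.5) {
  stopifnot(inherits(rmask, "label_mask"),
            pole_window > 0, pole_window <= 1)
  counts <- slice_counts(rmask$occupancy, 1L)
  occ_st <- which(counts > 0)
  if (length(occ_st) < 5L) stop("gland too small for pole analysis")
  s1 <- min(occ_st); s2 <- max(occ_st)
  L <- s2 - s1 + 1L
  areas <- counts * prod(rmask$spacing[2:3])

  half <- max(1L, ceiling(L * pole_window))
  cr_win <- s1:(s1 + half - 1L)
  ca_win <- (s2 - half + 1L):s2
  cr_area <- areas[cr_win]
  cranial <- cr_win[which(cr_area == max(cr_area))[1]]        # tie: cranial end
  ca_area <- areas[ca_win]
  cand <- ca_win[ca_area == max(ca_area)]
  caudal <- cand[length(cand)]                                # tie: caudal end

  isthmus <- NA_integer_
  if (caudal - cranial >= 2L) {
    mid_win <- (cranial + 1L):(caudal - 1L)
    m_area <- areas[mid_win]
    cand <- mid_win[m_area == min(m_area)]
    midpoint <- (cranial + caudal) / 2
    isthmus <- cand[which.min(abs(cand - midpoint))]
  } else {
    warning("no station strictly between the pole stations; isthmus undefined")
  }
  list(cranial = cranial, caudal = caudal, isthmus = isthmus,
       areas_mm2 = areas)
}

#' Height and width of a cross-section at a station
#'
#' In the adjusted transverse plane, height is the axis-aligned extent of
#' the cross-section along the dorsoventral direction and width the extent
#' along the mediolateral direction, measured voxel-center to voxel-center
#' plus one voxel (so a single-voxel section has extent one spacing).
#'
#' @param rmask a reoriented [label_mask()].
#' @param station station index along the first (length) axis.
#' @return named vector `c(H_mm = , W_mm = )`.
#' @export
height_width_at <- function(rmask, station) {
  stopifnot(inherits(rmask, "label_mask"))
  d <- dim(rmask$occupancy)
  if (!(station >= 1 && station <= d[1])) stop("station outside gland extent")
  sl <- rmask$occupancy[station, , , drop = TRUE]
  if (sum(sl) == 0L) stop("empty cross-section at station ", station)
  dv_axis <- which(rmask$axes == "DV")
  ml_axis <- which(rmask$axes == "ML")
  extent <- function(ax) {
    # ax is 2 or 3 in the full array; in the slice it is ax-1
    pres <- which(apply(sl, ax - 1L, sum) > 0)
    (max(pres) - min(pres) + 1L) * rmask$spacing[ax]
  }
  c(H_mm = extent(dv_axis), W_mm = extent(ml_axis))
}

#' Dorsoventral aortic diameter at a transverse station
#'
#' The DV extent of the aorta cross-section at a user-supplied transverse
#' station (the landmark — caudal to the cranial mesenteric artery — is
#' identified by the operator, not detected automatically).
#'
#' @param aorta_mask a [label_mask()] of the aorta in the original grid.
#' @param station slice index along the craniocaudal axis.
#' @return diameter in mm.
#' @export
aortic_dorsoventral_diameter <- function(aorta_mask, station) {
  stopifnot(inherits(aorta_mask, "label_mask"))
  if (sum(aorta_mask$occupancy) == 0L) stop("empty segmentation")
  cc_axis <- which(aorta_mask$axes == "CC")
  dv_axis <- which(aorta_mask$axes == "DV")
  d <- dim(aorta_mask$occupancy)
  if (!(station >= 1 && station <= d[cc_axis]))
    stop("station outside volume extent")
  sl <- index_slice(aorta_mask$occupancy, cc_axis, station)
  if (sum(sl) == 0L) stop("empty aorta cross-section at station ", station)
  rem_axes <- setdiff(1:3, cc_axis)
  dv_in_slice <- match(dv_axis, rem_axes)
  pres <- which(apply(sl, dv_in_slice, sum) > 0)
  (max(pres) - min(pres) + 1L) * aorta_mask$spacing[dv_axis]
}

index_slice <- function(arr, axis, i) {
  switch(axis,
         arr[i, , , drop = TRUE],
         arr[, i, , drop = TRUE],
         arr[, , i, drop = TRUE])
}

#' Full per-gland measurement pipeline
#'
#' Runs slice-addition volumetry, 3D-ROI attenuation, craniocaudal length,
#' gland-frame reorientation, pole/isthmus localization and caliper
#' height/width, and (when an aorta mask and station are supplied) the RVA.
#' Isthmus calipers are reported for the left gland only, following the
#' measurement protocol.
#'
#' @param grid an [image_grid()].
#' @param mask gland [label_mask()].
#' @param side `"left"` or `"right"`.
#' @param aorta_mask optional aorta [label_mask()].
#' @param aorta_station transverse station for the aortic diameter.
#' @param sd_threshold HU homogeneity threshold (see [mean_attenuation()]).
#' @param pole_window pole search window (see
#'   [locate_poles_and_isthmus()]).
#' @return object of class `gland_measurement`.
#' @export
measure_gland <- function(grid, mask, side, aorta_mask = NULL,
                          aorta_station = NULL, sd_threshold = 25,
                          pole_window = 0.5) {
  side <- match.arg(side, c("left", "right"))
  vol <- compute_volume(mask)
  att <- mean_attenuation(grid, mask, sd_threshold = sd_threshold)
  len <- craniocaudal_length(mask)
  rmask <- reorient_to_gland_frame(mask)
  st <- locate_poles_and_isthmus(rmask, pole_window = pole_window)
  hw_cr <- height_width_at(rmask, st$cranial)
  hw_ca <- height_width_at(rmask, st$caudal)
  isth_h <- isth_w <- NA_real_
  if (side == "left" && !is.na(st$isthmus)) {
    hw_is <- height_width_at(rmask, st$isthmus)
    isth_h <- hw_is[["H_mm"]]
    isth_w <- hw_is[["W_mm"]]
  }
  aorta_dv <- NA_real_
  rva <- NA_real_
  if (!is.null(aorta_mask)) {
    if (is.null(aorta_station))
      stop("aorta_station must be supplied with aorta_mask")
    aorta_dv <- aortic_dorsoventral_diameter(aorta_mask, aorta_station)
    rva <- compute_rva(vol$total_volume_cm3, aorta_dv)
  }
  gland_measurement(
    side = side,
    length_mm = len$length_mm,
    cranial_height_mm = hw_cr[["H_mm"]], cranial_width_mm = hw_cr[["W_mm"]],
    caudal_height_mm = hw_ca[["H_mm"]], caudal_width_mm = hw_ca[["W_mm"]],
    isthmus_height_mm = isth_h, isthmus_width_mm = isth_w,
    volume_cm3 = vol$total_volume_cm3, mean_hu = att$mean_hu,
    sd_hu = att$sd_hu, homogeneous = att$homogeneous,
    aorta_dv_mm = aorta_dv, rva = rva,
    tol_mm = sqrt(3) * max(rmask$spacing)
  )
}

#' Construct a per-gland measurement record
#'
#' Container for one gland's morphometry: volume, attenuation, craniocaudal
#' length, pole heights/widths, isthmus calipers (left gland only), and the
#' optional aortic diameter and RVA.
#'
#' @param side `"left"` or `"right"`.
#' @param length_mm,cranial_height_mm,cranial_width_mm,caudal_height_mm,caudal_width_mm
#'   caliper measurements in mm; all positive and no caliper may exceed the
#'   length.
#' @param isthmus_height_mm,isthmus_width_mm isthmus calipers, left side
#'   only (`NA` on the right).
#' @param volume_cm3 SAT volume.
#' @param mean_hu,sd_hu attenuation statistics.
#' @param homogeneous homogeneity flag.
#' @param aorta_dv_mm,rva optional aortic diameter and RVA.
#' @param tol_mm slack (mm) allowed between calipers and the length before
#'   the consistency check fails; pipelines pass one voxel diagonal to
#'   absorb the edge-inclusive caliper convention on near-spherical masks.
#' @return object of class `gland_measurement`.
#' @export
gland_measurement <- function(side, length_mm, cranial_height_mm,
                              cranial_width_mm, caudal_height_mm,
                              caudal_width_mm, isthmus_height_mm = NA_real_,
                              isthmus_width_mm = NA_real_, volume_cm3,
                              mean_hu = NA_real_, sd_hu = NA_real_,
                              homogeneous = NA, aorta_dv_mm = NA_real_,
                              rva = NA_real_, tol_mm = 0) {
  side <- match.arg(side, c("left", "right"))
  lin <- c(length_mm, cranial_height_mm, cranial_width_mm,
           caudal_height_mm, caudal_width_mm)
  if (any(!is.finite(lin)) || any(lin <= 0))
    stop("linear measurements must be positive")
  # calipers are taken across the gland, never beyond its length; `tol_mm`
  # grants the one-voxel slack between the center-to-center length and the
  # edge-inclusive caliper extents (relevant only for near-spherical masks)
  if (any(lin[-1] > length_mm + tol_mm + 1e-9))
    stop("height/width measurements cannot exceed the gland length")
  if (side == "right" && (!is.na(isthmus_height_mm) || !is.na(isthmus_width_mm)))
    stop("isthmus calipers are defined for the left gland only")
  if (!is.finite(volume_cm3) || volume_cm3 <= 0)
    stop("volume_cm3 must be positive")
  structure(
    list(side = side, length_mm = length_mm,
         cranial_height_mm = cranial_height_mm,
         cranial_width_mm = cranial_width_mm,
         caudal_height_mm = caudal_height_mm,
         caudal_width_mm = caudal_width_mm,
         isthmus_height_mm = isthmus_height_mm,
         isthmus_width_mm = isthmus_width_mm,
         volume_cm3 = volume_cm3, mean_hu = mean_hu, sd_hu = sd_hu,
         homogeneous = homogeneous, aorta_dv_mm = aorta_dv_mm, rva = rva),
    class = "gland_measurement"
  )
}

#' @export
print.gland_measurement <- function(x, ...) {
  cat(sprintf("%s adrenal gland: V = %.2f cm^3, L = %.1f mm, HU = %.1f\n",
              x$side, x$volume_cm3, x$length_mm, x$mean_hu))
  cat(sprintf("  cranial pole H x W: %.1f x %.1f mm; caudal pole: %.1f x %.1f mm\n",
              x$cranial_height_mm, x$cranial_width_mm,
              x$caudal_height_mm, x$caudal_width_mm))
  if (!is.na(x$isthmus_height_mm))
    cat(sprintf("  isthmus H x W: %.1f x %.1f mm\n",
                x$isthmus_height_mm, x$isthmus_width_mm))
  if (!is.na(x$rva))
    cat(sprintf("  aorta DV %.1f mm, RVA = %.2f\n", x$aorta_dv_mm, x$rva))
  invisible(x)
}

#' @export
as.data.frame.gland_measurement <- function(x, ...) {
  data.frame(side = x$side, volume_cm3 = x$volume_cm3, mean_hu = x$mean_hu,
             sd_hu = x$sd_hu, homogeneous = x$homogeneous,
             length_mm = x$length_mm,
             cranial_h_mm = x$cranial_height_mm,
             cranial_w_mm = x$cranial_width_mm,
             caudal_h_mm = x$caudal_height_mm,
             caudal_w_mm = x$caudal_width_mm,
             isthmus_h_mm = x$isthmus_height_mm,
             isthmus_w_mm = x$isthmus_width_mm,
             aorta_dv_mm = x$aorta_dv_mm, rva = x$rva,
             stringsAsFactors = FALSE)
}
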