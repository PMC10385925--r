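test_that("craniocaudal length matches a brute-force farthest-pair oracle", {
  m <- box_mask(8, 4, 3, spacing = c(1, 1, 1))
  # oracle: all occupied voxel centers, full pairwise scan in R
  idx <- which(m$occupancy == 1L, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, m$spacing, "*")
  oracle <- max(dist(pts))
  res <- craniocaudal_length(m)
  expect_equal(res$length_mm, oracle, tolerance = 1e-12)
  expect_equal(oracle, sqrt(7^2 + 3^2 + 2^2), tolerance = 1e-12)
})

test_that("length is the major axis of an ellipsoid and survives rotation", {
  sp <- 0.25    # lattice aligned with the 15 mm tip so the chord is exact
  ph0 <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(15, 5, 4),
                                   spacing = rep(sp, 3)))
  l0 <- craniocaudal_length(ph0$mask)$length_mm
  expect_lt(abs(l0 - 30), sqrt(3) * sp)      # within one voxel diagonal

  ph30 <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(15, 5, 4),
                                    pose = c(0, 30, 0), spacing = rep(sp, 3)))
  l30 <- craniocaudal_length(ph30$mask)$length_mm
  expect_lt(abs(l30 - l0) / l0, 0.02)
})

test_that("linear outputs are invariant under rigid rotation of the mask", {
  base <- phantom_spec("dumbbell", lobe_radii = c(6, 5), neck_radius = 2.5,
                       lobe_separation = 16, spacing = c(0.4, 0.4, 0.4))
  ref_mask <- make_phantom(base)$mask
  ref_r <- reorient_to_gland_frame(ref_mask)
  ref_st <- locate_poles_and_isthmus(ref_r)
  ref_cr <- height_width_at(ref_r, ref_st$cranial)
  ref_is <- height_width_at(ref_r, ref_st$isthmus)
  ref_len <- craniocaudal_length(ref_mask)$length_mm

  for (pose in list(c(25, 0, 0), c(15, 40, 10))) {
    spec <- phantom_spec("dumbbell", lobe_radii = c(6, 5), neck_radius = 2.5,
                         lobe_separation = 16, pose = pose,
                         spacing = c(0.4, 0.4, 0.4))
    ph <- make_phantom(spec)
    expect_lt(abs(craniocaudal_length(ph$mask)$length_mm - ref_len) /
                ref_len, 0.02)
    r <- reorient_to_gland_frame(ph$mask)
    st <- locate_poles_and_isthmus(r)
    cr <- height_width_at(r, st$cranial)
    is_ <- height_width_at(r, st$isthmus)
    expect_lt(abs(cr[["H_mm"]] - ref_cr[["H_mm"]]) / ref_cr[["H_mm"]], 0.06)
    # the 5 mm neck is ~12 voxels across: allow two voxels of thresholding
    # jitter on the thinnest feature
    expect_lt(abs(is_[["H_mm"]] - ref_is[["H_mm"]]) / ref_is[["H_mm"]], 0.17)
    # isthmus caliper tracks the analytic neck diameter
    expect_lt(abs(is_[["H_mm"]] - ph$truth$neck_diameter_mm) /
                ph$truth$neck_diameter_mm, 0.17)
  }
})

test_that("single-voxel masks yield zero length with a warning", {
  m <- box_mask(1, 1, 1)
  expect_warning(res <- craniocaudal_length(m), "single-voxel")
  expect_equal(res$length_mm, 0)
})

test_that("reorientation preserves volume and measurements of aligned glands", {
  ph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(12, 5, 4),
                                  spacing = c(0.5, 0.5, 0.5)))
  r <- reorient_to_gland_frame(ph$mask)
  v0 <- compute_volume(ph$mask)$total_volume_cm3
  v1 <- compute_volume(r)$total_volume_cm3
  expect_lt(abs(v1 - v0) / v0, 0.01)
  st <- locate_poles_and_isthmus(r)
  # mid-gland cross-section of the aligned ellipsoid: DV 10 mm, ML 8 mm
  mid <- round((st$cranial + st$caudal) / 2)
  hw <- height_width_at(r, mid)
  expect_equal(hw[["H_mm"]], 10, tolerance = 0.8)
  expect_equal(hw[["W_mm"]], 8, tolerance = 0.8)
  expect_identical(r$axes, c("CC", "DV", "ML"))
})

test_that("pole and isthmus stations follow the area-scan rule", {
  # dumbbell: poles in the lobes, isthmus at the neck center
  ph <- make_phantom(phantom_spec("dumbbell", lobe_radii = c(6, 5),
                                  neck_radius = 2, lobe_separation = 16,
                                  spacing = c(0.5, 0.5, 0.5)))
  r <- reorient_to_gland_frame(ph$mask)
  st <- locate_poles_and_isthmus(r)
  areas <- st$areas_mm2
  # exhaustive oracle: stations of global max area per half, min between
  occ_st <- which(areas > 0)
  s1 <- min(occ_st); s2 <- max(occ_st); L <- s2 - s1 + 1
  half <- ceiling(L * 0.5)
  cr_or <- (s1:(s1 + half - 1))[which.max(areas[s1:(s1 + half - 1)])]
  ca_win <- (s2 - half + 1):s2
  ca_or <- ca_win[max(which(areas[ca_win] == max(areas[ca_win])))]
  expect_identical(st$cranial, cr_or)
  expect_identical(st$caudal, ca_or)
  mid_or <- ((cr_or + 1):(ca_or - 1))
  expect_equal(areas[st$isthmus], min(areas[mid_or]))
  # the neck center sits midway between the lobe centers
  expect_lt(abs(st$isthmus - (cr_or + ca_or) / 2), 0.25 * (ca_or - cr_or))

  # uniform cylinder: end-adjacent poles, isthmus area equals pole area
  cy <- elliptic_cylinder_mask(20, 4, 4, spacing = 0.5)
  stc <- locate_poles_and_isthmus(cy)   # already aligned along axis 1
  ac <- stc$areas_mm2
  occ <- which(ac > 0)
  expect_identical(stc$cranial, min(occ))
  expect_identical(stc$caudal, max(occ))
  expect_equal(ac[stc$isthmus], ac[stc$cranial])

  # monotone cone: cranial pole at the wide end, isthmus adjacent to the
  # narrow pole station
  cn <- cone_mask(20, 6, spacing = 0.5)
  stn <- locate_poles_and_isthmus(cn)
  an <- stn$areas_mm2
  occn <- which(an > 0)
  expect_identical(stn$cranial, min(occn))        # widest section
  expect_gt(an[stn$cranial], an[stn$caudal])
  expect_equal(an[stn$isthmus], min(an[(stn$cranial + 1):(stn$caudal - 1)]))
  expect_lte(abs(stn$isthmus - stn$caudal), 1L)   # hugs the narrow pole

  expect_error(locate_poles_and_isthmus(box_mask(3, 3, 3)),
               "too small for pole analysis")
})

test_that("caliper extents match in-plane geometry and a projection oracle", {
  # circular section, radius 5 mm
  cy <- elliptic_cylinder_mask(20, 5, 5, spacing = 0.5)
  st <- locate_poles_and_isthmus(cy)
  hw <- height_width_at(cy, st$isthmus)
  expect_equal(hw[["H_mm"]], 10, tolerance = 0.55)
  expect_equal(hw[["W_mm"]], 10, tolerance = 0.55)

  # elliptical section, DV semi-axis 4, ML semi-axis 2
  el <- elliptic_cylinder_mask(20, 4, 2, spacing = 0.5)
  hw2 <- height_width_at(el, locate_poles_and_isthmus(el)$isthmus)
  expect_equal(hw2[["H_mm"]], 8, tolerance = 0.55)
  expect_equal(hw2[["W_mm"]], 4, tolerance = 0.55)

  # 45-degree rotated elliptical gland: extents equal the per-voxel
  # min/max projection of the cross-section onto the DV / ML axes
  ph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(12, 4, 2),
                                  pose = c(45, 0, 0),
                                  spacing = c(0.4, 0.4, 0.4)))
  r <- reorient_to_gland_frame(ph$mask)
  stp <- locate_poles_and_isthmus(r)
  mid <- round((stp$cranial + stp$caudal) / 2)
  hw3 <- height_width_at(r, mid)
  sl <- which(r$occupancy[mid, , ] == 1L, arr.ind = TRUE)
  oracle_H <- (max(sl[, 1]) - min(sl[, 1]) + 1L) * r$spacing[2]
  oracle_W <- (max(sl[, 2]) - min(sl[, 2]) + 1L) * r$spacing[3]
  expect_identical(hw3[["H_mm"]], oracle_H)
  expect_identical(hw3[["W_mm"]], oracle_W)

  expect_error(height_width_at(cy, 10000), "outside")
})

test_that("aortic DV diameter reads the transverse station correctly", {
  cy <- elliptic_cylinder_mask(30, 5, 5, spacing = 0.5)
  st <- round(dim(cy$occupancy)[1] / 2)
  expect_equal(aortic_dorsoventral_diameter(cy, st), 10, tolerance = 0.55)

  el <- elliptic_cylinder_mask(30, 6, 5, spacing = 0.5)
  expect_equal(aortic_dorsoventral_diameter(el, st), 12, tolerance = 0.55)

  expect_error(aortic_dorsoventral_diameter(cy, 1), "empty aorta")
  expect_error(aortic_dorsoventral_diameter(cy, 10000), "outside")
})

test_that("the full measurement pipeline honours the measurement contract", {
  ph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(12, 5, 4),
                                  pose = c(10, 20, 0),
                                  spacing = c(0.5, 0.5, 0.5),
                                  noise_sd = 5, seed = 9))
  aorta <- elliptic_cylinder_mask(30, 5, 5, spacing = 0.5)
  st <- round(dim(aorta$occupancy)[1] / 2)
  m <- measure_gland(ph$grid, ph$mask, side = "left",
                     aorta_mask = aorta, aorta_station = st)
  expect_s3_class(m, "gland_measurement")
  expect_lt(abs(1000 * m$volume_cm3 - ph$truth$volume_mm3) /
              ph$truth$volume_mm3, 0.01)
  expect_lt(abs(m$length_mm - ph$truth$length_mm) / ph$truth$length_mm, 0.03)
  lin <- c(m$cranial_height_mm, m$cranial_width_mm, m$caudal_height_mm,
           m$caudal_width_mm, m$isthmus_height_mm, m$isthmus_width_mm)
  expect_true(all(lin <= m$length_mm))
  expect_false(is.na(m$rva))
  expect_equal(m$rva, compute_rva(m$volume_cm3, m$aorta_dv_mm))

  # right side: no isthmus fields; no aorta: no RVA
  mr <- measure_gland(ph$grid, ph$mask, side = "right")
  expect_true(is.na(mr$isthmus_height_mm))
  expect_true(is.na(mr$rva))
})

test_that("spheres have equal length, height and width", {
  sp <- 0.4
  ph <- make_phantom(phantom_spec("ellipsoid", semi_axes = c(5, 5, 5),
                                  spacing = rep(sp, 3)))
  m <- measure_gland(ph$grid, ph$mask, side = "right")
  diag_vox <- sqrt(3) * sp
  expect_lt(abs(m$length_mm - 10), diag_vox)
  expect_lt(abs(m$cranial_height_mm - 10), 2 * diag_vox)
  expect_lt(abs(m$cranial_width_mm - 10), 2 * diag_vox)
})

test_that("degenerate gland frames are rejected", {
  expect_error(gland_frame(matrix(0, 3, 3)), "orthonormal")
  refl <- diag(c(1, 1, -1))
  expect_error(gland_frame(refl), "proper")
})
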