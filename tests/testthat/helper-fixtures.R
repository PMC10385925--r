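# programmatic fixtures shared across test files

# digitized ball of radius r (mm) on an isotropic lattice
ball_mask <- function(r, spacing = 0.4, margin = 2) {
  make_phantom(phantom_spec("ellipsoid", semi_axes = rep(r, 3),
                            spacing = rep(spacing, 3),
                            margin_mm = margin))$mask
}

# solid box mask of nx x ny x nz occupied voxels inside a padded grid
box_mask <- function(nx, ny, nz, spacing = c(1, 1, 1), pad = 1L) {
  occ <- array(0L, c(nx + 2L * pad, ny + 2L * pad, nz + 2L * pad))
  occ[pad + seq_len(nx), pad + seq_len(ny), pad + seq_len(nz)] <- 1L
  label_mask(occ, spacing)
}

# circular or elliptical cylinder along the first (CC) axis, built directly
# (radii in mm: r_dv along axis 2 / DV, r_ml along axis 3 / ML)
elliptic_cylinder_mask <- function(length_mm, r_dv, r_ml, spacing = 0.5,
                                   margin = 1.5) {
  nx <- ceiling((length_mm + 2 * margin) / spacing) + 1L
  ny <- ceiling((2 * r_dv + 2 * margin) / spacing) + 1L
  nz <- ceiling((2 * r_ml + 2 * margin) / spacing) + 1L
  cx <- ((seq_len(nx) - 1) - (nx - 1) / 2) * spacing
  cy <- ((seq_len(ny) - 1) - (ny - 1) / 2) * spacing
  cz <- ((seq_len(nz) - 1) - (nz - 1) / 2) * spacing
  X <- array(rep(cx, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(cy, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(cz, each = nx * ny), c(nx, ny, nz))
  occ <- abs(X) <= length_mm / 2 & (Y / r_dv)^2 + (Z / r_ml)^2 <= 1
  label_mask(occ, rep(spacing, 3))
}

# cone along the first axis: radius shrinking linearly from r0 to ~0
cone_mask <- function(length_mm, r0, spacing = 0.5, margin = 1.5) {
  nx <- ceiling((length_mm + 2 * margin) / spacing) + 1L
  nyz <- ceiling((2 * r0 + 2 * margin) / spacing) + 1L
  cx <- ((seq_len(nx) - 1) - (nx - 1) / 2) * spacing
  cy <- ((seq_len(nyz) - 1) - (nyz - 1) / 2) * spacing
  X <- array(rep(cx, times = nyz * nyz), c(nx, nyz, nyz))
  Y <- array(rep(rep(cy, each = nx), times = nyz), c(nx, nyz, nyz))
  Z <- array(rep(cy, each = nx * nyz), c(nx, nyz, nyz))
  t <- (X + length_mm / 2) / length_mm           # 0 at wide end
  rad <- r0 * (1 - 0.9 * t)
  occ <- X >= -length_mm / 2 & X <= length_mm / 2 & Y^2 + Z^2 <= rad^2
  label_mask(occ, rep(spacing, 3))
}

# minimal long-format cohort row constructor for inclusion/side tests
cohort_row <- function(id, side, age = 5, weight = 30, volume = 1.2,
                       hu = 80, homogeneous = TRUE) {
  data.frame(id = id, breed = "Beagle", sex = "male", neutered = FALSE,
             age_years = age, weight_kg = weight, side = side,
             volume_cm3 = volume, mean_hu = hu, length_mm = 25,
             cranial_h_mm = 12, cranial_w_mm = 6, caudal_h_mm = 7,
             caudal_w_mm = 6, isthmus_h_mm = 5, isthmus_w_mm = 5,
             aorta_dv_mm = 10, homogeneous = homogeneous,
             stringsAsFactors = FALSE)
}

# letter-sharing predicate used on grouping tables
letters_shared <- function(grouping, a, b) {
  tab <- grouping$groups
  la <- strsplit(tab$letters[tab$group == a], "")[[1]]
  lb <- strsplit(tab$letters[tab$group == b], "")[[1]]
  length(intersect(la, lb)) > 0
}
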