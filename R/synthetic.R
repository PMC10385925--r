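#' Specify a voxel phantom with analytic ground truth
#'
#' Phantoms are gland-like solids with closed-form volume, length and
#' cross-section dimensions, digitized on a CT-like lattice so every
#' imaging stage (volumetry, attenuation, surface extraction, caliper
#' morphometry) can be validated against analytic truth. Shapes:
#' \describe{
#'   \item{ellipsoid}{`semi_axes` (mm, 3 values; first axis craniocaudal).}
#'   \item{dumbbell}{two spherical lobes of `lobe_radii` (mm, 2 values)
#'     whose centers are `lobe_separation` mm apart along the length axis,
#'     joined by a cylindrical neck of `neck_radius` mm. Requires
#'     `lobe_separation >= 2 * max(lobe_radii)` and
#'     `neck_radius < min(lobe_radii)` so the closed-form union volume
#'     applies.}
#'   \item{cylinder}{`radius` and `height` (mm), axis along the length
#'     direction.}
#' }
#' The default spacing (0.2 x 0.2 mm in-plane, 2 mm through-plane) mirrors
#' a harmonized abdominal CT protocol.
#'
#' @param shape `"ellipsoid"`, `"dumbbell"` or `"cylinder"`.
#' @param semi_axes,lobe_radii,neck_radius,lobe_separation,radius,height
#'   shape parameters in mm (see above); all must be positive.
#' @param pose rotation angles in degrees about the grid x, y, z axes
#'   (applied in that order, intrinsic).
#' @param spacing voxel spacing in mm.
#' @param fg_hu,bg_hu foreground/background intensity (HU).
#' @param noise_sd additive Gaussian HU noise SD (0 = noiseless).
#' @param margin_mm background margin around the shape.
#' @param dims optional explicit grid dimensions; errors if the posed
#'   shape does not fit.
#' @param seed RNG seed for the noise (required when `noise_sd > 0`).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c("ellipsoid", "dumbbell", "cylinder"),
                         semi_axes = NULL, lobe_radii = NULL,
                         neck_radius = NULL, lobe_separation = NULL,
                         radius = NULL, height = NULL,
                         pose = c(0, 0, 0), spacing = c(0.2, 0.2, 2),
                         fg_hu = 80, bg_hu = -50, noise_sd = 0,
                         margin_mm = 2, dims = NULL, seed = 1L) {
  shape <- match.arg(shape)
  pos <- function(x, what, len) {
    if (is.null(x) || length(x) != len || any(!is.finite(x)) || any(x <= 0))
      stop(sprintf("%s must be %d positive value(s)", what, len))
    as.numeric(x)
  }
  params <- switch(shape,
    ellipsoid = list(semi_axes = pos(semi_axes, "semi_axes", 3L)),
    dumbbell = {
      lr <- pos(lobe_radii, "lobe_radii", 2L)
      nr <- pos(neck_radius, "neck_radius", 1L)
      sep <- pos(lobe_separation, "lobe_separation", 1L)
      if (nr >= min(lr)) stop("neck_radius must be smaller than both lobe radii")
      if (sep < 2 * max(lr))
        stop("lobe_separation must be at least twice the larger lobe radius")
      list(lobe_radii = lr, neck_radius = nr, lobe_separation = sep)
    },
    cylinder = list(radius = pos(radius, "radius", 1L),
                    height = pos(height, "height", 1L))
  )
  spacing <- check_spacing(spacing)
  stopifnot(length(pose) == 3L, is.finite(fg_hu), is.finite(bg_hu),
            noise_sd >= 0, margin_mm >= 0)
  structure(
    list(shape = shape, params = params, pose = as.numeric(pose),
         spacing = spacing, fg_hu = fg_hu, bg_hu = bg_hu,
         noise_sd = noise_sd, margin_mm = margin_mm, dims = dims,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

rotation_from_angles <- function(deg) {
  a <- deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a[1]), -sin(a[1])),
              c(0, sin(a[1]), cos(a[1])))
  ry <- rbind(c(cos(a[2]), 0, sin(a[2])), c(0, 1, 0),
              c(-sin(a[2]), 0, cos(a[2])))
  rz <- rbind(c(cos(a[3]), -sin(a[3]), 0), c(sin(a[3]), cos(a[3]), 0),
              c(0, 0, 1))
  rz %*% ry %*% rx
}

phantom_truth <- function(spec) {
  with(spec$params, switch(spec$shape,
    ellipsoid = list(
      volume_mm3 = 4 / 3 * pi * prod(semi_axes),
      length_mm = 2 * max(semi_axes)),
    cylinder = list(
      volume_mm3 = pi * radius^2 * height,
      length_mm = sqrt(height^2 + (2 * radius)^2)),
    dumbbell = {
      r1 <- lobe_radii[1]; r2 <- lobe_radii[2]
      rn <- neck_radius; h <- lobe_separation
      cap <- function(r) 2 * pi / 3 * (r^3 - (r^2 - rn^2)^(3 / 2))
      list(
        volume_mm3 = 4 / 3 * pi * (r1^3 + r2^3) + pi * rn^2 * h -
          cap(r1) - cap(r2),
        length_mm = h + r1 + r2,
        neck_diameter_mm = 2 * rn,
        lobe_diameters_mm = 2 * lobe_radii)
    }))
}

#' Digitize a phantom onto a CT lattice
#'
#' Voxels are occupied by center-inclusion (a voxel belongs to the shape
#' iff its center lies inside), matching the counting model of
#' slice-addition volumetry. Intensities are foreground/background HU plus
#' optional Gaussian noise; identical specs (including seed) give
#' bit-identical output.
#'
#' @param spec a [phantom_spec()].
#' @return list with `grid` ([image_grid()]), `mask` ([label_mask()]) and
#'   `truth` (analytic volume, length and, for the dumbbell, neck/lobe
#'   diameters).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  R <- rotation_from_angles(spec$pose)
  support <- with(spec$params, switch(spec$shape,
    ellipsoid = max(semi_axes),
    cylinder = sqrt((height / 2)^2 + radius^2),
    dumbbell = lobe_separation / 2 + max(lobe_radii)))
  extent <- support + spec$margin_mm
  dims <- spec$dims
  if (is.null(dims)) {
    dims <- ceiling(2 * extent / spec$spacing) + 1L
  } else {
    dims <- as.integer(dims)
    if (any((dims - 1) * spec$spacing < 2 * support))
      stop("shape extent exceeds the requested grid")
  }
  center <- (dims - 1) / 2 * spec$spacing

  cx <- (seq_len(dims[1]) - 1) * spec$spacing[1] - center[1]
  cy <- (seq_len(dims[2]) - 1) * spec$spacing[2] - center[2]
  cz <- (seq_len(dims[3]) - 1) * spec$spacing[3] - center[3]
  # body coordinates of all voxel centers: p = R^T x
  X <- array(rep(cx, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(cy, each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(cz, each = dims[1] * dims[2]), dims)
  px <- t(R)[1, 1] * X + t(R)[1, 2] * Y + t(R)[1, 3] * Z
  py <- t(R)[2, 1] * X + t(R)[2, 2] * Y + t(R)[2, 3] * Z
  pz <- t(R)[3, 1] * X + t(R)[3, 2] * Y + t(R)[3, 3] * Z

  inside <- with(spec$params, switch(spec$shape,
    ellipsoid = (px / semi_axes[1])^2 + (py / semi_axes[2])^2 +
      (pz / semi_axes[3])^2 <= 1,
    cylinder = abs(px) <= height / 2 & py^2 + pz^2 <= radius^2,
    dumbbell = {
      d <- lobe_separation / 2
      (px + d)^2 + py^2 + pz^2 <= lobe_radii[1]^2 |
        (px - d)^2 + py^2 + pz^2 <= lobe_radii[2]^2 |
        (abs(px) <= d & py^2 + pz^2 <= neck_radius^2)
    }))

  hu <- array(spec$bg_hu, dims)
  hu[inside] <- spec$fg_hu
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    hu <- hu + array(stats::rnorm(prod(dims), 0, spec$noise_sd), dims)
  }
  list(grid = image_grid(hu, spec$spacing),
       mask = label_mask(inside, spec$spacing),
       truth = phantom_truth(spec))
}

#' Default cohort simulation parameters
#'
#' Builds the full parameter set of the cohort simulator, calibrated once
#' from the published breed-level summaries:
#' \itemize{
#'   \item allometric volume model `V = a * W^b * exp(eps)` per side, with
#'     `a`, `b` from a least-squares fit of log mean volume on log mean
#'     weight over the six breeds, and `sd(eps)` from the mean within-breed
#'     coefficient of variation;
#'   \item aortic diameter model `D = c * W^d * exp(delta)`: `c`, `d`
#'     solved from the two weight-class RVA medians at the class mean
#'     weights, `sd(delta)` set so the population correlation of log
#'     diameter with log weight matches the published r = 0.82;
#'   \item linear-metric shape factors mapping the cube root of gland
#'     volume to each caliper metric, with residual noise completing the
#'     published within-breed CV of that metric;
#'   \item attenuation per breed: the left gland drawn from the published
#'     left mean/SD, the right gland as left plus the published side
#'     offset plus N(0, `attenuation_side_sd`) HU.
#' }
#'
#' @param seed master seed; fans out into per-dog substreams so that
#'   enlarging the cohort never changes earlier dogs.
#' @param n_scale multiplier applied to every breed's sample size
#'   (rounded, minimum 1); `n_scale = 1` gives the 66-dog design.
#' @param attenuation_side_sd SD (HU) of the within-dog side residual.
#' @return object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(seed = 1L, n_scale = 1,
                              attenuation_side_sd = 6) {
  stopifnot(n_scale > 0, attenuation_side_sd >= 0)
  bt <- calibration_breed_table()
  vt <- calibration_volume_stats()
  lt <- calibration_linear_stats()
  at <- calibration_attenuation_stats()
  stopifnot(identical(bt$breed, vt$breed), identical(bt$breed, at$breed))

  bt$n <- pmax(1L, as.integer(round(bt$n * n_scale)))

  fit_side <- function(mean_col, sd_col) {
    f <- stats::lm(log(vt[[mean_col]]) ~ log(bt$weight_mean))
    cv <- mean(vt[[sd_col]] / vt[[mean_col]])
    list(a = unname(exp(stats::coef(f)[1])), b = unname(stats::coef(f)[2]),
         sigma_log = sqrt(log(1 + cv^2)))
  }
  allometry <- list(left = fit_side("left_mean", "left_sd"),
                    right = fit_side("right_mean", "right_sd"))

  # aorta: two-point power-law fit through the class RVA medians
  wc <- weight_class(bt$weight_mean)
  w_light <- sum(bt$weight_mean[wc == "light"] * bt$n[wc == "light"]) /
    sum(bt$n[wc == "light"])
  w_heavy <- sum(bt$weight_mean[wc == "heavy"] * bt$n[wc == "heavy"]) /
    sum(bt$n[wc == "heavy"])
  pp <- published_reference_percentiles()
  med <- function(cls, met, sd_) pp$median[pp$weight_class == cls &
                                             pp$metric == met & pp$side == sd_]
  aorta_target <- function(cls, w) {
    mean(c((1000 * med(cls, "volume_cm3", "left"))^(1 / 3) /
             med(cls, "rva", "left"),
           (1000 * med(cls, "volume_cm3", "right"))^(1 / 3) /
             med(cls, "rva", "right")))
  }
  d_light <- aorta_target("light", w_light)
  d_heavy <- aorta_target("heavy", w_heavy)
  d_exp <- log(d_heavy / d_light) / log(w_heavy / w_light)
  c_coef <- d_light / w_light^d_exp
  # population sd of log weight under the breed mixture, for the noise
  # level that reproduces the published weight-diameter correlation
  w_mix_mean <- sum(bt$n * log(bt$weight_mean)) / sum(bt$n)
  sd_logw <- sqrt(sum(bt$n * ((log(bt$weight_mean) - w_mix_mean)^2 +
                                (bt$weight_sd / bt$weight_mean)^2)) /
                    sum(bt$n))
  r_target <- 0.82
  sigma_aorta <- d_exp * sd_logw * sqrt(1 / r_target^2 - 1)
  aorta <- list(c = c_coef, d = d_exp, sigma_log = sigma_aorta)

  # shape factors: metric ~ factor * (volume in mm^3)^(1/3)
  lt$vol_mean <- vapply(seq_len(nrow(lt)), function(i) {
    vt[[paste0(lt$side[i], "_mean")]][vt$breed == lt$breed[i]]
  }, 1)
  lt$factor <- lt$mean / (1000 * lt$vol_mean)^(1 / 3)
  shape <- do.call(rbind, lapply(split(lt, list(lt$metric, lt$side),
                                       drop = TRUE), function(g) {
    target_cv <- mean(g$sd / g$mean)
    vol_cv <- allometry[[g$side[1]]]$sigma_log / 3
    data.frame(metric = g$metric[1], side = g$side[1],
               factor = mean(g$factor),
               sigma_log = sqrt(max(target_cv^2 - vol_cv^2, 0.02^2)),
               stringsAsFactors = FALSE)
  }))
  rownames(shape) <- NULL

  structure(
    list(breed_table = bt, allometry = allometry, aorta = aorta,
         shape_factors = shape, attenuation = at,
         attenuation_side_sd = attenuation_side_sd,
         seed = as.integer(seed)),
    class = "cohort_sim_params"
  )
}

rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= lower)
  guard <- 0L
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(out <= lower)
    guard <- guard + 1L
    if (guard > 1000L) { out[bad] <- lower + sd / 100; break }
  }
  out
}

#' Simulate a multi-breed cohort of adrenal measurements
#'
#' Draws one dog at a time from the breed design in
#' `params$breed_table`: body weight (truncated-positive normal), age
#' (truncated at the 2-year inclusion bound), per-side gland volumes from
#' the allometric model, caliper metrics from the shape-factor model,
#' aortic diameter from the aorta power law, and attenuation from the
#' breed/side model. Each dog has its own RNG substream derived from the
#' master seed, so enlarging the cohort never changes earlier dogs.
#'
#' @param params a [cohort_sim_params()].
#' @return long data frame, one row per gland, with columns `id`, `breed`,
#'   `sex`, `neutered`, `age_years`, `weight_kg`, `side`, `volume_cm3`,
#'   `mean_hu`, `length_mm`, `cranial_h_mm`, `cranial_w_mm`,
#'   `caudal_h_mm`, `caudal_w_mm`, `isthmus_h_mm`, `isthmus_w_mm`,
#'   `aorta_dv_mm`, `rva`.
#' @export
simulate_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  bt <- params$breed_table
  at <- params$attenuation
  sf <- params$shape_factors

  breed_of_dog <- rep(bt$breed, bt$n)
  n_dogs <- length(breed_of_dog)
  # sex/neuter categories follow the design counts, scaled with the breed n
  sex_cat <- unlist(lapply(seq_len(nrow(bt)), function(i) {
    counts <- unlist(bt[i, c("male_intact", "female_intact",
                             "male_neutered", "female_neutered")])
    cat4 <- rep(names(counts), counts)
    rep_len(cat4, bt$n[i])
  }), use.names = FALSE)

  set.seed(params$seed)
  dog_seeds <- sample.int(.Machine$integer.max - 1L, n_dogs)

  rows <- vector("list", n_dogs)
  for (i in seq_len(n_dogs)) {
    set.seed(dog_seeds[i])
    b <- which(bt$breed == breed_of_dog[i])
    w <- rtruncnorm_pos(1, bt$weight_mean[b], bt$weight_sd[b])
    age <- rtruncnorm_pos(1, bt$age_mean[b], bt$age_sd[b], lower = 2)
    aorta <- params$aorta$c * w^params$aorta$d *
      exp(stats::rnorm(1, 0, params$aorta$sigma_log))
    att_left <- stats::rnorm(1, at$left_mean[b], at$left_sd[b])
    att_right <- att_left + (at$right_mean[b] - at$left_mean[b]) +
      stats::rnorm(1, 0, params$attenuation_side_sd)

    side_rows <- lapply(c("left", "right"), function(sd_) {
      al <- params$allometry[[sd_]]
      vol <- al$a * w^al$b * exp(stats::rnorm(1, 0, al$sigma_log))
      cuberoot <- (1000 * vol)^(1 / 3)
      met <- sf[sf$side == sd_, , drop = FALSE]
      vals <- stats::setNames(
        met$factor * cuberoot * exp(stats::rnorm(nrow(met), 0,
                                                 met$sigma_log)),
        met$metric)
      data.frame(
        id = sprintf("dog%03d", i), breed = breed_of_dog[i],
        sex = if (startsWith(sex_cat[i], "male_")) "male" else "female",
        neutered = grepl("neutered", sex_cat[i]),
        age_years = age, weight_kg = w, side = sd_,
        volume_cm3 = vol,
        mean_hu = if (sd_ == "left") att_left else att_right,
        length_mm = vals[["length"]],
        cranial_h_mm = vals[["cranial_h"]],
        cranial_w_mm = vals[["cranial_w"]],
        caudal_h_mm = vals[["caudal_h"]],
        caudal_w_mm = vals[["caudal_w"]],
        isthmus_h_mm = if (sd_ == "left") vals[["isthmus_h"]] else NA_real_,
        isthmus_w_mm = if (sd_ == "left") vals[["isthmus_w"]] else NA_real_,
        aorta_dv_mm = aorta,
        rva = compute_rva(vol, aorta),
        stringsAsFactors = FALSE)
    })
    rows[[i]] <- do.call(rbind, side_rows)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
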