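# Published summary statistics of a clinical reference cohort of 66
# endocrinologically healthy dogs across six breeds, used as calibration
# targets for the cohort simulator and as comparison values in the
# analysis scripts. Only breed-level summaries (means, SDs, medians,
# percentiles) are available; no per-dog data exist.

#' Breed table of the reference cohort
#'
#' Per-breed sample sizes by sex/neuter status, and age and body-weight
#' means and SDs, for the six-breed, 66-dog reference cohort the simulator
#' emulates.
#'
#' @return data frame, one row per breed.
#' @export
calibration_breed_table <- function() {
  data.frame(
    breed = c("German Shepherd", "Labrador Retriever", "Boxer",
              "Beagle", "Jack Russell Terrier", "Dachshund"),
    male_intact = c(1, 3, 3, 2, 1, 5),
    female_intact = c(1, 4, 1, 1, 3, 1),
    male_neutered = c(3, 5, 3, 7, 5, 0),
    female_neutered = c(5, 4, 1, 4, 3, 0),
    n = c(10, 16, 8, 14, 12, 6),
    age_mean = c(8.2, 7.2, 8.8, 7.3, 10.5, 9.8),
    age_sd = c(3.1, 3.2, 2.1, 4.3, 3.7, 2.6),
    weight_mean = c(34.2, 34.2, 36.4, 14.2, 7.9, 8.4),
    weight_sd = c(8.4, 6.6, 4.3, 3.9, 2.4, 2.6),
    stringsAsFactors = FALSE
  )
}

#' Per-breed adrenal volume summaries of the reference cohort
#' @return data frame with left/right volume means and SDs (cm^3) per breed.
#' @export
calibration_volume_stats <- function() {
  data.frame(
    breed = c("German Shepherd", "Labrador Retriever", "Boxer",
              "Beagle", "Jack Russell Terrier", "Dachshund"),
    left_mean = c(1.37, 1.26, 1.42, 0.74, 0.66, 0.71),
    left_sd = c(0.41, 0.31, 0.29, 0.13, 0.19, 0.17),
    right_mean = c(1.54, 1.34, 1.44, 0.76, 0.67, 0.74),
    right_sd = c(0.29, 0.37, 0.24, 0.16, 0.19, 0.18),
    stringsAsFactors = FALSE
  )
}

#' Per-breed linear measurement summaries of the reference cohort
#'
#' Means and SDs (mm) of the caliper measurements per breed and side.
#' Metrics: `length`, `cranial_h`, `cranial_w`, `caudal_h`, `caudal_w`
#' (both sides) and `isthmus_h`, `isthmus_w` (left gland only).
#'
#' @return long data frame with `metric`, `side`, `breed`, `mean`, `sd`.
#' @export
calibration_linear_stats <- function() {
  breeds <- c("German Shepherd", "Labrador Retriever", "Boxer",
              "Beagle", "Jack Russell Terrier", "Dachshund")
  rows <- list(
    list("length", "left", c(30.2, 27.8, 32.2, 22.4, 20.5, 20.3),
         c(2.9, 2.4, 3.5, 2.4, 2.6, 2.0)),
    list("length", "right", c(34.9, 29.2, 31.2, 25.7, 19.1, 21.4),
         c(3.3, 3.2, 3.7, 3.1, 2.7, 3.6)),
    list("cranial_h", "left", c(13.2, 12.9, 12.3, 11.0, 10.1, 9.8),
         c(1.9, 2.2, 1.3, 1.5, 1.2, 1.2)),
    list("cranial_h", "right", c(17.8, 14.9, 15.7, 12.4, 12.6, 12.7),
         c(3.0, 2.7, 2.5, 1.1, 2.0, 2.1)),
    list("cranial_w", "left", c(6.0, 6.4, 6.1, 5.5, 5.9, 6.7),
         c(0.8, 1.1, 0.6, 1.4, 1.1, 1.2)),
    list("cranial_w", "right", c(6.4, 6.5, 6.2, 5.2, 5.8, 5.9),
         c(0.6, 1.6, 1.1, 0.9, 1.1, 0.6)),
    list("caudal_h", "left", c(8.5, 8.3, 8.9, 7.4, 7.0, 7.7),
         c(1.2, 0.8, 1.4, 0.8, 0.6, 0.9)),
    list("caudal_h", "right", c(7.2, 7.3, 7.6, 5.8, 6.2, 6.4),
         c(0.8, 0.9, 1.4, 0.8, 0.8, 0.5)),
    list("caudal_w", "left", c(7.0, 7.7, 7.1, 6.3, 6.5, 6.8),
         c(1.2, 1.1, 1.2, 0.8, 1.0, 0.8)),
    list("caudal_w", "right", c(5.7, 6.7, 6.7, 5.2, 5.5, 5.5),
         c(0.5, 1.1, 0.8, 0.8, 0.6, 0.9)),
    list("isthmus_h", "left", c(5.9, 5.5, 6.1, 5.2, 4.4, 4.9),
         c(0.6, 0.7, 0.8, 0.7, 0.7, 1.0)),
    list("isthmus_w", "left", c(4.9, 4.9, 4.8, 4.6, 5.0, 5.1),
         c(1.1, 0.8, 1.0, 0.6, 1.4, 0.9))
  )
  do.call(rbind, lapply(rows, function(r)
    data.frame(metric = r[[1]], side = r[[2]], breed = breeds,
               mean = r[[3]], sd = r[[4]], stringsAsFactors = FALSE)))
}

#' Per-breed attenuation summaries of the reference cohort
#' @return data frame with left/right postcontrast HU means and SDs per
#'   breed.
#' @export
calibration_attenuation_stats <- function() {
  data.frame(
    breed = c("German Shepherd", "Labrador Retriever", "Boxer",
              "Beagle", "Jack Russell Terrier", "Dachshund"),
    left_mean = c(80.1, 68.1, 68.1, 78.8, 89.7, 82.3),
    left_sd = c(14.7, 14.1, 10.8, 15.4, 18.9, 9.1),
    right_mean = c(87.7, 78.9, 76.4, 89.4, 92.9, 91.1),
    right_sd = c(13.0, 15.4, 9.9, 17.3, 21.6, 13.1),
    stringsAsFactors = FALSE
  )
}

#' Published weight-class reference percentiles
#'
#' The published 10th/50th/90th percentile reference values for volume,
#' RVA and caudal-pole height by weight class and side, kept for
#' comparison with tables rebuilt from simulated cohorts.
#'
#' @return long data frame with `weight_class`, `side`, `metric`, `p10`,
#'   `median`, `p90`, `n`.
#' @export
published_reference_percentiles <- function() {
  g <- expand.grid(side = c("left", "right"),
                   metric = c("volume_cm3", "rva", "caudal_h_mm"),
                   weight_class = c("light", "heavy"),
                   stringsAsFactors = FALSE)
  g <- g[, c("weight_class", "side", "metric")]
  g$p10 <- c(0.47, 0.52, 0.93, 0.95, 6.37, 4.88,
             0.89, 0.97, 0.83, 0.83, 7.26, 6.04)
  g$median <- c(0.74, 0.74, 1.25, 1.21, 7.38, 6.07,
                1.41, 1.44, 0.98, 0.99, 8.62, 7.27)
  g$p90 <- c(0.82, 0.92, 1.44, 1.51, 8.09, 7.06,
             1.68, 1.82, 1.14, 1.22, 9.73, 8.52)
  g$n <- rep(c(32L, 34L), each = 6L)
  g
}
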