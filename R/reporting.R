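COHORT_SCHEMA <- c("id", "breed", "sex", "neutered", "age_years",
                   "weight_kg", "side", "volume_cm3", "mean_hu",
                   "length_mm", "cranial_h_mm", "cranial_w_mm",
                   "caudal_h_mm", "caudal_w_mm", "isthmus_h_mm",
                   "isthmus_w_mm", "aorta_dv_mm")

#' Validate a cohort table against the expected schema
#'
#' @param records data frame to check.
#' @return the records, invisibly, with an `rva` column added when absent
#'   and computable.
#' @export
validate_cohort <- function(records) {
  df <- as.data.frame(records)
  missing_cols <- setdiff(COHORT_SCHEMA, names(df))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  bad_side <- setdiff(unique(df$side), c("left", "right"))
  if (length(bad_side))
    stop("invalid side values: ", paste(bad_side, collapse = ", "))
  if (!("rva" %in% names(df))) {
    df$rva <- NA_real_
    ok <- is.finite(df$volume_cm3) & is.finite(df$aorta_dv_mm) &
      df$volume_cm3 > 0 & df$aorta_dv_mm > 0
    df$rva[ok] <- compute_rva(df$volume_cm3[ok], df$aorta_dv_mm[ok])
  }
  invisible(df)
}

#' Read / write a cohort CSV
#' @param path CSV path.
#' @return data frame (validated).
#' @export
read_cohort_csv <- function(path) {
  validate_cohort(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @rdname read_cohort_csv
#' @param records cohort data frame.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE)
  invisible(path)
}

#' Full cohort analysis report
#'
#' Runs the complete statistical battery over a cohort table and returns
#' (optionally writing as CSV/JSON) the four standard outputs:
#' \describe{
#'   \item{breed_comparison}{per side, breed mean +/- SD of gland volume
#'     with multiple-range letters and the paired left-right test per
#'     breed.}
#'   \item{reference_table}{weight-class percentile reference intervals
#'     for volume, RVA and caudal-pole height.}
#'   \item{cv_table}{per caliper metric: breed means, the between-breed
#'     coefficient of variation, and the Pearson correlation with body
#'     weight (with strength band; `NS` when p >= alpha).}
#'   \item{attenuation_table}{per breed and side: mean +/- SD, median and
#'     quartiles of attenuation, and the paired side test.}
#' }
#'
#' @param records cohort data frame (long form; see [validate_cohort()]).
#' @param alpha significance level (default 0.05).
#' @param qtype percentile definition for the reference table.
#' @param boundary_kg weight-class boundary (kg).
#' @param out_dir optional directory; when given, each table is written as
#'   CSV plus a JSON bundle with the run configuration.
#' @return list of class `cohort_report`.
#' @export
cohort_report <- function(records, alpha = 0.05, qtype = 7L,
                          boundary_kg = 20, out_dir = NULL) {
  df <- validate_cohort(records)
  breeds <- unique(df$breed)

  # breed comparison of volume, one block per side
  breed_comparison <- NULL
  comparisons <- list()
  if (length(breeds) < 2L) {
    warning("fewer than 2 breeds: breed comparison omitted")
  } else {
    blocks <- lapply(c("left", "right"), function(sd_) {
      cb <- compare_breeds(df, "volume_cm3", side = sd_, alpha = alpha)
      g <- cb$grouping$groups
      sds <- vapply(g$group, function(b)
        stats::sd(df$volume_cm3[df$breed == b & df$side == sd_]), 1)
      data.frame(side = sd_, breed = g$group, n = g$n,
                 mean_volume_cm3 = g$mean, sd_volume_cm3 = unname(sds),
                 letters = g$letters, test = cb$report$test,
                 p_value = cb$report$p_value, stringsAsFactors = FALSE)
    })
    comparisons <- list(left = compare_breeds(df, "volume_cm3", "left",
                                              alpha = alpha),
                        right = compare_breeds(df, "volume_cm3", "right",
                                               alpha = alpha))
    breed_comparison <- do.call(rbind, blocks)
    breed_comparison$paired_p <- vapply(seq_len(nrow(breed_comparison)),
      function(i) {
        b <- breed_comparison$breed[i]
        side_difference(df[df$breed == b, ], "volume_cm3",
                        alpha = alpha)$p_value
      }, 1)
  }

  reference_table <- build_reference_table(df, qtype = qtype,
                                           boundary_kg = boundary_kg)

  # between-breed CVs and weight correlations for the caliper metrics
  lin_metrics <- data.frame(
    metric = c("length_mm", "length_mm", "cranial_h_mm", "cranial_h_mm",
               "cranial_w_mm", "cranial_w_mm", "caudal_h_mm",
               "caudal_h_mm", "caudal_w_mm", "caudal_w_mm",
               "isthmus_h_mm", "isthmus_w_mm"),
    side = c("left", "right", "left", "right", "left", "right", "left",
             "right", "left", "right", "left", "left"),
    stringsAsFactors = FALSE)
  cv_rows <- lapply(seq_len(nrow(lin_metrics)), function(i) {
    m <- lin_metrics$metric[i]; sd_ <- lin_metrics$side[i]
    sub <- df[df$side == sd_ & is.finite(df[[m]]), ]
    breed_means <- tapply(sub[[m]], sub$breed, mean)
    cv <- if (length(breed_means) >= 2L) compute_cv(breed_means) else NA_real_
    ct <- correlate_with_weight(sub, m)
    data.frame(metric = m, side = sd_, cv = cv, cv_2dp = round(cv, 2),
               r = ct$r, r_p_value = ct$p_value,
               band = if (ct$p_value < alpha) ct$band else "NS",
               stringsAsFactors = FALSE)
  })
  cv_table <- do.call(rbind, cv_rows)

  att_rows <- lapply(breeds, function(b) {
    sub <- df[df$breed == b, ]
    stats_side <- function(sd_) {
      v <- sub$mean_hu[sub$side == sd_]
      c(mean = mean(v), sd = stats::sd(v),
        median = stats::median(v),
        q1 = unname(stats::quantile(v, 0.25, type = qtype)),
        q3 = unname(stats::quantile(v, 0.75, type = qtype)))
    }
    l <- stats_side("left"); r <- stats_side("right")
    sp <- side_difference(sub, "mean_hu", alpha = alpha)
    data.frame(breed = b,
               left_mean = l["mean"], left_sd = l["sd"],
               left_median = l["median"], left_q1 = l["q1"],
               left_q3 = l["q3"],
               right_mean = r["mean"], right_sd = r["sd"],
               right_median = r["median"], right_q1 = r["q1"],
               right_q3 = r["q3"],
               side_test = sp$test, side_p = sp$p_value,
               stringsAsFactors = FALSE)
  })
  attenuation_table <- do.call(rbind, att_rows)
  rownames(attenuation_table) <- NULL

  config <- list(alpha = alpha, qtype = qtype, boundary_kg = boundary_kg,
                 n_records = nrow(df), n_dogs = length(unique(df$id)))
  out <- structure(
    list(breed_comparison = breed_comparison,
         reference_table = reference_table,
         cv_table = cv_table,
         attenuation_table = attenuation_table,
         comparisons = comparisons,
         config = config),
    class = "cohort_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(breed_comparison))
      utils::write.csv(breed_comparison,
                       file.path(out_dir, "breed_comparison.csv"),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(reference_table),
                     file.path(out_dir, "reference_table.csv"),
                     row.names = FALSE)
    utils::write.csv(cv_table, file.path(out_dir, "cv_table.csv"),
                     row.names = FALSE)
    utils::write.csv(attenuation_table,
                     file.path(out_dir, "attenuation_table.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(config = config,
           breed_comparison = breed_comparison,
           reference_table = as.data.frame(reference_table),
           cv_table = cv_table,
           attenuation_table = attenuation_table),
      file.path(out_dir, "cohort_report.json"),
      auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("Cohort report:", x$config$n_dogs, "dogs,",
      x$config$n_records, "glands\n\n")
  if (!is.null(x$breed_comparison)) {
    cat("Breed comparison (volume):\n")
    print(x$breed_comparison, row.names = FALSE, digits = 3)
    cat("\n")
  }
  cat("Reference intervals:\n")
  print(as.data.frame(x$reference_table), row.names = FALSE, digits = 3)
  cat("\nBetween-breed CVs and weight correlations:\n")
  print(x$cv_table, row.names = FALSE, digits = 3)
  invisible(x)
}

#' JSON measurement report for a single gland
#'
#' @param m a [gland_measurement()].
#' @param path optional output path; when omitted the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
measurement_report <- function(m, path = NULL) {
  stopifnot(inherits(m, "gland_measurement"))
  payload <- unclass(m)
  payload <- payload[!vapply(payload, function(v)
    length(v) == 1L && is.na(v), TRUE)]
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
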