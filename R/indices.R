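#' Ratio volume-aorta (RVA)
#'
#' Body-size-normalized adrenal size index: the cube root of the gland
#' volume (in mm^3) divided by the dorsoventral aortic diameter (in mm).
#' The index is dimensionless and invariant under isotropic body scaling
#' (volume by s^3, diameter by s).
#'
#' @param volume_cm3 adrenal volume in cm^3 (> 0); vectorized.
#' @param aortic_diameter_mm dorsoventral aortic diameter in mm (> 0).
#' @return dimensionless RVA value(s).
#' @examples
#' compute_rva(1.0, 10)   # 1000^(1/3) / 10 = 1
#' compute_rva(0.74, 7.3) # 1.239
#' @export
compute_rva <- function(volume_cm3, aortic_diameter_mm) {
  if (any(!is.finite(volume_cm3)) || any(volume_cm3 <= 0))
    stop("volume_cm3 must be positive")
  if (any(!is.finite(aortic_diameter_mm)) || any(aortic_diameter_mm <= 0))
    stop("aortic_diameter_mm must be positive")
  (1000 * volume_cm3)^(1 / 3) / aortic_diameter_mm
}

#' Coefficient of variation of group mean values
#'
#' The between-breed dispersion statistic: sample standard deviation (n-1
#' denominator) of the group means divided by their arithmetic mean. For
#' table display the value is conventionally rounded to 2 decimals; the
#' unrounded value is returned.
#'
#' @param group_means numeric vector of at least two positive group means.
#' @return unrounded CV (ratio, not percent).
#' @examples
#' compute_cv(c(30.2, 27.8, 32.2, 22.4, 20.5, 20.3)) # ~0.20
#' @export
compute_cv <- function(group_means) {
  if (!is.numeric(group_means) || length(group_means) < 2L)
    stop("at least 2 group means are required")
  if (anyNA(group_means)) stop("group means must not contain NA")
  m <- mean(group_means)
  if (m == 0) stop("mean of group means is zero")
  stats::sd(group_means) / m
}

CORRELATION_BANDS <- data.frame(
  label = c("very weak", "weak", "moderate", "strong", "very strong"),
  lower = c(0.0, 0.2, 0.4, 0.6, 0.8),
  upper = c(0.2, 0.4, 0.6, 0.8, 1.0),
  stringsAsFactors = FALSE
)

#' Classify correlation strength
#'
#' Bands the absolute value of a Pearson correlation coefficient:
#' very weak \[0, 0.2), weak \[0.2, 0.4), moderate \[0.4, 0.6),
#' strong \[0.6, 0.8), very strong \[0.8, 1\]. Sign is ignored.
#'
#' @param r correlation coefficient(s) in \[-1, 1\].
#' @return character band label(s).
#' @examples
#' classify_correlation(0.84) # "very strong"
#' classify_correlation(0.47) # "moderate"
#' @export
classify_correlation <- function(r) {
  if (any(!is.finite(r)) || any(abs(r) > 1))
    stop("correlation must lie in [-1, 1]")
  a <- abs(r)
  idx <- findInterval(a, CORRELATION_BANDS$lower)
  CORRELATION_BANDS$label[idx]
}

#' Assign weight classes
#'
#' Dogs under 20 kg body weight form the light class, all others (including
#' exactly 20.0 kg) the heavy class.
#'
#' @param body_weight_kg numeric body weight(s) in kg (> 0).
#' @param boundary_kg class boundary, default 20.
#' @return factor with levels `c("light", "heavy")`.
#' @export
weight_class <- function(body_weight_kg, boundary_kg = 20) {
  if (any(!is.finite(body_weight_kg)) || any(body_weight_kg <= 0))
    stop("body weight must be positive")
  factor(ifelse(body_weight_kg < boundary_kg, "light", "heavy"),
         levels = c("light", "heavy"))
}

#' Build a weight-class percentile reference table
#'
#' For each weight class x side x metric stratum, computes the 10th
#' percentile, lower quartile, median, upper quartile and 90th percentile
#' of the metric, with the stratum size. Percentiles use linear
#' interpolation between order statistics by default (`qtype = 7`); the
#' definition is exposed because statistics suites differ in their
#' defaults.
#'
#' @param records cohort data frame in long (one row per gland) form; must
#'   contain `weight_kg`, `side` and the metric columns.
#' @param metrics character vector of metric column names (default: volume,
#'   RVA and caudal-pole height).
#' @param min_n minimum stratum size; smaller strata are omitted with a
#'   warning (default 5).
#' @param qtype quantile type passed to [stats::quantile()].
#' @param boundary_kg weight class boundary in kg.
#' @return data frame of class `reference_table` with columns
#'   `weight_class`, `side`, `metric`, `n`, `p10`, `q1`, `median`, `q3`,
#'   `p90`.
#' @export
build_reference_table <- function(records,
                                  metrics = c("volume_cm3", "rva",
                                              "caudal_h_mm"),
                                  min_n = 5L, qtype = 7L,
                                  boundary_kg = 20) {
  stopifnot(is.data.frame(records),
            all(c("weight_kg", "side") %in% names(records)))
  missing_cols <- setdiff(metrics, names(records))
  if (length(missing_cols))
    stop("metrics not present in records: ",
         paste(missing_cols, collapse = ", "))
  wc <- weight_class(records$weight_kg, boundary_kg)
  rows <- list()
  for (cls in levels(wc)) for (sd_ in c("left", "right")) for (m in metrics) {
    v <- records[[m]][wc == cls & records$side == sd_]
    v <- v[is.finite(v)]
    if (length(v) < min_n) {
      warning(sprintf("stratum %s/%s/%s has n=%d < %d; omitted",
                      cls, sd_, m, length(v), min_n))
      next
    }
    q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90),
                         type = qtype, names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      weight_class = cls, side = sd_, metric = m, n = length(v),
      p10 = q[1], q1 = q[2], median = q[3], q3 = q[4], p90 = q[5],
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no stratum met the minimum size")
  out <- do.call(rbind, rows)
  stopifnot(all(out$p10 <= out$q1), all(out$q1 <= out$median),
            all(out$median <= out$q3), all(out$q3 <= out$p90))
  class(out) <- c("reference_table", class(out))
  out
}

#' Assess a gland measurement against a reference table
#'
#' Flags each metric of a measurement as `below_p10`, `within` or
#' `above_p90` relative to its weight-class/side stratum, and additionally
#' reports whether the left caudal-pole height exceeds the
#' weight-independent 7.4 mm threshold historically used for adrenal
#' enlargement — the comparison the weight-specific intervals are meant to
#' replace.
#'
#' @param m a [gland_measurement()].
#' @param weight_class_label `"light"` or `"heavy"`.
#' @param table a reference table from [build_reference_table()].
#' @param universal_threshold_mm the legacy weight-independent caudal-pole
#'   height threshold (default 7.4 mm).
#' @return data frame with one row per assessed metric plus the
#'   `above_universal_threshold` attribute for a left gland.
#' @export
assess_against_reference <- function(m, weight_class_label, table,
                                     universal_threshold_mm = 7.4) {
  stopifnot(inherits(m, "gland_measurement"))
  weight_class_label <- match.arg(weight_class_label, c("light", "heavy"))
  vals <- c(volume_cm3 = m$volume_cm3, rva = m$rva,
            caudal_h_mm = m$caudal_height_mm)
  rows <- list()
  for (met in names(vals)) {
    if (!is.finite(vals[[met]])) next
    ref <- table[table$weight_class == weight_class_label &
                   table$side == m$side & table$metric == met, ]
    if (nrow(ref) == 0L)
      stop(sprintf("reference table does not cover stratum %s/%s/%s",
                   weight_class_label, m$side, met))
    flag <- if (vals[[met]] < ref$p10) "below_p10"
      else if (vals[[met]] > ref$p90) "above_p90" else "within"
    rows[[length(rows) + 1L]] <- data.frame(
      metric = met, value = vals[[met]], p10 = ref$p10, p90 = ref$p90,
      flag = flag, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (m$side == "left")
    attr(out, "above_universal_threshold") <-
      is.finite(m$caudal_height_mm) &&
      m$caudal_height_mm > universal_threshold_mm
  out
}
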