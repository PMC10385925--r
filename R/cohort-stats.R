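#' Shapiro-Wilk normality gate
#'
#' Returns `TRUE` ("treat as normal") when the Shapiro-Wilk p-value is at
#' least `alpha`. The gate decides between the parametric
#' (ANOVA + REGWQ, paired t) and nonparametric (Kruskal-Wallis/Wilcoxon)
#' branches of the cohort battery. Samples larger than the Shapiro-Wilk
#' implementation limit of 5000 are thinned deterministically (even
#' stride) before testing.
#'
#' @param values numeric sample, n >= 3, non-constant.
#' @param alpha gate level (default 0.05).
#' @return logical.
#' @export
normality_gate <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3L) stop("normality gate needs at least 3 values")
  if (diff(range(values)) == 0) stop("degenerate sample: all values identical")
  if (n > 5000L) values <- values[round(seq(1, n, length.out = 5000L))]
  stats::shapiro.test(values)$p.value >= alpha
}

#' Compare breeds on one metric
#'
#' The breed-comparison battery: every breed sample is screened with the
#' Shapiro-Wilk gate; if all pass, a one-way ANOVA is reported together
#' with REGWQ letter grouping; otherwise a Kruskal-Wallis test is reported
#' with letters built from protected pairwise two-sample Wilcoxon tests
#' (pairwise tests are consulted only when Kruskal-Wallis rejects).
#'
#' @param records long cohort data frame (one row per gland) with columns
#'   `breed` and the metric.
#' @param metric metric column name.
#' @param side optional `"left"`/`"right"` filter.
#' @param alpha significance level (default 0.05).
#' @param gate `"per_group"` (default; every breed must pass) or
#'   `"pooled"` (gate on the pooled residual sample, centred per breed).
#' @param p_adjust multiplicity correction for the nonparametric pairwise
#'   p-values (default `"none"`).
#' @return list of class `breed_comparison` with `report` (test name,
#'   statistic, p-value, gate outcome) and `grouping` (a
#'   `regwq_grouping`).
#' @export
compare_breeds <- function(records, metric, side = NULL, alpha = 0.05,
                           gate = c("per_group", "pooled"),
                           p_adjust = "none") {
  gate <- match.arg(gate)
  df <- as.data.frame(records)
  if (!is.null(side)) df <- df[df$side == side, , drop = FALSE]
  stopifnot(metric %in% names(df), "breed" %in% names(df))
  df <- df[is.finite(df[[metric]]), , drop = FALSE]
  groups <- split(df[[metric]], as.character(df$breed))
  if (length(groups) < 2L) stop("at least 2 breeds are required")
  ni <- vapply(groups, length, 1L)
  if (any(ni < 2L))
    stop("groups below minimum size: ",
         paste(names(groups)[ni < 2L], collapse = ", "))

  normal <- if (gate == "per_group") {
    all(vapply(groups, function(v) {
      if (length(v) < 3L) return(FALSE)
      normality_gate(v, alpha)
    }, TRUE))
  } else {
    resid <- unlist(lapply(groups, function(v) v - mean(v)),
                    use.names = FALSE)
    normality_gate(resid, alpha)
  }

  if (normal) {
    val <- unlist(groups, use.names = FALSE)
    fac <- factor(rep(names(groups), ni), levels = names(groups))
    ow <- stats::oneway.test(val ~ fac, var.equal = TRUE)
    grouping <- regwq(groups, alpha = alpha)
    report <- list(metric = metric, side = side, test = "one-way ANOVA + REGWQ",
                   statistic = unname(ow$statistic), p_value = ow$p.value,
                   gate_normal = TRUE, alpha = alpha)
  } else {
    grouping <- pairwise_wilcox_letters(groups, alpha = alpha,
                                        p_adjust = p_adjust)
    report <- list(metric = metric, side = side,
                   test = "Kruskal-Wallis + pairwise Wilcoxon",
                   statistic = NA_real_, p_value = grouping$kruskal_p,
                   gate_normal = FALSE, alpha = alpha)
  }
  structure(list(report = report, grouping = grouping),
            class = "breed_comparison")
}

#' @export
print.breed_comparison <- function(x, ...) {
  r <- x$report
  cat(sprintf("%s%s: %s, p = %.4g (gate: %s)\n", r$metric,
              if (!is.null(r$side)) paste0(" [", r$side, "]") else "",
              r$test, r$p_value,
              if (r$gate_normal) "normal" else "non-normal"))
  print(x$grouping$groups, row.names = FALSE)
  invisible(x)
}

#' Paired left-right side test
#'
#' Pairs the left and right values of each dog and tests the side
#' difference with a paired t-test when the differences pass the normality
#' gate, otherwise with the Wilcoxon signed-rank test.
#'
#' @param records long cohort data frame with `id`, `side` and the metric.
#' @param metric metric column name.
#' @param alpha gate and significance level.
#' @return list of class `stats_report` with `test`, `statistic`,
#'   `p_value`, `n_pairs`, `mean_difference` (left minus right) and
#'   `gate_normal`.
#' @export
side_difference <- function(records, metric, alpha = 0.05) {
  df <- as.data.frame(records)
  stopifnot(all(c("id", "side") %in% names(df)), metric %in% names(df))
  lf <- df[df$side == "left", c("id", metric)]
  rt <- df[df$side == "right", c("id", metric)]
  mrg <- merge(lf, rt, by = "id", suffixes = c("_left", "_right"))
  mrg <- mrg[stats::complete.cases(mrg), , drop = FALSE]
  if (nrow(mrg) < nrow(lf) || nrow(mrg) < nrow(rt))
    stop("unpaired records: every dog needs both sides for a side test")
  if (nrow(mrg) < 2L) stop("at least 2 pairs are required")
  d <- mrg[[paste0(metric, "_left")]] - mrg[[paste0(metric, "_right")]]
  if (diff(range(d)) == 0 && d[1] == 0) {
    out <- list(test = "identical pairs", statistic = NA_real_,
                p_value = 1, n_pairs = length(d), mean_difference = 0,
                gate_normal = NA)
  } else if (diff(range(d)) == 0 || normality_gate(d, alpha)) {
    tt <- stats::t.test(d)
    out <- list(test = "paired t-test", statistic = unname(tt$statistic),
                p_value = tt$p.value, n_pairs = length(d),
                mean_difference = mean(d), gate_normal = TRUE)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(d, exact = FALSE))
    out <- list(test = "Wilcoxon signed-rank",
                statistic = unname(wt$statistic), p_value = wt$p.value,
                n_pairs = length(d), mean_difference = mean(d),
                gate_normal = FALSE)
  }
  structure(c(out, list(metric = metric, alpha = alpha)),
            class = "stats_report")
}

#' @export
print.stats_report <- function(x, ...) {
  cat(sprintf("%s: %s, p = %.4g\n", x$metric, x$test, x$p_value))
  invisible(x)
}

#' Weight-group difference test
#'
#' Two-sample Wilcoxon rank-sum test of a metric between the light
#' (< 20 kg) and heavy (>= 20 kg) weight classes.
#'
#' @param records long cohort data frame with `weight_kg` and the metric.
#' @param metric metric column name.
#' @param side optional side filter.
#' @param boundary_kg weight class boundary (default 20).
#' @return `stats_report` list with the rank-sum statistic and p-value.
#' @export
weight_group_difference <- function(records, metric, side = NULL,
                                    boundary_kg = 20) {
  df <- as.data.frame(records)
  if (!is.null(side)) df <- df[df$side == side, , drop = FALSE]
  stopifnot(metric %in% names(df), "weight_kg" %in% names(df))
  df <- df[is.finite(df[[metric]]), , drop = FALSE]
  wc <- weight_class(df$weight_kg, boundary_kg)
  light <- df[[metric]][wc == "light"]
  heavy <- df[[metric]][wc == "heavy"]
  if (length(light) == 0L || length(heavy) == 0L)
    stop("both weight classes must be nonempty")
  wt <- suppressWarnings(stats::wilcox.test(light, heavy, exact = FALSE))
  structure(
    list(metric = metric, side = side, test = "Wilcoxon rank-sum",
         statistic = unname(wt$statistic), p_value = wt$p.value,
         n_light = length(light), n_heavy = length(heavy),
         median_light = stats::median(light),
         median_heavy = stats::median(heavy)),
    class = "stats_report"
  )
}

#' Pearson correlation of a metric with body weight
#'
#' @param records long cohort data frame with `weight_kg` and the metric.
#' @param metric metric column name.
#' @param side optional side filter.
#' @return list with `r`, `p_value`, `band` (see
#'   [classify_correlation()]), and `n`.
#' @export
correlate_with_weight <- function(records, metric, side = NULL) {
  df <- as.data.frame(records)
  if (!is.null(side)) df <- df[df$side == side, , drop = FALSE]
  stopifnot(metric %in% names(df), "weight_kg" %in% names(df))
  ok <- is.finite(df[[metric]]) & is.finite(df$weight_kg)
  x <- df$weight_kg[ok]; y <- df[[metric]][ok]
  if (length(x) < 3L) stop("at least 3 complete observations are required")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    stop("constant metric or weight: correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(metric = metric, side = side, r = unname(ct$estimate),
       p_value = ct$p.value, band = classify_correlation(unname(ct$estimate)),
       n = length(x))
}

#' Apply the cohort inclusion criteria
#'
#' Excludes dogs younger than two years, dogs without both adrenal glands
#' measurable, and (when a homogeneity flag is available) dogs with a
#' non-homogeneous contrast distribution in either gland. Each exclusion is
#' recorded with its reason.
#'
#' @param records long cohort data frame with `id`, `age_years`, `side`,
#'   `volume_cm3` and optionally `homogeneous`.
#' @return list with `kept` (data frame) and `excluded`
#'   (data frame `id`, `reason`).
#' @export
apply_inclusion_criteria <- function(records) {
  df <- as.data.frame(records)
  stopifnot(all(c("id", "age_years", "side", "volume_cm3") %in% names(df)))
  excl <- list()
  drop_ids <- character(0)
  for (id in unique(as.character(df$id))) {
    sub <- df[df$id == id, , drop = FALSE]
    reason <- NULL
    if (any(sub$age_years < 2)) {
      reason <- "age<2"
    } else if (!all(c("left", "right") %in%
                    sub$side[is.finite(sub$volume_cm3)])) {
      reason <- "missing gland"
    } else if ("homogeneous" %in% names(sub) &&
               any(!is.na(sub$homogeneous) & !sub$homogeneous)) {
      reason <- "non-homogeneous enhancement"
    }
    if (!is.null(reason)) {
      drop_ids <- c(drop_ids, id)
      excl[[length(excl) + 1L]] <- data.frame(id = id, reason = reason,
                                              stringsAsFactors = FALSE)
    }
  }
  list(kept = df[!(as.character(df$id) %in% drop_ids), , drop = FALSE],
       excluded = if (length(excl)) do.call(rbind, excl)
         else data.frame(id = character(0), reason = character(0)))
}
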