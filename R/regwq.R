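#' Ryan-Einot-Gabriel-Welsch (REGWQ) multiple range test
#'
#' Step-down multiple range procedure on the ordered group means using
#' studentized-range critical values. A contiguous range of `p` ordered
#' means is tested at level `alpha_p = 1 - (1 - alpha)^(p/k)` for
#' `p <= k - 2` and at `alpha_p = alpha` for `p` in `{k - 1, k}`; a range
#' that is not rejected is declared homogeneous and none of its sub-ranges
#' are tested. With unequal group sizes the standard error uses the
#' harmonic mean of the sizes of the groups in the range (the classical
#' unequal-n adaptation). Letters encode the maximal homogeneous ranges:
#' two groups share a letter exactly when some non-rejected range contains
#' both, i.e. when the procedure never declared them different.
#'
#' @param groups named list of numeric vectors (one per group), each with
#'   at least 2 observations.
#' @param alpha familywise significance level (default 0.05).
#' @return object of class `regwq_grouping`: data frame `groups` with
#'   `group`, `n`, `mean`, `letters` (ordered by descending mean), a
#'   logical matrix `different`, the list of homogeneous `subsets`, and the
#'   pooled `df` and `mse`.
#' @export
regwq <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least 2 groups are required")
  if (is.null(names(groups)) || anyNA(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[is.finite(v)])
  ni <- vapply(groups, length, 1L)
  if (any(ni < 2L))
    stop("groups below minimum size (n >= 2): ",
         paste(names(groups)[ni < 2L], collapse = ", "))
  stopifnot(alpha > 0, alpha < 1)

  k <- length(groups)
  means <- vapply(groups, mean, 1)
  vars <- vapply(groups, stats::var, 1)
  N <- sum(ni)
  df <- N - k
  mse <- sum((ni - 1) * vars) / df

  ord <- order(means)             # ascending
  om <- means[ord]
  on <- ni[ord]

  # step-down over contiguous ranges of the ordered means
  accepted <- list()
  covered <- function(i, j) {
    for (r in accepted) if (r[1] <= i && j <= r[2]) return(TRUE)
    FALSE
  }
  for (p in k:2) {
    a_p <- if (p >= k - 1) alpha else 1 - (1 - alpha)^(p / k)
    crit <- stats::qtukey(1 - a_p, p, df)
    for (i in 1:(k - p + 1)) {
      j <- i + p - 1L
      if (covered(i, j)) next
      diff <- om[j] - om[i]
      if (mse <= 0) {
        qstat <- if (diff > 1e-12) Inf else 0
      } else {
        nh <- p / sum(1 / on[i:j])
        qstat <- diff / sqrt(mse / nh)
      }
      if (qstat <= crit) accepted[[length(accepted) + 1L]] <- c(i, j)
      # rejected ranges leave their sub-ranges open for testing
    }
  }

  # maximal homogeneous subsets -> letters
  is_max <- vapply(seq_along(accepted), function(a) {
    r <- accepted[[a]]
    !any(vapply(seq_along(accepted), function(b) {
      s <- accepted[[b]]
      b != a && s[1] <= r[1] && r[2] <= s[2] &&
        (s[2] - s[1] > r[2] - r[1])
    }, TRUE))
  }, TRUE)
  subsets <- accepted[is_max]
  subsets <- subsets[order(vapply(subsets, `[`, 1, 1))]
  in_subset <- rep(FALSE, k)
  for (r in subsets) in_subset[r[1]:r[2]] <- TRUE
  for (i in which(!in_subset)) subsets[[length(subsets) + 1L]] <- c(i, i)
  subsets <- subsets[order(vapply(subsets, `[`, 1, 1))]

  letters_mat <- matrix(FALSE, k, length(subsets))
  for (s in seq_along(subsets))
    letters_mat[subsets[[s]][1]:subsets[[s]][2], s] <- TRUE
  letter_labels <- make_letter_labels(length(subsets))
  letters_by_rank <- apply(letters_mat, 1, function(z)
    paste(letter_labels[z], collapse = ""))

  different <- matrix(TRUE, k, k,
                      dimnames = list(names(om), names(om)))
  diag(different) <- FALSE
  for (r in accepted)
    different[r[1]:r[2], r[1]:r[2]] <- FALSE

  # report in descending-mean order, as grouping tables are printed
  desc <- k:1
  tab <- data.frame(group = names(om)[desc], n = unname(on[desc]),
                    mean = unname(om[desc]),
                    letters = letters_by_rank[desc],
                    stringsAsFactors = FALSE)
  # re-letter so the top mean gets "A"
  tab$letters <- relabel_letters(tab$letters)
  structure(
    list(groups = tab,
         different = different[desc, desc],
         subsets = lapply(subsets, function(r) names(om)[r[1]:r[2]]),
         df = df, mse = mse, alpha = alpha),
    class = "regwq_grouping"
  )
}

make_letter_labels <- function(n) {
  base <- LETTERS
  if (n <= 26) return(base[seq_len(n)])
  c(base, paste0(rep(base, each = 26), base))[seq_len(n)]
}

# remap letter symbols so they first appear in display order
relabel_letters <- function(x) {
  seen <- unique(unlist(strsplit(x, "")))
  map <- stats::setNames(make_letter_labels(length(seen)), seen)
  vapply(x, function(s)
    paste(map[strsplit(s, "")[[1]]], collapse = ""), "", USE.NAMES = FALSE)
}

#' @export
print.regwq_grouping <- function(x, ...) {
  cat(sprintf("REGWQ multiple range grouping (alpha = %g, df = %d)\n",
              x$alpha, x$df))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Letter grouping from pairwise non-rejections
#'
#' Builds a grouping display for the nonparametric branch: groups are
#' ordered by mean rank and letters are assigned to maximal contiguous runs
#' within which no pairwise test rejected. This extends pairwise reporting
#' into the letter-display convention used for the parametric branch.
#'
#' @param groups named list of numeric samples.
#' @param alpha significance level.
#' @param p_adjust multiplicity correction for the pairwise p-values
#'   (default `"none"`, mirroring raw pairwise reporting).
#' @param protected logical; when `TRUE` the pairwise tests are only
#'   consulted if the global Kruskal-Wallis test rejects, otherwise all
#'   groups share one letter.
#' @return object of class `regwq_grouping` (same display contract).
#' @export
pairwise_wilcox_letters <- function(groups, alpha = 0.05,
                                    p_adjust = "none", protected = TRUE) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  groups <- lapply(groups, function(v) v[is.finite(v)])
  k <- length(groups)
  ni <- vapply(groups, length, 1L)
  means <- vapply(groups, mean, 1)
  all_v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), ni), levels = names(groups))
  kw <- stats::kruskal.test(all_v, g)
  mean_rank <- tapply(rank(all_v), g, mean)
  ord <- order(mean_rank)

  pmat <- matrix(1, k, k)
  if (!protected || kw$p.value < alpha) {
    pr <- t(utils::combn(k, 2))
    pv <- apply(pr, 1, function(ij)
      suppressWarnings(stats::wilcox.test(groups[[ij[1]]],
                                          groups[[ij[2]]],
                                          exact = FALSE)$p.value))
    pv <- stats::p.adjust(pv, method = p_adjust)
    for (r in seq_len(nrow(pr))) {
      pmat[pr[r, 1], pr[r, 2]] <- pv[r]
      pmat[pr[r, 2], pr[r, 1]] <- pv[r]
    }
  }
  nondiff <- pmat >= alpha
  # maximal contiguous cliques in mean-rank order: for every start i find the
  # longest clique run [i, jmax(i)]; keep the runs not contained in another
  jmax <- integer(k)
  for (i in seq_len(k)) {
    j <- i
    while (j < k && all(nondiff[ord[i:(j + 1)], ord[i:(j + 1)]])) j <- j + 1L
    jmax[i] <- j
  }
  runs <- list()
  for (i in seq_len(k))
    if (i == 1L || jmax[i] > jmax[i - 1L])
      runs[[length(runs) + 1L]] <- c(i, jmax[i])
  letters_mat <- matrix(FALSE, k, length(runs))
  for (s in seq_along(runs)) letters_mat[runs[[s]][1]:runs[[s]][2], s] <- TRUE
  lab <- make_letter_labels(length(runs))
  letters_by_rank <- apply(letters_mat, 1, function(z)
    paste(lab[z], collapse = ""))

  different <- matrix(TRUE, k, k, dimnames = list(names(groups)[ord],
                                                  names(groups)[ord]))
  diag(different) <- FALSE
  for (r in runs) different[r[1]:r[2], r[1]:r[2]] <- FALSE

  desc <- k:1
  tab <- data.frame(group = names(groups)[ord][desc], n = unname(ni[ord][desc]),
                    mean = unname(means[ord][desc]),
                    letters = letters_by_rank[desc],
                    stringsAsFactors = FALSE)
  tab$letters <- relabel_letters(tab$letters)
  structure(
    list(groups = tab, different = different[desc, desc],
         subsets = lapply(runs, function(r) names(groups)[ord][r[1]:r[2]]),
         kruskal_p = kw$p.value, alpha = alpha),
    class = "regwq_grouping"
  )
}
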