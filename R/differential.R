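#' Two-sample Wilcoxon rank-sum test
#'
#' Midranks are used for ties. In `"auto"` mode the exact null distribution
#' is enumerated when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with tie-corrected variance
#' and continuity correction is used (via [stats::wilcox.test()]).
#'
#' @param x,y Numeric vectors, each with at least one observation.
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @return Tibble with `statistic` (rank-sum W of `x`), `p_value`, `method`.
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
wilcoxon_rank_sum <- function(x, y, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) abort("Both samples need at least one observation.")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
    exact = TRUE,
    normal_approx = FALSE,
    auto = (length(x) + length(y) <= 12) && !ties
  )
  if (exact && ties) {
    warn("Ties present; falling back to the normal approximation.")
    exact <- FALSE
  }
  res <- suppressWarnings(
    wilcox.test(x, y, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  tibble::tibble(
    statistic = unname(res$statistic),
    p_value = res$p.value,
    method = if (exact) "exact" else "normal_approx"
  )
}

#' Unpaired t-test from summary statistics
#'
#' Computes the two-sided unpaired t-test directly from group means,
#' standard deviations and sizes, as used to compare demographic and
#' clinical characteristics reported as mean +/- SD. Welch
#' (Welch-Satterthwaite degrees of freedom, default) and pooled-variance
#' variants are available.
#'
#' @param mean1,sd1,n1 Summary statistics of the first group.
#' @param mean2,sd2,n2 Summary statistics of the second group.
#' @param variant `"welch"` or `"pooled"`.
#' @return Tibble with `t`, `df`, `p_value`, `variant` and a `degenerate`
#'   flag for zero-variance inputs.
#' @export
#' @examples
#' t_test_from_summary(285.6, 102.4, 19, 65.3, 28.7, 17)
t_test_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                                variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (n1 < 2 || n2 < 2) abort("Both groups need n >= 2.")
  if (sd1 < 0 || sd2 < 0) abort("Standard deviations must be non-negative.")
  degenerate <- FALSE
  if (sd1 == 0 && sd2 == 0) {
    degenerate <- TRUE
    if (mean1 == mean2) {
      return(tibble::tibble(t = 0, df = NA_real_, p_value = 1,
                            variant = variant, degenerate = TRUE))
    }
    return(tibble::tibble(t = Inf * sign(mean1 - mean2), df = NA_real_,
                          p_value = 0, variant = variant, degenerate = TRUE))
  }
  if (variant == "welch") {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    t_stat <- (mean1 - mean2) / sqrt(se2)
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
    t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  tibble::tibble(t = t_stat, df = df,
                 p_value = 2 * pt(-abs(t_stat), df),
                 variant = variant, degenerate = degenerate)
}

#' Pearson chi-square test on a 2x2 table
#'
#' `chi^2 = N (ad - bc)^2 / (r1 r2 c1 c2)` with one degree of freedom;
#' Yates' continuity correction subtracts `N/2` from `|ad - bc|` (floored at
#' zero) and never increases the statistic.
#'
#' @param a,b,c,d Cell counts, row-wise: `(a, b)` first row, `(c, d)`
#'   second.
#' @param yates Apply Yates' continuity correction.
#' @return Tibble with `chi2`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_2x2(20, 10, 10, 20)
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  cells <- c(a, b, c, d)
  if (any(cells < 0)) abort("Cell counts must be non-negative.")
  n <- sum(cells)
  if (n == 0) abort("Table is empty.")
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("A zero row or column margin makes the test undefined.")
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - n / 2)
  chi2 <- n * num^2 / prod(margins)
  tibble::tibble(chi2 = chi2, df = 1, p_value = pchisq(chi2, 1, lower.tail = FALSE))
}

# Ridge-regularized two-class linear discriminant direction.
lda_direction <- function(m, labels) {
  cls <- unique(labels)
  x1 <- m[labels == cls[1], , drop = FALSE]
  x2 <- m[labels == cls[2], , drop = FALSE]
  sw <- ((nrow(x1) - 1) * stats::cov(x1) + (nrow(x2) - 1) * stats::cov(x2)) /
    (nrow(x1) + nrow(x2) - 2)
  ridge <- 1e-6 * mean(diag(sw))
  if (!is.finite(ridge) || ridge == 0) ridge <- 1e-6
  w <- solve(sw + diag(ridge, ncol(m)), colMeans(x1) - colMeans(x2))
  w / sqrt(sum(w^2))
}

#' LEfSe-style biomarker discovery
#'
#' Two-stage effect-size scoring for two-class cohorts. Stage 1 screens
#' each feature with a Kruskal-Wallis test (equivalent to the rank-sum test
#' for two classes) and keeps features whose Benjamini-Hochberg adjusted
#' p-value is below `kw_alpha`. Stage 2 rescales samples to a common sum of
#' one million and, over `n_boot` bootstrap rounds that subsample a
#' fraction `subsample` of each class, fits a ridge-regularized two-class
#' linear discriminant; the per-feature effect in each round is the average
#' of the absolute class-mean difference of the feature and the absolute
#' contribution of the feature's unit-normalized discriminant weight to the
#' difference in projected class means. The LDA score is
#' `sign * log10(1 + mean effect)`, signed positive when the feature is
#' enriched in the first class level (alphabetical order of `group`).
#' Features with `|score| >= lda_min` are flagged as biomarkers.
#'
#' @param x An [abund_tbl].
#' @param metadata Metadata tibble with `sample_id` and `group` (exactly two
#'   classes, at least 4 samples each).
#' @param kw_alpha Stage-1 BH-adjusted significance level (default 0.05).
#' @param lda_min Minimum absolute LDA score to flag (default 2; a stricter
#'   4 reproduces headline-biomarker style displays).
#' @param n_boot Bootstrap rounds (default 30).
#' @param subsample Fraction of each class subsampled per round.
#' @param seed Integer seed.
#' @return Tibble with per-taxon group means and SDs (percent of
#'   per-sample totals), `statistic`, `p_value`, `q_value`, `lda_score`
#'   (NA when stage 1 failed), `enriched_group`, `is_biomarker`.
#' @export
lefse_biomarkers <- function(x, metadata, kw_alpha = 0.05, lda_min = 2,
                             n_boot = 30, subsample = 2 / 3, seed = 1L) {
  metadata <- validate_metadata(metadata, x)
  classes <- sort(unique(metadata$group))
  if (length(classes) != 2) abort("LEfSe scoring here supports exactly two classes.")
  if (any(table(metadata$group) < 4)) abort("Each class needs at least 4 samples.")
  m <- abund_matrix(x)[metadata$sample_id, , drop = FALSE]
  labels <- metadata$group

  keep <- apply(m, 2, function(v) length(unique(v)) > 1)
  if (any(!keep)) {
    warn(paste0("Constant feature(s) excluded: ",
                paste(colnames(m)[!keep], collapse = ", ")))
  }

  # display scale: percent of per-sample total
  pct <- sweep(m, 1, pmax(rowSums(m), .Machine$double.eps), `/`) * 100
  in1 <- labels == classes[1]

  p_raw <- rep(NA_real_, ncol(m))
  stat <- rep(NA_real_, ncol(m))
  for (jj in which(keep)) {
    kt <- kruskal.test(m[, jj], factor(labels))
    p_raw[jj] <- kt$p.value
    stat[jj] <- unname(kt$statistic)
  }
  q <- rep(NA_real_, ncol(m))
  q[keep] <- bh_adjust(p_raw[keep])
  pass <- keep & !is.na(q) & q < kw_alpha

  lda_score <- rep(NA_real_, ncol(m))
  if (sum(pass) >= 1) {
    set.seed(seed)
    mm <- sweep(m, 1, pmax(rowSums(m), .Machine$double.eps), `/`) * 1e6
    mm <- mm[, pass, drop = FALSE]
    eff <- matrix(0, n_boot, ncol(mm))
    for (b in seq_len(n_boot)) {
      idx <- unlist(lapply(classes, function(cl) {
        pool <- which(labels == cl)
        sample(pool, max(2, floor(subsample * length(pool))))
      }))
      xb <- mm[idx, , drop = FALSE]
      lb <- labels[idx]
      dmeans <- colMeans(xb[lb == classes[1], , drop = FALSE]) -
        colMeans(xb[lb == classes[2], , drop = FALSE])
      w <- if (ncol(xb) == 1) {
        1
      } else {
        lda_direction(xb, lb)
      }
      dproj <- sum(w * dmeans)
      eff[b, ] <- (abs(dmeans) + abs(w * dproj)) / 2
    }
    mean_eff <- colMeans(eff)
    dm_all <- colMeans(mm[labels == classes[1], , drop = FALSE]) -
      colMeans(mm[labels == classes[2], , drop = FALSE])
    lda_score[pass] <- sign(dm_all) * log10(1 + mean_eff)
  }

  tibble::tibble(
    taxon_id = colnames(m),
    kingdom = x$kingdom[match(colnames(m), x$taxon_id)],
    mean_pct_1 = colMeans(pct[in1, , drop = FALSE]),
    sd_pct_1 = apply(pct[in1, , drop = FALSE], 2, sd),
    mean_pct_2 = colMeans(pct[!in1, , drop = FALSE]),
    sd_pct_2 = apply(pct[!in1, , drop = FALSE], 2, sd),
    statistic = stat,
    p_value = p_raw,
    q_value = q,
    lda_score = lda_score,
    enriched_group = dplyr::if_else(
      colMeans(m[in1, , drop = FALSE]) >= colMeans(m[!in1, , drop = FALSE]),
      classes[1], classes[2]),
    is_biomarker = !is.na(lda_score) & abs(lda_score) >= lda_min
  ) |>
    dplyr::rename(!!paste0("mean_pct_", classes[1]) := "mean_pct_1",
                  !!paste0("sd_pct_", classes[1]) := "sd_pct_1",
                  !!paste0("mean_pct_", classes[2]) := "mean_pct_2",
                  !!paste0("sd_pct_", classes[2]) := "sd_pct_2")
}
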