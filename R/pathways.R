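#' Per-KO signed group-difference z-scores
#'
#' For each KEGG Orthology (KO) feature, the two groups are compared with a
#' two-sided Wilcoxon rank-sum test (a t-test is selectable); the p-value,
#' clamped to `[1e-10, 1 - 1e-10]`, is converted to a signed z-score
#' `z = qnorm(1 - p/2) * sign(median_case - median_control)`. A zero median
#' difference gives sign 0 and hence `z = 0`, and swapping the groups flips
#' every sign. KOs absent from all samples are dropped with a message.
#'
#' @param ko Tibble with a `ko_id` column and one numeric column per
#'   sample.
#' @param metadata Metadata tibble with `sample_id` and `group`.
#' @param case Group treated as the case (positive z = enriched in case);
#'   defaults to the first sorted group label.
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @return Tibble with `ko_id`, `p_value`, `z`.
#' @export
ko_group_zscores <- function(ko, metadata, case = NULL,
                             test = c("wilcoxon", "t")) {
  test <- match.arg(test)
  if (!"ko_id" %in% names(ko)) abort("`ko` needs a `ko_id` column.")
  groups <- sort(unique(metadata$group))
  if (length(groups) != 2) abort("Exactly two groups are required.")
  if (is.null(case)) case <- groups[1]
  control <- setdiff(groups, case)
  case_ids <- intersect(metadata$sample_id[metadata$group == case], names(ko))
  ctrl_ids <- intersect(metadata$sample_id[metadata$group == control], names(ko))
  if (length(case_ids) < 3 || length(ctrl_ids) < 3) {
    abort("Each group needs at least 3 samples present in the KO table.")
  }
  m <- as.matrix(ko[, c(case_ids, ctrl_ids)])
  rownames(m) <- ko$ko_id
  absent <- rowSums(m) == 0
  if (any(absent)) {
    inform(paste0("Dropping KO(s) absent in all samples: ",
                  paste(rownames(m)[absent], collapse = ", ")))
    m <- m[!absent, , drop = FALSE]
  }
  is_case <- c(rep(TRUE, length(case_ids)), rep(FALSE, length(ctrl_ids)))
  p <- apply(m, 1, function(v) {
    if (test == "wilcoxon") {
      suppressWarnings(wilcox.test(v[is_case], v[!is_case], exact = FALSE,
                                   correct = TRUE)$p.value)
    } else {
      stats::t.test(v[is_case], v[!is_case])$p.value
    }
  })
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  delta <- apply(m, 1, function(v) median(v[is_case]) - median(v[!is_case]))
  tibble::tibble(
    ko_id = rownames(m),
    p_value = unname(p),
    z = unname(qnorm(1 - p / 2) * sign(delta))
  )
}

#' Reporter scores for pathway-level aggregation
#'
#' Aggregates per-KO signed z-scores into pathway scores
#' `z_raw = sum(z) / sqrt(k)` over the `k` member KOs observed, then
#' corrects against a size-matched random background: for each distinct
#' `k`, `n_background` random KO sets of size `k` are drawn (without
#' replacement within a set) from all observed KOs to estimate `mu_k` and
#' `sigma_k`, and `z_adjusted = (z_raw - mu_k) / sigma_k`. Pathways with
#' `|z_adjusted|` above `threshold` are flagged significant; direction is
#' up or down in the case group according to the sign.
#'
#' @param ko_z Output of [ko_group_zscores()].
#' @param pathway_map Tibble with `pathway_id` and `ko_id` membership.
#' @param n_background Background draws per pathway size (default 1000).
#' @param threshold Significance threshold on `|z_adjusted|` (default 1.5).
#' @param seed Integer seed for the background draws.
#' @return Tibble with `pathway_id`, `k`, `z_raw`, `z_adjusted`,
#'   `direction` (`up_in_case` / `down_in_case`), `significant`.
#' @export
reporter_scores <- function(ko_z, pathway_map, n_background = 1000,
                            threshold = 1.5, seed = 1L) {
  if (!all(c("pathway_id", "ko_id") %in% names(pathway_map))) {
    abort("`pathway_map` needs `pathway_id` and `ko_id` columns.")
  }
  members <- pathway_map[pathway_map$ko_id %in% ko_z$ko_id, ]
  dropped <- setdiff(unique(pathway_map$pathway_id), unique(members$pathway_id))
  if (length(dropped)) {
    warn(paste0("Pathway(s) with no observed member KOs dropped: ",
                paste(dropped, collapse = ", ")))
  }
  if (!nrow(members)) abort("No pathway has any observed member KO.")
  z <- setNames(ko_z$z, ko_z$ko_id)
  per_path <- members |>
    dplyr::group_by(.data$pathway_id) |>
    dplyr::summarise(k = dplyr::n(),
                     z_raw = sum(z[.data$ko_id]) / sqrt(dplyr::n()),
                     .groups = "drop")
  set.seed(seed)
  ks <- sort(unique(per_path$k))
  bg <- lapply(ks, function(k) {
    draws <- vapply(seq_len(n_background),
                    function(i) sum(sample(z, k, replace = FALSE)) / sqrt(k),
                    numeric(1))
    c(mu = mean(draws), sigma = sd(draws))
  })
  names(bg) <- as.character(ks)
  sigma <- vapply(bg, `[[`, numeric(1), "sigma")
  if (any(sigma == 0)) {
    abort("Degenerate background (sigma = 0); use a larger KO universe.")
  }
  mu_k <- vapply(as.character(per_path$k), function(k) bg[[k]][["mu"]], numeric(1))
  sd_k <- vapply(as.character(per_path$k), function(k) bg[[k]][["sigma"]], numeric(1))
  per_path |>
    dplyr::mutate(
      z_adjusted = unname((.data$z_raw - mu_k) / sd_k),
      direction = dplyr::if_else(.data$z_adjusted >= 0, "up_in_case", "down_in_case"),
      significant = abs(.data$z_adjusted) > threshold
    )
}
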