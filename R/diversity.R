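#' Chao1 richness estimate
#'
#' Non-parametric richness estimator from singleton/doubleton counts.
#' The bias-corrected form (default) is
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`; the classic form is
#' `S_obs + F1^2 / (2 F2)`, falling back to `S_obs + F1 (F1 - 1) / 2` when
#' no doubletons are present. Defined on integer counts only.
#'
#' @param counts Non-negative integer vector of per-taxon counts for one
#'   sample.
#' @param bias_corrected Use the bias-corrected estimator (default `TRUE`).
#' @return Estimated richness (always `>=` observed richness).
#' @export
#' @examples
#' chao1(c(5, 1, 1, 2), bias_corrected = FALSE)  # 6
#' chao1(c(5, 1, 1, 2))                          # 4.5
chao1 <- function(counts, bias_corrected = TRUE) {
  if (any(counts < 0) || any(!is.finite(counts))) abort("`counts` must be non-negative.")
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort("Chao1 is defined on integer counts; got non-integer abundances.")
  }
  counts <- round(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  if (bias_corrected) {
    s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
  } else if (f2 > 0) {
    s_obs + f1^2 / (2 * f2)
  } else {
    s_obs + f1 * (f1 - 1) / 2
  }
}

#' Shannon diversity
#'
#' `H = -sum p_i log p_i` over positive entries after normalizing to
#' proportions.
#'
#' @param abundances Non-negative vector with at least one positive entry.
#' @param base Logarithm base (natural log by default).
#' @return Shannon diversity.
#' @export
#' @examples
#' shannon(rep(1, 4))              # log(4)
#' shannon(c(0.5, 0.25, 0.25), 2)  # 1.5
shannon <- function(abundances, base = exp(1)) {
  if (any(abundances < 0)) abort("`abundances` must be non-negative.")
  tot <- sum(abundances)
  if (tot == 0) abort("Shannon diversity is undefined for an all-zero sample.")
  p <- abundances[abundances > 0] / tot
  -sum(p * log(p, base = base))
}

#' Per-sample alpha diversity
#'
#' @param x An [abund_tbl] of counts (Chao1 requires integers) or
#'   abundances (Shannon only).
#' @param kingdom Optional kingdom restriction.
#' @param indices Which indices to compute.
#' @return Tibble with `sample_id` and one column per index.
#' @export
alpha_diversity <- function(x, kingdom = NULL,
                            indices = c("chao1", "shannon")) {
  m <- abund_matrix(x, kingdom = kingdom)
  out <- tibble::tibble(sample_id = rownames(m))
  if ("chao1" %in% indices) out$chao1 <- apply(m, 1, chao1)
  if ("shannon" %in% indices) out$shannon <- apply(m, 1, shannon)
  out
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`, bounded in `[0, 1]`.
#' Computed with [vegan::vegdist()]. A pair of all-zero samples has no
#' defined distance and raises an error naming the samples.
#'
#' @param x An [abund_tbl], or a samples-by-taxa numeric matrix.
#' @param kingdom Optional kingdom restriction before computing distances.
#' @return Symmetric distance matrix with zero diagonal, class `codys_dist`.
#' @export
bray_curtis_matrix <- function(x, kingdom = NULL) {
  m <- if (inherits(x, "abund_tbl")) abund_matrix(x, kingdom = kingdom) else as.matrix(x)
  zero_rows <- rownames(m)[rowSums(m) == 0]
  if (length(zero_rows) > 1) {
    abort(paste0("Bray-Curtis is undefined between all-zero samples: ",
                 paste(zero_rows, collapse = ", ")))
  }
  d <- as.matrix(vegan::vegdist(m, method = "bray"))
  d[!is.finite(d)] <- 0
  diag(d) <- 0
  structure(d, class = c("codys_dist", "matrix", "array"))
}

as_dist_matrix <- function(d) {
  d <- as.matrix(d)
  if (!isSymmetric(unclass(d), tol = 1e-12)) abort("Distance matrix must be symmetric.")
  if (any(diag(d) != 0)) abort("Distance matrix must have a zero diagonal.")
  if (any(d < 0)) abort("Distances must be non-negative.")
  d
}

#' Principal coordinate analysis
#'
#' Eigendecomposition of the Gower-centred matrix `-1/2 J D^2 J`.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues, so pairwise Euclidean distances between
#' full-rank coordinates reproduce `D` whenever `D` is Euclidean-embeddable.
#' Negative eigenvalues - expected for Bray-Curtis, which is not Euclidean -
#' are discarded, not corrected, and their count is reported so the
#' approximation is visible.
#'
#' @param d Distance matrix (from [bray_curtis_matrix()] or compatible).
#' @param n_axes Number of axes to retain (capped at the number of positive
#'   eigenvalues).
#' @return Object of class `pcoa_ord`: `coordinates` (tibble with
#'   `sample_id` and `Axis*` columns), `eigenvalues`,
#'   `proportion_explained`, `n_negative_eigenvalues_discarded`.
#' @export
pcoa <- function(d, n_axes = 2) {
  if (n_axes < 1) abort("`n_axes` must be at least 1.")
  d <- as_dist_matrix(d)
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  g <- -0.5 * j %*% (d^2) %*% j
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-9
  pos <- e$values > tol
  n_neg <- sum(e$values < -tol)
  vals <- e$values[pos]
  k <- min(n_axes, length(vals))
  coords <- e$vectors[, which(pos)[seq_len(k)], drop = FALSE] %*%
    diag(sqrt(vals[seq_len(k)]), k)
  colnames(coords) <- paste0("Axis", seq_len(k))
  structure(list(
    coordinates = dplyr::bind_cols(
      tibble::tibble(sample_id = rownames(d)),
      tibble::as_tibble(coords)
    ),
    eigenvalues = vals,
    proportion_explained = vals / sum(vals),
    n_negative_eigenvalues_discarded = n_neg
  ), class = "pcoa_ord")
}

#' @export
print.pcoa_ord <- function(x, ...) {
  k <- ncol(x$coordinates) - 1
  cat(sprintf("# PCoA: %d samples, %d axes retained (%.1f%% of positive inertia), %d negative eigenvalue(s) discarded\n",
              nrow(x$coordinates), k,
              100 * sum(x$proportion_explained[seq_len(k)]),
              x$n_negative_eigenvalues_discarded))
  print(x$coordinates, ...)
  invisible(x)
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
  }
  c(total = ss_total, within = ss_within)
}

permanova_f <- function(d2, groups) {
  a <- length(unique(groups))
  n <- nrow(d2)
  ss <- permanova_ss(d2, groups)
  ss_between <- ss["total"] - ss["within"]
  f <- (ss_between / (a - 1)) / (ss["within"] / (n - a))
  c(f = unname(f), r2 = unname(ss_between / ss["total"]))
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on a distance matrix: `SS_total = (1/N) sum_{i<j}
#' d_ij^2`, within-group sums by the same formula per group, pseudo-F
#' `(SS_B / (a - 1)) / (SS_W / (N - a))`, and `R^2 = SS_B / SS_total`. The
#' p-value is obtained by permuting group labels with the add-one
#' correction `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`, or by exact
#' enumeration of all distinct label assignments when feasible (two groups,
#' at most 10,000 assignments) and `exact_if_feasible` is set, in which
#' case `p = #(F >= F_obs) / #assignments` with the observed assignment
#' included.
#'
#' @param d Distance matrix.
#' @param groups Group label per sample (at least 2 groups of at least 2).
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed recorded in the result.
#' @param exact_if_feasible Enumerate all assignments when feasible.
#' @return Object of class `permanova_fit` with `pseudo_f`, `r_squared`,
#'   `p_value`, `n_perm`, `seed`, `method`.
#' @export
permanova <- function(d, groups, n_perm = 9999, seed = 1L,
                      exact_if_feasible = FALSE) {
  d <- as_dist_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) abort("`groups` must match the distance matrix.")
  tab <- table(groups)
  if (length(tab) < 2) abort("PERMANOVA needs at least two groups.")
  if (any(tab < 2)) {
    abort(paste0("Each group needs >= 2 samples; too small: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  d2 <- d^2
  obs <- permanova_f(d2, groups)
  n <- nrow(d2)
  n_assign <- if (length(tab) == 2) choose(n, tab[[1]]) else Inf
  if (exact_if_feasible && n_assign <= 10000) {
    g1 <- names(tab)[1]
    assignments <- combn(n, tab[[1]])
    fs <- apply(assignments, 2, function(idx) {
      lab <- rep(names(tab)[2], n)
      lab[idx] <- g1
      permanova_f(d2, lab)[["f"]]
    })
    p <- mean(fs >= obs[["f"]] - 1e-12)
    method <- "exact"
    n_perm <- ncol(assignments)
  } else {
    set.seed(seed)
    count <- 0L
    for (i in seq_len(n_perm)) {
      fp <- permanova_f(d2, sample(groups))[["f"]]
      if (fp >= obs[["f"]] - 1e-12) count <- count + 1L
    }
    p <- (1 + count) / (1 + n_perm)
    method <- "permutation"
  }
  structure(list(pseudo_f = obs[["f"]], r_squared = obs[["r2"]],
                 p_value = p, n_perm = n_perm, seed = seed, method = method),
            class = "permanova_fit")
}

#' @export
print.permanova_fit <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s): pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d %s)\n",
              x$method, x$pseudo_f, x$r_squared, x$p_value, x$n_perm,
              if (x$method == "exact") "assignments" else "permutations"))
  invisible(x)
}

ord_coords <- function(x) {
  if (inherits(x, "pcoa_ord")) {
    m <- as.matrix(x$coordinates[, -1, drop = FALSE])
    rownames(m) <- x$coordinates$sample_id
    m
  } else {
    as.matrix(x)
  }
}

procrustes_m2 <- function(xc, yc) {
  s <- svd(crossprod(xc, yc))
  max(0, 1 - sum(s$d)^2)
}

#' Procrustes comparison of two ordinations with a PROTEST permutation test
#'
#' Both configurations are column-centred and scaled to unit sum of
#' squares; the optimal rotation comes from the singular value
#' decomposition of the cross-product, giving the residual
#' `M^2 = 1 - (sum of singular values)^2` and the concordance correlation
#' `R = sqrt(1 - M^2)`. Significance is assessed by permuting the rows of
#' the second configuration (the first is the reference) with the add-one
#' correction `p = (b + 1) / (n_perm + 1)`.
#'
#' @param x,y Ordinations ([pcoa()] results or coordinate matrices) over the
#'   same samples in the same order.
#' @param n_perm Number of row permutations (default 999).
#' @param seed Integer seed.
#' @return Object of class `procrustes_fit` with `m_squared`,
#'   `correlation_r`, `p_value`, `n_perm`, `seed`.
#' @export
procrustes_test <- function(x, y, n_perm = 999, seed = 1L) {
  xc <- ord_coords(x)
  yc <- ord_coords(y)
  if (nrow(xc) != nrow(yc)) abort("Configurations must cover the same samples.")
  if (!is.null(rownames(xc)) && !is.null(rownames(yc)) &&
      !identical(rownames(xc), rownames(yc))) {
    abort("Configurations must cover the same samples in the same order.")
  }
  k <- max(ncol(xc), ncol(yc))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  norm_cfg <- function(m) {
    m <- scale(m, center = TRUE, scale = FALSE)
    ss <- sum(m^2)
    if (ss == 0) abort("Degenerate (all-identical) configuration.")
    m / sqrt(ss)
  }
  xc <- norm_cfg(pad(xc))
  yc <- norm_cfg(pad(yc))
  m2 <- procrustes_m2(xc, yc)
  set.seed(seed)
  b <- 0L
  for (i in seq_len(n_perm)) {
    if (procrustes_m2(xc, yc[sample(nrow(yc)), , drop = FALSE]) <= m2 + 1e-12) {
      b <- b + 1L
    }
  }
  structure(list(m_squared = m2, correlation_r = sqrt(1 - m2),
                 p_value = (b + 1) / (n_perm + 1), n_perm = n_perm, seed = seed),
            class = "procrustes_fit")
}

#' @export
print.procrustes_fit <- function(x, ...) {
  cat(sprintf("Procrustes: M2 = %.4f, R = %.4f, PROTEST p = %.4g (%d permutations)\n",
              x$m_squared, x$correlation_r, x$p_value, x$n_perm))
  invisible(x)
}

#' Unique and shared taxa between two groups
#'
#' A taxon is present in a group when it has non-zero abundance in at least
#' one of the group's samples. Counts the taxa unique to each group and
#' shared by both (Venn-diagram accounting of detected taxa).
#'
#' @param x An [abund_tbl].
#' @param metadata Metadata tibble with `sample_id` and `group`.
#' @param groups Optional pair of group labels (defaults to the two levels
#'   present).
#' @return Tibble with `category` (`unique_<A>`, `unique_<B>`, `shared`),
#'   `n_taxa` and a `taxa` list-column.
#' @export
unique_shared_taxa <- function(x, metadata, groups = NULL) {
  metadata <- validate_metadata(metadata, x)
  if (is.null(groups)) groups <- sort(unique(metadata$group))
  if (length(groups) != 2) abort("Exactly two group labels are required.")
  unknown <- setdiff(groups, metadata$group)
  if (length(unknown)) abort(paste0("Unknown group label(s): ", paste(unknown, collapse = ", ")))
  present <- function(g) {
    ids <- metadata$sample_id[metadata$group == g]
    m <- abund_matrix(x)[ids, , drop = FALSE]
    colnames(m)[colSums(m) > 0]
  }
  a <- present(groups[1])
  b <- present(groups[2])
  tibble::tibble(
    category = c(paste0("unique_", groups), "shared"),
    n_taxa = c(length(setdiff(a, b)), length(setdiff(b, a)), length(intersect(a, b))),
    taxa = list(setdiff(a, b), setdiff(b, a), intersect(a, b))
  )
}
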