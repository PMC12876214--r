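#' Tidy a PERMANOVA fit
#' @param x A `permanova_fit`.
#' @param ... Unused.
#' @return One-row tibble with `pseudo_f`, `r_squared`, `p_value`.
#' @method tidy permanova_fit
#' @export
tidy.permanova_fit <- function(x, ...) {
  tibble::tibble(term = "group", pseudo_f = x$pseudo_f,
                 r_squared = x$r_squared, p_value = x$p_value)
}

#' @rdname tidy.permanova_fit
#' @method glance permanova_fit
#' @export
glance.permanova_fit <- function(x, ...) {
  tibble::tibble(pseudo_f = x$pseudo_f, r_squared = x$r_squared,
                 p_value = x$p_value, n_perm = x$n_perm,
                 method = x$method, seed = x$seed)
}

#' Tidy a Procrustes fit
#' @param x A `procrustes_fit`.
#' @param ... Unused.
#' @return One-row tibble with `m_squared`, `correlation_r`, `p_value`.
#' @method tidy procrustes_fit
#' @export
tidy.procrustes_fit <- function(x, ...) {
  tibble::tibble(m_squared = x$m_squared, correlation_r = x$correlation_r,
                 p_value = x$p_value)
}

#' @rdname tidy.procrustes_fit
#' @method glance procrustes_fit
#' @export
glance.procrustes_fit <- function(x, ...) {
  tibble::tibble(m_squared = x$m_squared, correlation_r = x$correlation_r,
                 p_value = x$p_value, n_perm = x$n_perm, seed = x$seed)
}

#' Tidy an ordination: one row per retained axis
#' @param x A `pcoa_ord`.
#' @param ... Unused.
#' @return Tibble with `axis`, `eigenvalue`, `proportion_explained`.
#' @method tidy pcoa_ord
#' @export
tidy.pcoa_ord <- function(x, ...) {
  tibble::tibble(axis = seq_along(x$eigenvalues),
                 eigenvalue = x$eigenvalues,
                 proportion_explained = x$proportion_explained)
}

#' @rdname tidy.pcoa_ord
#' @method glance pcoa_ord
#' @export
glance.pcoa_ord <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_axes_retained = ncol(x$coordinates) - 1L,
                 n_positive_eigenvalues = length(x$eigenvalues),
                 n_negative_eigenvalues_discarded = x$n_negative_eigenvalues_discarded)
}

#' Tidy a cross-kingdom network: its edge list
#' @param x A `ck_network`.
#' @param ... Unused.
#' @return Edge tibble.
#' @method tidy ck_network
#' @export
tidy.ck_network <- function(x, ...) x$edges

#' @rdname tidy.ck_network
#' @method glance ck_network
#' @export
glance.ck_network <- function(x, ...) {
  s <- summarize_network(x)
  tibble::tibble(group = x$group, n_nodes = nrow(x$nodes),
                 n_edges = s$n_edges, n_positive = s$n_positive,
                 n_negative = s$n_negative,
                 positivity_fraction = s$positivity_fraction,
                 n_pairs_tested = x$n_pairs_tested,
                 n_samples = x$n_samples)
}

#' Tidy a random-forest report: its importance table
#' @param x An `rf_report`.
#' @param ... Unused.
#' @return Importance tibble.
#' @method tidy rf_report
#' @export
tidy.rf_report <- function(x, ...) x$importance

#' @rdname tidy.rf_report
#' @method glance rf_report
#' @export
glance.rf_report <- function(x, ...) {
  tibble::tibble(cv_auc = x$cv_auc, oob_error = x$oob_error,
                 n_folds = x$n_folds, n_trees = x$n_trees, seed = x$seed)
}
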