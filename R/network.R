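#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed vectors; invariant under any
#' strictly increasing transform of either argument.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`, each with at least
#'   two distinct values.
#' @return Spearman's rho in `[-1, 1]`.
#' @export
#' @examples
#' spearman_rho(1:5, c(2, 1, 4, 3, 5))  # 0.8
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("`x` and `y` must have equal length >= 3.")
  }
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    abort("Undefined correlation: constant vector.")
  }
  cor(x, y, method = "spearman")
}

#' Two-sided p-value for a Spearman correlation
#'
#' Uses the t approximation `t = |rho| sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom, doubled for a two-sided test. A perfect
#' correlation (`|rho| = 1`) returns the exact-permutation floor `2 / n!`
#' with a warning, the smallest two-sided p attainable by rank permutation.
#'
#' @param rho Spearman correlation.
#' @param n Number of paired observations (`n >= 4`).
#' @return Two-sided p-value.
#' @export
#' @examples
#' round(spearman_pvalue(-0.75, 17), 4)  # 0.0005
#' round(spearman_pvalue(0.71, 19), 4)   # 0.0007
spearman_pvalue <- function(rho, n) {
  if (n < 4) abort("Need n >= 4 for a Spearman p-value.")
  if (abs(rho) > 1) abort("`rho` must lie in [-1, 1].")
  if (abs(rho) == 1) {
    warn("|rho| = 1: returning the exact-permutation floor 2/n!.")
    return(min(1, 2 / factorial(n)))
  }
  t_stat <- abs(rho) * sqrt((n - 2) / (1 - rho^2))
  2 * pt(t_stat, df = n - 2, lower.tail = FALSE)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q_(i) = min_(j >= i) p_(j) m / j`, mapped back to the
#' input order; always `q >= p` and `q <= 1`.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @return Adjusted q-values in input order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.04, 0.03, 0.005))
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Build a cross-kingdom correlation network for one group
#'
#' For a single group's samples, computes Spearman's rho and its t-based
#' p-value for every (bacterial genus, fungal genus) pair that survives the
#' prevalence filter - within-kingdom pairs are never tested - then adjusts
#' p-values with Benjamini-Hochberg across all tested pairs within the
#' group, and retains edges with `|rho| >= rho_min` and `q < q_alpha`.
#' Pairs involving a constant taxon are skipped and logged rather than
#' failing the build. Nodes of the resulting network are the taxa incident
#' to at least one edge, annotated with the group-mean relative abundance
#' and degree.
#'
#' @param x A normalized [abund_tbl] (see [to_relative_abundance()]).
#' @param metadata Metadata tibble with `sample_id` and `group`.
#' @param group Group label to build the network for (>= 4 samples).
#' @param config A [pipeline_config()] supplying `rho_min`, `q_alpha` and
#'   `prevalence_min`.
#' @return Object of class `ck_network`: `group`, `nodes` (tibble: `taxon`,
#'   `kingdom`, `mean_abundance`, `degree`), `edges` (tibble:
#'   `bacterial_taxon`, `fungal_taxon`, `rho`, `p_value`, `q_value`,
#'   `sign`), `thresholds`, `n_pairs_tested`, `n_samples`.
#' @export
build_cross_kingdom_network <- function(x, metadata, group,
                                        config = pipeline_config()) {
  validate_abund_tbl(x)
  if (!is_normalized(x)) {
    abort("Network construction expects a normalized table; call to_relative_abundance() first.")
  }
  metadata <- validate_metadata(metadata, x)
  ids <- metadata$sample_id[metadata$group == group]
  if (length(ids) < 4) abort(sprintf("Group '%s' needs >= 4 samples.", group))

  sub <- x[, c("taxon_id", "kingdom", "rank", ids)]
  sub <- new_abund_tbl(sub, normalized = TRUE)
  sub <- prevalence_filter(sub, config$prevalence_min)
  m <- abund_matrix(sub)

  non_constant <- apply(m, 2, function(v) length(unique(v)) > 1)
  skipped <- colnames(m)[!non_constant]
  if (length(skipped)) {
    inform(paste0("Skipping constant taxa: ", paste(skipped, collapse = ", ")))
  }
  bact <- sub$taxon_id[sub$kingdom == "bacteria" & non_constant[sub$taxon_id]]
  fung <- sub$taxon_id[sub$kingdom == "fungi" & non_constant[sub$taxon_id]]

  pairs <- tidyr::expand_grid(bacterial_taxon = bact, fungal_taxon = fung)
  n_pairs <- nrow(pairs)
  if (n_pairs == 0) {
    inform(sprintf("No eligible cross-kingdom pairs in group '%s'; returning an empty network.", group))
    edges <- tibble::tibble(bacterial_taxon = character(), fungal_taxon = character(),
                            rho = double(), p_value = double(), q_value = double(),
                            sign = character())
  } else {
    # Spearman for all pairs at once: correlate rank-transformed matrices.
    rb <- apply(m[, bact, drop = FALSE], 2, rank)
    rf <- apply(m[, fung, drop = FALSE], 2, rank)
    rho_mat <- suppressWarnings(cor(rb, rf))
    rho <- rho_mat[cbind(match(pairs$bacterial_taxon, bact),
                         match(pairs$fungal_taxon, fung))]
    rho <- pmin(1, pmax(-1, rho))
    p <- vapply(rho, function(r) {
      if (abs(r) >= 1) suppressWarnings(spearman_pvalue(r, length(ids)))
      else spearman_pvalue(r, length(ids))
    }, numeric(1))
    q <- bh_adjust(p)
    keep <- abs(rho) >= config$rho_min & q < config$q_alpha
    edges <- pairs[keep, ]
    edges$rho <- rho[keep]
    edges$p_value <- p[keep]
    edges$q_value <- q[keep]
    edges$sign <- dplyr::if_else(edges$rho > 0, "positive", "negative")
  }

  node_names <- unique(c(edges$bacterial_taxon, edges$fungal_taxon))
  mean_ab <- colMeans(abund_matrix(x)[ids, , drop = FALSE])
  deg <- table(c(edges$bacterial_taxon, edges$fungal_taxon))
  nodes <- tibble::tibble(
    taxon = node_names,
    kingdom = x$kingdom[match(node_names, x$taxon_id)],
    mean_abundance = unname(mean_ab[node_names]),
    degree = as.integer(deg[node_names])
  ) |> dplyr::arrange(dplyr::desc(.data$degree), dplyr::desc(.data$mean_abundance),
                      .data$taxon)

  structure(list(
    group = group, nodes = nodes, edges = tibble::as_tibble(edges),
    thresholds = list(rho_min = config$rho_min, q_alpha = config$q_alpha,
                      prevalence_min = config$prevalence_min),
    n_pairs_tested = n_pairs, n_samples = length(ids)
  ), class = "ck_network")
}

#' @export
print.ck_network <- function(x, ...) {
  cat(sprintf("# Cross-kingdom network [%s]: %d nodes, %d edges (of %d pairs tested, |rho| >= %.2f, q < %.2g)\n",
              x$group, nrow(x$nodes), nrow(x$edges), x$n_pairs_tested,
              x$thresholds$rho_min, x$thresholds$q_alpha))
  if (nrow(x$edges)) print(x$edges, ...)
  invisible(x)
}

#' Summarize cross-kingdom network topology
#'
#' Counts edges by sign and computes the co-dysbiosis index - the
#' positivity fraction `n_positive / n_edges` of significant edges. A
#' network dominated by positive (cooperative) correlations with loss of
#' negative (competitive) edges scores near 1. Hubs are the top-degree
#' nodes, with ties broken by mean abundance and then name so reports are
#' deterministic.
#'
#' @param net A `ck_network`.
#' @param n_hubs Number of hub nodes to report.
#' @return Object of class `network_summary` with `n_edges`, `n_positive`,
#'   `n_negative`, `positivity_fraction` (NA with `defined = FALSE` for an
#'   empty network), `hubs`, `node_sign_degree`.
#' @export
summarize_network <- function(net, n_hubs = 5) {
  stopifnot(inherits(net, "ck_network"))
  e <- net$edges
  n_edges <- nrow(e)
  n_pos <- sum(e$sign == "positive")
  n_neg <- n_edges - n_pos
  node_sign <- if (n_edges) {
    dplyr::bind_rows(
      tibble::tibble(taxon = e$bacterial_taxon, sign = e$sign),
      tibble::tibble(taxon = e$fungal_taxon, sign = e$sign)
    ) |>
      dplyr::count(.data$taxon, .data$sign) |>
      tidyr::pivot_wider(names_from = "sign", values_from = "n",
                         values_fill = 0L, names_prefix = "degree_")
  } else {
    tibble::tibble(taxon = character())
  }
  structure(list(
    group = net$group,
    n_edges = n_edges, n_positive = n_pos, n_negative = n_neg,
    positivity_fraction = if (n_edges) n_pos / n_edges else NA_real_,
    defined = n_edges > 0,
    hubs = head(net$nodes, n_hubs),
    node_sign_degree = node_sign
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("# Network summary [%s]: %d edges (%d positive / %d negative)\n",
              x$group, x$n_edges, x$n_positive, x$n_negative))
  if (x$defined) {
    cat(sprintf("  co-dysbiosis index (positivity fraction): %.3f\n",
                x$positivity_fraction))
  } else {
    cat("  co-dysbiosis index: undefined (no edges)\n")
  }
  if (nrow(x$hubs)) {
    cat("  hubs:\n")
    print(x$hubs, ...)
  }
  invisible(x)
}

#' Compare two cross-kingdom networks
#'
#' Reports the overlap of edge sets (as unordered bacterium-fungus pairs),
#' sign flips among shared pairs, per-group sign counts, the difference in
#' positivity fraction, and hub turnover between two networks built with
#' identical thresholds (differing thresholds are an error since the edge
#' sets would not be comparable).
#'
#' @param net_a,net_b `ck_network` objects.
#' @param n_hubs Hub list size used for turnover.
#' @return Object of class `network_comparison`.
#' @export
compare_networks <- function(net_a, net_b, n_hubs = 5) {
  stopifnot(inherits(net_a, "ck_network"), inherits(net_b, "ck_network"))
  if (!identical(net_a$thresholds, net_b$thresholds)) {
    abort("Networks were built with different thresholds; rebuild with a common config.")
  }
  key <- function(e) paste(e$bacterial_taxon, e$fungal_taxon, sep = "~")
  ea <- net_a$edges; eb <- net_b$edges
  shared_keys <- intersect(key(ea), key(eb))
  shared <- tibble::tibble(
    pair = shared_keys,
    sign_a = ea$sign[match(shared_keys, key(ea))],
    sign_b = eb$sign[match(shared_keys, key(eb))],
    rho_a = ea$rho[match(shared_keys, key(ea))],
    rho_b = eb$rho[match(shared_keys, key(eb))]
  )
  shared$sign_flip <- shared$sign_a != shared$sign_b
  sa <- summarize_network(net_a, n_hubs)
  sb <- summarize_network(net_b, n_hubs)
  structure(list(
    groups = c(net_a$group, net_b$group),
    n_edges = c(sa$n_edges, sb$n_edges),
    n_positive = c(sa$n_positive, sb$n_positive),
    n_negative = c(sa$n_negative, sb$n_negative),
    positivity_fraction = c(sa$positivity_fraction, sb$positivity_fraction),
    positivity_difference = sb$positivity_fraction - sa$positivity_fraction,
    shared_pairs = shared,
    n_sign_flips = sum(shared$sign_flip),
    n_only_a = nrow(ea) - nrow(shared),
    n_only_b = nrow(eb) - nrow(shared),
    hub_turnover = length(setdiff(sb$hubs$taxon, sa$hubs$taxon)) /
      max(1, nrow(sb$hubs))
  ), class = "network_comparison")
}

#' @export
print.network_comparison <- function(x, ...) {
  cat(sprintf("# Network comparison: %s vs %s\n", x$groups[1], x$groups[2]))
  cat(sprintf("  edges: %d vs %d; positive: %d vs %d; negative: %d vs %d\n",
              x$n_edges[1], x$n_edges[2], x$n_positive[1], x$n_positive[2],
              x$n_negative[1], x$n_negative[2]))
  cat(sprintf("  positivity fraction: %.3f vs %.3f (difference %.3f)\n",
              x$positivity_fraction[1], x$positivity_fraction[2],
              x$positivity_difference))
  cat(sprintf("  shared pairs: %d (%d sign flips); unique: %d / %d; hub turnover: %.2f\n",
              nrow(x$shared_pairs), x$n_sign_flips, x$n_only_a, x$n_only_b,
              x$hub_turnover))
  invisible(x)
}

#' Convert a cross-kingdom network to an igraph object
#'
#' Node attributes: `kingdom`, `mean_abundance`, `degree`, plus display
#' conventions (`shape` circle for bacteria / square for fungi, `color`
#' yellow / green). Edge attributes: `rho`, `p_value`, `q_value`, `sign`,
#' and `color` (red positive / blue negative).
#'
#' @param net A `ck_network`.
#' @return An [igraph::graph] object.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ck_network"))
  nodes <- net$nodes
  nodes$shape <- ifelse(nodes$kingdom == "bacteria", "circle", "square")
  nodes$color <- ifelse(nodes$kingdom == "bacteria", "yellow", "green")
  edges <- net$edges
  edges$color <- ifelse(edges$sign == "positive", "red", "blue")
  igraph::graph_from_data_frame(
    d = edges[, c("bacterial_taxon", "fungal_taxon", "rho", "p_value",
                  "q_value", "sign", "color")],
    directed = FALSE,
    vertices = nodes[, c("taxon", "kingdom", "mean_abundance", "degree",
                         "shape", "color")]
  )
}

#' Export a cross-kingdom network to GraphML
#'
#' Writes an attribute-complete GraphML file suitable for Gephi: node
#' kingdom/abundance/degree plus shape and colour conventions, and signed
#' edge correlation attributes.
#'
#' @param net A `ck_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(as_igraph(net), path, format = "graphml")
  invisible(path)
}

#' Export network edges as TSV
#' @param net A `ck_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_edges_tsv <- function(net, path) {
  readr::write_tsv(net$edges, path, progress = FALSE)
  invisible(path)
}
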