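#' Analysis configuration
#'
#' Bundles the thresholds of the full workflow: the network correlation
#' floor `rho_min` (|rho| >= 0.6 by default), FDR level `q_alpha` (0.05),
#' permutation count `n_perm` (9999), minimum absolute LDA score `lda_min`
#' (2), reporter-score significance threshold (1.5), prevalence floor for
#' network taxa (0.25; 0 disables), random-forest fold count (10) and the
#' master seed.
#'
#' @param rho_min Minimum absolute Spearman correlation for a network edge,
#'   in `(0, 1]`.
#' @param q_alpha BH-adjusted significance level, in `(0, 1)`.
#' @param n_perm Permutations for PERMANOVA / PROTEST (>= 1).
#' @param lda_min Minimum absolute LDA score (> 0).
#' @param reporter_threshold Reporter-score significance threshold (> 0).
#' @param prevalence_min Prevalence floor in `[0, 1]`.
#' @param rf_folds Random-forest cross-validation folds.
#' @param seed Master integer seed; per-stage seeds are derived from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(rho_min = 0.6, q_alpha = 0.05, n_perm = 9999,
                            lda_min = 2, reporter_threshold = 1.5,
                            prevalence_min = 0.25, rf_folds = 10, seed = 1L) {
  if (rho_min <= 0 || rho_min > 1) abort("`rho_min` must be in (0, 1].")
  if (q_alpha <= 0 || q_alpha >= 1) abort("`q_alpha` must be in (0, 1).")
  if (n_perm < 1) abort("`n_perm` must be >= 1.")
  if (lda_min <= 0 || reporter_threshold <= 0) abort("Thresholds must be positive.")
  if (prevalence_min < 0 || prevalence_min > 1) abort("`prevalence_min` must be in [0, 1].")
  structure(list(rho_min = rho_min, q_alpha = q_alpha, n_perm = n_perm,
                 lda_min = lda_min, reporter_threshold = reporter_threshold,
                 prevalence_min = prevalence_min, rf_folds = rf_folds,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_seed <- function(config, offset) (config$seed %% 100000L) * 1000L + offset

#' Run the full analysis workflow
#'
#' Executes the end-to-end case-control workflow on either supplied data or
#' a simulated cohort: alpha diversity (Chao1 on pseudo-counts, Shannon)
#' with rank-sum comparison; Bray-Curtis beta diversity with PCoA,
#' PERMANOVA and a Procrustes/PROTEST comparison of the bacterial and
#' fungal ordinations; unique/shared taxon accounting; LEfSe-style
#' biomarkers; per-group cross-kingdom networks, summaries and comparison;
#' random-forest discrimination from fungal genera plus total IgE; and
#' reporter-score pathway aggregation when a KO table is given (simulated
#' otherwise). Per-stage outputs are written to `outdir` as TSV/JSON and
#' listed in the returned manifest; all randomness flows from the config
#' seed via fixed per-stage offsets, so two runs with the same inputs and
#' config are identical.
#'
#' @param outdir Output directory (created if missing).
#' @param abundance Optional [abund_tbl] of raw abundances; when `NULL` a
#'   cohort is simulated from `spec`.
#' @param metadata Optional metadata tibble (required with `abundance`).
#' @param spec [synthetic_spec()] used when no abundance table is given.
#' @param config A [pipeline_config()].
#' @param ko Optional KO tibble (`ko_id` + sample columns).
#' @param pathway_map Optional pathway membership tibble.
#' @return The manifest: a tibble of stage, output file and description,
#'   with the stage results attached as attribute `results`.
#' @export
run_pipeline <- function(outdir, abundance = NULL, metadata = NULL,
                         spec = synthetic_spec(), config = pipeline_config(),
                         ko = NULL, pathway_map = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  results <- list()
  emit <- function(stage, file, desc) {
    manifest[[length(manifest) + 1]] <<- tibble::tibble(
      stage = stage, output = file, description = desc)
  }

  if (is.null(abundance)) {
    spec$seed <- stage_seed(config, 1L)
    sim <- simulate_cohort(spec)
    abundance <- sim$abundance
    metadata <- sim$metadata
    write_abundance_tsv(abundance, file.path(outdir, "abundance.tsv"))
    readr::write_tsv(metadata, file.path(outdir, "metadata.tsv"), progress = FALSE)
    emit("simulate", "abundance.tsv", "simulated raw abundance table")
    emit("simulate", "metadata.tsv", "simulated sample metadata")
  } else {
    if (is.null(metadata)) abort("`metadata` is required when `abundance` is given.")
    metadata <- validate_metadata(metadata, abundance)
  }
  if (is_normalized(abundance)) {
    abort("`run_pipeline()` expects raw abundances; it normalizes internally.")
  }

  groups <- sort(unique(metadata$group))
  rel <- to_relative_abundance(abundance)

  # alpha diversity on fungal pseudo-counts
  rel_f <- abund_matrix(rel, kingdom = "fungi")
  counts <- abund_tbl(round(t(rel_f) * 1e5),
                      kingdom = "fungi", rank = "genus")
  alpha <- alpha_diversity(counts) |>
    dplyr::left_join(metadata[, c("sample_id", "group")], by = "sample_id")
  alpha_tests <- purrr::map_dfr(c("chao1", "shannon"), function(ix) {
    wilcoxon_rank_sum(alpha[[ix]][alpha$group == groups[1]],
                      alpha[[ix]][alpha$group == groups[2]]) |>
      dplyr::mutate(index = ix, .before = 1)
  })
  readr::write_tsv(alpha, file.path(outdir, "alpha_diversity.tsv"), progress = FALSE)
  readr::write_tsv(alpha_tests, file.path(outdir, "alpha_tests.tsv"), progress = FALSE)
  emit("diversity", "alpha_diversity.tsv", "per-sample Chao1 and Shannon")
  emit("diversity", "alpha_tests.tsv", "rank-sum comparison of alpha diversity")
  results$alpha <- alpha; results$alpha_tests <- alpha_tests

  d_f <- bray_curtis_matrix(rel, kingdom = "fungi")
  ord_f <- pcoa(d_f, n_axes = 2)
  perma <- permanova(d_f, metadata$group[match(rownames(d_f), metadata$sample_id)],
                     n_perm = config$n_perm, seed = stage_seed(config, 2L))
  d_b <- bray_curtis_matrix(rel, kingdom = "bacteria")
  ord_b <- pcoa(d_b, n_axes = 2)
  proc <- procrustes_test(ord_b, ord_f, n_perm = min(config$n_perm, 999),
                          seed = stage_seed(config, 3L))
  venn <- unique_shared_taxa(rel, metadata)
  readr::write_tsv(ord_f$coordinates, file.path(outdir, "pcoa_fungi.tsv"), progress = FALSE)
  jsonlite::write_json(
    list(permanova = unclass(perma), procrustes = unclass(proc),
         unique_shared = venn[, c("category", "n_taxa")]),
    file.path(outdir, "beta_diversity.json"), auto_unbox = TRUE, digits = NA)
  emit("ordination", "pcoa_fungi.tsv", "fungal PCoA coordinates")
  emit("ordination", "beta_diversity.json", "PERMANOVA, Procrustes, Venn counts")
  results$pcoa_fungi <- ord_f; results$pcoa_bacteria <- ord_b
  results$permanova <- perma; results$procrustes <- proc; results$venn <- venn

  lefse <- lefse_biomarkers(abundance, metadata, lda_min = config$lda_min,
                            seed = stage_seed(config, 4L))
  readr::write_tsv(lefse, file.path(outdir, "lefse.tsv"), progress = FALSE)
  emit("lefse", "lefse.tsv", "LEfSe-style differential biomarkers")
  results$lefse <- lefse

  nets <- lapply(groups, function(g)
    build_cross_kingdom_network(rel, metadata, g, config))
  names(nets) <- groups
  for (g in groups) {
    write_network_edges_tsv(nets[[g]], file.path(outdir, paste0("network_", g, ".tsv")))
    write_network_graphml(nets[[g]], file.path(outdir, paste0("network_", g, ".graphml")))
    emit("network", paste0("network_", g, ".tsv"), paste0("edge list, group ", g))
    emit("network", paste0("network_", g, ".graphml"), paste0("GraphML export, group ", g))
  }
  summaries <- lapply(nets, summarize_network)
  comparison <- compare_networks(nets[[1]], nets[[2]])
  jsonlite::write_json(
    lapply(summaries, function(s) unclass(s)[c("group", "n_edges", "n_positive",
                                               "n_negative", "positivity_fraction")]),
    file.path(outdir, "network_summary.json"), auto_unbox = TRUE, digits = NA)
  emit("netsummary", "network_summary.json", "per-group topology summaries")
  results$networks <- nets; results$network_summaries <- summaries
  results$network_comparison <- comparison

  feats <- as.data.frame(rel_f)
  feats$total_ige <- metadata$total_ige[match(rownames(feats), metadata$sample_id)]
  rf <- cv_random_forest(feats, metadata$group[match(rownames(feats), metadata$sample_id)],
                         n_folds = config$rf_folds,
                         seed = stage_seed(config, 5L))
  readr::write_tsv(rf$importance, file.path(outdir, "rf_importance.tsv"), progress = FALSE)
  emit("classify", "rf_importance.tsv", "random-forest variable importance")
  results$rf <- rf

  if (is.null(ko)) {
    ko_sim <- simulate_ko_dataset(seed = stage_seed(config, 6L),
                                  n_per_group = table_to_counts(metadata))
    ko <- ko_sim$ko; pathway_map <- ko_sim$pathway_map
    ko_meta <- ko_sim$metadata
  } else {
    if (is.null(pathway_map)) abort("`pathway_map` is required with `ko`.")
    ko_meta <- metadata
  }
  kz <- ko_group_zscores(ko, ko_meta)
  rep_scores <- reporter_scores(kz, pathway_map,
                                threshold = config$reporter_threshold,
                                seed = stage_seed(config, 7L))
  readr::write_tsv(rep_scores, file.path(outdir, "reporter_scores.tsv"), progress = FALSE)
  emit("reporter", "reporter_scores.tsv", "pathway reporter scores")
  results$reporter <- rep_scores

  manifest <- dplyr::bind_rows(manifest)
  manifest$exists <- file.exists(file.path(outdir, manifest$output))
  jsonlite::write_json(
    list(seed = config$seed, config = unclass(config),
         outputs = manifest[, c("stage", "output")]),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  attr(manifest, "results") <- results
  attr(manifest, "config") <- config
  manifest
}

table_to_counts <- function(metadata) {
  tab <- table(metadata$group)
  setNames(as.integer(tab), names(tab))
}
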