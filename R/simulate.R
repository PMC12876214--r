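#' Convert a target Spearman correlation to a latent Pearson correlation
#'
#' For a bivariate Gaussian copula, a latent Pearson correlation of
#' `r = 2 sin(pi * rho_s / 6)` yields exactly the Spearman correlation
#' `rho_s` after any monotone transformation of the margins. This is the
#' calibration used to plant rank correlations in simulated cohorts: because
#' Spearman correlation is rank-based, the planted value survives the
#' lognormal margin transform and per-kingdom total-sum scaling.
#'
#' @param rho_s Target Spearman correlation(s) in `[-1, 1]`.
#' @return Latent Pearson correlation(s), same sign, `|r| >= |rho_s|`.
#' @export
#' @examples
#' spearman_to_pearson(c(-0.8, 0, 0.6, 1))
spearman_to_pearson <- function(rho_s) {
  if (any(!is.finite(rho_s)) || any(abs(rho_s) > 1)) {
    abort("`rho_s` must lie in [-1, 1].")
  }
  2 * sin(pi * rho_s / 6)
}

default_fungal_names <- function(n) {
  named <- c("Dentiscutata", "Cenococcum", "Saccharomyces", "Ambispora")
  c(named, sprintf("f__genus_%02d", seq_len(max(0, n - length(named)))))[seq_len(n)]
}

default_bacterial_names <- function(n) {
  named <- c("Bacillus", "Anaerostipes", "Subdoligranulum", "Flavonifractor", "Dielma")
  c(named, sprintf("b__genus_%02d", seq_len(max(0, n - length(named)))))[seq_len(n)]
}

#' Planted cross-kingdom edges mirroring the two cohort regimes
#'
#' Convenience constructors for the planted-edge tables used by
#' [synthetic_spec()]: a control-like regime dominated by negative
#' bacterial-fungal couplings with a few positive ones, and a case-like
#' regime of exclusively positive couplings. Pairs are disjoint so the
#' latent correlation matrix stays positive definite at strong couplings.
#'
#' @param group Group label the edges are planted in.
#' @param n_negative,n_positive Number of planted edges of each sign.
#' @param rho Magnitude of the target Spearman correlation.
#' @param bacteria,fungi Taxon name pools to draw pairs from.
#' @param offset Index of the first taxon used for pairing (leaves the
#'   leading named taxa free for depletion/IgE structure).
#' @return Tibble with columns `group`, `bacterial_taxon`, `fungal_taxon`,
#'   `target_spearman`.
#' @export
planted_edges <- function(group, n_negative = 0, n_positive = 0, rho = 0.8,
                          bacteria, fungi, offset = 5L) {
  n <- n_negative + n_positive
  if (n == 0) {
    return(tibble::tibble(group = character(), bacterial_taxon = character(),
                          fungal_taxon = character(), target_spearman = double()))
  }
  idx <- seq.int(offset, length.out = n)
  if (max(idx) > length(bacteria) || max(idx) > length(fungi)) {
    abort("Not enough taxa to plant disjoint edges; increase n_bacteria/n_fungi.")
  }
  tibble::tibble(
    group = group,
    bacterial_taxon = bacteria[idx],
    fungal_taxon = fungi[idx],
    target_spearman = rho * c(rep(-1, n_negative), rep(1, n_positive))
  )
}

#' Specify a synthetic two-group multi-kingdom cohort
#'
#' Defines all parameters of a simulated case-control cohort: group sizes,
#' taxon counts per kingdom, planted cross-kingdom Spearman couplings per
#' group, taxa with planted group-mean differences, zero inflation,
#' lognormal dispersion, and total-IgE covariates rank-coupled to focal
#' taxa. Defaults emulate a paediatric allergy case-control study: 19 cases
#' (`ARFC`, comorbid allergic rhinitis + functional constipation) versus 17
#' healthy controls (`HC`); a control network regime of 44 negative + 7
#' positive couplings against an exclusively positive case regime of 17;
#' depleted fungal genera (Dentiscutata 3.70% vs 1.49%, Cenococcum 1.74% vs
#' 0.30% mean relative abundance); and total IgE of 285.6 +/- 102.4 IU/mL in
#' cases versus 65.3 +/- 28.7 in controls, inversely rank-correlated
#' (Spearman around -0.4) with the focal fungi.
#'
#' @param n_per_group Named integer vector of group sizes (>= 3 each).
#' @param n_bacteria,n_fungi Number of genera per kingdom.
#' @param planted_edges Tibble of planted couplings (`group`,
#'   `bacterial_taxon`, `fungal_taxon`, `target_spearman` in (-1, 1)); `NULL`
#'   for the default two-regime structure above.
#' @param depleted_taxa Tibble (`taxon`, plus one mean-fraction column per
#'   group) of taxa with planted group differences in mean relative
#'   abundance (fractions in (0, 1)).
#' @param zero_inflation Probability that a taxon is structurally absent in
#'   a sample (applied to unstructured background taxa; see
#'   `zero_inflate_planted`).
#' @param lognormal_sigma Log-scale standard deviation of taxon abundances.
#' @param ige_coupling Tibble (`taxon`, `target_spearman`) of taxa whose
#'   abundance is rank-coupled to total IgE through the same latent copula.
#' @param ige_mean_sd Named list of `c(mean, sd)` of total IgE per group
#'   (IU/mL); a moment-matched lognormal is used since IgE is positive and
#'   right-skewed.
#' @param zero_inflate_planted Also zero-inflate taxa carrying planted
#'   structure (off by default so recovery studies isolate inference
#'   behaviour from sparsity).
#' @param seed Integer seed; every draw in [simulate_cohort()] flows from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(ARFC = 19L, HC = 17L),
                           n_bacteria = 60L, n_fungi = 60L,
                           planted_edges = NULL,
                           depleted_taxa = NULL,
                           zero_inflation = 0.3,
                           lognormal_sigma = 1,
                           ige_coupling = NULL,
                           ige_mean_sd = list(ARFC = c(285.6, 102.4),
                                              HC = c(65.3, 28.7)),
                           zero_inflate_planted = FALSE,
                           seed = 1L) {
  if (is.null(names(n_per_group)) || any(n_per_group < 3)) {
    abort("`n_per_group` must be a named vector with >= 3 samples per group.")
  }
  for (g in names(n_per_group)) {
    if (is.null(ige_mean_sd[[g]])) ige_mean_sd[[g]] <- c(100, 50)
  }
  bacteria <- default_bacterial_names(n_bacteria)
  fungi <- default_fungal_names(n_fungi)
  groups <- names(n_per_group)
  if (is.null(planted_edges)) {
    planted_edges <- dplyr::bind_rows(
      codysbiosis::planted_edges(groups[2], n_negative = 44, n_positive = 7,
                                 bacteria = bacteria, fungi = fungi),
      codysbiosis::planted_edges(groups[1], n_positive = 17,
                                 bacteria = bacteria, fungi = fungi)
    )
  }
  if (nrow(planted_edges)) {
    if (any(abs(planted_edges$target_spearman) >= 1) ||
        any(planted_edges$target_spearman == 0)) {
      abort("Planted target Spearman values must lie in (-1, 1) and be non-zero.")
    }
    unknown <- setdiff(c(planted_edges$bacterial_taxon, planted_edges$fungal_taxon),
                       c(bacteria, fungi))
    if (length(unknown)) {
      abort(paste0("Planted edge names unknown: ", paste(unknown, collapse = ", ")))
    }
  }
  if (is.null(depleted_taxa)) {
    depleted_taxa <- tibble::tibble(
      taxon = c("Dentiscutata", "Cenococcum"),
      ARFC = c(0.0149, 0.0030),
      HC = c(0.0370, 0.0174)
    )
    names(depleted_taxa) <- c("taxon", groups[1], groups[2])
  }
  if (is.null(ige_coupling)) {
    ige_coupling <- tibble::tibble(
      taxon = c("Dentiscutata", "Cenococcum", "Saccharomyces", "Ambispora"),
      target_spearman = c(-0.43, -0.40, -0.39, -0.40)
    )
    ige_coupling <- ige_coupling[ige_coupling$taxon %in% fungi, ]
  }
  structure(list(
    n_per_group = n_per_group, groups = groups,
    bacteria = bacteria, fungi = fungi,
    planted_edges = planted_edges, depleted_taxa = depleted_taxa,
    zero_inflation = zero_inflation, lognormal_sigma = lognormal_sigma,
    ige_coupling = ige_coupling, ige_mean_sd = ige_mean_sd,
    zero_inflate_planted = zero_inflate_planted,
    seed = as.integer(seed)
  ), class = "synthetic_spec")
}

# Latent correlation matrix over (bacteria, fungi, IgE) for one group.
latent_correlation <- function(spec, group) {
  taxa <- c(spec$bacteria, spec$fungi)
  p <- length(taxa) + 1L
  R <- diag(p)
  edges <- spec$planted_edges[spec$planted_edges$group == group, , drop = FALSE]
  if (nrow(edges)) {
    bi <- match(edges$bacterial_taxon, taxa)
    fi <- match(edges$fungal_taxon, taxa)
    r <- spearman_to_pearson(edges$target_spearman)
    R[cbind(bi, fi)] <- r
    R[cbind(fi, bi)] <- r
  }
  if (nrow(spec$ige_coupling)) {
    ti <- match(spec$ige_coupling$taxon, taxa)
    r <- spearman_to_pearson(spec$ige_coupling$target_spearman)
    R[cbind(ti, p)] <- r
    R[cbind(p, ti)] <- r
  }
  R
}

lognormal_moments <- function(mean, sd) {
  sig2 <- log(1 + sd^2 / mean^2)
  c(mu = log(mean) - sig2 / 2, sigma = sqrt(sig2))
}

#' Simulate a two-group cohort with planted correlation structure
#'
#' Draws, per group, a latent multivariate normal whose correlation matrix
#' embeds every planted cross-kingdom coupling and every IgE coupling via
#' the Gaussian-copula calibration [spearman_to_pearson()] (identity
#' elsewhere). Taxon margins are transformed to lognormal, structural zeros
#' are injected, and abundances are left raw (call
#' [to_relative_abundance()] to total-sum scale per kingdom; Spearman
#' structure is unaffected either way within a kingdom up to the scaling's
#' rank perturbation). Taxa listed in `depleted_taxa` have their expected
#' within-kingdom relative abundance matched to the requested group means.
#' Total IgE is drawn from a per-group moment-matched lognormal whose latent
#' normal is the copula's IgE dimension, so each `ige_coupling` entry is an
#' exact target Spearman correlation.
#'
#' @param spec A [synthetic_spec()].
#' @return List with elements `abundance` (a raw [abund_tbl]) and `metadata`
#'   (tibble with `sample_id`, `group`, `age`, `sex`, `total_ige`).
#' @export
#' @examples
#' sim <- simulate_cohort(synthetic_spec(seed = 42))
#' sim$abundance
#' dplyr::count(sim$metadata, group)
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  taxa <- c(spec$bacteria, spec$fungi)
  kingdom <- rep(c("bacteria", "fungi"), c(length(spec$bacteria), length(spec$fungi)))
  p <- length(taxa) + 1L

  structured <- unique(c(spec$planted_edges$bacterial_taxon,
                         spec$planted_edges$fungal_taxon,
                         spec$ige_coupling$taxon, spec$depleted_taxa$taxon))
  zi <- rep(spec$zero_inflation, length(taxa))
  if (!spec$zero_inflate_planted) zi[taxa %in% structured] <- 0

  # Background mean weights, shared across groups; right-skewed so a few
  # genera dominate, as in real communities. Kept moderate so that the
  # expected per-kingdom fraction of a depleted taxon tracks its target
  # (heavier weight tails inflate E[X/sum] via the random denominator).
  w_bg <- exp(rnorm(length(taxa), mean = 0, sd = 1))
  names(w_bg) <- taxa

  weights_for_group <- function(group) {
    w <- w_bg
    dep <- spec$depleted_taxa
    if (!is.null(dep) && nrow(dep) && group %in% names(dep)) {
      for (k in unique(kingdom[taxa %in% dep$taxon])) {
        in_k <- dep$taxon[kingdom[match(dep$taxon, taxa)] == k]
        targets <- dep[[group]][match(in_k, dep$taxon)]
        others <- setdiff(taxa[kingdom == k], in_k)
        bg_total <- sum(w[others] * (1 - zi[match(others, taxa)]))
        tt <- sum(targets)
        if (tt >= 1) abort("Depleted-taxon target fractions must sum below 1 per kingdom.")
        w[in_k] <- targets * bg_total / (1 - tt) /
          pmax(1 - zi[match(in_k, taxa)], .Machine$double.eps)
      }
    }
    w
  }

  abund <- list(); meta <- list()
  for (group in spec$groups) {
    n <- spec$n_per_group[[group]]
    R <- latent_correlation(spec, group)
    U <- tryCatch(chol(R), error = function(e) {
      abort("Planted correlation matrix is not positive definite; use fewer or weaker planted edges.")
    })
    Z <- matrix(rnorm(n * p), n, p) %*% U
    Zt <- Z[, seq_along(taxa), drop = FALSE]
    w <- weights_for_group(group)
    X <- sweep(exp(spec$lognormal_sigma * Zt -
                     spec$lognormal_sigma^2 / 2), 2, w, `*`)
    drop_mask <- matrix(runif(n * length(taxa)), n) <
      matrix(zi, n, length(taxa), byrow = TRUE)
    X[drop_mask] <- 0

    ms <- lognormal_moments(spec$ige_mean_sd[[group]][1], spec$ige_mean_sd[[group]][2])
    ige <- exp(ms["mu"] + ms["sigma"] * Z[, p])

    ids <- sprintf("%s_%02d", group, seq_len(n))
    rownames(X) <- ids
    abund[[group]] <- X
    meta[[group]] <- tibble::tibble(
      sample_id = ids, group = group,
      age = round(rnorm(n, 4.6, 1), 1),
      sex = sample(c("M", "F"), n, replace = TRUE),
      total_ige = as.numeric(ige)
    )
  }
  values <- t(do.call(rbind, abund))  # taxa x samples
  rownames(values) <- taxa
  list(
    abundance = abund_tbl(values, kingdom = kingdom, rank = "genus"),
    metadata = dplyr::bind_rows(meta),
    spec = spec
  )
}

#' Simulate a KEGG Orthology abundance dataset with shifted pathways
#'
#' Generates lognormal KO abundances for a two-group cohort and a KO-to-
#' pathway membership map. KOs belonging to the first `n_shifted_pathways`
#' pathways receive a group-mean shift of `shift_size` log-scale standard
#' deviations in the first group, giving pathway-level signal for
#' reporter-score aggregation; `shift_size = 0` yields an exchangeable null.
#'
#' @param n_ko Total number of KOs (pathway members plus background).
#' @param n_pathways Number of pathways.
#' @param ko_per_pathway Members per pathway (disjoint membership).
#' @param n_shifted_pathways Number of pathways given a group shift.
#' @param shift_size Shift in units of the log-scale standard deviation.
#' @param n_per_group Named vector of group sizes.
#' @param sigma Log-scale standard deviation.
#' @param seed Integer seed.
#' @return List with `ko` (tibble, `ko_id` x sample columns), `pathway_map`
#'   (tibble `pathway_id`, `ko_id`), and `metadata`.
#' @export
simulate_ko_dataset <- function(n_ko = 300L, n_pathways = 20L,
                                ko_per_pathway = 10L, n_shifted_pathways = 0L,
                                shift_size = 0, n_per_group = c(ARFC = 19L, HC = 17L),
                                sigma = 1, seed = 1L) {
  if (n_shifted_pathways > n_pathways) {
    abort("`n_shifted_pathways` cannot exceed `n_pathways`.")
  }
  if (n_pathways * ko_per_pathway > n_ko) {
    abort("`n_ko` must cover n_pathways * ko_per_pathway members.")
  }
  set.seed(seed)
  kos <- sprintf("K%05d", seq_len(n_ko))
  pathways <- sprintf("map%05d", seq_len(n_pathways))
  pathway_map <- tibble::tibble(
    pathway_id = rep(pathways, each = ko_per_pathway),
    ko_id = kos[seq_len(n_pathways * ko_per_pathway)]
  )
  groups <- names(n_per_group)
  base_mu <- rnorm(n_ko, 0, 1)
  shifted_kos <- pathway_map$ko_id[pathway_map$pathway_id %in% pathways[seq_len(n_shifted_pathways)]]
  cols <- list(); meta <- list()
  for (g in groups) {
    n <- n_per_group[[g]]
    mu <- base_mu
    if (g == groups[1]) mu[kos %in% shifted_kos] <- mu[kos %in% shifted_kos] + shift_size * sigma
    X <- exp(matrix(rnorm(n_ko * n, mu, sigma), n_ko, n))
    ids <- sprintf("%s_%02d", g, seq_len(n))
    colnames(X) <- ids
    cols[[g]] <- X
    meta[[g]] <- tibble::tibble(sample_id = ids, group = g)
  }
  ko <- tibble::as_tibble(do.call(cbind, cols))
  ko <- dplyr::bind_cols(tibble::tibble(ko_id = kos), ko)
  list(ko = ko, pathway_map = pathway_map, metadata = dplyr::bind_rows(meta))
}
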