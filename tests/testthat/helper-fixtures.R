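# Small in-code fixtures shared across tests.

toy_table <- function(values = NULL, kingdom = c("bacteria", "bacteria", "fungi", "fungi"),
                      samples = c("s1", "s2"), normalized = FALSE) {
  if (is.null(values)) {
    values <- matrix(c(2, 1, 1, 3,
                       2, 1, 3, 1), nrow = 4,
                     dimnames = list(c("b1", "b2", "f1", "f2"), samples))
  }
  abund_tbl(values, kingdom = kingdom, normalized = normalized)
}

toy_metadata <- function(samples, groups) {
  tibble::tibble(sample_id = samples, group = groups)
}

# A 20-sample two-kingdom table, built directly on the fraction scale, with
# one strictly monotone positive bacterium-fungus pair (driven by one latent
# order), one strictly monotone negative pair (driven by an independent
# order), and independent noise taxa absorbing the remaining mass.
planted_pair_table <- function(n = 20, n_noise = 8, seed = 3) {
  set.seed(seed)
  u1 <- sample(n)            # latent order of the positive pair
  u2 <- sample(n)            # independent latent order of the negative pair
  frac_block <- function(a, b) {
    noise <- matrix(exp(rnorm(n_noise * n)), n_noise, n)
    noise <- sweep(noise, 2, colSums(noise) / (1 - a - b), `/`)
    rbind(a, b, noise)
  }
  bact <- frac_block(0.05 + 0.01 * u1, 0.05 + 0.01 * u2)
  fung <- frac_block(0.02 + 0.012 * u1, 0.02 + 0.012 * (n + 1 - u2))
  vals <- rbind(bact, fung)
  rownames(vals) <- c("b_pos", "b_neg", sprintf("b_noise%02d", seq_len(n_noise)),
                      "f_pos", "f_neg", sprintf("f_noise%02d", seq_len(n_noise)))
  colnames(vals) <- sprintf("s%02d", seq_len(n))
  kingdom <- rep(c("bacteria", "fungi"), each = 2 + n_noise)
  abund_tbl(vals, kingdom = kingdom, normalized = TRUE)
}

# Spec for an ARFC-like regime: exclusively positive planted couplings in
# the case group against a large null background. Background taxa keep the
# generator's default zero inflation; planted taxa are exempt (the
# generator default), so recovery reflects network inference, not sparsity.
arfc_like_spec <- function(seed, n_case = 19, n_edges = 17,
                           n_bacteria = 37, n_fungi = 37, rho = 0.8,
                           zero_inflation = 0.3) {
  synthetic_spec(
    n_per_group = c(ARFC = n_case, HC = 17),
    n_bacteria = n_bacteria, n_fungi = n_fungi,
    planted_edges = tibble::tibble(
      group = "ARFC",
      bacterial_taxon = paste0("b__genus_", sprintf("%02d", seq_len(n_edges))),
      fungal_taxon = paste0("f__genus_", sprintf("%02d", seq_len(n_edges))),
      target_spearman = rho
    ),
    depleted_taxa = tibble::tibble(taxon = character(), ARFC = double(), HC = double()),
    ige_coupling = tibble::tibble(taxon = character(), target_spearman = double()),
    zero_inflation = zero_inflation,
    seed = seed
  )
}
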