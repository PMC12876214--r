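test_that("Spearman rho matches the rank formula and monotone invariance", {
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 0.8)  # 1 - 6*4/(5*24)
  expect_equal(spearman_rho(1:6, exp(1:6)), 1)
  expect_equal(spearman_rho(1:6, -(1:6)), -1)
  set.seed(31)
  x <- rnorm(25); y <- rnorm(25) + 0.5 * x
  expect_equal(spearman_rho(exp(x), y^3 + y * 2), spearman_rho(x, y * 2 + y^3))
  expect_equal(spearman_rho(x, y), spearman_rho(exp(x), y))
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
  expect_error(spearman_rho(1:2, 1:2), "length")
})

test_that("Spearman p-values reproduce printed correlation anchors", {
  expect_equal(round(spearman_pvalue(-0.75, 17), 4), 0.0005)
  expect_equal(round(spearman_pvalue(0.71, 19), 4), 0.0007)
  expect_equal(round(spearman_pvalue(0.66, 17), 4), 0.0039)
  expect_equal(spearman_pvalue(0, 20), 1)
  expect_warning(p1 <- spearman_pvalue(1, 6), "floor")
  expect_equal(p1, 2 / factorial(6))
  expect_error(spearman_pvalue(0.5, 3), "n >= 4")
  # monotone in |rho| at fixed n, and in n at fixed |rho|
  rhos <- seq(0.1, 0.9, 0.1)
  expect_true(all(diff(vapply(rhos, spearman_pvalue, numeric(1), n = 15)) < 0))
  ns <- c(5, 10, 20, 40)
  expect_true(all(diff(vapply(ns, function(n) spearman_pvalue(0.5, n), numeric(1))) < 0))
})

test_that("BH adjustment matches the hand step-up and calibrates on null p", {
  expect_equal(bh_adjust(0.02), 0.02)
  expect_equal(bh_adjust(c(0.01, 0.04, 0.03, 0.005)), c(0.02, 0.04, 0.04, 0.02))
  set.seed(32)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p) && all(q <= 1))
  expect_equal(order(q[order(p)]), 1:50)  # q monotone in p order
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  # all-null calibration: average discovery fraction at q < 0.05 stays <= 0.05
  frac <- replicate(500, mean(bh_adjust(runif(200)) < 0.05))
  expect_lte(mean(frac), 0.05)
})

test_that("network construction recovers exactly the planted monotone pairs", {
  tbl <- planted_pair_table()
  md <- toy_metadata(sample_ids(tbl), rep("G", 20))
  net <- build_cross_kingdom_network(tbl, md, "G")
  expect_s3_class(net, "ck_network")
  expect_equal(nrow(net$edges), 2)
  key <- paste(net$edges$bacterial_taxon, net$edges$fungal_taxon)
  expect_setequal(key, c("b_pos f_pos", "b_neg f_neg"))
  expect_equal(net$edges$sign[match("b_pos f_pos", key)], "positive")
  expect_equal(net$edges$sign[match("b_neg f_neg", key)], "negative")
  expect_equal(net$n_pairs_tested, 10 * 10)
  # node degrees equal incident edge counts
  expect_equal(sort(net$nodes$degree), c(1, 1, 1, 1))
  # every edge joins one bacterium and one fungus
  expect_true(all(net$edges$bacterial_taxon %in% tbl$taxon_id[tbl$kingdom == "bacteria"]))
  expect_true(all(net$edges$fungal_taxon %in% tbl$taxon_id[tbl$kingdom == "fungi"]))
})

test_that("network thresholds and preconditions are enforced", {
  tbl <- planted_pair_table()
  md <- toy_metadata(sample_ids(tbl), rep("G", 20))
  # weakly associated taxa below the correlation floor yield an empty edge set
  set.seed(44)
  weak <- matrix(exp(rnorm(8 * 20)), 8, 20,
                 dimnames = list(c(paste0("b", 1:4), paste0("f", 1:4)),
                                 sprintf("s%02d", 1:20)))
  weak_tbl <- to_relative_abundance(
    abund_tbl(weak, kingdom = rep(c("bacteria", "fungi"), each = 4)))
  weak_net <- build_cross_kingdom_network(
    weak_tbl, toy_metadata(sprintf("s%02d", 1:20), rep("G", 20)), "G",
    pipeline_config(prevalence_min = 0))
  expect_equal(nrow(weak_net$edges), 0)
  raw <- abund_tbl(t(abund_matrix(tbl)) * 100, kingdom = tbl$kingdom)
  expect_error(build_cross_kingdom_network(raw, md, "G"), "normalized")
  expect_error(build_cross_kingdom_network(tbl, md[1:3, ], "G"), ">= 4 samples")
})

test_that("raw-significant but FDR-insignificant pairs are excluded", {
  # moderate correlation among many null pairs: p < 0.05 but q >= 0.05
  set.seed(33)
  n <- 20
  z <- rnorm(n)
  border_b <- z + rnorm(n, sd = 0.75)
  border_f <- z + rnorm(n, sd = 0.75)
  vals <- rbind(border_b = exp(border_b),
                matrix(exp(rnorm(14 * n)), 14),
                border_f = exp(border_f),
                matrix(exp(rnorm(14 * n)), 14))
  rownames(vals) <- c("border_b", sprintf("b%02d", 1:14),
                      "border_f", sprintf("f%02d", 1:14))
  colnames(vals) <- sprintf("s%02d", 1:n)
  tbl <- to_relative_abundance(
    abund_tbl(vals, kingdom = rep(c("bacteria", "fungi"), each = 15)))
  md <- toy_metadata(colnames(vals), rep("G", n))
  rho <- spearman_rho(vals["border_b", ], vals["border_f", ])
  p <- spearman_pvalue(rho, n)
  expect_true(p < 0.05 && abs(rho) >= 0.6)  # the pair is raw-significant
  cfg <- pipeline_config(rho_min = 0.6, q_alpha = 0.05, prevalence_min = 0)
  net <- build_cross_kingdom_network(tbl, md, "G", cfg)
  key <- paste(net$edges$bacterial_taxon, net$edges$fungal_taxon)
  expect_false("border_b border_f" %in% key)
})

test_that("network summaries count signs, flag empties, and rank hubs", {
  edges <- tibble::tibble(
    bacterial_taxon = c("b1", "b2", "b3", "b4"),
    fungal_taxon = c("f1", "f1", "f1", "f2"),
    rho = c(0.8, 0.7, 0.9, -0.65),
    p_value = 1e-4, q_value = 1e-3,
    sign = c("positive", "positive", "positive", "negative"))
  nodes <- tibble::tibble(
    taxon = c("f1", "b1", "b2", "b3", "b4", "f2"),
    kingdom = c("fungi", rep("bacteria", 4), "fungi"),
    mean_abundance = c(0.2, 0.1, 0.1, 0.1, 0.05, 0.01),
    degree = c(3L, 1L, 1L, 1L, 1L, 1L))
  net <- structure(list(group = "G", nodes = nodes, edges = edges,
                        thresholds = list(rho_min = 0.6, q_alpha = 0.05,
                                          prevalence_min = 0.25),
                        n_pairs_tested = 100L, n_samples = 19L),
                   class = "ck_network")
  s <- summarize_network(net, n_hubs = 3)
  expect_equal(s$n_edges, 4)
  expect_equal(s$n_positive + s$n_negative, s$n_edges)
  expect_equal(s$positivity_fraction, 0.75)
  expect_true(s$defined)
  expect_equal(s$hubs$taxon[1], "f1")
  expect_equal(s$hubs$degree[1], 3)

  empty <- net; empty$edges <- edges[0, ]; empty$nodes <- nodes[0, ]
  s0 <- summarize_network(empty)
  expect_false(s0$defined)
  expect_true(is.na(s0$positivity_fraction))

  # a star hub mirrors a fungus with seven bacterial partners
  star <- net
  star$edges <- tibble::tibble(
    bacterial_taxon = paste0("b", 1:7), fungal_taxon = "hub_fungus",
    rho = 0.7, p_value = 1e-4, q_value = 1e-3, sign = "positive")
  star$nodes <- tibble::tibble(
    taxon = c("hub_fungus", paste0("b", 1:7)),
    kingdom = c("fungi", rep("bacteria", 7)),
    mean_abundance = 0.05, degree = c(7L, rep(1L, 7)))
  expect_equal(summarize_network(star, 1)$hubs$taxon, "hub_fungus")
  expect_equal(summarize_network(star, 1)$positivity_fraction, 1)
})

test_that("network comparison reports flips, uniques and positivity shift", {
  tbl <- planted_pair_table()
  md <- toy_metadata(sample_ids(tbl), rep("G", 20))
  net <- build_cross_kingdom_network(tbl, md, "G")
  same <- compare_networks(net, net)
  expect_equal(same$n_sign_flips, 0)
  expect_equal(same$positivity_difference, 0)
  expect_equal(same$n_only_a + same$n_only_b, 0)

  flipped <- net
  flipped$edges$rho <- -flipped$edges$rho
  flipped$edges$sign <- ifelse(flipped$edges$sign == "positive", "negative", "positive")
  cmp <- compare_networks(net, flipped)
  expect_equal(cmp$n_sign_flips, 2)

  other <- net
  other$thresholds$rho_min <- 0.7
  expect_error(compare_networks(net, other), "thresholds")
})

test_that("planted-edge recovery is sign-faithful with few spurious edges", {
  n_runs <- 20
  sign_ok <- logical(n_runs)
  spurious <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    spec <- arfc_like_spec(seed = i, n_edges = 6, n_bacteria = 20, n_fungi = 20)
    sim <- simulate_cohort(spec)
    rel <- to_relative_abundance(sim$abundance)
    net <- build_cross_kingdom_network(rel, sim$metadata, "ARFC",
                                       pipeline_config(prevalence_min = 0))
    planted_key <- paste(spec$planted_edges$bacterial_taxon,
                         spec$planted_edges$fungal_taxon)
    key <- paste(net$edges$bacterial_taxon, net$edges$fungal_taxon)
    found_planted <- key %in% planted_key
    sign_ok[i] <- all(net$edges$sign[found_planted] == "positive")
    spurious[i] <- sum(!found_planted)
  }
  expect_gte(sum(sign_ok), 19)
  expect_lt(mean(spurious), 0.5)
})

test_that("GraphML export carries the display conventions", {
  tbl <- planted_pair_table()
  md <- toy_metadata(sample_ids(tbl), rep("G", 20))
  net <- build_cross_kingdom_network(tbl, md, "G")
  g <- as_igraph(net)
  expect_setequal(igraph::vertex_attr_names(g),
                  c("name", "kingdom", "mean_abundance", "degree", "shape", "color"))
  expect_setequal(igraph::edge_attr_names(g),
                  c("rho", "p_value", "q_value", "sign", "color"))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_network_graphml(net, path)
  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::gorder(back), igraph::gorder(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$kingdom, c("bacteria", "fungi"))
})
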