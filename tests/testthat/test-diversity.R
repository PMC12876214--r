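test_that("Chao1 matches hand evaluation and never undershoots richness", {
  # S_obs = 4, F1 = 2, F2 = 1
  expect_equal(chao1(c(5, 1, 1, 2), bias_corrected = FALSE), 6)
  expect_equal(chao1(c(5, 1, 1, 2)), 4.5)
  expect_equal(chao1(c(5, 3, 2)), 3)   # no singletons -> S_obs
  expect_equal(chao1(c(0, 0, 0)), 0)
  expect_error(chao1(c(1.5, 2)), "integer")

  set.seed(8)
  for (i in 1:20) {
    counts <- stats::rpois(30, lambda = sample(1:4, 1))
    expect_gte(chao1(counts), sum(counts > 0))
    expect_gte(chao1(counts, bias_corrected = FALSE), sum(counts > 0))
  }
  # agreement with the vegan estimator (bias-corrected form)
  counts <- c(5, 1, 1, 2, 1, 0, 3, 2, 2, 1)
  expect_equal(chao1(counts),
               unname(vegan::estimateR(counts)["S.chao1"]))
})

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon(rep(1, 4)), log(4))
  expect_equal(shannon(c(0, 7, 0)), 0)
  expect_equal(shannon(c(0.5, 0.25, 0.25), base = 2), 1.5)
  expect_error(shannon(c(0, 0)), "all-zero")
  expect_equal(shannon(c(1, 2, 3)), vegan::diversity(c(1, 2, 3), "shannon"))
})

test_that("Bray-Curtis distances match the definition and vegan", {
  x <- c(2, 2); y <- c(1, 3)
  m <- rbind(s1 = x, s2 = y, s3 = x, s4 = c(0, 5))
  colnames(m) <- c("t1", "t2")
  d <- bray_curtis_matrix(m)
  expect_equal(d["s1", "s2"], 0.25)          # 2/8
  expect_equal(d["s1", "s3"], 0)             # identical samples
  disjoint <- rbind(a = c(1, 0), b = c(0, 1))
  expect_equal(bray_curtis_matrix(disjoint)["a", "b"], 1)
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(d >= 0 & d <= 1))
  # joint rescaling of all samples leaves distances unchanged
  expect_equal(unclass(bray_curtis_matrix(m * 13)), unclass(d))
  # a pair of all-zero samples is undefined
  zz <- rbind(u = c(0, 0), v = c(0, 0), w = c(1, 2))
  expect_error(bray_curtis_matrix(zz), "u, v")
})

test_that("PCoA reproduces embeddable distances and flags negative eigenvalues", {
  # 3 collinear points: distances 3, 2, 5
  d <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  d["a", "b"] <- d["b", "a"] <- 3
  d["b", "c"] <- d["c", "b"] <- 2
  d["a", "c"] <- d["c", "a"] <- 5
  ord <- pcoa(d, n_axes = 3)
  expect_equal(length(ord$eigenvalues), 1)      # one positive axis
  expect_equal(sum(ord$proportion_explained), 1)
  coords <- as.matrix(ord$coordinates[, -1])
  rownames(coords) <- ord$coordinates$sample_id
  expect_equal(abs(coords["a", 1] - coords["b", 1]), 3, tolerance = 1e-9)
  expect_equal(abs(coords["a", 1] - coords["c", 1]), 5, tolerance = 1e-9)

  # Euclidean input: full-rank coordinates reproduce all pairwise distances
  set.seed(2)
  pts <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5), NULL))
  de <- as.matrix(dist(pts))
  orde <- pcoa(de, n_axes = 4)
  expect_equal(length(orde$eigenvalues), 2)     # 2 positive, rest ~0
  expect_equal(orde$n_negative_eigenvalues_discarded, 0)
  rec <- as.matrix(dist(as.matrix(orde$coordinates[, -1])))
  expect_equal(unname(rec), unname(de), tolerance = 1e-9)

  # duplicated samples land on identical coordinates
  ddup <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  dimnames(ddup) <- list(paste0("s", 1:4), paste0("s", 1:4))
  od <- pcoa(ddup, 2)
  expect_equal(unlist(od$coordinates[1, -1]), unlist(od$coordinates[2, -1]))

  # non-Euclidean (Bray-Curtis) input reports discarded negative eigenvalues
  set.seed(3)
  comm <- matrix(stats::rpois(80, 4), 8, 10,
                 dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  ordb <- pcoa(bray_curtis_matrix(comm), 2)
  expect_gt(ordb$n_negative_eigenvalues_discarded, 0)
  expect_error(pcoa(d, n_axes = 0), "n_axes")
})

test_that("PERMANOVA partitions sums of squares and matches vegan", {
  set.seed(4)
  m <- matrix(rnorm(60), 12, 5, dimnames = list(paste0("s", 1:12), NULL))
  m <- abs(m)
  groups <- rep(c("A", "B"), each = 6)
  d <- bray_curtis_matrix(m)
  fit <- permanova(d, groups, n_perm = 999, seed = 1)
  ref <- vegan::adonis2(stats::as.dist(d) ~ g,
                        data = data.frame(g = groups), permutations = 99)
  expect_equal(fit$pseudo_f, ref$F[1], tolerance = 1e-10)
  expect_equal(fit$r_squared, ref$R2[1], tolerance = 1e-10)
  expect_true(fit$r_squared >= 0 && fit$r_squared <= 1)
  expect_gt(fit$p_value, 0)   # add-one correction forbids p = 0
  expect_error(permanova(d, rep(c("A", "B", "C"), c(6, 5, 1))), ">= 2 samples")
})

test_that("PERMANOVA exact enumeration gives 1/3 on the separated 4-point toy", {
  pts <- c(0, 1, 10, 11)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  groups <- c("A", "A", "B", "B")
  fit <- permanova(d, groups, exact_if_feasible = TRUE)
  expect_equal(fit$method, "exact")
  expect_equal(fit$n_perm, 6)          # C(4,2) assignments
  expect_equal(fit$p_value, 1 / 3)
  # Monte-Carlo p approaches the exact value
  mc <- permanova(d, groups, n_perm = 9999, seed = 2)
  expect_equal(mc$p_value, 1 / 3, tolerance = 0.05)
})

test_that("Procrustes is invariant to similarity transforms and matches vegan", {
  set.seed(5)
  x <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  theta <- 0.7
  rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
  y <- 3.2 * x %*% rot + matrix(c(5, -2), 10, 2, byrow = TRUE)
  rownames(y) <- rownames(x)
  fit <- procrustes_test(x, y, n_perm = 99, seed = 1)
  expect_equal(fit$m_squared, 0, tolerance = 1e-9)
  expect_equal(fit$correlation_r, 1, tolerance = 1e-9)

  # independent configurations: agreement with vegan::protest statistic
  z <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  fit2 <- procrustes_test(x, z, n_perm = 199, seed = 1)
  ref <- vegan::protest(x, z, permutations = 199)
  expect_equal(fit2$m_squared, ref$ss, tolerance = 1e-9)
  expect_equal(fit2$correlation_r, ref$t0, tolerance = 1e-9)
  expect_error(procrustes_test(x, z[c(2, 1, 3:10), ]), "same samples")
})

test_that("PROTEST p-values are uniform under the null", {
  set.seed(6)
  pvals <- replicate(200, {
    x <- matrix(rnorm(20), 10, 2)
    y <- matrix(rnorm(20), 10, 2)
    procrustes_test(x, y, n_perm = 99, seed = sample.int(1e6, 1))$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("unique/shared taxon accounting is exact set arithmetic", {
  vals <- matrix(0, 4, 4, dimnames = list(paste0("t", 1:4), paste0("s", 1:4)))
  vals[c("t1", "t2", "t3"), c("s1", "s2")] <- 1   # group A sees t1-t3
  vals[c("t2", "t3", "t4"), c("s3", "s4")] <- 1   # group B sees t2-t4
  tbl <- abund_tbl(vals, kingdom = "fungi")
  md <- toy_metadata(paste0("s", 1:4), rep(c("A", "B"), each = 2))
  res <- unique_shared_taxa(tbl, md)
  expect_equal(res$n_taxa, c(1, 1, 2))
  expect_equal(res$taxa[[3]], c("t2", "t3"))
  # unique_A + shared = total present in A
  expect_equal(res$n_taxa[1] + res$n_taxa[3], 3)

  # identical groups share everything; an empty group owns nothing
  vals2 <- vals; vals2[, ] <- 1
  res2 <- unique_shared_taxa(abund_tbl(vals2, kingdom = "fungi"), md)
  expect_equal(res2$n_taxa, c(0, 0, 4))
  vals3 <- vals; vals3[, c("s3", "s4")] <- 0
  res3 <- unique_shared_taxa(abund_tbl(vals3, kingdom = "fungi"), md)
  expect_equal(res3$n_taxa, c(3, 0, 0))
  expect_error(unique_shared_taxa(tbl, md, groups = c("A", "ghost")), "ghost")
})
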