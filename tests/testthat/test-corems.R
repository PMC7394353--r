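test_that("binary distance matches direct counting on constructed profiles", {
  m <- rbind(g1 = c(1, 1, 0), g2 = c(1, 1, 0), g3 = c(0, 0, 1),
             g4 = c(1, 0, 1))
  colnames(m) <- paste0("c", 1:3)
  d <- binary_distance(m)
  expect_equal(d["g1", "g2"], 0)      # identical rows
  expect_equal(d["g1", "g3"], 1)      # disjoint rows
  expect_equal(d["g1", "g4"], 2 / 3)  # 2 mismatches over 3 informative corems
  expect_equal(diag(d), setNames(rep(0, 4), rownames(m)))
})

test_that("binary distance equals the brute-force counter on random matrices", {
  set.seed(40)
  for (i in 1:25) {
    m <- matrix(rbinom(36, 1, 0.5), 6, 6,
                dimnames = list(paste0("g", 1:6), paste0("c", 1:6)))
    m[rowSums(m) == 0, 1] <- 1 # keep every gene in at least one corem
    expect_equal(binary_distance(m), oracle_binary_dist(m),
                 ignore_attr = TRUE)
  }
})

test_that("genes in no corem are excluded before clustering", {
  m <- rbind(g1 = c(1, 1), g2 = c(1, 0), g3 = c(0, 0))
  colnames(m) <- c("c1", "c2")
  d <- binary_distance(m)
  expect_equal(rownames(d), c("g1", "g2"))
  expect_equal(attr(d, "excluded"), "g3")
  expect_error(binary_distance(rbind(g1 = c(0, 0), g2 = c(1, 0))), "fewer than 2")
})

test_that("UPGMA reproduces the hand-computed merge heights", {
  d <- matrix(c(0, 0.1, 0.9, 0.1, 0, 0.9, 0.9, 0.9, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  hc <- upgma_cluster(d)
  expect_equal(hc$height, c(0.1, 0.9))
  expect_setequal(hc$labels[-hc$merge[1, ]], c("A", "B"))
})

test_that("UPGMA is a fixed point on ultrametric input and label-permutation invariant", {
  # tie-free random distances: the UPGMA tree is unique
  set.seed(41)
  pts <- matrix(rnorm(20 * 3), 20)
  rownames(pts) <- paste0("g", 1:20)
  d <- as.matrix(dist(pts))
  hc <- upgma_cluster(d)
  coph <- as.matrix(stats::cophenetic(hc))
  # an ultrametric matrix is a fixed point of the clustering
  hc2 <- upgma_cluster(coph)
  expect_equal(as.matrix(stats::cophenetic(hc2))[rownames(coph), colnames(coph)],
               coph, tolerance = 1e-12)
  # permuting labels leaves the clade structure unchanged
  perm <- sample(nrow(d))
  hcp <- upgma_cluster(d[perm, perm])
  keys <- function(h) sort(riboshift:::.clade_keys(h)$keys)
  expect_equal(keys(hcp), keys(hc))
  expect_error(upgma_cluster(matrix(c(0, NA, NA, 0), 2, 2,
                                    dimnames = list(c("a", "b"), c("a", "b")))),
               "NA")
})

test_that("noise-free block membership yields perfectly supported classes", {
  sc <- simulate_corems(noise_rate = 0, seed = 2)
  a <- bootstrap_cluster_support(sc$membership, n_boot = 200, seed = 7)
  tab <- table(a$class_label)
  expect_setequal(names(tab), c("I", "II", "III", "IV"))
  expect_equal(unname(sort(as.vector(tab), decreasing = TRUE)), c(38, 7, 6, 3))
  expect_equal(unique(a$cluster_support), 1)
  # classes coincide with the planted partition
  expect_equal(length(unique(paste(a$class_label, sc$truth$true_class))), 4)
})

test_that("bootstrap supports are reproducible and seed-stable", {
  sc <- simulate_corems(noise_rate = 0, seed = 2)
  a1 <- bootstrap_cluster_support(sc$membership, n_boot = 150, seed = 3)
  a2 <- bootstrap_cluster_support(sc$membership, n_boot = 150, seed = 3)
  expect_identical(a1$cluster_support, a2$cluster_support)
  # on the noise-free fixture two different seeds agree to within 0.02
  a3 <- bootstrap_cluster_support(sc$membership, n_boot = 150, seed = 99)
  expect_lt(max(abs(a1$cluster_support - a3$cluster_support)), 0.02)
  expect_warning(bootstrap_cluster_support(sc$membership, n_boot = 50, seed = 1),
                 "unstable")
})

test_that("genes without membership are excluded and reported by the bootstrap", {
  sc <- simulate_corems(n_genes = 20, class_sizes = c(10, 10), n_corems = 24,
                        noise_rate = 0, n_unassigned = 3, seed = 4)
  a <- bootstrap_cluster_support(sc$membership, n_boot = 120, seed = 5)
  expect_equal(nrow(a), 20)
  expect_length(attr(a, "excluded"), 3)
})

test_that("corem signatures are per-condition medians across member genes", {
  set.seed(42)
  comp <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("c", 1:10)))
  s1 <- corem_signature(comp, "g2")
  expect_equal(s1$median, unname(comp["g2", ]))
  # duplicated member ids do not change the signature
  s2 <- corem_signature(comp, c("g2", "g2"))
  expect_equal(s2$median, s1$median)
  s3 <- corem_signature(comp, c("g1", "g3", "g4"))
  expect_equal(s3$median, unname(apply(comp[c("g1", "g3", "g4"), ], 2, median)))
  expect_equal(s3$q1, unname(apply(comp[c("g1", "g3", "g4"), ], 2, quantile, 0.25)))
  expect_error(corem_signature(comp, "nope"), "no member gene")
})

test_that("the corem-pair similarity decision follows the SRCC and KS rules", {
  cfg <- pipeline_config()
  set.seed(43)
  base <- data.frame(condition = paste0("c", 1:100),
                     median = rnorm(100), q1 = 0, q3 = 0)
  # identical non-constant signatures: perfectly similar
  d1 <- corem_pair_similarity(base, base, cfg)
  expect_equal(d1$srcc, 1)
  expect_equal(d1$ks_d, 0)
  expect_true(d1$similar)
  # a large additive shift keeps SRCC = 1 but the KS test rejects
  shifted <- base
  shifted$median <- base$median + 10
  d2 <- corem_pair_similarity(base, shifted, cfg)
  expect_equal(d2$srcc, 1)
  expect_lt(d2$ks_p, 0.05)
  expect_false(d2$similar)
  # constant signature: undefined correlation, flagged, not similar
  const <- base
  const$median <- rep(1, 100)
  d3 <- corem_pair_similarity(base, const, cfg)
  expect_true(d3$degenerate)
  expect_false(d3$similar)
  # decision is symmetric
  other <- base
  other$median <- base$median * 0.5 + rnorm(100, 0, 0.2)
  expect_equal(corem_pair_similarity(base, other, cfg)$similar,
               corem_pair_similarity(other, base, cfg)$similar)
})

test_that("independent signatures are rarely called similar", {
  cfg <- pipeline_config()
  set.seed(44)
  hits <- replicate(60, {
    a <- data.frame(condition = paste0("c", 1:100), median = rnorm(100),
                    q1 = 0, q3 = 0)
    b <- a
    b$median <- rnorm(100)
    corem_pair_similarity(a, b, cfg)$similar
  })
  expect_lt(mean(hits), 0.02)
})

test_that("class similarity matrices are symmetric with saturated diagonals for coherent classes", {
  cfg <- pipeline_config()
  sc <- simulate_corems(noise_rate = 0, gene_noise_sd = 0.2, seed = 6)
  a <- bootstrap_cluster_support(sc$membership, n_boot = 150, seed = 7)
  sim <- class_similarity_matrix(a, sc$membership, sc$compendium,
                                 sc$condition_categories, cfg)
  expect_named(sim, unique(sc$condition_categories$category))
  for (m in unclass(sim)) {
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) > 0.9, na.rm = TRUE))
  }
  # a category with fewer than 3 conditions is untestable
  cc <- sc$condition_categories
  cc$category[cc$category == cc$category[1]][-(1:2)] <- cc$category[nrow(cc)]
  sim2 <- class_similarity_matrix(a, sc$membership, sc$compendium, cc, cfg)
  expect_true(all(is.na(sim2[[cc$category[1]]])))
})
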