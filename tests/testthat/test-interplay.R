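fake_result <- function(lfc, padj, assay = "rna") {
  res <- data.frame(gene_id = sprintf("g%03d", seq_along(lfc)), log2fc = lfc,
                    se = 0.1, pvalue = padj, padj = padj,
                    mean_expression = 100, assay = assay,
                    stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  res
}

test_that("regulatory classes follow the threshold rules", {
  cfg <- pipeline_config()
  mr <- fake_result(c(2.0, 1.5, 0.3, -1.8, 0.1, 0.2, 2.2, 1.1),
                    c(1e-3, 0.01, 0.9, 1e-4, 0.9, 0.7, 1e-3, NA))
  rb <- fake_result(c(1.8, 0.2, 0.1, -0.4, 1.7, -2.5, -1.9, 1.0),
                    c(1e-3, 0.9, 0.8, 0.6, 1e-3, 1e-4, 1e-3, 0.2), "ribo")
  cl <- classify_regulation(mr, rb, cfg)
  expect_equal(as.character(cl$class),
               c("TC+",          # both significant, same sign
                 "COMP-",        # mRNA up, footprints flat
                 "NR",           # neither significant
                 "COMP+",        # mRNA down, footprints flat
                 "TL+",          # footprints up alone
                 "TL-",          # footprints down alone
                 "DISCORDANT",   # both significant, opposite signs
                 "NOT_ASSESSED"))# missing padj
  expect_equal(sum(attr(cl, "counts")), nrow(cl))
})

test_that("classification is total over random inputs and errors on mismatched universes", {
  cfg <- pipeline_config()
  set.seed(20)
  for (i in 1:10) {
    n <- sample(20:100, 1)
    mr <- fake_result(runif(n, -3, 3),
                      ifelse(runif(n) < 0.1, NA, runif(n)))
    rb <- fake_result(runif(n, -3, 3),
                      ifelse(runif(n) < 0.1, NA, runif(n)), "ribo")
    cl <- classify_regulation(mr, rb, cfg)
    expect_false(anyNA(cl$class))
    expect_equal(sum(attr(cl, "counts")), n)
  }
  expect_error(classify_regulation(fake_result(1, 0.5), fake_result(c(1, 2), c(0.5, 0.5))),
               "universe")
})

test_that("TE is the exact log2 footprint/mRNA ratio with NA for zero abundance", {
  design_r <- make_design(1, 3, "rna")
  design_b <- make_design(1, 3, "ribo")
  rna <- matrix(c(50, 50, 50, 100, 100, 100, 10, 10, 10), 3, 3, byrow = TRUE,
                dimnames = list(c("g1", "g2", "g3"), design_r$sample_id))
  ribo <- matrix(c(50, 50, 50, 25, 25, 25, 0, 0, 0), 3, 3, byrow = TRUE,
                 dimnames = list(c("g1", "g2", "g3"), design_b$sample_id))
  te <- compute_te(rna, ribo, design_r, design_b, "TP1")
  expect_equal(te$te, c(0, -2, NA))
  # the NA-TE gene is excluded from the regression input
  expect_error(regress_te_on_abundance(te), "at least 3")
})

test_that("replicate summary uses the median by default and the mean on request", {
  design_r <- make_design(1, 3, "rna")
  design_b <- make_design(1, 3, "ribo")
  rna <- matrix(rep(c(10, 20, 90), each = 1), 1, 3,
                dimnames = list("g1", design_r$sample_id))
  ribo <- matrix(rep(40, 3), 1, 3, dimnames = list("g1", design_b$sample_id))
  te_med <- compute_te(rna, ribo, design_r, design_b, "TP1")
  expect_equal(te_med$tpm_rna, 20)
  te_mean <- compute_te(rna, ribo, design_r, design_b, "TP1",
                        pipeline_config(te_summary = "mean"))
  expect_equal(te_mean$tpm_rna, 40)
})

test_that("a noiseless line is recovered exactly by the TE regression", {
  tpm <- 10^seq(0.5, 4, length.out = 50)
  te <- data.frame(gene_id = paste0("g", 1:50),
                   te = 1 - 1.10 * log10(tpm + 1),
                   tpm_rna = tpm, tpm_ribo = 1, time_point = "TP1")
  fit <- suppressWarnings(regress_te_on_abundance(te)) # perfect-fit lm warning
  expect_equal(fit$slope, -1.10, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$r, -1, tolerance = 1e-10)
  expect_equal(coef(fit), c(intercept = 1, slope = -1.10), tolerance = 1e-10)

  te$te <- rep(2, 50) # constant TE: null slope
  fit0 <- suppressWarnings(regress_te_on_abundance(te))
  expect_equal(fit0$slope, 0, tolerance = 1e-12)

  te$tpm_rna <- rep(100, 50)
  expect_error(regress_te_on_abundance(te), "degenerate")
})

test_that("TE fit invariants hold on noisy data", {
  set.seed(21)
  tpm <- 10^runif(300, 0.5, 4)
  te <- data.frame(gene_id = paste0("g", 1:300),
                   te = 2 - 1.1 * log10(tpm + 1) + rnorm(300),
                   tpm_rna = tpm, tpm_ribo = 1, time_point = "TP1")
  fit <- regress_te_on_abundance(te)
  expect_lt(abs(mean(residuals(fit))), 1e-10)
  # R^2 consistent with explained variance
  expect_equal(fit$r_squared, 1 - var(residuals(fit)) / var(te$te),
               tolerance = 1e-10)
  expect_equal(fit$r^2, fit$r_squared, tolerance = 1e-10)
  # adding a constant shifts the intercept only; residuals unchanged
  te2 <- te
  te2$te <- te$te + 5
  fit2 <- regress_te_on_abundance(te2)
  expect_equal(fit2$slope, fit$slope, tolerance = 1e-12)
  expect_equal(fit2$intercept, fit$intercept + 5, tolerance = 1e-10)
  expect_equal(residuals(fit2), residuals(fit), tolerance = 1e-10)
})

test_that("the Mann-Whitney wrapper reproduces the exact small-sample test", {
  t1 <- mw_u_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(t1$U, 0)
  expect_equal(t1$p, 0.1)
  # identical samples: no evidence of a shift
  t2 <- mw_u_test(c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14),
                  c(5, 6, 7, 8, 9, 10, 11, 12, 13, 14))
  expect_gt(t2$p, 0.99)
  # strong separation at moderate n
  set.seed(22)
  t3 <- mw_u_test(rnorm(50, 1, 0.1), rnorm(50, 0, 0.1))
  expect_lt(t3$p, 1e-10)
  expect_equal(t3$U, 2500) # complete separation: all pairs won
})

test_that("binned TE deviation tests report groups, untestable bins and separation", {
  set.seed(23)
  n <- 240
  tpm <- 10^runif(n, 1.05, 4) # inside the (10, 10000] bin range
  group <- sample(c("up", "down", "non"), n, replace = TRUE)
  shift <- ifelse(group == "up", 1, ifelse(group == "down", -1, 0))
  te <- data.frame(gene_id = paste0("g", 1:n),
                   te = 2 - 1.1 * log10(tpm + 1) + shift + rnorm(n, 0, 0.1),
                   tpm_rna = tpm, tpm_ribo = 1, time_point = "TP1")
  fit <- regress_te_on_abundance(te)
  mr <- fake_result(ifelse(group == "up", 2, ifelse(group == "down", -2, 0.1)),
                    ifelse(group == "non", 0.9, 1e-4))
  mr$gene_id <- te$gene_id
  tab <- te_deviation_by_group(fit, mr)
  expect_equal(nrow(tab), 9) # 3 bins x 3 comparisons
  updown <- tab[tab$comparison == "up vs down", ]
  expect_true(all(updown$p < 1e-6))
  expect_true(all(updown$significance == "**"))

  # starve one bin: everything below 100 TPM removed -> low bin untestable
  keep <- tpm > 100
  te2 <- te[keep, ]
  fit2 <- regress_te_on_abundance(te2)
  tab2 <- te_deviation_by_group(fit2, mr)
  expect_true(all(tab2$significance[tab2$bin == "low"] == "untestable"))
})

test_that("permutation abundance test honours its degenerate contracts", {
  set.seed(24)
  ab <- setNames(10^rnorm(500, 2, 0.5), paste0("g", 1:500))
  # whole universe: every null mean equals the observed mean
  expect_equal(permutation_abundance_test(names(ab), ab, 200, seed = 1)$p, 1)
  # reproducibility
  s <- sample(names(ab), 25)
  p1 <- permutation_abundance_test(s, ab, 500, seed = 9)
  p2 <- permutation_abundance_test(s, ab, 500, seed = 9)
  expect_identical(p1$p, p2$p)
  expect_error(permutation_abundance_test(c(s, "nope"), ab, 10), "universe")
  expect_error(permutation_abundance_test(paste0("g", 1:501), ab[1:400], 10))
  # upper and two-sided tails relate to the lower tail
  pl <- permutation_abundance_test(s, ab, 500, seed = 2, tail = "lower")$p
  pu <- permutation_abundance_test(s, ab, 500, seed = 2, tail = "upper")$p
  pt <- permutation_abundance_test(s, ab, 500, seed = 2, tail = "two")$p
  expect_equal(pt, min(1, 2 * min(pl, pu)))
})

test_that("prediction-interval outliers flag constructed deviants only", {
  set.seed(25)
  x <- seq(-3, 3, length.out = 58)
  y <- 0.7 * x + rnorm(58, 0, 0.05)
  y[30] <- 0.7 * x[30] + 10 * 0.05 * 10 # displaced by 10 sigma
  out <- prediction_interval_outliers(x, y, gene_ids = paste0("g", 1:58))
  expect_true(out$table$outlier[30])
  expect_equal(sum(out$table$outlier), 1)
  # three collinear points: zero residual variance, nothing flagged
  out3 <- suppressWarnings(prediction_interval_outliers(c(1, 2, 3), c(2, 4, 6)))
  expect_false(any(out3$table$outlier))
  expect_error(prediction_interval_outliers(rep(1, 5), rnorm(5)), "degenerate")
})

test_that("log2 fold changes convert to the fold values reported in the field", {
  f <- log2fc_to_fold(c(-4.70, -2.78, 0, 1))
  expect_equal(round(f$fold), c(26, 7, 1, 2))
  expect_equal(f$fold[2], 6.87, tolerance = 0.01)
  expect_equal(f$direction, c("down", "down", "none", "up"))
  expect_error(log2fc_to_fold(c(1, Inf)))
})
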