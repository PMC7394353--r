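intensity_fixture <- function(lg2, design, noise = 0) {
  # lg2: protein x time-point log2 means; expand over replicates
  tps <- unique(design$time_point)
  m <- matrix(0, nrow(lg2), nrow(design),
              dimnames = list(rownames(lg2), design$sample_id))
  for (j in seq_len(nrow(design))) {
    k <- match(design$time_point[j], tps)
    m[, j] <- 2^(lg2[, k] + if (noise > 0) rnorm(nrow(lg2), 0, noise) else 0)
  }
  m
}

test_that("protein log2 fold changes recover planted trends exactly at zero noise", {
  design <- make_design(4, 3, "protein")
  trend <- c(0, -0.3, -0.7, -1.04)
  lg2 <- outer(rnorm(30, 14, 1), trend, "+")
  rownames(lg2) <- paste0("P", 1:30)
  m <- intensity_fixture(lg2, design)
  lfc <- protein_log2fc(m, design)
  expect_equal(unname(apply(lfc, 2, median)), trend, tolerance = 1e-10)
  expect_equal(unname(lfc[, "TP1"]), rep(0, 30))
  expect_equal(attr(lfc, "n_detected"), c(TP1 = 30, TP2 = 30, TP3 = 30, TP4 = 30))
})

test_that("uniform intensity scaling shifts all fold changes equally", {
  design <- make_design(2, 3, "protein")
  set.seed(30)
  lg2 <- cbind(rnorm(25, 14), rnorm(25, 14))
  rownames(lg2) <- paste0("P", 1:25)
  m <- intensity_fixture(lg2, design)
  m2 <- m
  m2[, design$time_point == "TP2"] <- m2[, design$time_point == "TP2"] / 2
  lfc <- protein_log2fc(m, design)
  lfc2 <- protein_log2fc(m2, design)
  expect_equal(lfc2[, "TP2"], lfc[, "TP2"] - 1, tolerance = 1e-10)
})

test_that("zero intensities propagate as NA, never imputed", {
  design <- make_design(2, 2, "protein")
  m <- matrix(2^14, 4, 4, dimnames = list(paste0("P", 1:4), design$sample_id))
  m[1, design$time_point == "TP2"] <- 0
  lfc <- suppressWarnings(protein_log2fc(m, design))
  expect_true(is.na(lfc[1, "TP2"]))
  expect_false(anyNA(lfc[-1, ]))
})

test_that("stoichiometry ratios are median-centered per time point", {
  set.seed(31)
  lfc <- matrix(rnorm(50 * 3, -0.5, 0.4), 50, 3,
                dimnames = list(paste0("P", 1:50), c("TP1", "TP2", "TP3")))
  sr <- stoichiometry_ratio(lfc)
  expect_equal(unname(apply(sr, 2, median)), rep(0, 3), tolerance = 1e-10)
  # translation invariance: adding a constant to every protein changes nothing
  sr2 <- stoichiometry_ratio(lfc + 0.77)
  expect_equal(unname(sr2), unname(sr), tolerance = 1e-12, ignore_attr = TRUE)
  # identical changes across proteins collapse to zero SR
  same <- matrix(rep(c(0, -0.4, -1), each = 50), 50, 3,
                 dimnames = dimnames(lfc))
  expect_true(all(stoichiometry_ratio(same) == 0))
})

test_that("printed trend and SR values are arithmetically consistent", {
  # a protein whose log2 FC is -0.10 while the collective median is -1.04
  # must carry SR = 0.94
  lfc <- matrix(-1.04, 21, 2, dimnames = list(paste0("P", 1:21), c("TP1", "TP4")))
  lfc[, "TP1"] <- 0
  lfc[1:10, "TP4"] <- -1.04 + seq(-0.05, 0.05, length.out = 10) # keep the median at -1.04
  lfc[21, "TP4"] <- -0.10
  sr <- stoichiometry_ratio(lfc)
  expect_equal(unname(sr[21, "TP4"]), 0.94, tolerance = 1e-10)
})

test_that("deviation flagging needs repeated events and full scale equivariance holds", {
  cfg <- pipeline_config()
  design <- make_design(4, 3, "protein")
  set.seed(32)
  trend <- c(0, -0.35, -0.7, -1.04)
  lg2 <- outer(rnorm(50, 14, 1), trend, "+")
  rownames(lg2) <- paste0("P", 1:50)
  two_tp <- lg2; two_tp[1, 3:4] <- two_tp[1, 3:4] + 0.94
  one_tp <- lg2; one_tp[1, 4] <- one_tp[1, 4] + 0.94
  m_two <- intensity_fixture(two_tp, design, noise = 0.1)
  m_one <- intensity_fixture(one_tp, design, noise = 0.1)
  st_two <- stoichiometry_analysis(m_two, design, cfg)
  st_one <- stoichiometry_analysis(m_one, design, cfg)
  expect_true("P1" %in% st_two$rp_name[st_two$flagged])
  expect_false("P1" %in% st_one$rp_name[st_one$flagged])

  # global rescaling leaves log2 FC and SR untouched
  st_glob <- stoichiometry_analysis(m_two * 3.7, design, cfg)
  expect_equal(st_glob$log2fc, st_two$log2fc, tolerance = 1e-10)
  expect_equal(st_glob$sr, st_two$sr, tolerance = 1e-10)
  # per-time-point rescaling (replicates share a constant) shifts every
  # protein's log2 FC equally, so the centered SR and the flags are unchanged
  tp_scale <- c(TP1 = 1, TP2 = 0.5, TP3 = 2, TP4 = 1.3)
  st_scaled <- stoichiometry_analysis(
    sweep(m_two, 2, tp_scale[design$time_point], "*"), design, cfg)
  expect_equal(st_scaled$sr, st_two$sr, tolerance = 1e-10)
  expect_equal(st_scaled$flagged, st_two$flagged)
})

test_that("a zero-noise no-deviant fixture yields all-zero SR and no flags", {
  sim <- simulate_rp_proteomics(stoich_sim_params(replicate_sd = 0, seed = 2))
  st <- stoichiometry_analysis(sim$intensity, sim$design)
  expect_equal(st$sr, rep(0, nrow(st)), tolerance = 1e-10)
  expect_false(any(st$flagged))
})
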