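# Synthetic-data generators with planted ground truth. Every generator
# returns its truth alongside the data; analysis stages never see the truth.

REGULATORY_CLASSES <- c("TC+", "TC-", "COMP+", "COMP-", "TL+", "TL-", "NR",
                        "DISCORDANT", "NOT_ASSESSED")

# observed growth-phase class sizes, used as default class proportions
.default_class_counts <- c("TC+" = 442, "TC-" = 433, "COMP-" = 110,
                           "COMP+" = 79, "TL+" = 15, "TL-" = 24, "NR" = 304)

#' Simulation parameters for paired RNA/footprint counts
#'
#' @param te_slope Planted slope of TE (log2 units) per log10(TPM + 1) unit
#'   (default -1.10).
#' @param te_intercept Planted TE intercept in log2 units (default 2.2, which
#'   puts TE near zero at ~100 TPM).
#' @param te_scatter_sd Per-gene biological TE offset sd in log2 units
#'   (default 1.0, giving a TE~abundance Pearson R near -0.5).
#' @param nb_dispersion Shared negative-binomial dispersion (default 0.02;
#'   0 gives noise-free rounded means).
#' @param library_size Expected reads per sample, recycled over samples
#'   (default 5e6).
#' @param abundance_meanlog10,abundance_sdlog10 Log10-TPM distribution of
#'   baseline abundance (default N(2, 0.6), spanning the 10-10000 TPM bins).
#' @param fc_range Range of planted |log2 FC| for regulated directions
#'   (default 1.5 to 3).
#' @param null_fc_max Maximum |log2 FC| for unregulated directions
#'   (default 0.25).
#' @param tl_up_abundance_shift Shift (log10 units) applied to the baseline
#'   abundance of TL+ genes, which the study found to be low-abundance
#'   (default -0.8).
#' @param seed Integer seed.
#' @return A list of class `"sim_params"`.
#' @export
sim_params <- function(te_slope = -1.10, te_intercept = 2.2,
                       te_scatter_sd = 1.0, nb_dispersion = 0.02,
                       library_size = 5e6,
                       abundance_meanlog10 = 2, abundance_sdlog10 = 0.6,
                       fc_range = c(1.5, 3), null_fc_max = 0.25,
                       tl_up_abundance_shift = -0.8, seed = 1L) {
  stopifnot(nb_dispersion >= 0, all(library_size > 0),
            length(fc_range) == 2L, fc_range[1] > 0, diff(fc_range) >= 0,
            null_fc_max >= 0, te_scatter_sd >= 0)
  structure(list(te_slope = te_slope, te_intercept = te_intercept,
                 te_scatter_sd = te_scatter_sd, nb_dispersion = nb_dispersion,
                 library_size = library_size,
                 abundance_meanlog10 = abundance_meanlog10,
                 abundance_sdlog10 = abundance_sdlog10,
                 fc_range = fc_range, null_fc_max = null_fc_max,
                 tl_up_abundance_shift = tl_up_abundance_shift,
                 seed = as.integer(seed)),
            class = "sim_params")
}

#' Plant a per-gene regulatory truth table
#'
#' Draws baseline abundances, regulatory classes and consistent log2 fold
#' changes. Class proportions default to the relative sizes observed in the
#' growth-phase study (TC 875, COMP 189, TL 39, NR 304). Genes of class
#' `NOT_ASSESSED` are planted at very low abundance so that they fall under
#' the mean-count floor of the differential stage.
#'
#' @param n_genes Number of genes.
#' @param class_proportions Named numeric vector over a subset of
#'   `REGULATORY_CLASSES`; normalized to sum to 1.
#' @param params A [sim_params()] object (source of abundance and fold-change
#'   distributions and the seed).
#' @return A data frame with columns `gene_id`, `true_class`,
#'   `base_abundance_tpm`, `true_lfc_mrna`, `true_lfc_ribo`, `te_offset`,
#'   `is_rp`.
#' @export
simulate_truth <- function(n_genes,
                           class_proportions = NULL,
                           params = sim_params()) {
  if (is.null(class_proportions)) {
    class_proportions <- .default_class_counts
  }
  stopifnot(!is.null(names(class_proportions)),
            all(names(class_proportions) %in% REGULATORY_CLASSES),
            all(class_proportions >= 0), sum(class_proportions) > 0)
  set.seed(stage_seed(params$seed, "truth"))
  pr <- class_proportions / sum(class_proportions)
  n_cls <- round(pr * n_genes)
  # fix rounding drift on the largest class
  n_cls[which.max(n_cls)] <- n_cls[which.max(n_cls)] + (n_genes - sum(n_cls))
  cls <- rep(names(n_cls), times = n_cls)

  lg10 <- stats::rnorm(n_genes, params$abundance_meanlog10,
                       params$abundance_sdlog10)
  lg10[cls == "TL+"] <- lg10[cls == "TL+"] + params$tl_up_abundance_shift
  # essentially undetected: far below the differential stage's count floor
  lg10[cls == "NOT_ASSESSED"] <- stats::rnorm(sum(cls == "NOT_ASSESSED"), -2.5, 0.3)

  r_fc <- function(n) stats::runif(n, params$fc_range[1], params$fc_range[2])
  r_null <- function(n) stats::runif(n, -params$null_fc_max, params$null_fc_max)
  n <- n_genes
  lm_ <- r_null(n)
  lr_ <- r_null(n)
  up <- cls == "TC+"; lm_[up] <- r_fc(sum(up)); lr_[up] <- lm_[up] + stats::runif(sum(up), -0.2, 0.2)
  dn <- cls == "TC-"; lm_[dn] <- -r_fc(sum(dn)); lr_[dn] <- lm_[dn] + stats::runif(sum(dn), -0.2, 0.2)
  cm <- cls == "COMP-"; lm_[cm] <- r_fc(sum(cm))
  cp <- cls == "COMP+"; lm_[cp] <- -r_fc(sum(cp))
  tp <- cls == "TL+"; lr_[tp] <- r_fc(sum(tp))
  tn <- cls == "TL-"; lr_[tn] <- -r_fc(sum(tn))
  na <- cls == "NOT_ASSESSED"; lm_[na] <- 0; lr_[na] <- 0
  dc <- cls == "DISCORDANT"
  lm_[dc] <- r_fc(sum(dc)) * sample(c(-1, 1), sum(dc), replace = TRUE)
  lr_[dc] <- -sign(lm_[dc]) * r_fc(sum(dc))

  data.frame(
    gene_id = sprintf("VNG%04d", seq_len(n_genes)),
    true_class = cls,
    base_abundance_tpm = 10^lg10,
    true_lfc_mrna = lm_,
    true_lfc_ribo = lr_,
    te_offset = stats::rnorm(n_genes, 0, params$te_scatter_sd),
    is_rp = FALSE,
    stringsAsFactors = FALSE
  )
}

#' Simulate paired mRNA and footprint count matrices
#'
#' Mean model, on the TPM scale: the mRNA mean at the reference time point is
#' the planted baseline abundance and reaches `base * 2^true_lfc_mrna` at the
#' final time point, interpolating log-linearly in between. Translational
#' efficiency at the reference point follows the planted line
#' `te_intercept + te_slope * log10(TPM + 1)` plus the per-gene offset, and
#' the footprint mean scales by the interpolated `true_lfc_ribo`, so the
#' measured footprint log2 FC equals the planted one on the mean scale.
#' Counts are drawn negative-binomially with the shared dispersion
#' (deterministic rounded means when `nb_dispersion = 0`); TPM matrices are
#' derived from the counts with unit gene lengths.
#'
#' @param truth A truth table from [simulate_truth()].
#' @param design_rna,design_ribo Sample designs (defaults: 4 time points x 3
#'   replicates per assay).
#' @param params A [sim_params()] object.
#' @return A list with `mrna_counts`, `ribo_counts`, `mrna_tpm`, `ribo_tpm`,
#'   `design_rna`, `design_ribo`, `truth`, `params`.
#' @export
simulate_paired_counts <- function(truth,
                                   design_rna = make_design(assay = "rna"),
                                   design_ribo = make_design(assay = "ribo"),
                                   params = sim_params()) {
  set.seed(stage_seed(params$seed, "paired_counts"))
  tps <- unique(design_rna$time_point)
  n_tp <- length(tps)
  frac <- if (n_tp == 1) 0 else (seq_len(n_tp) - 1) / (n_tp - 1)
  base <- truth$base_abundance_tpm
  te1 <- params$te_intercept + params$te_slope * log10(base + 1) + truth$te_offset

  mean_tpm <- function(assay, k) {
    if (assay == "rna") base * 2^(frac[k] * truth$true_lfc_mrna)
    else base * 2^(te1 + frac[k] * truth$true_lfc_ribo)
  }
  draw <- function(design, assay) {
    libs <- rep_len(params$library_size, nrow(design))
    m <- matrix(0, nrow(truth), nrow(design),
                dimnames = list(truth$gene_id, design$sample_id))
    for (j in seq_len(nrow(design))) {
      k <- match(design$time_point[j], tps)
      mu_tpm <- mean_tpm(assay, k)
      mu <- mu_tpm / sum(mu_tpm) * libs[j]
      m[, j] <- if (params$nb_dispersion > 0) {
        stats::rnbinom(length(mu), mu = mu, size = 1 / params$nb_dispersion)
      } else {
        round(mu)
      }
    }
    m
  }
  mrna <- draw(design_rna, "rna")
  ribo <- draw(design_ribo, "ribo")
  to_tpm <- function(m) {
    cs <- colSums(m)
    cs[cs == 0] <- 1
    sweep(m, 2, cs, "/") * 1e6
  }
  list(mrna_counts = mrna, ribo_counts = ribo,
       mrna_tpm = to_tpm(mrna), ribo_tpm = to_tpm(ribo),
       design_rna = design_rna, design_ribo = design_ribo,
       truth = truth, params = params)
}

#' Parameters for the ribosomal-protein proteomics simulation
#'
#' @param n_rp Number of ribosomal proteins (default 50, the number detected
#'   in the ribosome-enriched fractions).
#' @param global_trend Per-time-point median log2 FC of the assembled-ribosome
#'   fraction relative to the reference (default 0, -0.35, -0.70, -1.04).
#' @param deviant_offsets Named list mapping an RP name to its per-time-point
#'   stoichiometry-ratio offsets (log2 units), e.g. the output of
#'   [default_deviant_rps()].
#' @param replicate_sd Replicate noise sd on the log2 intensity scale
#'   (default 0.1).
#' @param base_log2_intensity Mean/sd of baseline log2 intensities
#'   (default 14, 1).
#' @param seed Integer seed.
#' @return A list of class `"stoich_sim_params"`.
#' @export
stoich_sim_params <- function(n_rp = 50,
                              global_trend = c(0, -0.35, -0.70, -1.04),
                              deviant_offsets = list(),
                              replicate_sd = 0.1,
                              base_log2_intensity = c(14, 1),
                              seed = 1L) {
  stopifnot(n_rp >= 5, replicate_sd >= 0,
            all(vapply(deviant_offsets, function(x) all(is.finite(x)), TRUE)))
  structure(list(n_rp = as.integer(n_rp), global_trend = global_trend,
                 deviant_offsets = deviant_offsets,
                 replicate_sd = replicate_sd,
                 base_log2_intensity = base_log2_intensity,
                 seed = as.integer(seed)),
            class = "stoich_sim_params")
}

#' The study-mimicking set of planted stoichiometry deviants
#'
#' Five ribosomal proteins with the reported stoichiometry-ratio magnitudes
#' (S28E +0.94, L44E +0.39, S10-like -0.94, S13 -0.35, L24E -0.30), planted
#' at the last two time points of a four-point design.
#'
#' @param n_tp Number of time points (default 4).
#' @return A named list of per-time-point offset vectors.
#' @export
default_deviant_rps <- function(n_tp = 4) {
  mk <- function(sr) {
    v <- rep(0, n_tp)
    v[c(n_tp - 1, n_tp)] <- sr
    v
  }
  list(S28E = mk(0.94), L44E = mk(0.39), S10L = mk(-0.94),
       S13 = mk(-0.35), L24E = mk(-0.30))
}

#' Simulate ribosome-enriched fraction protein intensities
#'
#' Non-deviant RPs follow the global per-time-point trend plus replicate
#' noise; deviant RPs additionally carry their planted stoichiometry-ratio
#' offsets.
#'
#' @param params A [stoich_sim_params()] object.
#' @param design A protein sample design (default 4 time points x 3
#'   replicates).
#' @return A list with `intensity` (RP-by-sample matrix), `design`, and
#'   `truth` (planted offsets per RP and time point).
#' @export
simulate_rp_proteomics <- function(params = stoich_sim_params(),
                                   design = make_design(assay = "protein")) {
  set.seed(stage_seed(params$seed, "rp_proteomics"))
  tps <- unique(design$time_point)
  stopifnot(length(params$global_trend) == length(tps))
  dev_names <- names(params$deviant_offsets)
  n_other <- params$n_rp - length(dev_names)
  stopifnot(n_other >= 0)
  rps <- c(dev_names, sprintf("RP%02d", seq_len(n_other)))
  offsets <- matrix(0, params$n_rp, length(tps), dimnames = list(rps, tps))
  for (rp in dev_names) {
    stopifnot(length(params$deviant_offsets[[rp]]) == length(tps))
    offsets[rp, ] <- params$deviant_offsets[[rp]]
  }
  base <- stats::rnorm(params$n_rp, params$base_log2_intensity[1],
                       params$base_log2_intensity[2])
  m <- matrix(0, params$n_rp, nrow(design),
              dimnames = list(rps, design$sample_id))
  for (j in seq_len(nrow(design))) {
    k <- match(design$time_point[j], tps)
    lg <- base + params$global_trend[k] + offsets[, k] +
      stats::rnorm(params$n_rp, 0, params$replicate_sd)
    m[, j] <- 2^lg
  }
  list(intensity = m, design = design,
       truth = data.frame(rp_name = rps,
                          is_deviant = rps %in% dev_names,
                          offsets, check.names = FALSE,
                          stringsAsFactors = FALSE))
}

#' Simulate block-structured corem membership and a condition compendium
#'
#' Membership is block-diagonal (genes of class k sit in the corems of block
#' k) with each bit flipped independently with probability `noise_rate`.
#' The compendium gives genes of one class a shared per-condition response
#' (so corems of the same class have correlated expression signatures), plus
#' gene-level noise. Conditions are split into named categories.
#'
#' @param n_genes Number of genes placed in corems (default 54).
#' @param n_corems Number of corems (default 72).
#' @param class_sizes Planted class sizes, summing to `n_genes`
#'   (default 38, 7, 6, 3).
#' @param noise_rate Membership bit-flip probability in `[0, 0.5)`.
#' @param n_unassigned Additional genes present in no corem (default 0).
#' @param n_conditions Number of compendium conditions (default 135).
#' @param n_categories Number of condition categories (default 9).
#' @param class_effect_sd Sd of the shared per-class condition response
#'   (default 1.5).
#' @param gene_noise_sd Sd of gene-level expression noise (default 0.4).
#' @param seed Integer seed.
#' @return A list with `membership`, `truth` (gene/class), `compendium`,
#'   `condition_categories` (condition/category data frame).
#' @export
simulate_corems <- function(n_genes = 54, n_corems = 72,
                            class_sizes = c(38, 7, 6, 3),
                            noise_rate = 0.05, n_unassigned = 0,
                            n_conditions = 135, n_categories = 9,
                            class_effect_sd = 1.5, gene_noise_sd = 0.4,
                            seed = 1L) {
  stopifnot(sum(class_sizes) == n_genes, noise_rate >= 0, noise_rate < 0.5,
            n_corems >= length(class_sizes))
  set.seed(stage_seed(seed, "corems"))
  n_cls <- length(class_sizes)
  gene_cls <- rep(seq_len(n_cls), times = class_sizes)
  # corem blocks proportional to class sizes, at least 6 corems per class
  blk <- pmax(6L, as.integer(round(class_sizes / sum(class_sizes) * n_corems)))
  while (sum(blk) > n_corems) blk[which.max(blk)] <- blk[which.max(blk)] - 1L
  while (sum(blk) < n_corems) blk[which.max(class_sizes)] <- blk[which.max(class_sizes)] + 1L
  corem_cls <- rep(seq_len(n_cls), times = blk)

  genes <- sprintf("rpg%03d", seq_len(n_genes + n_unassigned))
  corems <- sprintf("corem%03d", seq_len(n_corems))
  m <- outer(gene_cls, corem_cls, "==") * 1L
  flip <- matrix(stats::runif(length(m)) < noise_rate, nrow(m))
  m <- abs(m - flip * 1L)
  if (n_unassigned > 0) m <- rbind(m, matrix(0L, n_unassigned, n_corems))
  dimnames(m) <- list(genes, corems)

  conds <- sprintf("cond%03d", seq_len(n_conditions))
  cat_of <- rep_len(sprintf("category_%d", seq_len(n_categories)), n_conditions)
  cat_of <- sort(cat_of)
  class_eff <- matrix(stats::rnorm(n_cls * n_conditions, 0, class_effect_sd),
                      n_cls, n_conditions)
  expr <- class_eff[c(gene_cls, rep_len(seq_len(n_cls), n_unassigned)), , drop = FALSE] +
    matrix(stats::rnorm((n_genes + n_unassigned) * n_conditions, 0, gene_noise_sd),
           n_genes + n_unassigned, n_conditions)
  dimnames(expr) <- list(genes, conds)

  list(membership = m,
       truth = data.frame(gene_id = genes,
                          true_class = c(gene_cls, rep(NA_integer_, n_unassigned)),
                          stringsAsFactors = FALSE),
       compendium = expr,
       condition_categories = data.frame(condition = conds, category = cat_of,
                                         stringsAsFactors = FALSE))
}

#' Simulate a planted-partition bait-prey interaction network
#'
#' Undirected edge sampling on a planted partition (within-module probability
#' `p_in`, between-module `p_out`), directed from the designated bait
#' endpoint. By default every node may act as a bait; with `n_baits` per
#' module only pairs touching a bait are eligible, mimicking a tagged-bait
#' immunoprecipitation screen.
#'
#' @param n_nodes Number of proteins (default 126).
#' @param n_modules Number of planted modules (default 7).
#' @param p_in,p_out Within/between-module edge probabilities (`p_in > p_out`).
#' @param n_baits Baits per module, or `NULL` (default) for all nodes.
#' @param rp_fraction Fraction of non-bait nodes annotated as ribosomal
#'   proteins (default 0.1).
#' @param seed Integer seed.
#' @return A list with `edges` (bait, prey, bait_role), `roles` (node role
#'   table), `truth` (node/module), `baits`.
#' @export
simulate_ppi <- function(n_nodes = 126, n_modules = 7, p_in = 0.8,
                         p_out = 0.05, n_baits = NULL, rp_fraction = 0.1,
                         seed = 1L) {
  stopifnot(p_in > p_out, p_in <= 1, p_out >= 0)
  set.seed(stage_seed(seed, "ppi"))
  nodes <- sprintf("P%03d", seq_len(n_nodes))
  module <- sort(rep_len(seq_len(n_modules), n_nodes))
  if (is.null(n_baits)) {
    baits <- nodes
  } else {
    baits <- unlist(lapply(seq_len(n_modules), function(k) {
      nodes[module == k][seq_len(min(n_baits, sum(module == k)))]
    }))
  }
  is_bait <- nodes %in% baits
  pairs <- utils::combn(n_nodes, 2)
  eligible <- is_bait[pairs[1, ]] | is_bait[pairs[2, ]]
  same <- module[pairs[1, ]] == module[pairs[2, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- eligible & (stats::runif(ncol(pairs)) < p)
  a <- pairs[1, keep]
  b <- pairs[2, keep]
  # direct from a bait endpoint; both baits -> lower index is the bait
  from_a <- is_bait[a]
  bait <- ifelse(from_a, nodes[a], nodes[b])
  prey <- ifelse(from_a, nodes[b], nodes[a])

  bait_role <- rep("other", n_nodes)
  names(bait_role) <- nodes
  roles <- c("TBP", "TFB", "Bat")
  bait_role[baits] <- rep_len(roles, length(baits))
  non_bait <- setdiff(nodes, baits)
  n_rp <- round(length(non_bait) * rp_fraction)
  rp_nodes <- if (n_rp > 0) sample(non_bait, n_rp) else character(0)
  role_tab <- data.frame(
    node = nodes,
    role = ifelse(nodes %in% rp_nodes, "RP", bait_role),
    subunit = NA_character_,
    stringsAsFactors = FALSE
  )
  role_tab$subunit[role_tab$role == "RP"] <-
    sample(c("small", "large"), sum(role_tab$role == "RP"), replace = TRUE)

  list(edges = data.frame(bait = bait, prey = prey,
                          bait_role = bait_role[bait],
                          stringsAsFactors = FALSE),
       roles = role_tab,
       truth = data.frame(node = nodes, module = module,
                          stringsAsFactors = FALSE),
       baits = baits)
}
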