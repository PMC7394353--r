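# Self-contained differential-abundance stage ("DE-lite"): median-of-ratios
# normalization, method-of-moments NB dispersion with shrinkage toward a
# fitted mean-dispersion trend, Wald test on the log2 fold change. An import
# path for externally computed results tables is provided so a full
# shrinkage-based fit can be slotted in instead.

#' Median-of-ratios size factors
#'
#' `factor_j = median over genes of count_gj / geometric mean_g(counts)`,
#' using only genes with nonzero counts in every sample.
#'
#' @param counts Gene-by-sample count matrix.
#' @return A named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  validate_counts(counts)
  use <- rowSums(counts == 0) == 0
  if (!any(use)) stop("no gene has nonzero counts in all samples")
  lg <- log(counts[use, , drop = FALSE])
  geo <- rowMeans(lg)
  sf <- apply(exp(lg - geo), 2, stats::median)
  if (any(!is.finite(sf)) || any(sf <= 0)) stop("degenerate size factors")
  sf
}

#' Benjamini-Hochberg adjustment with NA pass-through
#'
#' Step-up BH over the non-missing p-values (`m` = number tested); `NA`s are
#' preserved in place.
#'
#' @param pvalues Numeric vector of p-values in `[0,1]`, possibly with `NA`s.
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1)) stop("p-values outside [0,1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(pvalues[ok], method = "BH")
  out
}

# method-of-moments dispersion from two groups of normalized counts,
# shrunk 50/50 toward an a + b/mu trend fitted across genes
.moderated_dispersion <- function(q1, q2, mu1, mu2, mean_inv_sf, shrink = 0.5) {
  n1 <- ncol(q1); n2 <- ncol(q2)
  v1 <- if (n1 > 1) apply(q1, 1, stats::var) else rep(NA_real_, nrow(q1))
  v2 <- if (n2 > 1) apply(q2, 1, stats::var) else rep(NA_real_, nrow(q2))
  pool_v <- (v1 * (n1 - 1) + v2 * (n2 - 1)) / pmax(1, n1 + n2 - 2)
  mu <- (mu1 * n1 + mu2 * n2) / (n1 + n2)
  raw <- (pool_v - mu * mean_inv_sf) / mu^2
  raw[!is.finite(raw)] <- 0
  raw <- pmin(pmax(raw, 1e-8), 10)
  use <- mu > 0
  trend <- rep(1e-8, length(mu))
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a <- max(unname(stats::coef(fit)[1]), 1e-8)
    b <- max(unname(stats::coef(fit)[2]), 0)
    trend[use] <- a + b / mu[use]
  } else {
    trend[use] <- mean(raw[use])
  }
  pmin(pmax((1 - shrink) * raw + shrink * trend, 1e-8), 10)
}

#' Two-group differential test on counts
#'
#' Normalizes both groups jointly by median-of-ratios, estimates a moderated
#' gene-wise NB dispersion, and tests the log2 fold change
#' (group2 over group1) with a two-sided Wald statistic referred to a
#' moderated t distribution whose degrees of freedom credit the
#' across-gene dispersion trend with twice the gene-wise residual df
#' (for triplicates: 12 df). Genes whose overall mean normalized
#' count falls below the floor get `NA` adjusted p-values and are reported as
#' not assessed downstream.
#'
#' @param counts1,counts2 Count matrices for the reference and contrast
#'   groups (same genes, >= 2 replicates each unless `dispersion` is given).
#' @param cfg A [pipeline_config()].
#' @param dispersion Optional fixed dispersion (scalar or per-gene), replacing
#'   estimation; required when a group has a single replicate.
#' @param assay Label recorded in the result (`"rna"` or `"ribo"`).
#' @return A data frame of class `"differential_result"` with columns
#'   `gene_id`, `log2fc`, `se`, `stat`, `pvalue`, `padj`, `mean_expression`,
#'   `assay`.
#' @export
test_differential <- function(counts1, counts2, cfg = pipeline_config(),
                              dispersion = NULL, assay = "rna") {
  stopifnot(identical(rownames(counts1), rownames(counts2)))
  n1 <- ncol(counts1); n2 <- ncol(counts2)
  if (is.null(dispersion) && (n1 < 2 || n2 < 2)) {
    stop("single-replicate groups need an explicit dispersion")
  }
  all_counts <- cbind(counts1, counts2)
  sf <- size_factors(all_counts)
  sf1 <- sf[seq_len(n1)]; sf2 <- sf[n1 + seq_len(n2)]
  q1 <- sweep(counts1, 2, sf1, "/")
  q2 <- sweep(counts2, 2, sf2, "/")
  mu1 <- rowMeans(q1); mu2 <- rowMeans(q2)
  mu0 <- (mu1 * n1 + mu2 * n2) / (n1 + n2)

  disp <- if (is.null(dispersion)) {
    .moderated_dispersion(q1, q2, mu1, mu2, mean(1 / sf))
  } else {
    rep_len(dispersion, nrow(counts1))
  }

  pc <- 0.5 # symmetric pseudocount: lfc antisymmetric under group swap
  lfc <- log2((mu2 + pc) / (mu1 + pc))
  # delta-method variance of log2 group means under NB sampling
  v_grp <- function(mu, sfg, n) {
    (mu + pc) / n * mean(1 / sfg) + disp * (mu + pc)^2 / n
  }
  se <- sqrt(v_grp(mu1, sf1, n1) / (mu1 + pc)^2 +
             v_grp(mu2, sf2, n2) / (mu2 + pc)^2) / log(2)
  stat <- ifelse(lfc == 0, 0, lfc / se)
  # moderated-t reference: the dispersion trend is fitted across all genes,
  # which adds prior information worth about twice the gene-wise residual df
  df <- 3 * max(1, n1 + n2 - 2)
  pvalue <- 2 * stats::pt(-abs(stat), df = df)
  padj <- rep(NA_real_, length(pvalue))
  tested <- mu0 >= cfg$min_mean_count
  padj[tested] <- bh_adjust(pvalue[tested])

  res <- data.frame(gene_id = rownames(counts1), log2fc = lfc, se = se,
                    stat = stat, pvalue = pvalue, padj = padj,
                    mean_expression = mu0, assay = assay,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("differential_result", "data.frame")
  res
}

#' Differential test for one time-point contrast
#'
#' Convenience wrapper selecting the columns of `time_point` and
#' `reference` from a full count matrix via the design, then calling
#' [test_differential()].
#'
#' @param counts Full gene-by-sample count matrix.
#' @param design Sample design covering the matrix columns.
#' @param time_point Contrast time point (e.g. `"TP4"`).
#' @param reference Reference time point (default `"TP1"`).
#' @inheritParams test_differential
#' @return See [test_differential()].
#' @export
differential_expression <- function(counts, design, time_point,
                                    reference = "TP1",
                                    cfg = pipeline_config(),
                                    dispersion = NULL, assay = "rna") {
  c1 <- .tp_columns(counts, design, reference)
  c2 <- .tp_columns(counts, design, time_point)
  test_differential(c1, c2, cfg = cfg, dispersion = dispersion, assay = assay)
}

#' Import an externally computed differential results table
#'
#' Accepts a tab-separated table with columns `gene_id`, `log2fc`, `pvalue`,
#' `padj` (e.g. from a full shrinkage-based NB fit) so the downstream
#' classification runs unchanged on external results.
#'
#' @param path File path.
#' @param assay Label recorded in the result.
#' @return A `"differential_result"` data frame.
#' @export
import_differential <- function(path, assay = "rna") {
  df <- read_table(path, "differential")
  if (!"se" %in% names(df)) df$se <- NA_real_
  if (!"mean_expression" %in% names(df)) df$mean_expression <- NA_real_
  df$assay <- assay
  keep <- c("gene_id", "log2fc", "se", "pvalue", "padj", "mean_expression", "assay")
  res <- df[, keep]
  class(res) <- c("differential_result", "data.frame")
  res
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("Differential result (%s): %d genes, %d significant (padj < 0.05), %d not assessed\n",
              x$assay[1], nrow(x), sum(x$padj < 0.05, na.rm = TRUE),
              sum(is.na(x$padj))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...\n")
  invisible(x)
}
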