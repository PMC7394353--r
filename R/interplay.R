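# Core translatome statistics: regulatory-class assignment, translational
# efficiency, TE~abundance regression with residual analysis, permutation
# abundance null, binned rank tests, prediction-interval outliers.

#' Assign regulatory classes from paired differential results
#'
#' Per gene, with `sig(x) := |log2FC| > fc_threshold and padj < alpha`:
#' both assays significant with the same sign gives `TC+`/`TC-`
#' (transcriptional regulation, footprints follow transcripts); mRNA
#' significant up with non-significant footprints gives `COMP-` and mRNA down
#' gives `COMP+` (compensatory buffering); footprints significant alone give
#' `TL+`/`TL-` (translational regulation); neither significant is `NR`; both
#' significant with opposite signs is `DISCORDANT`; any missing adjusted p
#' gives `NOT_ASSESSED`.
#'
#' @param mrna,ribo `"differential_result"` tables over the same gene universe.
#' @param cfg A [pipeline_config()] supplying `fc_threshold` and `alpha`.
#' @return A data frame of class `"regulatory_classes"` with columns
#'   `gene_id`, `class`, `mrna_lfc`, `mrna_padj`, `ribo_lfc`, `ribo_padj`;
#'   class counts in `attr(, "counts")`.
#' @export
classify_regulation <- function(mrna, ribo, cfg = pipeline_config()) {
  if (!setequal(mrna$gene_id, ribo$gene_id)) {
    stop("mRNA and footprint results cover different gene universes")
  }
  ribo <- ribo[match(mrna$gene_id, ribo$gene_id), ]
  thr <- cfg$fc_threshold
  a <- cfg$alpha
  sig_m <- !is.na(mrna$padj) & mrna$padj < a & abs(mrna$log2fc) > thr
  sig_r <- !is.na(ribo$padj) & ribo$padj < a & abs(ribo$log2fc) > thr
  na_any <- is.na(mrna$padj) | is.na(ribo$padj)

  cls <- rep("NR", nrow(mrna))
  cls[sig_m & sig_r & sign(mrna$log2fc) == sign(ribo$log2fc) & mrna$log2fc > 0] <- "TC+"
  cls[sig_m & sig_r & sign(mrna$log2fc) == sign(ribo$log2fc) & mrna$log2fc < 0] <- "TC-"
  cls[sig_m & sig_r & sign(mrna$log2fc) != sign(ribo$log2fc)] <- "DISCORDANT"
  cls[sig_m & !sig_r & mrna$log2fc > 0] <- "COMP-"
  cls[sig_m & !sig_r & mrna$log2fc < 0] <- "COMP+"
  cls[!sig_m & sig_r & ribo$log2fc > 0] <- "TL+"
  cls[!sig_m & sig_r & ribo$log2fc < 0] <- "TL-"
  cls[na_any] <- "NOT_ASSESSED"

  out <- data.frame(gene_id = mrna$gene_id,
                    class = factor(cls, levels = REGULATORY_CLASSES),
                    mrna_lfc = mrna$log2fc, mrna_padj = mrna$padj,
                    ribo_lfc = ribo$log2fc, ribo_padj = ribo$padj,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$class)
  class(out) <- c("regulatory_classes", "data.frame")
  out
}

#' @export
print.regulatory_classes <- function(x, ...) {
  cat(sprintf("Regulatory classification of %d genes\n", nrow(x)))
  print(attr(x, "counts"))
  invisible(x)
}

#' Translational efficiency per gene
#'
#' TE is the log2 ratio of ribosome-footprint abundance over transcript
#' abundance, computed from replicate-summarized TPM (median by default)
#' within one time point. Genes with zero abundance in either assay get `NA`
#' and are excluded from the regression.
#'
#' @param rna_tpm,ribo_tpm Gene-by-sample TPM matrices for the two assays.
#' @param design_rna,design_ribo Sample designs for the matrix columns.
#' @param time_point Time point to summarize.
#' @param cfg A [pipeline_config()] (`te_summary` picks median or mean).
#' @return A data frame with columns `gene_id`, `te`, `tpm_rna`, `tpm_ribo`,
#'   `time_point`.
#' @export
compute_te <- function(rna_tpm, ribo_tpm, design_rna, design_ribo,
                       time_point, cfg = pipeline_config()) {
  stopifnot(identical(rownames(rna_tpm), rownames(ribo_tpm)))
  f <- if (cfg$te_summary == "median") stats::median else mean
  r <- apply(.tp_columns(rna_tpm, design_rna, time_point), 1, f)
  b <- apply(.tp_columns(ribo_tpm, design_ribo, time_point), 1, f)
  te <- ifelse(r > 0 & b > 0, log2(b / r), NA_real_)
  data.frame(gene_id = rownames(rna_tpm), te = te, tpm_rna = r, tpm_ribo = b,
             time_point = time_point, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Regress translational efficiency on transcript abundance
#'
#' Ordinary least squares of TE on `log10(TPM_rna + 1)`. The residuals are
#' each gene's deviation from the TE expected at its expression level; the
#' prediction interval supports outlier calls.
#'
#' @param te A TE table from [compute_te()] (rows with `NA` TE are dropped).
#' @param level Prediction-interval coverage (default 0.95).
#' @return An object of class `"te_fit"`: slope, intercept, Pearson `r`,
#'   two-sided p-value of the slope, residuals (named by gene), and the
#'   underlying `lm` fit.
#' @export
regress_te_on_abundance <- function(te, level = 0.95) {
  use <- !is.na(te$te)
  if (sum(use) < 3) stop("need at least 3 genes with defined TE")
  d <- data.frame(x = log10(te$tpm_rna[use] + 1), y = te$te[use],
                  gene_id = te$gene_id[use], stringsAsFactors = FALSE)
  if (stats::var(d$x) == 0) stop("degenerate abundance covariate (all equal)")
  fit <- stats::lm(y ~ x, data = d)
  sm <- summary(fit)
  pred <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level)
  )
  res <- stats::residuals(fit)
  names(res) <- d$gene_id
  out <- list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = if (stats::sd(d$y) == 0) 0 else unname(stats::cor(d$x, d$y)),
    r_squared = sm$r.squared,
    pvalue = unname(sm$coefficients[2, 4]),
    n = nrow(d),
    residuals = res,
    pi_halfwidth = unname((pred[, "upr"] - pred[, "lwr"]) / 2),
    level = level,
    lm = fit,
    data = d,
    time_point = te$time_point[1]
  )
  class(out) <- "te_fit"
  out
}

#' @export
print.te_fit <- function(x, ...) {
  cat(sprintf("TE ~ log10(TPM + 1) regression (%s, n = %d)\n",
              x$time_point, x$n))
  cat(sprintf("  slope a = %.4f, intercept = %.4f\n", x$slope, x$intercept))
  cat(sprintf("  Pearson R = %.4f (R^2 = %.4f), slope p = %.3g\n",
              x$r, x$r_squared, x$pvalue))
  invisible(x)
}

#' @export
coef.te_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
residuals.te_fit <- function(object, ...) object$residuals

#' @export
predict.te_fit <- function(object, newdata = NULL, interval = "prediction", ...) {
  if (is.null(newdata)) {
    stats::predict(object$lm, interval = interval, level = object$level, ...)
  } else {
    stats::predict(object$lm, newdata = newdata, interval = interval,
                   level = object$level, ...)
  }
}

#' @export
plot.te_fit <- function(x, ...) {
  d <- x$data[order(x$data$x), ]
  pred <- stats::predict(x$lm, newdata = d, interval = "prediction",
                         level = x$level)
  graphics::plot(x$data$x, x$data$y, pch = 16, cex = 0.4,
                 col = grDevices::grey(0.4, 0.5),
                 xlab = "log10(TPM + 1)", ylab = "TE (log2 footprints/mRNA)",
                 ...)
  graphics::polygon(c(d$x, rev(d$x)), c(pred[, "lwr"], rev(pred[, "upr"])),
                    col = grDevices::grey(0.8, 0.4), border = NA)
  graphics::abline(x$lm, lwd = 2)
  invisible(x)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test wrapper returning the U statistic for the first
#' sample. Exact enumeration when `n1 + n2 <= 8` without ties, normal
#' approximation with tie/continuity correction otherwise.
#'
#' @param x,y Numeric samples.
#' @return A list with `U`, `p`, `n1`, `n2`.
#' @export
mw_u_test <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 8) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE)
  )
  list(U = unname(ht$statistic), p = ht$p.value,
       n1 = length(x), n2 = length(y))
}

#' Compare TE deviations between transcriptional groups within abundance bins
#'
#' Residuals from the TE regression ("deviation from the TE expected at a
#' gene's expression") are compared between transcriptionally up- and
#' downregulated genes, and each against non-differentially expressed genes,
#' within half-open abundance bins (low, medium, high). Comparison is a
#' two-sided Mann-Whitney U test; bins with fewer than 3 genes on a side are
#' reported untestable.
#'
#' @param fit A `"te_fit"` from [regress_te_on_abundance()].
#' @param mrna The mRNA `"differential_result"` defining the groups: up/down
#'   are significant by `cfg`; non-DET is `padj >= alpha` at the transcript
#'   level.
#' @param cfg A [pipeline_config()] (`abundance_bins` gives the bin edges).
#' @return A data frame with one row per bin and comparison: `bin`,
#'   `comparison`, `n1`, `n2`, `U`, `p`, `significance`.
#' @export
te_deviation_by_group <- function(fit, mrna, cfg = pipeline_config()) {
  res <- fit$residuals
  d <- fit$data
  m <- mrna[match(d$gene_id, mrna$gene_id), ]
  sig <- !is.na(m$padj) & m$padj < cfg$alpha & abs(m$log2fc) > cfg$fc_threshold
  group <- rep(NA_character_, nrow(d))
  group[sig & m$log2fc > 0] <- "up"
  group[sig & m$log2fc < 0] <- "down"
  group[!is.na(m$padj) & m$padj >= cfg$alpha] <- "non_det"

  edges <- cfg$abundance_bins
  labels <- if (length(edges) == 4) c("low", "medium", "high") else
    paste0("bin", seq_len(length(edges) - 1))
  tpm <- 10^d$x - 1
  bin <- cut(tpm, breaks = edges, labels = labels, right = TRUE)

  comps <- list(c("up", "down"), c("up", "non_det"), c("down", "non_det"))
  rows <- list()
  for (b in labels) {
    for (cmp in comps) {
      i1 <- which(!is.na(bin) & bin == b & group %in% cmp[1])
      i2 <- which(!is.na(bin) & bin == b & group %in% cmp[2])
      if (length(i1) >= 3 && length(i2) >= 3) {
        t_ <- mw_u_test(res[i1], res[i2])
        star <- if (t_$p < 0.01) "**" else if (t_$p < 0.05) "*" else "ns"
        rows[[length(rows) + 1]] <- data.frame(
          bin = b, comparison = paste(cmp, collapse = " vs "),
          n1 = t_$n1, n2 = t_$n2, U = t_$U, p = t_$p, significance = star,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          bin = b, comparison = paste(cmp, collapse = " vs "),
          n1 = length(i1), n2 = length(i2), U = NA_real_, p = NA_real_,
          significance = "untestable", stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Permutation test for the mean abundance of a gene set
#'
#' Compares the mean abundance of a gene set against `n_perm` uniformly drawn
#' gene sets of the same size (without replacement within each draw). The
#' empirical p-value for `tail = "lower"` is
#' `(#\{null mean <= observed\} + 1) / (n_perm + 1)`.
#'
#' @param gene_set Character vector of gene ids (non-empty, within the
#'   universe).
#' @param abundance Named per-gene abundance vector (the universe).
#' @param n_perm Number of random sets.
#' @param seed Integer seed.
#' @param tail `"lower"` (default), `"upper"`, or `"two"`.
#' @return A list of class `"perm_test"`: `p`, `observed`, `null_mean`,
#'   `null_sd`, `null_quantiles`, `n_perm`, `tail`, `set_size`.
#' @export
permutation_abundance_test <- function(gene_set, abundance, n_perm = 1e4,
                                       seed = 1L,
                                       tail = c("lower", "upper", "two")) {
  tail <- match.arg(tail)
  stopifnot(length(gene_set) >= 1, !is.null(names(abundance)))
  miss <- setdiff(gene_set, names(abundance))
  if (length(miss)) stop("gene set outside universe: ", paste(miss, collapse = ", "))
  m <- length(gene_set)
  if (m > length(abundance)) stop("gene set larger than universe")
  set.seed(seed)
  obs <- mean(abundance[gene_set])
  ab <- unname(abundance)
  n_univ <- length(ab)
  null <- vapply(seq_len(n_perm),
                 function(i) mean(ab[sample.int(n_univ, m)]), numeric(1))
  p_lo <- (sum(null <= obs) + 1) / (n_perm + 1)
  p_hi <- (sum(null >= obs) + 1) / (n_perm + 1)
  p <- switch(tail, lower = p_lo, upper = p_hi, two = min(1, 2 * min(p_lo, p_hi)))
  out <- list(p = p, observed = obs, null_mean = mean(null),
              null_sd = stats::sd(null),
              null_quantiles = stats::quantile(null, c(0.025, 0.5, 0.975)),
              n_perm = n_perm, tail = tail, set_size = m)
  class(out) <- "perm_test"
  out
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation abundance test (n = %d genes, %d permutations, %s tail)\n",
              x$set_size, x$n_perm, x$tail))
  cat(sprintf("  observed mean = %.4g, null mean = %.4g (sd %.4g)\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  empirical p = %.4g\n", x$p))
  invisible(x)
}

#' Prediction-interval outliers of a y~x regression
#'
#' Fits OLS of `y` on `x` and flags points whose `y` falls outside the
#' per-point prediction interval — e.g. footprint log2 fold changes not
#' explained by transcript fold changes.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @param gene_ids Optional point labels.
#' @param level Interval coverage (default 0.95).
#' @return A list with `slope`, `intercept`, `r`, `pvalue`, and `table`
#'   (a data frame with `gene_id`, `x`, `y`, `fit`, `lwr`, `upr`, `outlier`).
#' @export
prediction_interval_outliers <- function(x, y, gene_ids = NULL, level = 0.95) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("degenerate x (all equal)")
  if (is.null(gene_ids)) gene_ids <- paste0("g", seq_along(x))
  fit <- stats::lm(y ~ x)
  pred <- suppressWarnings(
    stats::predict(fit, interval = "prediction", level = level)
  )
  tab <- data.frame(gene_id = gene_ids, x = x, y = y,
                    fit = pred[, "fit"], lwr = pred[, "lwr"], upr = pred[, "upr"],
                    outlier = y < pred[, "lwr"] | y > pred[, "upr"],
                    row.names = NULL, stringsAsFactors = FALSE)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y),
       pvalue = unname(sm$coefficients[2, 4]),
       level = level,
       table = tab)
}

#' Convert a log2 fold change to a linear fold change
#'
#' @param lfc Finite numeric vector of log2 fold changes.
#' @return A data frame with `log2fc`, `fold` (`2^|lfc|`) and `direction`
#'   (`"up"`, `"down"`, `"none"`).
#' @export
log2fc_to_fold <- function(lfc) {
  stopifnot(all(is.finite(lfc)))
  data.frame(log2fc = lfc, fold = 2^abs(lfc),
             direction = c("down", "none", "up")[sign(lfc) + 2],
             stringsAsFactors = FALSE)
}
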