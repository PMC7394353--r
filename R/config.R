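#' Pipeline configuration
#'
#' Collects every tunable threshold used by the analysis stages in one
#' validated object. All fold changes are in log2 units and all abundances in
#' TPM unless a table is explicitly declared "normalized counts".
#'
#' @param fc_threshold Absolute log2 fold-change threshold for calling a gene
#'   regulated (default 1, i.e. two-fold).
#' @param alpha Significance level for adjusted p-values (default 0.05).
#' @param n_permutations Number of random gene sets drawn by
#'   [permutation_abundance_test()] (default 1e6).
#' @param n_bootstrap Number of column resamples used by
#'   [bootstrap_cluster_support()] (default 1e4).
#' @param ci_level Coverage of percentile / prediction intervals (default 0.95).
#' @param min_deviation_events Minimum number of per-time-point deviation
#'   events before a ribosomal protein is flagged (default 2).
#' @param srcc_threshold Minimum Spearman rank correlation for two corem
#'   expression signatures to count as similar (default 0.4).
#' @param abundance_bins Strictly increasing breakpoints delimiting the
#'   low/medium/high expression bins, in TPM (default 10, 100, 1000, 10000).
#'   Intervals are half-open: lower edge exclusive, upper inclusive.
#' @param min_mean_count Mean-normalized-count floor below which a gene is not
#'   assessed (adjusted p set to `NA`; default 1).
#' @param te_summary How replicate TPM values are summarized within a time
#'   point before the TE log ratio: `"median"` (default) or `"mean"`.
#' @param sr_center Centering statistic for the stoichiometry ratio:
#'   `"median"` (default) or `"mean"`.
#' @param random_seed Integer seed from which per-stage seeds are derived.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(fc_threshold = 1,
                            alpha = 0.05,
                            n_permutations = 1e6,
                            n_bootstrap = 1e4,
                            ci_level = 0.95,
                            min_deviation_events = 2,
                            srcc_threshold = 0.4,
                            abundance_bins = c(10, 100, 1000, 10000),
                            min_mean_count = 1,
                            te_summary = c("median", "mean"),
                            sr_center = c("median", "mean"),
                            random_seed = 1L) {
  te_summary <- match.arg(te_summary)
  sr_center <- match.arg(sr_center)
  stopifnot(
    is.numeric(fc_threshold), length(fc_threshold) == 1L, fc_threshold > 0,
    is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1,
    is.numeric(n_permutations), n_permutations >= 1,
    is.numeric(n_bootstrap), n_bootstrap >= 1,
    is.numeric(ci_level), ci_level > 0, ci_level < 1,
    is.numeric(min_deviation_events), min_deviation_events >= 1,
    is.numeric(srcc_threshold),
    is.numeric(abundance_bins), length(abundance_bins) >= 2,
    is.numeric(min_mean_count), min_mean_count >= 0
  )
  if (any(diff(abundance_bins) <= 0)) {
    stop("'abundance_bins' must be strictly increasing")
  }
  cfg <- list(
    fc_threshold = fc_threshold,
    alpha = alpha,
    n_permutations = as.integer(n_permutations),
    n_bootstrap = as.integer(n_bootstrap),
    ci_level = ci_level,
    min_deviation_events = as.integer(min_deviation_events),
    srcc_threshold = srcc_threshold,
    abundance_bins = abundance_bins,
    min_mean_count = min_mean_count,
    te_summary = te_summary,
    sr_center = sr_center,
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  |log2 FC| threshold : %g\n", x$fc_threshold))
  cat(sprintf("  alpha               : %g\n", x$alpha))
  cat(sprintf("  permutations        : %d\n", x$n_permutations))
  cat(sprintf("  bootstrap resamples : %d\n", x$n_bootstrap))
  cat(sprintf("  interval level      : %g\n", x$ci_level))
  cat(sprintf("  min deviation events: %d\n", x$min_deviation_events))
  cat(sprintf("  SRCC threshold      : %g\n", x$srcc_threshold))
  cat(sprintf("  abundance bins      : %s\n",
              paste(x$abundance_bins, collapse = ", ")))
  cat(sprintf("  mean-count floor    : %g\n", x$min_mean_count))
  cat(sprintf("  TE replicate summary: %s\n", x$te_summary))
  cat(sprintf("  SR centering        : %s\n", x$sr_center))
  cat(sprintf("  seed                : %d\n", x$random_seed))
  invisible(x)
}

#' Read / write a pipeline configuration file
#'
#' The configuration is stored as YAML with fields mirroring
#' [pipeline_config()].
#'
#' @param path File path.
#' @return `read_config()` returns a `"pipeline_config"`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' @rdname read_config
#' @param cfg A `"pipeline_config"` object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Derive a per-stage seed from the master seed
#'
#' A single configured seed fans out into one seed per stage by stable hashing
#' of the stage name, so a stage is reproducible independently of execution
#' order.
#'
#' @param seed Integer master seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}
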