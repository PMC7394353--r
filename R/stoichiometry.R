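# Ribosomal-protein abundance and stoichiometry within the assembled-ribosome
# fraction: replicate-median log2 fold changes, centering against the
# collective trend, percentile-interval deviation events.

#' Per-protein log2 fold changes versus the reference time point
#'
#' Per protein and time point: log2 of the replicate-median intensity at the
#' time point over the replicate median at the reference. Zero or missing
#' intensities propagate as `NA` (dropouts are informative; nothing is
#' imputed).
#'
#' @param intensity Protein-by-sample intensity matrix (non-negative).
#' @param design Protein sample design.
#' @param reference_tp Reference time point (default `"TP1"`).
#' @return A protein-by-time-point matrix of log2 fold changes (reference
#'   column included, all zeros); per-time-point detection counts in
#'   `attr(, "n_detected")`.
#' @export
protein_log2fc <- function(intensity, design, reference_tp = "TP1") {
  tps <- unique(design$time_point)
  if (!reference_tp %in% tps) stop("reference time point absent: ", reference_tp)
  med <- sapply(tps, function(tp) {
    apply(.tp_columns(intensity, design, tp), 1, stats::median)
  })
  med[med <= 0] <- NA_real_
  if (all(is.na(med[, reference_tp]))) {
    stop("no protein detected at the reference time point")
  }
  lfc <- log2(med / med[, reference_tp])
  attr(lfc, "n_detected") <- colSums(!is.na(lfc))
  lfc
}

#' Stoichiometry ratio: deviation from the collective trend
#'
#' The stoichiometry ratio of a protein at a time point is its log2 fold
#' change minus the per-time-point center (median by default) over all
#' detected proteins, so the per-time-point median SR is 0 by construction.
#'
#' @param log2fc A protein-by-time-point log2 FC matrix from
#'   [protein_log2fc()].
#' @param cfg A [pipeline_config()] (`sr_center` picks median or mean).
#' @return A matrix of the same shape; per-time-point centers in
#'   `attr(, "trend")`.
#' @export
stoichiometry_ratio <- function(log2fc, cfg = pipeline_config()) {
  if (any(colSums(!is.na(log2fc)) == 0)) stop("time point with no detected protein")
  if (any(colSums(!is.na(log2fc)) < 5)) {
    warning("fewer than 5 detected proteins at some time point")
  }
  f <- if (cfg$sr_center == "median") stats::median else mean
  trend <- apply(log2fc, 2, f, na.rm = TRUE)
  sr <- sweep(log2fc, 2, trend, "-")
  attr(sr, "trend") <- trend
  sr
}

#' Flag proteins with repeated stoichiometry deviations
#'
#' Per non-reference time point, an SR outside the central `ci_level`
#' interval of the cross-protein SR distribution is a deviation event; a
#' protein is flagged when it accumulates at least `min_deviation_events`
#' events. The default interval is robust — `median +/- z * 1.4826 * MAD` —
#' so that the deviants being hunted do not widen the interval that is
#' supposed to catch them; `interval = "percentile"` uses the raw
#' `(2.5, 97.5)` percentile range instead.
#'
#' @param sr An SR matrix from [stoichiometry_ratio()].
#' @param cfg A [pipeline_config()] (`ci_level`, `min_deviation_events`).
#' @param reference_tp Reference time point, excluded from event counting.
#' @param interval `"robust"` (default) or `"percentile"`.
#' @return A long data frame of class `"stoich_table"` with columns
#'   `rp_name`, `time_point`, `log2fc`, `sr`, `deviation_event`, `n_events`,
#'   `flagged`; interval bounds in `attr(, "intervals")`.
#' @export
flag_deviant_rps <- function(sr, cfg = pipeline_config(), reference_tp = "TP1",
                             interval = c("robust", "percentile")) {
  interval <- match.arg(interval)
  if (nrow(sr) < 20) warning("fewer than 20 proteins: interval unstable")
  lfc <- sweep(sr, 2, attr(sr, "trend"), "+")
  tps <- setdiff(colnames(sr), reference_tp)
  lo <- (1 - cfg$ci_level) / 2
  ints <- sapply(tps, function(tp) {
    if (interval == "robust") {
      ctr <- stats::median(sr[, tp], na.rm = TRUE)
      hw <- stats::qnorm(1 - lo) * stats::mad(sr[, tp], na.rm = TRUE)
      c(ctr - hw, ctr + hw)
    } else {
      stats::quantile(sr[, tp], c(lo, 1 - lo), na.rm = TRUE, names = FALSE)
    }
  })
  rownames(ints) <- c("lower", "upper")
  eps <- 1e-8 # guard against float jitter when the SR spread is exactly zero
  ev <- sapply(tps, function(tp) {
    e <- sr[, tp] < ints["lower", tp] - eps | sr[, tp] > ints["upper", tp] + eps
    e & !is.na(e)
  })
  n_events <- rowSums(ev)
  flagged <- n_events >= cfg$min_deviation_events

  out <- do.call(rbind, lapply(colnames(sr), function(tp) {
    data.frame(rp_name = rownames(sr), time_point = tp,
               log2fc = lfc[, tp], sr = sr[, tp],
               deviation_event = if (tp %in% tps) ev[, tp] else FALSE,
               n_events = n_events, flagged = flagged,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "intervals") <- ints
  attr(out, "trend") <- attr(sr, "trend")
  class(out) <- c("stoich_table", "data.frame")
  out
}

#' @export
print.stoich_table <- function(x, ...) {
  n_rp <- length(unique(x$rp_name))
  fl <- unique(x$rp_name[x$flagged])
  cat(sprintf("Stoichiometry table: %d proteins x %d time points\n",
              n_rp, length(unique(x$time_point))))
  cat(sprintf("  collective trend (log2 FC): %s\n",
              paste(sprintf("%.2f", attr(x, "trend")), collapse = ", ")))
  if (length(fl)) {
    cat(sprintf("  flagged (>= %d deviation events): %s\n",
                min(x$n_events[x$flagged]), paste(fl, collapse = ", ")))
  } else {
    cat("  no protein flagged\n")
  }
  invisible(x)
}

#' Full stoichiometry stage
#'
#' Chains [protein_log2fc()], [stoichiometry_ratio()] and
#' [flag_deviant_rps()].
#'
#' @inheritParams protein_log2fc
#' @inheritParams stoichiometry_ratio
#' @return A `"stoich_table"`.
#' @export
stoichiometry_analysis <- function(intensity, design, cfg = pipeline_config(),
                                   reference_tp = "TP1") {
  lfc <- protein_log2fc(intensity, design, reference_tp)
  sr <- stoichiometry_ratio(lfc, cfg)
  flag_deviant_rps(sr, cfg, reference_tp)
}
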