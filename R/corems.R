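# Corem-membership clustering: binary distance, UPGMA, bootstrap clade
# support, class selection, and condition-specific expression similarity
# between corem classes.

#' Binary distance between gene membership profiles
#'
#' `d(g, h)` is the number of corems containing exactly one of the two genes
#' divided by the number containing at least one — the asymmetric binary
#' (Jaccard) dissimilarity. Genes present in no corem are excluded.
#'
#' @param membership Binary gene-by-corem matrix.
#' @return A symmetric gene-by-gene distance matrix with zero diagonal;
#'   excluded genes in `attr(, "excluded")`.
#' @export
binary_distance <- function(membership) {
  validate_membership(membership)
  keep <- rowSums(membership) > 0
  if (sum(keep) < 2) stop("fewer than 2 genes with any corem membership")
  m <- membership[keep, , drop = FALSE]
  d <- as.matrix(stats::dist(m, method = "binary"))
  attr(d, "excluded") <- rownames(membership)[!keep]
  d
}

# distance for bootstrap resamples: genes that end up with no membership in
# the resampled columns are identical all-zero profiles -> distance 0
.boot_distance <- function(m) {
  d <- stats::dist(m, method = "binary")
  d[is.nan(d)] <- 0
  d
}

#' Average-linkage (UPGMA) clustering
#'
#' @param d A symmetric distance matrix (or `dist`) with zero diagonal.
#' @return An `hclust` tree.
#' @export
upgma_cluster <- function(d) {
  if (is.matrix(d)) {
    stopifnot(isSymmetric(unname(d)), all(diag(d) == 0))
    d <- stats::as.dist(d)
  }
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  stats::hclust(d, method = "average")
}

# every internal-node clade of an hclust tree as a sorted label key
.clade_keys <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", nrow(hc$merge))
  keys <- character(nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    mem <- unlist(lapply(hc$merge[i, ], function(j) {
      if (j < 0) hc$labels[-j] else sets[[j]]
    }))
    sets[[i]] <- mem
    keys[i] <- paste(sort(mem), collapse = "\r")
  }
  list(sets = sets, keys = keys)
}

#' Bootstrap support for membership-based gene classes
#'
#' Resamples corems (columns) with replacement `n_boot` times, recomputes the
#' binary distance and UPGMA tree each time, and scores every clade of the
#' observed tree by the fraction of resampled trees containing it (ordinary
#' bootstrap probability). Classes are the maximal supported clades: clades
#' with support at or above the threshold that are not contained in a larger
#' supported clade, excluding the root and singletons. Genes outside every
#' such clade are `unassigned`; genes in no corem are excluded beforehand.
#'
#' @param membership Binary gene-by-corem matrix.
#' @param n_boot Number of resamples (default 10000; < 100 warns).
#' @param seed Integer seed.
#' @param support_threshold Minimum clade support (default 0.95).
#' @return A data frame of class `"corem_classes"` with columns `gene_id`,
#'   `class_label` (Roman numerals by decreasing size, or `"unassigned"`),
#'   `cluster_support`. Attributes: `tree` (the observed `hclust`),
#'   `clade_support` (named support vector), `excluded`, `n_boot`.
#' @export
bootstrap_cluster_support <- function(membership, n_boot = 10000, seed = 1L,
                                      support_threshold = 0.95) {
  if (n_boot < 100) warning("n_boot < 100: supports will be unstable")
  d0 <- binary_distance(membership)
  excluded <- attr(d0, "excluded")
  genes <- rownames(d0)
  if (length(genes) < 3) stop("need at least 3 genes in corems")
  m <- membership[genes, , drop = FALSE]
  hc0 <- upgma_cluster(d0)
  cl0 <- .clade_keys(hc0)
  count <- stats::setNames(integer(length(cl0$keys)), cl0$keys)

  set.seed(seed)
  nc <- ncol(m)
  n_g <- nrow(m)
  for (b in seq_len(n_boot)) {
    # permuting gene order makes tie-breaking unbiased, so clade supports are
    # invariant in expectation to input order even on exactly tied distances
    mb <- m[sample.int(n_g), sample.int(nc, nc, replace = TRUE), drop = FALSE]
    hb <- stats::hclust(.boot_distance(mb), method = "average")
    kb <- .clade_keys(hb)$keys
    hit <- intersect(kb, cl0$keys)
    count[hit] <- count[hit] + 1L
  }
  support <- count / n_boot

  n <- length(genes)
  sizes <- lengths(cl0$sets)
  ok <- support >= support_threshold & sizes < n & sizes >= 2
  # maximal: drop supported clades contained in a larger supported clade
  ord <- order(sizes[ok], decreasing = TRUE)
  idx <- which(ok)[ord]
  chosen <- list()
  for (i in idx) {
    s <- cl0$sets[[i]]
    contained <- any(vapply(chosen, function(ch) all(s %in% ch$set), TRUE))
    if (!contained) chosen[[length(chosen) + 1]] <- list(set = s, support = support[i])
  }
  label <- stats::setNames(rep("unassigned", n), genes)
  supp <- stats::setNames(rep(NA_real_, n), genes)
  if (length(chosen)) {
    ord2 <- order(vapply(chosen, function(ch) length(ch$set), 1L), decreasing = TRUE)
    roman <- as.character(utils::as.roman(seq_along(chosen)))
    for (k in seq_along(ord2)) {
      ch <- chosen[[ord2[k]]]
      label[ch$set] <- roman[k]
      supp[ch$set] <- ch$support
    }
  }
  out <- data.frame(gene_id = genes, class_label = unname(label[genes]),
                    cluster_support = unname(supp[genes]),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "tree") <- hc0
  attr(out, "clade_support") <- support
  attr(out, "excluded") <- excluded
  attr(out, "n_boot") <- n_boot
  class(out) <- c("corem_classes", "data.frame")
  out
}

#' @export
print.corem_classes <- function(x, ...) {
  tab <- table(x$class_label)
  cat(sprintf("Corem-membership classes for %d genes (%d bootstrap resamples)\n",
              nrow(x), attr(x, "n_boot")))
  for (cl in setdiff(names(tab), "unassigned")) {
    cat(sprintf("  class %-4s: %2d genes, support %.3f\n", cl, tab[[cl]],
                unique(x$cluster_support[x$class_label == cl])))
  }
  if ("unassigned" %in% names(tab)) {
    cat(sprintf("  unassigned: %2d genes\n", tab[["unassigned"]]))
  }
  if (length(attr(x, "excluded"))) {
    cat(sprintf("  excluded (no corem): %s\n",
                paste(attr(x, "excluded"), collapse = ", ")))
  }
  invisible(x)
}

#' Expression signature of a corem
#'
#' Per condition, the median (and interquartile range) of expression across
#' the corem's member genes present in the compendium.
#'
#' @param compendium Gene-by-condition expression matrix.
#' @param member_genes Character vector of member gene ids.
#' @param corem_id Optional corem identifier recorded on the result.
#' @return A data frame with columns `condition`, `median`, `q1`, `q3`.
#' @export
corem_signature <- function(compendium, member_genes, corem_id = NULL) {
  genes <- intersect(unique(member_genes), rownames(compendium))
  if (!length(genes)) stop("no member gene present in the compendium")
  e <- compendium[genes, , drop = FALSE]
  out <- data.frame(
    condition = colnames(compendium),
    median = apply(e, 2, stats::median),
    q1 = apply(e, 2, stats::quantile, 0.25, names = FALSE),
    q3 = apply(e, 2, stats::quantile, 0.75, names = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "corem_id") <- corem_id
  attr(out, "n_genes") <- length(genes)
  out
}

#' Decide whether two corems share an expression signature
#'
#' Spearman rank correlation plus a two-sample Kolmogorov-Smirnov test on the
#' two median-expression signatures. The corems are "similar" (no significant
#' expression difference) when the correlation is positive and significant
#' (SRCC above the threshold, p below alpha) and the KS test is
#' non-significant. A constant signature leaves the correlation undefined:
#' not similar, flagged degenerate.
#'
#' @param sig_a,sig_b Signatures from [corem_signature()] over the same
#'   condition set.
#' @param cfg A [pipeline_config()] (`srcc_threshold`, `alpha`).
#' @return A list of class `"similarity_decision"`: `srcc`, `srcc_p`, `ks_d`,
#'   `ks_p`, `similar`, `degenerate`.
#' @export
corem_pair_similarity <- function(sig_a, sig_b, cfg = pipeline_config()) {
  stopifnot(identical(sig_a$condition, sig_b$condition))
  a <- sig_a$median
  b <- sig_b$median
  n <- length(a)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    out <- list(srcc = NA_real_, srcc_p = NA_real_, ks_d = NA_real_,
                ks_p = NA_real_, similar = FALSE, degenerate = TRUE)
    class(out) <- "similarity_decision"
    return(out)
  }
  ct <- suppressWarnings(
    stats::cor.test(a, b, method = "spearman", exact = n <= 9)
  )
  ks <- suppressWarnings(stats::ks.test(a, b, exact = max(n, n) <= 25))
  out <- list(srcc = unname(ct$estimate), srcc_p = ct$p.value,
              ks_d = unname(ks$statistic), ks_p = ks$p.value,
              similar = unname(ct$estimate) > cfg$srcc_threshold &&
                ct$p.value < cfg$alpha && ks$p.value > cfg$alpha,
              degenerate = FALSE)
  class(out) <- "similarity_decision"
  out
}

#' @export
print.similarity_decision <- function(x, ...) {
  cat(sprintf("SRCC = %.3f (p = %.3g), KS D = %.3f (p = %.3g) -> %s\n",
              x$srcc, x$srcc_p, x$ks_d, x$ks_p,
              if (isTRUE(x$similar)) "similar" else "not similar"))
  invisible(x)
}

# map corems to classes by the majority class of their labelled member genes
.corem_classes_of <- function(membership, assignment) {
  lab <- stats::setNames(assignment$class_label, assignment$gene_id)
  vapply(colnames(membership), function(cm) {
    genes <- rownames(membership)[membership[, cm] == 1]
    cls <- lab[intersect(genes, names(lab))]
    cls <- cls[!is.na(cls) & cls != "unassigned"]
    if (!length(cls)) return(NA_character_)
    tab <- sort(table(cls), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) return(NA_character_)
    names(tab)[1]
  }, character(1))
}

#' Condition-specific similarity between corem classes
#'
#' For every condition category, corem signatures are restricted to the
#' category's conditions and each class pair (i, j) scores the proportion of
#' corem pairs — one corem from class i, one from class j; unordered pairs
#' excluding self-pairs within a class — decided "similar" by
#' [corem_pair_similarity()]. Corems are assigned to the class holding the
#' majority of their labelled member genes.
#'
#' @param assignment A `"corem_classes"` table from
#'   [bootstrap_cluster_support()].
#' @param membership Binary gene-by-corem matrix.
#' @param compendium Gene-by-condition expression matrix.
#' @param condition_categories Data frame with columns `condition`,
#'   `category`.
#' @param cfg A [pipeline_config()].
#' @return A list of class `"class_similarity"`: one symmetric class-by-class
#'   matrix per category (categories with fewer than 3 conditions are
#'   reported untestable as all-`NA` matrices); corem-class mapping in
#'   `attr(, "corem_class")`.
#' @export
class_similarity_matrix <- function(assignment, membership, compendium,
                                    condition_categories,
                                    cfg = pipeline_config()) {
  corem_cls <- .corem_classes_of(membership, assignment)
  classes <- sort(unique(stats::na.omit(corem_cls)))
  if (!length(classes)) stop("no corem could be assigned to a class")
  cats <- unique(condition_categories$category)
  out <- vector("list", length(cats))
  names(out) <- cats
  for (cat_ in cats) {
    conds <- condition_categories$condition[condition_categories$category == cat_]
    mat <- matrix(NA_real_, length(classes), length(classes),
                  dimnames = list(classes, classes))
    if (length(conds) >= 3) {
      comp <- compendium[, conds, drop = FALSE]
      sigs <- lapply(colnames(membership), function(cm) {
        genes <- rownames(membership)[membership[, cm] == 1]
        if (!length(intersect(genes, rownames(comp)))) return(NULL)
        corem_signature(comp, genes, cm)
      })
      names(sigs) <- colnames(membership)
      for (i in seq_along(classes)) {
        for (j in i:length(classes)) {
          ci <- names(corem_cls)[!is.na(corem_cls) & corem_cls == classes[i]]
          cj <- names(corem_cls)[!is.na(corem_cls) & corem_cls == classes[j]]
          pairs <- if (i == j) {
            if (length(ci) < 2) NULL else utils::combn(ci, 2)
          } else {
            if (!length(ci) || !length(cj)) NULL else
              rbind(rep(ci, each = length(cj)), rep(cj, length(ci)))
          }
          if (is.null(pairs)) next
          dec <- vapply(seq_len(ncol(pairs)), function(k) {
            sa <- sigs[[pairs[1, k]]]
            sb <- sigs[[pairs[2, k]]]
            if (is.null(sa) || is.null(sb)) return(NA)
            corem_pair_similarity(sa, sb, cfg)$similar
          }, logical(1))
          mat[i, j] <- mat[j, i] <- mean(dec, na.rm = TRUE)
        }
      }
    }
    out[[cat_]] <- mat
  }
  attr(out, "corem_class") <- corem_cls
  class(out) <- "class_similarity"
  out
}

#' @export
print.class_similarity <- function(x, ...) {
  cat(sprintf("Class similarity matrices over %d condition categories\n",
              length(x)))
  for (nm in names(x)) {
    cat("--", nm, "--\n")
    print(round(x[[nm]], 2))
  }
  invisible(x)
}
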