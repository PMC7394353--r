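# Shared file dialect: UTF-8, tab-separated, header row, "NA" for missing,
# first column is the identifier. "." is disallowed as an identifier.

VALID_SCHEMAS <- c("counts", "abundance", "design", "annotation", "protein",
                   "membership", "compendium", "edges", "differential")

.check_ids <- function(ids, what) {
  if (anyNA(ids) || any(ids == "")) stop("missing ", what, " identifier")
  if (any(ids == ".")) stop("'.' is not a valid ", what, " identifier")
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate ", what, " identifiers: ", paste(unique(dup), collapse = ", "))
  }
  invisible(ids)
}

.as_id_matrix <- function(df, what = "gene") {
  ids <- as.character(df[[1L]])
  .check_ids(ids, what)
  m <- as.matrix(df[, -1L, drop = FALSE])
  .check_ids(colnames(m), "sample")
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(m, 2, as.numeric))) & !is.na(m),
                 arr.ind = TRUE)
    if (nrow(bad)) {
      stop(sprintf("non-numeric value at row '%s', column '%s'",
                   ids[bad[1, 1]], colnames(m)[bad[1, 2]]))
    }
    m <- apply(m, 2, as.numeric)
  }
  rownames(m) <- ids
  m
}

.first_bad_cell <- function(m, bad) {
  idx <- which(bad, arr.ind = TRUE)
  sprintf("gene '%s', sample '%s'", rownames(m)[idx[1, 1]], colnames(m)[idx[1, 2]])
}

#' Validate typed tables
#'
#' Each validator checks the invariants of one table type and errors with
#' row/column context on the first violation.
#'
#' @param counts,abundance,design,membership Objects as returned by
#'   [read_table()].
#' @param tpm For `validate_abundance()`: if `TRUE` the matrix is declared
#'   TPM-normalized and each nonzero column must sum to 1e6 within relative
#'   tolerance 1e-6.
#' @return The validated object, invisibly.
#' @name validators
NULL

#' @rdname validators
#' @export
validate_counts <- function(counts) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  .check_ids(rownames(counts), "gene")
  .check_ids(colnames(counts), "sample")
  if (anyNA(counts)) stop("count matrix contains NA at ", .first_bad_cell(counts, is.na(counts)))
  if (any(counts < 0)) stop("negative count at ", .first_bad_cell(counts, counts < 0))
  if (any(counts != round(counts))) {
    stop("non-integer count at ", .first_bad_cell(counts, counts != round(counts)))
  }
  invisible(counts)
}

#' @rdname validators
#' @export
validate_abundance <- function(abundance, tpm = FALSE) {
  stopifnot(is.matrix(abundance), is.numeric(abundance))
  .check_ids(rownames(abundance), "gene")
  if (anyNA(abundance) || any(!is.finite(abundance))) {
    stop("non-finite abundance at ",
         .first_bad_cell(abundance, !is.finite(abundance)))
  }
  if (any(abundance < 0)) {
    stop("negative abundance at ", .first_bad_cell(abundance, abundance < 0))
  }
  if (tpm) {
    cs <- colSums(abundance)
    nz <- cs > 0
    off <- abs(cs[nz] - 1e6) / 1e6 > 1e-6
    if (any(off)) {
      stop("column '", names(which(off))[1],
           "' declared TPM but sums to ", cs[nz][off][1])
    }
  }
  invisible(abundance)
}

#' @rdname validators
#' @export
validate_design <- function(design) {
  need <- c("sample_id", "time_point", "replicate", "assay")
  miss <- setdiff(need, names(design))
  if (length(miss)) stop("design lacks columns: ", paste(miss, collapse = ", "))
  .check_ids(design$sample_id, "sample")
  if (any(design$replicate < 1)) stop("replicate numbers must be positive")
  if (!all(design$assay %in% c("rna", "ribo", "protein"))) {
    stop("assay must be one of rna, ribo, protein")
  }
  invisible(design)
}

#' @rdname validators
#' @export
validate_membership <- function(membership) {
  stopifnot(is.matrix(membership), is.numeric(membership))
  .check_ids(rownames(membership), "gene")
  .check_ids(colnames(membership), "corem")
  if (!all(membership %in% c(0, 1))) {
    stop("non-binary membership at ",
         .first_bad_cell(membership, !(membership %in% c(0, 1))))
  }
  invisible(membership)
}

#' Read a typed tab-separated table
#'
#' All pipeline inputs are UTF-8 tab-separated files with a header row; the
#' first column holds the identifier (except `design` and `edges`, which are
#' plain record tables). `"NA"` is the missing-value literal.
#'
#' @param path File path.
#' @param schema One of `"counts"`, `"abundance"`, `"design"`, `"annotation"`,
#'   `"protein"`, `"membership"`, `"compendium"`, `"edges"`, `"differential"`.
#' @param design Optional sample design; when given, matrix column ids must be
#'   a subset of its `sample_id`s.
#' @param tpm For `schema = "abundance"`: declare the table TPM-normalized and
#'   check column sums (see [validate_abundance()]).
#' @return The validated object: a numeric matrix for matrix-shaped schemas, a
#'   data frame otherwise.
#' @export
read_table <- function(path, schema = VALID_SCHEMAS, design = NULL, tpm = FALSE) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          na.strings = "NA", check.names = FALSE,
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  obj <- switch(schema,
    counts = validate_counts(.as_id_matrix(df)),
    abundance = validate_abundance(.as_id_matrix(df), tpm = tpm),
    protein = {
      m <- .as_id_matrix(df, "protein")
      if (anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
        stop("protein intensities must be finite and non-negative")
      }
      m
    },
    membership = validate_membership(.as_id_matrix(df)),
    compendium = .as_id_matrix(df),
    design = validate_design(df),
    annotation = {
      need <- c("gene_id", "is_rp")
      if (!all(need %in% names(df))) stop("annotation lacks gene_id/is_rp")
      .check_ids(df$gene_id, "gene")
      df$is_rp <- as.logical(df$is_rp)
      if (!"rp_name" %in% names(df)) df$rp_name <- NA_character_
      if (any(df$is_rp & is.na(df$rp_name)) || any(!df$is_rp & !is.na(df$rp_name))) {
        stop("rp_name must be present iff is_rp")
      }
      df
    },
    edges = {
      if (!all(c("bait", "prey") %in% names(df))) stop("edge list lacks bait/prey")
      .check_ids(unique(c(df$bait, df$prey)), "node")
      df
    },
    differential = {
      need <- c("gene_id", "log2fc", "pvalue", "padj")
      miss <- setdiff(need, names(df))
      if (length(miss)) stop("differential table lacks columns: ",
                             paste(miss, collapse = ", "))
      .check_ids(df$gene_id, "gene")
      df
    }
  )
  if (!is.null(design) && is.matrix(obj)) {
    unknown <- setdiff(colnames(obj), design$sample_id)
    if (length(unknown)) {
      stop("unknown sample ids: ", paste(unknown, collapse = ", "))
    }
  }
  obj
}

#' Write a typed table
#'
#' Inverse of [read_table()]: tab-separated, `"NA"` for missing, full numeric
#' precision (integer tables round-trip bit-identically, reals within 1e-12
#' relative).
#'
#' @param obj A matrix with row identifiers, or a data frame.
#' @param path Output file path.
#' @param id_name Header for the identifier column when `obj` is a matrix.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path, id_name = "gene_id") {
  if (is.matrix(obj)) {
    df <- data.frame(rownames(obj), obj, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df)[1L] <- id_name
  } else {
    df <- as.data.frame(obj)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

#' Transcripts-per-million from raw counts
#'
#' Per column: `rate_g = count_g / length_g`; `TPM_g = 1e6 * rate_g /
#' sum(rate)`. Columns of the result sum to 1e6 (all-zero columns excepted).
#'
#' @param counts Gene-by-sample count matrix.
#' @param lengths Positive gene lengths in nucleotides, named by gene or in
#'   row order.
#' @param zero_columns `"error"` (default) to refuse all-zero columns, or
#'   `"keep"` to pass them through as all-zero.
#' @return A TPM abundance matrix of the same shape.
#' @export
tpm_from_counts <- function(counts, lengths, zero_columns = c("error", "keep")) {
  zero_columns <- match.arg(zero_columns)
  validate_counts(counts)
  if (!is.null(names(lengths))) {
    miss <- setdiff(rownames(counts), names(lengths))
    if (length(miss)) stop("lengths missing for genes: ", paste(miss, collapse = ", "))
    lengths <- lengths[rownames(counts)]
  }
  stopifnot(length(lengths) == nrow(counts))
  if (any(lengths <= 0)) stop("zero or negative gene length")
  rate <- counts / lengths
  tot <- colSums(rate)
  if (any(tot == 0)) {
    if (zero_columns == "error") {
      stop("all-zero column: ", paste(colnames(counts)[tot == 0], collapse = ", "))
    }
    tot[tot == 0] <- 1 # leaves the column all-zero
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Build a sample design table
#'
#' @param n_tp Number of time points (labelled `TP1..TPn`; `TP1` is the
#'   reference).
#' @param n_rep Replicates per time point.
#' @param assay `"rna"`, `"ribo"` or `"protein"`.
#' @param time_points Optional explicit ordered time-point labels.
#' @return A design data frame with columns `sample_id`, `time_point`,
#'   `replicate`, `assay`.
#' @export
make_design <- function(n_tp = 4, n_rep = 3, assay = c("rna", "ribo", "protein"),
                        time_points = NULL) {
  assay <- match.arg(assay)
  if (is.null(time_points)) time_points <- paste0("TP", seq_len(n_tp))
  d <- expand.grid(replicate = seq_len(n_rep), time_point = time_points,
                   stringsAsFactors = FALSE)
  d <- d[, c("time_point", "replicate")]
  d$assay <- assay
  d$sample_id <- sprintf("%s_%s_r%d", assay, d$time_point, d$replicate)
  validate_design(d[, c("sample_id", "time_point", "replicate", "assay")])
  d[, c("sample_id", "time_point", "replicate", "assay")]
}

# columns of `m` belonging to one time point of one assay, in design order
.tp_columns <- function(m, design, time_point, assay = NULL) {
  keep <- design$time_point == time_point
  if (!is.null(assay)) keep <- keep & design$assay == assay
  ids <- intersect(design$sample_id[keep], colnames(m))
  if (!length(ids)) {
    stop("no samples for time point ", time_point,
         if (!is.null(assay)) paste0(" (assay ", assay, ")"))
  }
  m[, ids, drop = FALSE]
}
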