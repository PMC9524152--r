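#' Sparse gene-by-nucleus count matrix
#'
#' Lightweight container for 10x-style single-nucleus counts: a sparse
#' nonnegative integer matrix (genes in rows, nuclei in columns) plus gene
#' identifiers and nucleus barcodes. Gene identifiers must be unique after
#' uppercasing; raw counts are never renormalized in place.
#'
#' @param counts matrix or sparse Matrix, genes x nuclei, nonnegative integers.
#' @param gene_ids character vector, one per row.
#' @param barcodes character vector, one per column.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, gene_ids, barcodes) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(gene_ids))
    stop("gene_ids length does not match row count")
  if (ncol(counts) != length(barcodes))
    stop("barcodes length does not match column count")
  if (any(counts@x < 0)) stop("counts must be nonnegative")
  if (any(abs(counts@x - round(counts@x)) > 1e-8))
    stop("counts must be integers")
  gene_ids <- toupper(as.character(gene_ids))
  if (anyDuplicated(gene_ids))
    stop("gene_ids must be unique after uppercase normalization")
  if (anyDuplicated(barcodes)) stop("barcodes must be unique")
  rownames(counts) <- gene_ids
  colnames(counts) <- barcodes
  structure(list(counts = counts, gene_ids = gene_ids,
                 barcodes = as.character(barcodes)),
            class = "count_matrix")
}

#' @exportS3Method print count_matrix
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d nuclei (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' @exportS3Method dim count_matrix
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by genes and/or nuclei
#'
#' Subsetting preserves raw counts exactly; no renormalization happens here.
#'
#' @param x a `count_matrix`.
#' @param genes,barcodes identifiers or indices to keep (default: all).
#' @return A `count_matrix`.
#' @export
subset_count_matrix <- function(x, genes = NULL, barcodes = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  gi <- if (is.null(genes)) seq_len(nrow(x$counts)) else genes
  bi <- if (is.null(barcodes)) seq_len(ncol(x$counts)) else barcodes
  if (is.character(gi)) {
    gi <- match(toupper(gi), x$gene_ids)
    if (anyNA(gi)) stop("unknown gene identifier(s)")
  }
  if (is.character(bi)) {
    bi <- match(bi, x$barcodes)
    if (anyNA(bi)) stop("unknown barcode(s)")
  }
  count_matrix(x$counts[gi, bi, drop = FALSE], x$gene_ids[gi], x$barcodes[bi])
}

#' Per-nucleus metadata table
#'
#' Validates the nucleus-level metadata against a count matrix: every barcode
#' must be present in the matrix, treatment arms are one of `untreated`,
#' `CRT`, `CRTL` (chemoradiation without/with losartan), and untreated nuclei
#' carry no radiation dose group or modality.
#'
#' @param metadata data.frame with columns `barcode`, `patient_id`, `arm`,
#'   `dose_group`, `modality`, `sex` and optionally `cell_type`.
#' @param x optional `count_matrix` to validate barcodes against.
#' @return The validated data.frame.
#' @export
validate_metadata <- function(metadata, x = NULL) {
  need <- c("barcode", "patient_id", "arm", "dose_group", "modality", "sex")
  missing_cols <- setdiff(need, names(metadata))
  if (length(missing_cols))
    stop("metadata missing columns: ", paste(missing_cols, collapse = ", "))
  if (!all(metadata$arm %in% c("untreated", "CRT", "CRTL")))
    stop("arm must be one of untreated, CRT, CRTL")
  if (!all(metadata$dose_group %in% c("none", "low", "high")))
    stop("dose_group must be one of none, low, high")
  if (!all(metadata$modality %in% c("none", "photon", "proton")))
    stop("modality must be one of none, photon, proton")
  untr <- metadata$arm == "untreated"
  if (any(metadata$dose_group[untr] != "none" | metadata$modality[untr] != "none"))
    stop("untreated nuclei must have dose_group = none and modality = none")
  if (!is.null(x)) {
    stray <- setdiff(metadata$barcode, x$barcodes)
    if (length(stray))
      stop("metadata barcode(s) absent from count matrix: ",
           paste(head(stray, 5), collapse = ", "))
  }
  metadata
}

# CP10K + log1p normalization; returns dgCMatrix genes x nuclei
normalize_log_cp10k <- function(counts) {
  tot <- Matrix::colSums(counts)
  tot[tot == 0] <- 1
  log1p(counts %*% Matrix::Diagonal(x = 1e4 / tot))
}
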