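#' Score nuclei against a marker panel
#'
#' For every nucleus and cell type, the score is the mean log1p(CP10K)
#' expression of the panel genes present in the matrix. Panel genes absent
#' from the matrix are reported in the `missing_genes` attribute; a cell type
#' with no gene present is an error.
#'
#' @param x a [count_matrix()].
#' @param panel named list of marker gene vectors (see [ec_marker_panel()]).
#' @return data.frame with `barcode` and one score column per type; attribute
#'   `missing_genes` lists absent panel genes per type.
#' @export
score_markers <- function(x, panel) {
  stopifnot(inherits(x, "count_matrix"))
  panel <- suppressWarnings(validate_marker_panel(panel))
  norm <- normalize_log_cp10k(x$counts)
  missing <- lapply(panel, setdiff, y = x$gene_ids)
  present <- mapply(intersect, panel, MoreArgs = list(y = x$gene_ids),
                    SIMPLIFY = FALSE)
  empty <- names(present)[lengths(present) == 0L]
  if (length(empty))
    stop("no panel genes present for type(s): ", paste(empty, collapse = ", "))
  scores <- vapply(present, function(g) {
    sub <- norm[match(g, x$gene_ids), , drop = FALSE]
    as.numeric(Matrix::colMeans(sub))
  }, numeric(ncol(x$counts)))
  out <- data.frame(barcode = x$barcodes, scores,
                    stringsAsFactors = FALSE, check.names = FALSE)
  attr(out, "missing_genes") <- missing[lengths(missing) > 0]
  out
}

#' Extract endothelial nuclei from a count matrix
#'
#' Two paths: `precomputed_labels` keeps nuclei whose `metadata$cell_type`
#' equals `"endothelial"` (case-insensitive) — the default when curated
#' cell-type labels are available; `cluster_then_annotate` clusters
#' nuclei by k-means on the top principal components of the log-normalized
#' matrix and keeps clusters whose mean endothelial score exceeds the mean
#' score of every other panel type. Raw counts are subset, never rescaled.
#'
#' @param x a [count_matrix()].
#' @param metadata per-nucleus metadata (see [validate_metadata()]).
#' @param panel marker panel; the first type is treated as the endothelial
#'   score, remaining types as competitors. For `cluster_then_annotate` the
#'   panel must include the non-endothelial cell types expected in the data
#'   (e.g. a subset of [bulk_deconvolution_markers()]); the default EC-only
#'   panel can only separate endothelial subtypes, not ECs from other cells.
#' @param method `"precomputed_labels"` or `"cluster_then_annotate"`.
#' @param n_clusters,n_pcs,seed clustering controls for the annotate path.
#' @param min_genes nuclei with fewer detected genes are dropped first
#'   (minimal quality filter; set 0 to disable).
#' @return list with `counts` (subset [count_matrix()]) and `metadata`
#'   (subset data.frame).
#' @export
extract_endothelial <- function(x, metadata, panel = ec_marker_panel(),
                                method = c("precomputed_labels",
                                           "cluster_then_annotate"),
                                n_clusters = 8, n_pcs = 10, seed = 1L,
                                min_genes = 0) {
  method <- match.arg(method)
  stopifnot(inherits(x, "count_matrix"))
  metadata <- validate_metadata(metadata, x)
  if (min_genes > 0) {
    detected <- Matrix::colSums(x$counts > 0)
    keep_qc <- x$barcodes[detected >= min_genes]
    x <- subset_count_matrix(x, barcodes = keep_qc)
    metadata <- metadata[metadata$barcode %in% keep_qc, , drop = FALSE]
  }
  if (method == "precomputed_labels") {
    if (is.null(metadata$cell_type))
      stop("precomputed_labels requires metadata$cell_type")
    keep <- metadata$barcode[tolower(metadata$cell_type) == "endothelial"]
  } else {
    sc <- score_markers(x, panel)
    norm <- normalize_log_cp10k(x$counts)
    pcs <- compute_pcs(Matrix::t(norm), n_pcs = min(n_pcs, ncol(x$counts) - 1,
                                                    nrow(x$counts) - 1))
    set.seed(as.integer(seed))
    km <- kmeans(pcs, centers = min(n_clusters, nrow(pcs) - 1),
                 nstart = 5, iter.max = 50)
    type_cols <- setdiff(names(sc), "barcode")
    ec_col <- type_cols[1]
    keep <- character()
    for (cl in sort(unique(km$cluster))) {
      in_cl <- km$cluster == cl
      means <- colMeans(sc[in_cl, type_cols, drop = FALSE])
      if (which.max(means) == 1L) keep <- c(keep, sc$barcode[in_cl])
    }
  }
  if (length(keep) == 0L)
    stop("no endothelial nuclei found; review marker panel or score thresholds")
  list(counts = subset_count_matrix(x, barcodes = keep),
       metadata = metadata[match(keep, metadata$barcode), , drop = FALSE])
}
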