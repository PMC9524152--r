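#' Annotate programs by overlap with reference signatures
#'
#' For every (program, reference) pair, tests the overlap between the
#' program's top-weighted genes and the reference signature within the gene
#' universe using the two-sided hypergeometric test, then BH-adjusts across
#' the whole table. The universe defaults to the genes of the analyzed matrix
#' (overlap probabilities must condition on testable genes); references with
#' no gene in the universe are skipped with a warning, and reference genes
#' outside the universe are dropped from the test.
#'
#' @param ps a [program_set()].
#' @param references named list of reference gene sets (e.g. from
#'   [read_gmt()]).
#' @param universe character vector of testable genes; defaults to the gene
#'   axis of the program spectra.
#' @param fdr_level BH significance level (default 0.1).
#' @return data.frame: `program`, `reference_signature`, `overlap_count`,
#'   `p_two_sided`, `p_adj`, `significant`.
#' @export
annotate_programs <- function(ps, references, universe = NULL,
                              fdr_level = 0.1) {
  stopifnot(inherits(ps, "program_set"))
  if (length(references) == 0L) stop("references must be nonempty")
  if (is.null(names(references)) || any(!nzchar(names(references))))
    stop("references must be named")
  if (is.null(universe)) universe <- colnames(ps$spectra)
  universe <- unique(toupper(universe))
  sets <- program_gene_sets(ps)
  rows <- list()
  for (rn in names(references)) {
    ref <- intersect(unique(toupper(references[[rn]])), universe)
    if (length(ref) == 0L) {
      warning("reference '", rn, "' fully absent from universe; skipped")
      next
    }
    for (pn in names(sets)) {
      top <- intersect(sets[[pn]], universe)
      tr <- hypergeometric_overlap_test(top, ref, universe)
      rows[[length(rows) + 1L]] <- data.frame(
        program = pn, reference_signature = rn,
        overlap_count = tr$statistic, p_two_sided = tr$p_value,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no reference overlapped the universe")
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p_two_sided, "benjamini_hochberg", fdr_level)
  out$p_adj <- adj$adjusted
  out$significant <- adj$significant
  out[order(out$p_adj, out$p_two_sided), , drop = FALSE]
}

#' Over-representation of programs against pathway collections
#'
#' The same hypergeometric machinery as [annotate_programs()], applied to an
#' arbitrary GMT collection in place of curated reference signatures (a
#' deliberate replacement for ranked enrichment analysis).
#'
#' @param ps a [program_set()].
#' @param pathways named list of pathway gene sets (e.g. from [read_gmt()]).
#' @inheritParams annotate_programs
#' @return Same shape as [annotate_programs()].
#' @export
over_representation <- function(ps, pathways, universe = NULL,
                                fdr_level = 0.1) {
  annotate_programs(ps, pathways, universe = universe, fdr_level = fdr_level)
}
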