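#' Default endothelial marker panel
#'
#' Marker genes used to identify endothelial-cell profiles in single-nucleus
#' data: general endothelial (PECAM1, VWF), vascular endothelial (ESAM, FLT1,
#' EPAS1), and lymphatic endothelial (FLT4, SEMA3A, SEMA3D).
#'
#' @return Named list of uppercase gene vectors (a marker panel).
#' @export
ec_marker_panel <- function() {
  list(
    endothelial = c("PECAM1", "VWF"),
    vascular_endothelial = c("ESAM", "FLT1", "EPAS1"),
    lymphatic_endothelial = c("FLT4", "SEMA3A", "SEMA3D")
  )
}

#' Marker table for bulk cell-type deconvolution
#'
#' The full marker panel used to score cell-type proportions in bulk tumor
#' expression: endothelial, epithelial/acinar, myeloid, lymphoid,
#' cancer-associated fibroblast, pericyte, Schwann, endocrine, neuronal and
#' adipocyte markers. Two entries (CSM1, KZF1) are not standard HGNC symbols;
#' they are kept verbatim and flagged by [validate_marker_panel()].
#'
#' @return Named list of uppercase gene vectors.
#' @export
bulk_deconvolution_markers <- function() {
  list(
    endothelial = c("PECAM1", "VWF"),
    epithelial_acinar = c("CFTR", "KRT19", "KRT7", "KRT17", "EPCAM", "CEACAM6",
                          "COL17A1", "MECOM", "CPB1", "PRSS3", "AMY1A"),
    myeloid = c("CD68", "CD163", "MRC1", "CD80", "CD86", "TGFB1", "CSM1",
                "XCR1", "CST3", "CLEC9A", "LGALS2", "CD1A", "CD207", "CD1E",
                "FCER1A", "NDRG2", "FSCN1", "LAMP3", "CCL19", "CCR7", "IRF7",
                "LILRA4", "TCF4", "CXCR3", "IRF4", "CSF3R", "CXCL8"),
    lymphoid = c("CD4", "CD8A", "CD8B", "CD3D", "THEMIS", "CD96", "KZF1",
                 "GZMA", "FOXP3", "BANK1", "CD19", "KLRD1", "KIR2DL3",
                 "IL18R1", "KIR2DL1", "KIR3DL2", "SDC1", "IGLC2"),
    fibroblast = c("COL1A1", "FN1", "PDPN", "DCN", "VIM", "FAP", "ACTA2",
                   "IL6", "C3", "LIF", "POSTN", "FBLN1"),
    pericyte = c("PDGFRB", "DLK1", "ACTA1", "RGS5", "CSPG4", "MCAM"),
    schwann = c("SOX10", "S100B", "NGFR"),
    endocrine = c("GCG", "INS", "APP", "SST", "PPY", "GHRL", "SYP", "CHGA", "VGF"),
    neuronal = c("TH", "CHAT", "ENO2", "TAC1"),
    adipocyte = c("PLIN1", "LPL")
  )
}

# symbols in the shipped tables known not to be standard HGNC symbols
NONSTANDARD_SYMBOLS <- c("CSM1", "KZF1")

#' Validate a marker panel
#'
#' Checks that every cell type has a nonempty uppercase gene list and warns
#' about known non-standard symbols kept verbatim from the source table.
#'
#' @param panel named list of character vectors.
#' @return The panel, with genes uppercased.
#' @export
validate_marker_panel <- function(panel) {
  if (!is.list(panel) || is.null(names(panel)) || any(!nzchar(names(panel))))
    stop("panel must be a named list of gene vectors")
  if (any(lengths(panel) == 0L))
    stop("empty gene list for type(s): ",
         paste(names(panel)[lengths(panel) == 0L], collapse = ", "))
  panel <- lapply(panel, function(g) unique(toupper(g)))
  odd <- intersect(unlist(panel), NONSTANDARD_SYMBOLS)
  if (length(odd))
    warning("non-standard gene symbol(s) kept verbatim: ",
            paste(odd, collapse = ", "))
  panel
}
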