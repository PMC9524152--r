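#' Read a 10x-style sparse count matrix
#'
#' Reads a Matrix Market file with `genes.tsv` / `barcodes.tsv` sidecars (one
#' identifier per line; a second tab-separated column, if present, is ignored).
#'
#' @param mtx path to the `.mtx` file.
#' @param genes,barcodes paths to the sidecar TSVs; default to `genes.tsv` and
#'   `barcodes.tsv` next to `mtx`.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(mtx,
                              genes = file.path(dirname(mtx), "genes.tsv"),
                              barcodes = file.path(dirname(mtx), "barcodes.tsv")) {
  m <- Matrix::readMM(mtx)
  g <- read.delim(genes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  b <- read.delim(barcodes, header = FALSE, stringsAsFactors = FALSE)[[1]]
  count_matrix(m, g, b)
}

#' Write a count matrix as Matrix Market plus sidecars
#'
#' @param x a [count_matrix()].
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_count_matrix <- function(x, dir) {
  stopifnot(inherits(x, "count_matrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  writeLines(x$gene_ids, file.path(dir, "genes.tsv"))
  writeLines(x$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited GMT: set name, description, then member genes.
#' Gene symbols are uppercased.
#'
#' @param path GMT file path.
#' @return Named list of character vectors; descriptions in attribute
#'   `description`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(fields) < 3
  if (any(bad)) stop("GMT line(s) with fewer than 3 fields: ",
                     paste(which(bad), collapse = ", "))
  sets <- lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  attr(sets, "description") <- vapply(fields, `[[`, "", 2L)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets named list of character vectors.
#' @param path output path.
#' @param description optional per-set description column (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "ecprograms") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], toupper(sets[[i]])), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
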