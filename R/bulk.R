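#' Marker-based deconvolution of bulk expression
#'
#' The default `marker_score` method scores each cell type as the mean log1p
#' expression of its present markers, z-scores each type across samples,
#' shifts each type's scores to be nonnegative, and normalizes per sample to
#' the simplex. An `nnls` alternative regresses each sample's log1p
#' expression onto binary marker profiles by nonnegative least squares.
#' A cell type with no marker present in the expression matrix is an error.
#'
#' @param expression samples x genes nonnegative matrix with gene colnames.
#' @param markers named list of marker gene vectors (default
#'   [bulk_deconvolution_markers()]).
#' @param method `"marker_score"` (default) or `"nnls"`.
#' @return list with `proportions` (samples x types, rows sum to 1) and
#'   `marker_coverage` (fraction of each type's markers present).
#' @export
deconvolve <- function(expression, markers = bulk_deconvolution_markers(),
                       method = c("marker_score", "nnls")) {
  method <- match.arg(method)
  markers <- suppressWarnings(validate_marker_panel(markers))
  genes <- toupper(colnames(expression))
  if (is.null(genes)) stop("expression must have gene colnames")
  present <- lapply(markers, intersect, y = genes)
  absent <- names(present)[lengths(present) == 0L]
  if (length(absent))
    stop("no marker present for type(s): ", paste(absent, collapse = ", "))
  coverage <- lengths(present) / lengths(markers)

  le <- log1p(as.matrix(expression))
  colnames(le) <- genes
  if (method == "marker_score") {
    raw <- vapply(present, function(g)
      rowMeans(le[, g, drop = FALSE]), numeric(nrow(le)))
    z <- scale(raw)
    z[, attr(z, "scaled:scale") == 0] <- 0
    z <- sweep(z, 2, apply(z, 2, min), "-")       # shift each type to >= 0
    props <- z / pmax(rowSums(z), .Machine$double.eps)
    uniform <- rowSums(z) == 0
    if (any(uniform)) props[uniform, ] <- 1 / ncol(z)
  } else {
    P <- t(vapply(present, function(g) {
      v <- numeric(ncol(le)); v[match(g, genes)] <- 1 / length(g); v
    }, numeric(ncol(le))))
    U <- .cpp_nnls_rows(P, le)
    rs <- rowSums(U)
    rs[rs == 0] <- 1
    props <- U / rs
    uniform <- rowSums(U) == 0
    if (any(uniform)) props[uniform, ] <- 1 / nrow(P)
  }
  dimnames(props) <- list(rownames(expression), names(markers))
  list(proportions = props, marker_coverage = coverage)
}

#' Score programs in bulk cohorts with within-cohort z-normalization
#'
#' The raw score of a program in a sample is the summed expression of the
#' program's top-weighted genes present in the matrix; scores are then
#' z-normalized within each cohort label independently (to absorb cohort
#' batch effects). Programs with fewer than `min_genes` present genes are
#' skipped with a warning.
#'
#' @param expression samples x genes matrix with gene colnames.
#' @param signatures named list of program gene sets (e.g.
#'   [program_gene_sets()]).
#' @param cohort per-sample cohort label (single cohort if NULL).
#' @param min_genes minimum present genes per program (default 10).
#' @return samples x programs matrix of z-scores.
#' @export
score_programs <- function(expression, signatures, cohort = NULL,
                           min_genes = 10) {
  genes <- toupper(colnames(expression))
  if (is.null(genes)) stop("expression must have gene colnames")
  if (is.null(cohort)) cohort <- rep("all", nrow(expression))
  if (length(cohort) != nrow(expression))
    stop("cohort must have one label per sample")
  expr <- as.matrix(expression)
  out <- list()
  for (sn in names(signatures)) {
    idx <- match(intersect(toupper(signatures[[sn]]), genes), genes)
    if (length(idx) < min_genes) {
      warning("program '", sn, "' has ", length(idx),
              " genes present (< ", min_genes, "); skipped")
      next
    }
    raw <- rowSums(expr[, idx, drop = FALSE])
    z <- raw
    for (ch in unique(cohort)) {
      i <- cohort == ch
      s <- sd(raw[i])
      z[i] <- if (s > 0) (raw[i] - mean(raw[i])) / s else 0
    }
    out[[sn]] <- z
  }
  if (length(out) == 0L) stop("no program had enough genes on the matrix")
  zs <- do.call(cbind, out)
  rownames(zs) <- rownames(expression)
  zs
}

#' Multivariable Cox regression of survival on program scores
#'
#' Fits a proportional-hazards model for the chosen endpoint with clinical
#' covariates plus program z-scores, using Efron handling of tied event
#' times, and reports per-covariate hazard ratios with Wald confidence
#' intervals and p-values. Lineage-program and state-program covariate sets
#' are intended to be fit as separate models. Metastatic samples are excluded
#' when the clinical table flags them.
#'
#' @param clinical data.frame with `sample_id`, `<endpoint>_time`,
#'   `<endpoint>_event`, the clinical covariates, and optionally `metastatic`.
#' @param zscores samples x programs matrix (rownames matching `sample_id`).
#' @param endpoint `"OS"` or `"TTP"`.
#' @param covariates clinical covariate names (default age, sex, grade,
#'   stage; grade/stage are treated as ordinal integers).
#' @param conf_level Wald CI level.
#' @param min_events minimum number of events required (default 10; lower it
#'   only for worked examples on toy data).
#' @return data.frame: `covariate`, `hazard_ratio`, `ci_low`, `ci_high`, `p`,
#'   `endpoint`, `flagged` (monotone-likelihood / separation warning).
#' @export
cox_regression <- function(clinical, zscores, endpoint = c("OS", "TTP"),
                           covariates = c("age", "sex", "grade", "stage"),
                           conf_level = 0.95, min_events = 10) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  if (!all(c(tcol, ecol) %in% names(clinical)))
    stop("clinical must carry ", tcol, " and ", ecol)
  if (!is.null(clinical$metastatic)) clinical <- clinical[!clinical$metastatic, ]
  zs <- zscores[match(clinical$sample_id, rownames(zscores)), , drop = FALSE]
  if (anyNA(zs)) stop("zscores missing for some samples")
  df <- data.frame(time = clinical[[tcol]], event = clinical[[ecol]],
                   clinical[, intersect(covariates, names(clinical)),
                            drop = FALSE],
                   as.data.frame(zs), check.names = FALSE)
  if (any(df$time <= 0)) stop("survival times must be positive")
  if (sum(df$event) < min_events) stop("need >= ", min_events, " events")
  terms <- setdiff(names(df), c("time", "event"))
  const <- terms[vapply(terms, function(v) length(unique(df[[v]])) < 2, TRUE)]
  if (length(const))
    stop("constant covariate(s): ", paste(const, collapse = ", "))

  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ .,
                    data = df, ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|singular", conditionMessage(w),
                ignore.case = TRUE)) flagged <<- TRUE
      invokeRestart("muffleWarning")
    })
  sf <- summary(fit, conf.int = conf_level)
  out <- data.frame(
    covariate = rownames(sf$coefficients),
    hazard_ratio = sf$conf.int[, "exp(coef)"],
    ci_low = sf$conf.int[, 3], ci_high = sf$conf.int[, 4],
    p = sf$coefficients[, "Pr(>|z|)"],
    endpoint = endpoint, flagged = flagged,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Program scores versus nodal status
#'
#' Two-sided Mann-Whitney U test of each program's z-scores between
#' node-positive and node-negative samples, BH-adjusted across programs.
#'
#' @param zscores samples x programs matrix.
#' @param N_status per-sample `"N+"` / `"N0"` labels.
#' @param fdr_level BH level.
#' @return data.frame: `program`, `n_pos`, `n_neg`, `statistic`, `p`,
#'   `p_adj`, `significant`.
#' @export
node_association <- function(zscores, N_status, fdr_level = 0.1) {
  if (length(N_status) != nrow(zscores))
    stop("N_status must have one label per sample")
  pos <- N_status == "N+"
  if (all(pos) || all(!pos)) stop("both N groups must be nonempty")
  rows <- lapply(colnames(zscores), function(pg) {
    tr <- mann_whitney_u(zscores[pos, pg], zscores[!pos, pg])
    data.frame(program = pg, n_pos = sum(pos), n_neg = sum(!pos),
               statistic = tr$statistic, p = tr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, "benjamini_hochberg", fdr_level)
  out$p_adj <- adj$adjusted
  out$significant <- adj$significant
  out
}
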