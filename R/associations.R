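#' Per-patient program proportions
#'
#' Fraction of each patient's endothelial nuclei assigned to each program,
#' computed separately within the lineage and state program families (each
#' family's proportions sum to 1 per patient). Patients with zero assigned
#' nuclei are excluded with a warning.
#'
#' @param assignments output of [assign_nuclei()] (must carry `barcode`).
#' @param metadata per-nucleus metadata with `barcode`, `patient_id`, `arm`,
#'   `dose_group`, `modality`.
#' @param ps optional [program_set()] fixing the full set of programs per
#'   family (so absent programs appear as 0).
#' @return data.frame with patient-level metadata, `n_ec_nuclei`, and one
#'   proportion column per program; attribute `programs` maps columns to
#'   families.
#' @export
program_proportions <- function(assignments, metadata, ps = NULL) {
  if (is.null(assignments$barcode)) stop("assignments must carry barcodes")
  m <- match(assignments$barcode, metadata$barcode)
  if (anyNA(m)) stop("assignment barcode(s) missing from metadata")
  info <- metadata[m, , drop = FALSE]
  lost <- setdiff(unique(metadata$patient_id), unique(info$patient_id))
  if (length(lost))
    warning("patient(s) with zero assigned nuclei excluded: ",
            paste(lost, collapse = ", "))

  fam_levels <- function(col, cls) {
    if (!is.null(ps)) {
      classes <- vapply(ps$programs, `[[`, "", "class")
      names(ps$programs)[classes == cls]
    } else sort(unique(stats::na.omit(assignments[[col]])))
  }
  lin_lev <- fam_levels("lineage_program", "lineage")
  st_lev <- fam_levels("state_program", "state")

  pats <- unique(info$patient_id)
  prop_block <- function(col, levels) {
    if (length(levels) == 0L)
      return(matrix(numeric(0), length(pats), 0))
    tab <- table(factor(info$patient_id, levels = pats),
                 factor(assignments[[col]], levels = levels))
    tot <- rowSums(tab)
    tot[tot == 0] <- 1
    matrix(tab / tot, nrow(tab), ncol(tab), dimnames = dimnames(tab))
  }
  lin <- prop_block("lineage_program", lin_lev)
  st <- prop_block("state_program", st_lev)

  pat_meta <- unique(info[, intersect(c("patient_id", "arm", "dose_group",
                                        "modality", "sex"), names(info))])
  pat_meta <- pat_meta[match(pats, pat_meta$patient_id), , drop = FALSE]
  out <- cbind(pat_meta,
               n_ec_nuclei = as.integer(table(factor(info$patient_id,
                                                     levels = pats))),
               as.data.frame(lin), as.data.frame(st))
  rownames(out) <- NULL
  attr(out, "programs") <- list(lineage = lin_lev, state = st_lev)
  out
}

#' Compare program proportions across treatment strata
#'
#' One two-sided Mann-Whitney U test per (program, stratum pair) on the
#' per-patient proportions, with Benjamini-Hochberg control across the whole
#' family of tests for the chosen stratification (pipeline default FDR = 0.1).
#' Pairs involving a stratum with fewer than 2 patients are skipped with a
#' warning.
#'
#' @param tab output of [program_proportions()].
#' @param stratification `"arm"`, `"dose_group"` or `"modality"`.
#' @param pairs optional list of length-2 character vectors of stratum levels;
#'   defaults to all unordered pairs present.
#' @param programs program columns to test; defaults to all proportion
#'   columns recorded by [program_proportions()].
#' @param fdr_level BH level.
#' @return data.frame: `comparison`, `program`, `stratum_a`, `stratum_b`,
#'   `n_a`, `n_b`, `statistic`, `p`, `p_adj`, `procedure`, `significant`.
#' @export
compare_strata <- function(tab, stratification = c("arm", "dose_group",
                                                   "modality"),
                           pairs = NULL, programs = NULL, fdr_level = 0.1) {
  stratification <- match.arg(stratification)
  if (is.null(programs))
    programs <- unlist(attr(tab, "programs"), use.names = FALSE)
  if (is.null(programs) || length(programs) == 0L)
    stop("no program columns to test")
  strata <- tab[[stratification]]
  levs <- unique(strata)
  if (is.null(pairs)) {
    if (length(levs) < 2) stop("need >= 2 strata")
    pairs <- combn(sort(levs), 2, simplify = FALSE)
  }
  rows <- list()
  for (pr in pairs) {
    a <- tab[strata == pr[1], , drop = FALSE]
    b <- tab[strata == pr[2], , drop = FALSE]
    if (nrow(a) < 2 || nrow(b) < 2) {
      warning("stratum pair ", pr[1], " vs ", pr[2],
              " has < 2 patients on a side; skipped")
      next
    }
    for (pg in programs) {
      tr <- mann_whitney_u(a[[pg]], b[[pg]])
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0(pg, ": ", pr[1], " vs ", pr[2]),
        program = pg, stratum_a = pr[1], stratum_b = pr[2],
        n_a = nrow(a), n_b = nrow(b),
        statistic = tr$statistic, p = tr$p_value, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no testable stratum pair")
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, "benjamini_hochberg", fdr_level)
  out$p_adj <- adj$adjusted
  out$procedure <- "benjamini_hochberg"
  out$significant <- adj$significant
  out
}

#' Patient-level program expression
#'
#' The patient-level score of a program: mean usage weight of that program
#' across the patient's endothelial nuclei.
#'
#' @param usage nuclei x programs matrix with barcode rownames.
#' @param metadata per-nucleus metadata mapping barcodes to patients.
#' @return patients x programs matrix.
#' @export
patient_program_expression <- function(usage, metadata) {
  m <- match(rownames(usage), metadata$barcode)
  if (anyNA(m)) stop("usage barcode(s) missing from metadata")
  pat <- metadata$patient_id[m]
  agg <- rowsum(usage, pat) / as.vector(table(pat)[sort(unique(pat))])
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Top-vs-bottom quartile association
#'
#' Splits patients into top and bottom quartiles of a program score (rank
#' cuts of size floor(n/4); ties broken by patient identifier) and compares
#' each response between the quartiles with a two-sided Mann-Whitney U test,
#' BH-adjusted across responses. The fold change is the ratio of quartile
#' means; a zero bottom mean yields an NA sentinel with a warning.
#'
#' @param scores named numeric vector (patient -> program score).
#' @param responses data.frame or matrix of patient-level responses with
#'   rownames (or a `patient_id` column) matching `names(scores)`.
#' @param fdr_level BH level (default 0.1).
#' @return data.frame: `response_name`, `top_quartile_mean`,
#'   `bottom_quartile_mean`, `fold_change`, `p`, `p_adj`, `significant`.
#' @export
quartile_association <- function(scores, responses, fdr_level = 0.1) {
  if (length(scores) < 8) stop("need >= 8 patients for quartiles")
  if (diff(range(scores)) == 0)
    stop("constant scores: quartiles are undefined")
  responses <- as.data.frame(responses)
  if ("patient_id" %in% names(responses)) {
    rownames(responses) <- responses$patient_id
    responses$patient_id <- NULL
  }
  if (!all(names(scores) %in% rownames(responses)))
    stop("responses missing for some patients")
  responses <- responses[names(scores), , drop = FALSE]

  n <- length(scores)
  qsize <- floor(n / 4)
  ord <- order(scores, names(scores))
  bottom <- ord[seq_len(qsize)]
  top <- ord[(n - qsize + 1):n]

  rows <- lapply(names(responses), function(rn) {
    rv <- responses[[rn]]
    tm <- mean(rv[top]); bm <- mean(rv[bottom])
    if (bm == 0) {
      warning("bottom-quartile mean is zero for ", rn, "; fold change is NA")
      fc <- NA_real_
    } else fc <- tm / bm
    tr <- mann_whitney_u(rv[top], rv[bottom])
    data.frame(response_name = rn, top_quartile_mean = tm,
               bottom_quartile_mean = bm, fold_change = fc, p = tr$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  adj <- adjust_pvalues(out$p, "benjamini_hochberg", fdr_level)
  out$p_adj <- adj$adjusted
  out$significant <- adj$significant
  out
}

#' Stromal-to-endothelial cell-count ratios
#'
#' Per patient, the ratio of each non-endothelial cell type's nucleus count
#' to the endothelial nucleus count. Patients without endothelial nuclei are
#' excluded with a warning. When program scores are supplied the ratios are
#' fed to [quartile_association()].
#'
#' @param metadata per-nucleus metadata with `patient_id` and `cell_type`
#'   covering all cell types (label `"endothelial"` marks ECs).
#' @param ec_scores optional named patient-level program score vector.
#' @param fdr_level BH level for the quartile tests.
#' @return list with `ratios` (patients x cell types data.frame) and `tests`
#'   (quartile comparison rows, or NULL).
#' @export
stromal_to_ec_ratio <- function(metadata, ec_scores = NULL, fdr_level = 0.1) {
  if (!all(c("patient_id", "cell_type") %in% names(metadata)))
    stop("metadata must have patient_id and cell_type")
  tab <- table(metadata$patient_id, metadata$cell_type)
  if (!"endothelial" %in% colnames(tab)) stop("no endothelial nuclei present")
  ec <- tab[, "endothelial"]
  keep <- ec > 0
  if (any(!keep))
    warning("patient(s) with zero endothelial nuclei excluded: ",
            paste(rownames(tab)[!keep], collapse = ", "))
  tab <- tab[keep, , drop = FALSE]
  ec <- ec[keep]
  types <- setdiff(colnames(tab), "endothelial")
  if (length(types) == 0L) stop("metadata contains only endothelial nuclei")
  cnt <- matrix(tab[, types, drop = FALSE], nrow(tab), length(types),
                dimnames = list(rownames(tab), types))
  ratios <- as.data.frame(cnt / as.numeric(ec))
  tests <- NULL
  if (!is.null(ec_scores)) {
    common <- intersect(names(ec_scores), rownames(ratios))
    tests <- quartile_association(ec_scores[common],
                                  ratios[common, , drop = FALSE],
                                  fdr_level = fdr_level)
  }
  list(ratios = ratios, tests = tests)
}

#' Score program signatures on a paired targeted panel
#'
#' Per sample and signature, the score is the mean panel expression of the
#' genes overlapping the signature (signatures without overlap are skipped
#' with a warning). Scores are compared between the two conditions with a
#' paired two-sided Wilcoxon signed-rank test (pairing by `pair_id`), with
#' Bonferroni adjustment across signatures. Pairing must be explicit: the
#' panel metadata defines which samples form a pair.
#'
#' @param panel list with `expression` (samples x genes) and `info`
#'   (`sample_id`, `pair_id`, `condition` with exactly 2 levels), as produced
#'   by [simulate_huvec_panel()].
#' @param signatures named list of gene sets (e.g. program top-200 lists).
#' @param alpha Bonferroni significance level.
#' @return list with `scores` (long data.frame) and `tests` (per-signature
#'   signed-rank results).
#' @export
score_panel <- function(panel, signatures, alpha = 0.05) {
  expr <- panel$expression
  info <- panel$info
  conds <- unique(info$condition)
  if (length(conds) != 2) stop("panel must have exactly 2 conditions")
  rows <- list()
  score_tab <- list()
  for (sn in names(signatures)) {
    genes <- intersect(toupper(signatures[[sn]]), colnames(expr))
    if (length(genes) == 0L) {
      warning("signature '", sn, "' has no gene on the panel; skipped")
      next
    }
    sc <- rowMeans(expr[, genes, drop = FALSE])
    score_tab[[sn]] <- data.frame(info, signature = sn, score = sc,
                                  row.names = NULL)
    pairs <- intersect(info$pair_id[info$condition == conds[1]],
                       info$pair_id[info$condition == conds[2]])
    s1 <- sc[info$condition == conds[1]][match(pairs,
            info$pair_id[info$condition == conds[1]])]
    s2 <- sc[info$condition == conds[2]][match(pairs,
            info$pair_id[info$condition == conds[2]])]
    tr <- wilcoxon_signed_rank(s1, s2)
    rows[[sn]] <- data.frame(
      signature = sn, n_genes = length(genes), n_pairs = length(pairs),
      statistic = tr$statistic, p = tr$p_value, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no signature overlaps the panel")
  tests <- do.call(rbind, rows)
  adj <- adjust_pvalues(tests$p, "bonferroni", alpha)
  tests$p_adj <- adj$adjusted
  tests$procedure <- "bonferroni"
  tests$significant <- tests$p_adj <= alpha
  rownames(tests) <- NULL
  list(scores = do.call(rbind, score_tab), tests = tests)
}
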