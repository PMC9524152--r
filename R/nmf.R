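#' Prepare a count matrix for factorization
#'
#' Normalization fed to the NMF: per-nucleus CP10K + log1p, restriction to the
#' `n_hvg` highest-variance genes (zero-variance genes are never selected),
#' then per-gene unit-variance scaling without mean-centering so the matrix
#' stays nonnegative (any numerical negatives are clipped at 0).
#'
#' @param x a [count_matrix()].
#' @param n_hvg number of highly variable genes to keep.
#' @return Dense nuclei x genes matrix with gene/barcode dimnames.
#' @export
prepare_matrix <- function(x, n_hvg = 1500) {
  stopifnot(inherits(x, "count_matrix"))
  norm <- normalize_log_cp10k(x$counts)
  mu <- Matrix::rowMeans(norm)
  mu2 <- Matrix::rowMeans(norm^2)
  n <- ncol(norm)
  v <- pmax(0, (mu2 - mu^2) * n / max(1, n - 1))
  usable <- which(v > 0)
  if (n_hvg > length(usable))
    stop("n_hvg exceeds the ", length(usable), " genes with nonzero variance")
  hvg <- usable[order(v[usable], decreasing = TRUE)[seq_len(n_hvg)]]
  hvg <- sort(hvg)
  M <- as.matrix(Matrix::t(norm[hvg, , drop = FALSE]))
  M <- sweep(M, 2, sqrt(v[hvg]), "/")
  M <- pmax(M, 0)
  dimnames(M) <- list(x$barcodes, x$gene_ids[hvg])
  M
}

#' Run repeated NMF replicates
#'
#' Each replicate solves \eqn{\min \|M - WH\|_F, W, H \ge 0} by HALS block
#' coordinate descent from a random nonnegative initialization seeded at
#' `base_seed + i - 1`. H rows are rescaled onto the simplex with the scale
#' absorbed into W. Non-converged replicates are kept and flagged.
#'
#' @param M nonnegative matrix (nuclei x genes), e.g. from [prepare_matrix()].
#' @param k factorization rank, `1 <= k <= min(dim(M))`.
#' @param n_replicates number of random restarts (default 50).
#' @param base_seed integer; replicate i uses seed `base_seed + i - 1`.
#' @param max_iter,tol sweep budget and relative-error stopping tolerance.
#' @return list of replicates, each with `spectra` (k x genes, rows on the
#'   simplex), `usage_raw`, `seed`, `frobenius_error`, `converged`.
#' @export
run_nmf_replicates <- function(M, k, n_replicates = 50, base_seed = 1L,
                               max_iter = 200, tol = 1e-4) {
  if (k < 1 || k > min(dim(M))) stop("k must satisfy 1 <= k <= min(dim(M))")
  if (any(M < 0)) stop("M must be nonnegative")
  lapply(seq_len(n_replicates), function(i) {
    seed <- (as.integer(base_seed) + i - 1L) %% .Machine$integer.max
    fit <- .cpp_nmf_hals(M, as.integer(k), as.integer(seed),
                         as.integer(max_iter), tol)
    spectra <- fit$H
    colnames(spectra) <- colnames(M)
    if (!fit$converged)
      warning("replicate ", i, " (seed ", seed, ") not converged after ",
              max_iter, " iterations; kept and flagged")
    list(spectra = spectra, usage_raw = fit$W, seed = seed,
         frobenius_error = fit$frobenius_error, converged = fit$converged)
  })
}

# mean silhouette width; rows of singleton clusters are excluded (with the
# exclusion reported via attribute)
silhouette_mean <- function(d, cluster) {
  d <- as.matrix(d)
  n <- length(cluster)
  sizes <- table(cluster)
  singletons <- names(sizes)[sizes < 2]
  s <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    ci <- as.character(cluster[i])
    if (ci %in% singletons) next
    same <- cluster == cluster[i]
    a <- sum(d[i, same]) / (sum(same) - 1)
    b <- Inf
    for (cj in names(sizes)) {
      if (cj == ci) next
      b <- min(b, mean(d[i, cluster == as.integer(cj)]))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  structure(mean(s, na.rm = TRUE), n_excluded = sum(is.na(s)))
}

# k-means++ seeding, deterministic under the current RNG state
kmeanspp_centers <- function(P, k) {
  n <- nrow(P)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((P - matrix(P[centers[1], ], n, ncol(P), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 <= 0)) {
      pool <- setdiff(seq_len(n), centers[seq_len(j)])
      centers[j + 1] <- pool[1]
    } else {
      centers[j + 1] <- sample.int(n, 1, prob = d2 / sum(d2))
    }
    dn <- rowSums((P - matrix(P[centers[j + 1], ], n, ncol(P), byrow = TRUE))^2)
    d2 <- pmin(d2, dn)
  }
  P[centers, , drop = FALSE]
}

#' Aggregate NMF replicates into consensus programs
#'
#' Pools all replicate spectra rows, removes outlier components (rows whose
#' mean Euclidean distance to their `outlier_knn` nearest neighbours exceeds
#' the `outlier_quantile` quantile of that statistic), clusters the retained
#' rows into `k` groups by k-means (k-means++ seeding, fixed seed), and takes
#' the component-wise median of each cluster — renormalized to the simplex —
#' as the consensus spectra. Stability is the mean silhouette width of the
#' clustering; usage is refit by nonnegative least squares of `M` onto the
#' consensus spectra and row-normalized; the reconstruction error comes from
#' the refit.
#'
#' @param M the matrix passed to [run_nmf_replicates()].
#' @param replicates output of [run_nmf_replicates()] (>= 2 replicates).
#' @param k number of consensus programs.
#' @param outlier_knn neighbours used in the outlier statistic; default 30%
#'   of the pool size.
#' @param outlier_quantile retention quantile (default 0.9); set 1 to disable
#'   filtering.
#' @param seed RNG seed for the clustering.
#' @return A `consensus_result`: `k`, `consensus_spectra` (k x genes, simplex
#'   rows), `usage` (nuclei x k, simplex rows), `stability`,
#'   `reconstruction_error`, `n_replicates`, `outlier_fraction_removed`,
#'   `cluster_sizes`, `component_retained` (which pooled rows survived the
#'   outlier filter).
#' @export
build_consensus <- function(M, replicates, k, outlier_knn = NULL,
                            outlier_quantile = 0.9, seed = 1L) {
  if (length(replicates) < 2) stop("need >= 2 replicates")
  P <- do.call(rbind, lapply(replicates, `[[`, "spectra"))
  n_pool <- nrow(P)
  if (is.null(outlier_knn)) outlier_knn <- max(1L, round(0.3 * n_pool))
  outlier_knn <- min(outlier_knn, n_pool - 1L)

  D <- as.matrix(dist(P))
  knn_mean <- vapply(seq_len(n_pool), function(i)
    mean(sort(D[i, -i], partial = outlier_knn)[seq_len(outlier_knn)]),
    numeric(1))
  thr <- quantile(knn_mean, outlier_quantile, names = FALSE)
  keep <- knn_mean <= thr
  if (sum(keep) < k) keep <- rep(TRUE, n_pool)
  Pk <- P[keep, , drop = FALSE]
  Dk <- D[keep, keep, drop = FALSE]

  set.seed(as.integer(seed))
  centers <- kmeanspp_centers(Pk, k)
  km <- suppressWarnings(kmeans(Pk, centers = centers, iter.max = 100))
  sizes <- tabulate(km$cluster, nbins = k)
  if (any(sizes < 2))
    warning(sum(sizes < 2), " consensus cluster(s) received < 2 components; ",
            "excluded from the stability estimate")

  consensus <- t(vapply(seq_len(k), function(j) {
    rows <- Pk[km$cluster == j, , drop = FALSE]
    apply(rows, 2, median)
  }, numeric(ncol(Pk))))
  rs <- rowSums(consensus)
  rs[rs == 0] <- 1
  consensus <- consensus / rs
  rownames(consensus) <- sprintf("program_%d", seq_len(k))
  colnames(consensus) <- colnames(P)

  stability <- as.numeric(silhouette_mean(Dk, km$cluster))

  U <- .cpp_nnls_rows(consensus, M)
  recon <- sqrt(max(0, sum(M^2) - 2 * sum(U * (M %*% t(consensus))) +
                      sum(crossprod(U) * (consensus %*% t(consensus)))))
  urs <- rowSums(U)
  zero_rows <- urs == 0
  if (any(zero_rows)) U[zero_rows, ] <- 1 / k
  urs[zero_rows] <- 1
  usage <- U / urs
  dimnames(usage) <- list(rownames(M), rownames(consensus))

  structure(list(
    k = k, consensus_spectra = consensus, usage = usage,
    stability = stability, reconstruction_error = recon,
    n_replicates = length(replicates),
    outlier_fraction_removed = 1 - mean(keep),
    cluster_sizes = sizes,
    component_retained = keep
  ), class = "consensus_result")
}

#' @exportS3Method print consensus_result
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k = %d, stability = %.3f, error = %.4g (%d replicates, %.0f%% outliers removed)\n",
              x$k, x$stability, x$reconstruction_error, x$n_replicates,
              100 * x$outlier_fraction_removed))
  invisible(x)
}

#' Run the full consensus factorization for one k
#'
#' Convenience wrapper: [run_nmf_replicates()] followed by
#' [build_consensus()].
#'
#' @inheritParams run_nmf_replicates
#' @inheritParams build_consensus
#' @return A `consensus_result`.
#' @export
consensus_nmf <- function(M, k, n_replicates = 50, base_seed = 1L,
                          max_iter = 200, tol = 1e-4, outlier_knn = NULL,
                          outlier_quantile = 0.9) {
  reps <- run_nmf_replicates(M, k, n_replicates, base_seed, max_iter, tol)
  build_consensus(M, reps, k, outlier_knn, outlier_quantile,
                  seed = as.integer(base_seed))
}

#' Select the number of programs from a diagnostics grid
#'
#' Scores each candidate k by min-max-normalized `stability - lambda * error`
#' across the grid and returns the maximizer (smallest k on ties) together
#' with the full diagnostics table, so the choice can be overridden by
#' inspection — model choice on real data typically also weighs parsimony and
#' biological coherence.
#'
#' @param results list of `consensus_result` objects over a grid of >= 3 ks.
#' @param lambda weight on the normalized reconstruction error.
#' @return list with `selected_k`, `diagnostics` (k, stability, error, score),
#'   `lambda`.
#' @export
select_k <- function(results, lambda = 1) {
  if (length(results) < 3) stop("k grid must have >= 3 values")
  diag_df <- data.frame(
    k = vapply(results, `[[`, 0, "k"),
    stability = vapply(results, `[[`, 0, "stability"),
    error = vapply(results, `[[`, 0, "reconstruction_error")
  )
  mm <- function(v) if (diff(range(v)) == 0) rep(0, length(v)) else
    (v - min(v)) / diff(range(v))
  diag_df$score <- mm(diag_df$stability) - lambda * mm(diag_df$error)
  best <- diag_df$k[diag_df$score == max(diag_df$score)]
  list(selected_k = min(best), diagnostics = diag_df, lambda = lambda)
}

#' Define a program set from consensus spectra
#'
#' Annotates each consensus program with its `n_top` highest-weight genes
#' (ties broken lexicographically) and a user-supplied class label
#' (`lineage` or `state`); the class split is annotation, not automatic.
#'
#' @param consensus a `consensus_result` (or a spectra matrix with gene
#'   colnames).
#' @param classes character vector (`"lineage"`/`"state"`), one per program.
#' @param n_top genes kept per program (default 200).
#' @return A `program_set`: list of programs with `name`, `class`,
#'   `top_genes`, `spectra_row`.
#' @export
program_set <- function(consensus, classes, n_top = 200) {
  spectra <- if (inherits(consensus, "consensus_result"))
    consensus$consensus_spectra else consensus
  if (is.null(colnames(spectra))) stop("spectra must carry gene colnames")
  k <- nrow(spectra)
  if (length(classes) != k) stop("need one class per program")
  if (!all(classes %in% c("lineage", "state")))
    stop("classes must be 'lineage' or 'state'")
  n_top <- min(n_top, ncol(spectra))
  programs <- lapply(seq_len(k), function(j) {
    w <- spectra[j, ]
    ord <- order(-w, colnames(spectra))
    list(name = rownames(spectra)[j] %||% sprintf("program_%d", j),
         class = classes[j],
         top_genes = colnames(spectra)[ord[seq_len(n_top)]],
         spectra_row = w)
  })
  names(programs) <- vapply(programs, `[[`, "", "name")
  structure(list(programs = programs, spectra = spectra), class = "program_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Top-weighted gene lists of a program set, as GMT-ready sets
#'
#' @param ps a [program_set()].
#' @return named list of character vectors.
#' @export
program_gene_sets <- function(ps) {
  stopifnot(inherits(ps, "program_set"))
  lapply(ps$programs, `[[`, "top_genes")
}

#' Classify nuclei by top-weighted program
#'
#' Each nucleus gets a lineage label (argmax of usage over lineage programs)
#' and a state label (argmax over state programs). Exact ties go to the
#' lowest program index and are flagged. If a class has no programs its label
#' is NA.
#'
#' @param usage nuclei x programs matrix with program colnames (e.g.
#'   `consensus_result$usage`).
#' @param ps a [program_set()] supplying the class of each program.
#' @return data.frame: `barcode` (if usage has rownames), `lineage_program`,
#'   `state_program`, `lineage_tie`, `state_tie`.
#' @export
assign_nuclei <- function(usage, ps) {
  stopifnot(inherits(ps, "program_set"))
  classes <- vapply(ps$programs, `[[`, "", "class")
  prog_names <- names(ps$programs)
  if (!all(prog_names %in% colnames(usage)))
    stop("usage columns do not cover the program set")
  pick <- function(cls) {
    cols <- prog_names[classes == cls]
    if (length(cols) == 0L)
      return(data.frame(label = rep(NA_character_, nrow(usage)),
                        tie = FALSE))
    sub <- usage[, cols, drop = FALSE]
    idx <- apply(sub, 1, which.max)
    mx <- sub[cbind(seq_len(nrow(sub)), idx)]
    tie <- rowSums(sub == mx) > 1
    data.frame(label = cols[idx], tie = tie, stringsAsFactors = FALSE)
  }
  lin <- pick("lineage"); st <- pick("state")
  out <- data.frame(lineage_program = lin$label, state_program = st$label,
                    lineage_tie = lin$tie, state_tie = st$tie,
                    stringsAsFactors = FALSE)
  if (!is.null(rownames(usage))) out <- cbind(barcode = rownames(usage), out)
  out
}

#' Refit usages of a matrix onto fixed program spectra
#'
#' Nonnegative least-squares projection of each nucleus's profile onto a
#' fixed spectra matrix, with rows renormalized to the simplex: the operation
#' used to carry a discovered (or otherwise fixed) program set to new nuclei.
#'
#' @param M nuclei x genes nonnegative matrix (columns aligned with
#'   `spectra`).
#' @param spectra k x genes nonnegative matrix (e.g.
#'   `consensus_result$consensus_spectra`).
#' @return nuclei x k usage matrix with simplex rows.
#' @export
refit_usage <- function(M, spectra) {
  if (ncol(M) != ncol(spectra)) stop("M and spectra must share the gene axis")
  U <- .cpp_nnls_rows(spectra, M)
  rs <- rowSums(U)
  zero <- rs == 0
  if (any(zero)) { U[zero, ] <- 1 / nrow(spectra); rs[zero] <- 1 }
  U <- U / rs
  dimnames(U) <- list(rownames(M), rownames(spectra))
  U
}

#' Project known usages onto a matrix to obtain reference spectra
#'
#' Given true (or otherwise fixed) per-nucleus usages, recovers the spectra
#' they induce in the space of a prepared matrix by nonnegative least squares:
#' \eqn{\hat H = \arg\min_{H \ge 0} \|M - U H\|_F}, rows renormalized to the
#' simplex. This maps planted rate-space spectra through the same
#' normalization the factorization sees, giving the like-for-like reference
#' when scoring recovery of planted programs.
#'
#' @param M prepared nuclei x genes matrix (see [prepare_matrix()]).
#' @param usage nuclei x k nonnegative usage matrix.
#' @return k x genes matrix with simplex rows.
#' @export
project_spectra <- function(M, usage) {
  if (nrow(usage) != nrow(M)) stop("usage and M must have matching nuclei")
  H <- t(.cpp_nnls_rows(t(usage), t(M)))
  rs <- rowSums(H)
  rs[rs == 0] <- 1
  H <- H / rs
  dimnames(H) <- list(colnames(usage), colnames(M))
  H
}

#' Match two sets of program spectra by maximal total cosine similarity
#'
#' Exact solution of the assignment problem (Hungarian-equivalent) by dynamic
#' programming over subsets of the smaller side; intended for comparing
#' discovered spectra to planted or reference spectra with at most ~15
#' programs per side.
#'
#' @param A,B matrices with programs in rows over a shared gene axis
#'   (columns aligned).
#' @return list with `pairs` (data.frame `row_a`, `row_b`, `cosine`) and
#'   `mean_cosine`.
#' @export
match_programs <- function(A, B) {
  if (ncol(A) != ncol(B)) stop("A and B must share the gene axis")
  na <- nrow(A); nb <- nrow(B)
  norm_rows <- function(X) {
    n <- sqrt(rowSums(X^2)); n[n == 0] <- 1; X / n
  }
  S <- norm_rows(A) %*% t(norm_rows(B))   # na x nb cosine
  flip <- na > nb
  if (flip) S <- t(S)
  ns <- nrow(S); nl <- ncol(S)
  if (ns > 16) stop("too many programs for exact matching")
  # f[j+1, mask+1] = best total assigning row subset 'mask' within columns 1..j
  nmask <- 2L^ns
  f <- matrix(-Inf, nl + 1L, nmask)
  f[1L, 1L] <- 0
  for (j in seq_len(nl)) {
    f[j + 1L, ] <- f[j, ]                       # column j unused
    for (mask in 0:(nmask - 1L)) {
      if (!is.finite(f[j, mask + 1L])) next
      base <- f[j, mask + 1L]
      for (i in seq_len(ns)) {
        bit <- bitwShiftL(1L, i - 1L)
        if (bitwAnd(mask, bit) > 0L) next
        nm <- bitwOr(mask, bit) + 1L
        val <- base + S[i, j]
        if (val > f[j + 1L, nm]) f[j + 1L, nm] <- val
      }
    }
  }
  # backtrack from the full mask
  assign_small <- integer(ns)
  mask <- nmask - 1L
  j <- nl
  while (mask > 0L && j > 0L) {
    if (abs(f[j + 1L, mask + 1L] - f[j, mask + 1L]) < 1e-12) {
      j <- j - 1L
      next
    }
    done <- FALSE
    for (i in seq_len(ns)) {
      bit <- bitwShiftL(1L, i - 1L)
      if (bitwAnd(mask, bit) == 0L) next
      prev <- mask - bit
      if (abs(f[j + 1L, mask + 1L] - (f[j, prev + 1L] + S[i, j])) < 1e-9) {
        assign_small[i] <- j
        mask <- prev
        j <- j - 1L
        done <- TRUE
        break
      }
    }
    if (!done) stop("internal error: assignment backtracking failed")
  }
  pairs <- data.frame(
    row_a = if (flip) assign_small else seq_len(ns),
    row_b = if (flip) seq_len(ns) else assign_small
  )
  pairs$cosine <- S[cbind(seq_len(ns), assign_small)]
  list(pairs = pairs, mean_cosine = mean(pairs$cosine))
}

#' Write consensus outputs to TSV/GMT files
#'
#' @param res a `consensus_result`.
#' @param dir output directory; writes `spectra.tsv` (programs x genes),
#'   `usage.tsv`, and, given a program set, `top_genes.gmt`.
#' @param ps optional [program_set()] for the GMT.
#' @return `dir`, invisibly.
#' @export
write_consensus <- function(res, dir, ps = NULL) {
  stopifnot(inherits(res, "consensus_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(res$consensus_spectra, file.path(dir, "spectra.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  write.table(res$usage, file.path(dir, "usage.tsv"),
              sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(ps)) write_gmt(program_gene_sets(ps), file.path(dir, "top_genes.gmt"))
  invisible(dir)
}
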