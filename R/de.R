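#' Principal components of a normalized expression matrix
#'
#' PCA of the log-normalized matrix with a deterministic sign convention:
#' within each component, the loading of largest magnitude is made positive.
#' Used to supply the fixed-effect PC covariates of the differential
#' expression model.
#'
#' @param M nuclei x genes numeric matrix (dense or sparse).
#' @param n_pcs number of components (must not exceed the matrix rank).
#' @return nuclei x n_pcs score matrix (columns `PC1`, ...).
#' @export
compute_pcs <- function(M, n_pcs = 3) {
  M <- as.matrix(M)
  if (n_pcs > min(nrow(M) - 1, ncol(M)))
    stop("n_pcs exceeds the matrix rank bound")
  pc <- prcomp(M, center = TRUE, scale. = FALSE, rank. = n_pcs)
  if (ncol(pc$x) < n_pcs) stop("n_pcs exceeds the rank of the matrix")
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  scores <- pc$x[, seq_len(n_pcs), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(n_pcs))
  scores
}

# One-gene Poisson GLMM with a single random intercept, fit by penalized
# IRLS (joint mode of beta and b given sigma^2) inside a 1-D profile of the
# Laplace-approximate log-likelihood over sigma^2. Exploits the diagonal
# structure of Z'WZ for a patient-indicator Z via the Schur complement.
pglmm_pirls <- function(y, X, pat, q, off, inv_s2, max_iter = 50, tol = 1e-8) {
  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- log(mean(y) + 1e-8) - mean(off)   # column 1 is the intercept
  b <- numeric(q)
  eta <- drop(X %*% beta) + b[pat] + off
  C <- NULL
  for (it in seq_len(max_iter)) {
    eta <- pmin(eta, 30)
    mu <- exp(eta)
    w <- mu
    z <- (eta - off) + (y - mu) / mu
    Xw <- X * w
    A <- crossprod(X, Xw)
    Bq <- rowsum(Xw, pat)                      # q x p
    D <- drop(rowsum(w, pat)) + inv_s2
    rx <- drop(crossprod(X, w * z))
    rb <- drop(rowsum(w * z, pat))
    if (is.finite(inv_s2)) {
      C <- A - crossprod(Bq, Bq / D)
      rhs <- rx - drop(crossprod(Bq, rb / D))
    } else {                                   # sigma = 0: plain GLM
      C <- A
      rhs <- rx
    }
    beta_new <- tryCatch(solve(C, rhs), error = function(e) rep(NA_real_, p))
    if (anyNA(beta_new)) return(list(ok = FALSE))
    b_new <- if (is.finite(inv_s2)) (rb - drop(Bq %*% beta_new)) / D else numeric(q)
    delta <- max(abs(c(beta_new - beta, b_new - b)))
    beta <- beta_new; b <- b_new
    eta <- drop(X %*% beta) + b[pat] + off
    if (delta < tol) break
  }
  eta <- pmin(eta, 30)
  mu <- exp(eta)
  wsum <- drop(rowsum(mu, pat))
  ll <- sum(y * eta - mu - lgamma(y + 1))
  if (is.finite(inv_s2)) {
    s2 <- 1 / inv_s2
    ll <- ll - sum(b^2) * inv_s2 / 2 - 0.5 * sum(log1p(s2 * wsum))
  }
  list(ok = TRUE, beta = beta, b = b, C = C, loglik = ll, mu = mu,
       iterations = it)
}

fit_pglmm_one <- function(y, X, pat, q, off, s2_max = 9) {
  glm_fit <- pglmm_pirls(y, X, pat, q, off, Inf)
  if (!glm_fit$ok) return(NULL)
  obj <- function(log_s2) {
    f <- pglmm_pirls(y, X, pat, q, off, exp(-log_s2))
    if (!f$ok) return(-1e12)
    f$loglik
  }
  opt <- optimize(obj, interval = c(log(s2_max) - 14, log(s2_max)),
                  maximum = TRUE, tol = 1e-4)
  if (opt$objective > glm_fit$loglik + 1e-6) {
    s2 <- exp(opt$maximum)
    fit <- pglmm_pirls(y, X, pat, q, off, 1 / s2)
  } else {
    s2 <- 0
    fit <- glm_fit
  }
  se <- tryCatch(sqrt(diag(solve(fit$C))), error = function(e) rep(Inf, ncol(X)))
  list(beta = fit$beta, se = se, sigma2 = s2, loglik = fit$loglik)
}

#' Mixed-effects Poisson differential expression
#'
#' For each gene, fits \eqn{\log E[y] = X\beta + b_{patient} + \mathrm{offset}}
#' with \eqn{b \sim N(0, \sigma^2)} by Laplace-approximated maximum likelihood
#' (penalized IRLS inner loop, 1-D profile over \eqn{\sigma}), and reports the
#' Wald test of the in-program group coefficient with Bonferroni adjustment
#' across tested genes. Fixed effects are the group indicator plus any
#' supplied covariates (typically treatment arm, sex and the first principal
#' components); the offset is the log of per-nucleus total UMIs divided by
#' their median. Genes expressed in fewer than `min_expr_frac` of nuclei are
#' not tested; genes whose fit degenerates (e.g. group separation within
#' patients) are flagged with an infinite standard error, not dropped.
#'
#' @param counts genes x nuclei count matrix (sparse or dense, raw counts).
#' @param group per-nucleus 0/1 indicator (in-program vs other).
#' @param patient per-nucleus patient/sample identifier (random intercept).
#' @param covariates optional per-nucleus data.frame of fixed-effect
#'   covariates; factors are expanded via `model.matrix`.
#' @param total_umis per-nucleus totals for the offset; defaults to
#'   `colSums(counts)`.
#' @param min_expr_frac expression filter (fraction of nuclei with a count).
#' @param s2_max upper bound of the random-intercept variance profile search;
#'   values near 0 constrain the model to its plain Poisson GLM limit.
#' @return data.frame: `gene`, `beta`, `se`, `p`, `p_adj`, `converged`,
#'   `sigma_patient`.
#' @export
fit_poisson_glmm <- function(counts, group, patient, covariates = NULL,
                             total_umis = NULL, min_expr_frac = 0.01,
                             s2_max = 9) {
  n <- ncol(counts)
  if (length(group) != n || length(patient) != n)
    stop("group and patient must have one entry per nucleus")
  group <- as.integer(group)
  if (!all(group %in% c(0L, 1L))) stop("group must be 0/1")
  if (length(unique(group)) < 2) stop("group must have nuclei on both sides")
  pat <- as.integer(factor(patient))
  q <- max(pat)
  if (q < 2) stop("need >= 2 patients for a random intercept")
  if (is.null(total_umis)) total_umis <- Matrix::colSums(counts)
  if (any(total_umis <= 0)) stop("total_umis must be positive")
  off <- log(total_umis / median(total_umis))

  X <- cbind(`(Intercept)` = 1, group = group)
  if (!is.null(covariates)) {
    mm <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    X <- cbind(X, mm)
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank-deficient")

  expr_frac <- Matrix::rowMeans(counts > 0)
  test_idx <- which(expr_frac >= min_expr_frac)
  if (length(test_idx) == 0L) stop("no gene passes the expression filter")

  genes <- rownames(counts) %||% sprintf("gene_%d", seq_len(nrow(counts)))
  res <- lapply(test_idx, function(g) {
    y <- as.numeric(counts[g, ])
    fit <- fit_pglmm_one(y, X, pat, q, off, s2_max = s2_max)
    if (is.null(fit))
      return(data.frame(gene = genes[g], beta = NA_real_, se = Inf, p = 1,
                        converged = FALSE, sigma_patient = NA_real_))
    bhat <- fit$beta[2]
    se <- fit$se[2]
    bad <- !is.finite(bhat) || !is.finite(se) || abs(bhat) > 15
    p <- if (bad) 1 else min(1, 2 * pnorm(-abs(bhat / se)))
    data.frame(gene = genes[g], beta = bhat, se = if (bad) Inf else se, p = p,
               converged = !bad, sigma_patient = sqrt(fit$sigma2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out$p_adj <- adjust_pvalues(out$p, "bonferroni")$adjusted
  out[, c("gene", "beta", "se", "p", "p_adj", "converged", "sigma_patient")]
}
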