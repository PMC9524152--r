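#' Statistical primitives
#'
#' Self-contained implementations of the tests used throughout the pipeline:
#' the two-sided hypergeometric overlap test, the two-sided Mann-Whitney U
#' test, the two-sided Wilcoxon signed-rank test, and Benjamini-Hochberg /
#' Bonferroni multiplicity control. Each is written from first principles so
#' it can be verified against brute-force enumeration.
#'
#' @name stats-primitives
NULL

new_test_result <- function(statistic, p_value, method, n1, n2, flags = character()) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    list(statistic = statistic, p_value = p_value, method = method,
         n1 = n1, n2 = n2, flags = flags),
    class = "ec_test_result"
  )
}

#' @exportS3Method print ec_test_result
print.ec_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g (n1 = %d, n2 = %d)\n",
              x$method, x$statistic, x$p_value, x$n1, x$n2))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

# log hypergeometric pmf at x for population N, K successes, n draws
hyper_lpmf <- function(x, N, K, n) {
  lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
}

#' Two-sided hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap between `set_a` and `set_b`, drawn from a common
#' `universe`, is larger or smaller than expected by chance. With
#' \eqn{N = |universe|}, \eqn{K = |A|}, \eqn{n = |B|} and observed overlap
#' \eqn{k = |A \cap B|}, the two-sided p-value is
#' \eqn{\min(1, 2 \min(P(X \le k), P(X \ge k)))} under the hypergeometric
#' distribution — doubling the smaller tail, capped at 1.
#'
#' @param set_a,set_b character vectors of gene identifiers; must be subsets
#'   of `universe`.
#' @param universe character vector of all testable genes.
#' @return An `ec_test_result` with the overlap size as `statistic`.
#' @examples
#' u <- paste0("G", 1:40)
#' hypergeometric_overlap_test(u[1:10], u[c(1:2, 20:27)], u)
#' @export
hypergeometric_overlap_test <- function(set_a, set_b, universe) {
  if (length(universe) == 0L) stop("universe must be nonempty")
  if (length(set_a) == 0L || length(set_b) == 0L)
    stop("set_a and set_b must be nonempty")
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  miss_a <- setdiff(set_a, universe)
  if (length(miss_a))
    stop("set_a gene(s) absent from universe: ", paste(head(miss_a, 5), collapse = ", "))
  miss_b <- setdiff(set_b, universe)
  if (length(miss_b))
    stop("set_b gene(s) absent from universe: ", paste(head(miss_b, 5), collapse = ", "))

  N <- length(universe); K <- length(set_a); n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  support <- max(0L, n - (N - K)):min(K, n)
  pmf <- exp(hyper_lpmf(support, N, K, n))
  lower <- sum(pmf[support <= k])
  upper <- sum(pmf[support >= k])
  p <- min(1, 2 * min(lower, upper))
  new_test_result(statistic = k, p_value = p,
                  method = "hypergeometric_two_sided", n1 = K, n2 = n)
}

# exact two-sided MWU p by enumerating all C(n1+n2, n1) group labelings
mwu_exact_p <- function(r, n1) {
  n <- length(r)
  idx <- combn(n, n1)
  u_all <- colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
  mu <- n1 * (n - n1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

#' Two-sided Mann-Whitney U test
#'
#' Rank-sum test with midrank handling of ties. For pooled sample size of at
#' most 12 with no ties the p-value is exact, obtained by enumerating all
#' group labelings of the pooled ranks; otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric vectors (each nonempty).
#' @return An `ec_test_result` with the U statistic for `x`.
#' @examples
#' mann_whitney_u(c(1, 2, 3, 4), c(5, 6, 7, 8))
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("x and y must be nonempty")
  x <- as.numeric(x); y <- as.numeric(y)
  if (anyNA(x) || anyNA(y)) stop("NA values are not supported")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(x, y))
  has_ties <- any(ties > 1)
  flags <- character()

  if (n <= 12 && !has_ties) {
    p <- mwu_exact_p(r, n1)
    flags <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
    if (sigma2 <= 0) {
      p <- 1
      flags <- "degenerate_all_ties"
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      flags <- "normal_approx"
    }
  }
  new_test_result(statistic = u, p_value = p,
                  method = "mann_whitney_u_two_sided", n1 = n1, n2 = n2,
                  flags = flags)
}

# exact two-sided signed-rank p by enumerating all 2^m sign assignments
signed_rank_exact_p <- function(ranks, v_obs) {
  m <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
  v_all <- as.vector(signs %*% ranks)
  mu <- m * (m + 1) / 4
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-9)
}

#' Two-sided Wilcoxon signed-rank test for paired samples
#'
#' Pairs are matched by index. Zero differences are dropped (Wilcoxon's
#' convention); if all differences are zero the test returns p = 1 with an
#' `all_zero_differences` flag. The p-value is exact (enumeration of all
#' sign assignments) for at most 12 nonzero pairs with untied absolute
#' differences, otherwise a tie-corrected normal approximation with
#' continuity correction.
#'
#' @param before,after numeric vectors of equal length.
#' @return An `ec_test_result`; `statistic` is the positive-rank sum V.
#' @examples
#' wilcoxon_signed_rank(1:5, 1:5 + c(1, 2, 3, 4, 5))
#' @export
wilcoxon_signed_rank <- function(before, after) {
  if (length(before) != length(after)) stop("before and after must have equal length")
  if (length(before) == 0L) stop("inputs must be nonempty")
  d <- as.numeric(after) - as.numeric(before)
  if (anyNA(d)) stop("NA values are not supported")
  n_pairs <- length(d)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all differences are zero; returning p = 1")
    return(new_test_result(statistic = 0, p_value = 1,
                           method = "wilcoxon_signed_rank_two_sided",
                           n1 = n_pairs, n2 = n_pairs,
                           flags = "all_zero_differences"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  has_ties <- any(table(abs(d)) > 1)
  if (m <= 12 && !has_ties) {
    p <- signed_rank_exact_p(r, v)
    flags <- "exact"
  } else {
    mu <- m * (m + 1) / 4
    tt <- table(abs(d))
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tt^3 - tt) / 48
    if (sigma2 <= 0) {
      p <- 1
      flags <- "degenerate"
    } else {
      z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
      flags <- "normal_approx"
    }
  }
  new_test_result(statistic = v, p_value = p,
                  method = "wilcoxon_signed_rank_two_sided",
                  n1 = n_pairs, n2 = n_pairs, flags = flags)
}

#' Multiple-testing adjustment (Benjamini-Hochberg or Bonferroni)
#'
#' Benjamini-Hochberg adjusted values follow the step-up definition
#' \eqn{\tilde p_{(i)} = \min_{j \ge i} \min(1, p_{(j)} m / j)}; Bonferroni is
#' \eqn{\min(1, m p)}. Significance is called at `fdr_level` on the adjusted
#' values (the pipeline default is FDR = 0.1 for BH families).
#'
#' @param raw numeric vector of raw p-values in \[0, 1\].
#' @param procedure `"benjamini_hochberg"` or `"bonferroni"`.
#' @param fdr_level level at which `significant` is called on adjusted values.
#' @return A list with `raw`, `adjusted`, `procedure`, `fdr_level`,
#'   `significant` (class `adjusted_pvalues`).
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03, 0.5))$adjusted
#' @export
adjust_pvalues <- function(raw,
                           procedure = c("benjamini_hochberg", "bonferroni"),
                           fdr_level = 0.1) {
  procedure <- match.arg(procedure)
  raw <- as.numeric(raw)
  if (anyNA(raw) || any(raw < 0 | raw > 1))
    stop("raw p-values must lie in [0, 1]")
  m <- length(raw)
  if (procedure == "bonferroni") {
    adjusted <- pmin(1, m * raw)
  } else {
    o <- order(raw, decreasing = TRUE)
    ro <- order(o)
    adjusted <- pmin(1, cummin(m / (m:1) * raw[o]))[ro]
  }
  structure(
    list(raw = raw, adjusted = adjusted, procedure = procedure,
         fdr_level = fdr_level, significant = adjusted <= fdr_level),
    class = "adjusted_pvalues"
  )
}

#' Write a table of test results to TSV
#'
#' Standard serialization used by the association analyses: columns
#' `comparison`, `statistic`, `p`, `p_adj`, `procedure`.
#'
#' @param results data.frame with at least those columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_test_results <- function(results, path) {
  need <- c("comparison", "statistic", "p", "p_adj", "procedure")
  missing_cols <- setdiff(need, names(results))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  write.table(results[, c(need, setdiff(names(results), need))], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
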