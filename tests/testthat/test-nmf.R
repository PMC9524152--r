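test_that("prepare_matrix normalizes, selects HVGs, and stays nonnegative", {
  # with equal nucleus totals, a constant gene has zero variance after
  # normalization and can never enter the HVG set
  m <- rbind(rep(4L, 4), c(1L, 3L, 2L, 0L), c(5L, 3L, 4L, 6L))
  stopifnot(length(unique(colSums(m))) == 1)
  x <- tiny_counts(m)
  M <- prepare_matrix(x, n_hvg = 2)
  expect_false("G001" %in% colnames(M))
  expect_error(prepare_matrix(x, n_hvg = 1000), "nonzero variance")
  set.seed(4)
  for (i in 1:10) {
    x2 <- tiny_counts(matrix(rpois(300, 2), 20, 15))
    M2 <- prepare_matrix(x2, n_hvg = 10)
    expect_true(all(M2 >= 0))
    # unit variance scaling of retained genes
    expect_equal(unname(apply(M2, 2, sd)), rep(1, 10), tolerance = 1e-8)
  }
})

test_that("planted program markers land in the HVG set", {
  fx <- small_sim()
  M <- prepare_matrix(fx$sim$counts, n_hvg = 300)
  planted <- unlist(fx$sim$truth$planted_gene_sets)
  expect_true(all(planted %in% colnames(M)))
})

test_that("factorization is exact on rank-1 input and deterministic", {
  set.seed(2)
  M1 <- outer(runif(50, 1, 2), runif(30, 0.5, 2))
  colnames(M1) <- sprintf("g%02d", 1:30)
  f <- run_nmf_replicates(M1, k = 1, n_replicates = 1, base_seed = 6)
  expect_lte(f[[1]]$frobenius_error, 1e-6)

  pf <- planted_factors()
  # exact planted data converges geometrically; the sweep-budget flag is expected
  r1 <- suppressWarnings(run_nmf_replicates(pf$M, 4, 3, base_seed = 42))
  r2 <- suppressWarnings(run_nmf_replicates(pf$M, 4, 3, base_seed = 42))
  expect_identical(r1[[1]]$spectra, r2[[1]]$spectra)
  expect_identical(r1[[3]]$usage_raw, r2[[3]]$usage_raw)
})

test_that("replicates recover well-separated planted spectra", {
  pf <- planted_factors()
  reps <- suppressWarnings(run_nmf_replicates(pf$M, 4, 6, base_seed = 13))
  for (r in reps) {
    mt <- match_programs(r$spectra, pf$H)
    expect_gte(min(mt$pairs$cosine), 0.8)
  }
})

test_that("gene permutation permutes spectra columns identically", {
  pf <- planted_factors(n = 80, g = 60)
  perm <- sample(60)
  r1 <- suppressWarnings(run_nmf_replicates(pf$M, 3, 1, base_seed = 5))
  r2 <- suppressWarnings(run_nmf_replicates(pf$M[, perm], 3, 1, base_seed = 5))
  expect_equal(r1[[1]]$spectra[, perm], r2[[1]]$spectra,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("consensus of identical replicates is perfectly stable", {
  pf <- planted_factors()
  one <- suppressWarnings(run_nmf_replicates(pf$M, 4, 1, base_seed = 3))[[1]]
  res <- build_consensus(pf$M, rep(list(one), 10), k = 4)
  expect_equal(res$stability, 1, tolerance = 1e-6)
  mt <- match_programs(res$consensus_spectra, one$spectra)
  expect_gte(min(mt$pairs$cosine), 1 - 1e-8)
  # simplex invariants
  expect_equal(unname(rowSums(res$consensus_spectra)), rep(1, 4),
               tolerance = 1e-8)
  expect_equal(unname(rowSums(res$usage)), rep(1, nrow(pf$M)),
               tolerance = 1e-6)
})

test_that("consensus beats single replicates on planted data", {
  fx <- small_sim()
  M <- prepare_matrix(fx$sim$counts, n_hvg = 300)
  Href <- project_spectra(M, fx$sim$truth$usage_true)
  reps <- run_nmf_replicates(M, 4, 15, base_seed = 77)
  res <- build_consensus(M, reps, 4, seed = 77)
  cons_cos <- match_programs(res$consensus_spectra, Href)$mean_cosine
  rep_cos <- vapply(reps, function(r) match_programs(r$spectra, Href)$mean_cosine, 0)
  expect_gte(cons_cos, 0.9)
  expect_gte(cons_cos, mean(rep_cos) - 1e-8)
})

test_that("outlier filtering removes injected noise components", {
  pf <- planted_factors()
  reps <- suppressWarnings(run_nmf_replicates(pf$M, 4, 10, base_seed = 21))
  set.seed(9)
  noise <- matrix(runif(4 * ncol(pf$M)), 4)
  noise <- noise / rowSums(noise)
  colnames(noise) <- colnames(pf$M)
  fake <- list(spectra = noise, usage_raw = NULL, seed = -1,
               frobenius_error = Inf, converged = TRUE)
  res <- build_consensus(pf$M, c(reps, list(fake)), k = 4,
                         outlier_quantile = 0.9, seed = 1)
  noise_idx <- 40 + 1:4   # pooled after the 10 genuine replicates
  expect_gte(sum(!res$component_retained[noise_idx]), 2)
})

test_that("k selection maximizes the normalized stability-error score", {
  fake <- function(k, stab, err)
    structure(list(k = k, stability = stab, reconstruction_error = err),
              class = "consensus_result")
  # a dominating k (max stability, min error) must be selected
  res <- select_k(list(fake(4, 0.7, 10), fake(5, 1.0, 5), fake(6, 0.6, 9)))
  expect_equal(res$selected_k, 5)
  # monotone case: equals the hand-evaluated score maximizer
  stab <- c(0.95, 0.9, 0.85, 0.8)
  err <- c(10, 8, 7, 6.5)
  res2 <- select_k(list(fake(3, stab[1], err[1]), fake(4, stab[2], err[2]),
                        fake(5, stab[3], err[3]), fake(6, stab[4], err[4])))
  mm <- function(v) (v - min(v)) / diff(range(v))
  score <- mm(stab) - mm(err)
  expect_equal(res2$selected_k, c(3, 4, 5, 6)[which.max(score)])
  expect_equal(res2$diagnostics$score, score, tolerance = 1e-12)
  expect_error(select_k(list(fake(3, 1, 1), fake(4, 1, 1))), ">= 3")
})

test_that("nucleus assignment follows the argmax-within-class rule", {
  spectra <- matrix(runif(3 * 20), 3, 20,
                    dimnames = list(paste0("program_", 1:3),
                                    sprintf("g%02d", 1:20)))
  ps <- program_set(spectra, classes = c("lineage", "lineage", "state"),
                    n_top = 5)
  usage <- rbind(c(1, 0, 0), c(0.2, 0.2, 0.6), c(0.4, 0.4, 0.2))
  colnames(usage) <- names(ps$programs)
  rownames(usage) <- paste0("n", 1:3)
  a <- assign_nuclei(usage, ps)
  expect_equal(a$lineage_program, c("program_1", "program_1", "program_1"))
  expect_equal(a$state_program, rep("program_3", 3))
  # exact tie goes to the lowest index and is flagged
  expect_true(a$lineage_tie[3])
  expect_false(a$lineage_tie[1])
  # no state programs defined: label is NA
  ps_lin <- program_set(spectra, classes = rep("lineage", 3), n_top = 5)
  a2 <- assign_nuclei(usage, ps_lin)
  expect_true(all(is.na(a2$state_program)))
})

test_that("program top genes are ordered by weight with lexicographic ties", {
  spectra <- matrix(0, 1, 4,
                    dimnames = list("program_1", c("B", "A", "D", "C")))
  spectra[1, ] <- c(0.3, 0.3, 0.2, 0.2)
  ps <- program_set(spectra, classes = "lineage", n_top = 4)
  expect_identical(ps$programs$program_1$top_genes, c("A", "B", "C", "D"))
})

test_that("exact program matching agrees with permutation enumeration", {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  set.seed(14)
  for (rep in 1:5) {
    A <- matrix(runif(4 * 12), 4)
    B <- matrix(runif(4 * 12), 4)
    norm_r <- function(X) X / sqrt(rowSums(X^2))
    S <- norm_r(A) %*% t(norm_r(B))
    best <- max(vapply(perms(1:4), function(p)
      sum(S[cbind(1:4, p)]), 0)) / 4
    expect_equal(match_programs(A, B)$mean_cosine, best, tolerance = 1e-12)
  }
})
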