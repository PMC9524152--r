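# shared fixtures and oracles; heavy objects are built once per session
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fun) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- fun()
  .fixtures[[name]]
}

# area under the ROC curve via the rank-sum identity
auroc <- function(score, positive) {
  r <- rank(score)
  (mean(r[positive]) - (sum(positive) + 1) / 2) / sum(!positive)
}

# independent two-sided hypergeometric oracle by binomial-coefficient sums
hyper_oracle_p <- function(N, K, n, k) {
  xs <- max(0, n - (N - K)):min(K, n)
  pmf <- choose(K, xs) * choose(N - K, n - xs) / choose(N, n)
  min(1, 2 * min(sum(pmf[xs <= k]), sum(pmf[xs >= k])))
}

# hand-made count_matrix with controlled entries (genes x nuclei)
tiny_counts <- function(mat, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(mat)))
  if (is.null(cells)) cells <- sprintf("C%03d", seq_len(ncol(mat)))
  count_matrix(mat, genes, cells)
}

# small planted simulation reused across files (pure ECs, 4 programs)
small_sim <- function() fixture("small_sim", function() {
  cfg <- sim_config(n_patients = c(untreated = 6, CRT = 5, CRTL = 2),
                    n_nuclei_per_patient = c(80, 80), n_genes = 600,
                    k_true = 4, n_lineage = 3, shifted_program = 3,
                    complement_program = 1, markers_per_program = 25,
                    seed = 101)
  sim <- simulate_snrnaseq(cfg)
  list(cfg = cfg, sim = sim)
})

# mixed cell-type simulation for extraction tests
mixed_sim <- function() fixture("mixed_sim", function() {
  cfg <- sim_config(n_patients = c(untreated = 5, CRT = 4, CRTL = 2),
                    n_nuclei_per_patient = c(70, 70), n_genes = 600,
                    k_true = 4, n_lineage = 3, shifted_program = 3,
                    complement_program = 1, markers_per_program = 25,
                    frac_endothelial = 0.3,
                    other_cell_types = c("fibroblast", "myeloid", "lymphoid"),
                    seed = 202)
  list(cfg = cfg, sim = simulate_snrnaseq(cfg))
})

# exact planted factorization with well-separated programs
planted_factors <- function(n = 150, g = 120, k = 4, seed = 33) {
  set.seed(seed)
  H <- matrix(rgamma(k * g, shape = 0.2), k, g)
  block <- split(seq_len(g), rep(seq_len(k), length.out = g))
  for (j in seq_len(k)) H[j, block[[j]]] <- H[j, block[[j]]] + 3
  H <- H / rowSums(H)
  colnames(H) <- sprintf("g%03d", seq_len(g))
  W <- matrix(rgamma(n * k, shape = 0.3), n, k)
  W[cbind(seq_len(n), rep(seq_len(k), length.out = n))] <- 4
  list(W = W, H = H, M = W %*% H)
}
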