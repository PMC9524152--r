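test_that("simulators are pure functions of config and seed", {
  cfg <- sim_config(n_patients = c(untreated = 3, CRT = 2, CRTL = 1),
                    n_nuclei_per_patient = c(30, 50), n_genes = 200,
                    k_true = 5, markers_per_program = 10, seed = 7)
  a <- simulate_snrnaseq(cfg)
  b <- simulate_snrnaseq(cfg)
  expect_identical(as.matrix(a$counts$counts), as.matrix(b$counts$counts))
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$usage_true, b$truth$usage_true)

  sigs <- list(p1 = sprintf("S1_%02d", 1:20), p2 = sprintf("S2_%02d", 1:20))
  bc <- bulk_config(n_samples = 40, program_signatures = sigs, seed = 5)
  expect_identical(simulate_bulk_cohort(bc)$expression,
                   simulate_bulk_cohort(bc)$expression)

  pn1 <- simulate_huvec_panel(sigs, effect_sizes = c(p1 = 1), seed = 9)
  pn2 <- simulate_huvec_panel(sigs, effect_sizes = c(p1 = 1), seed = 9)
  expect_identical(pn1$expression, pn2$expression)
})

test_that("counts follow the Poisson library-size identity", {
  # spectra rows and usages are simplexes, so each nucleus's expected total
  # is its library size
  L <- 1500
  cfg <- sim_config(n_patients = c(untreated = 2, CRT = 2, CRTL = 1),
                    n_nuclei_per_patient = c(200, 200), n_genes = 300,
                    k_true = 3, n_lineage = 2, shifted_program = 2,
                    complement_program = 1, markers_per_program = 10,
                    patient_effect_sd = 0,
                    library_size_log_mean = log(L), library_size_log_sd = 0,
                    seed = 12)
  sim <- simulate_snrnaseq(cfg)
  tot <- Matrix::colSums(sim$counts$counts)
  expect_lt(abs(mean(tot) - L), 4 * sqrt(L / length(tot)))
  expect_gt(mean(abs(tot - L) <= 4 * sqrt(L)), 0.99)
  # counts are nonnegative integers; usages on the simplex
  expect_true(all(sim$counts$counts@x >= 0))
  expect_equal(unname(rowSums(sim$truth$usage_true)),
               rep(1, nrow(sim$truth$usage_true)))
})

test_that("planted prevalence shift is recovered from nucleus labels", {
  cfg <- sim_config(n_nuclei_per_patient = c(500, 500), n_genes = 300,
                    k_true = 7, markers_per_program = 20, seed = 40)
  sim <- simulate_snrnaseq(cfg)
  lab <- sim$truth$nucleus_program_label
  arm <- sim$metadata$arm
  prop5 <- tapply(lab == cfg$shifted_program, sim$metadata$patient_id, mean)
  pat_arm <- sim$truth$patient_arm[names(prop5)]
  d <- mean(prop5[pat_arm != "untreated"]) - mean(prop5[pat_arm == "untreated"])
  # Dirichlet usage spreads mass off the primary program, but the argmax
  # proportion difference tracks the planted 0.25 prevalence shift
  expect_lt(abs(d - 0.25), 0.05)
  # genuinely null programs: identical planted prevalence in all arms
  null_prog <- setdiff(seq_len(cfg$k_true),
                       c(cfg$shifted_program, cfg$complement_program))
  prev <- cfg$program_prevalence_by_arm
  expect_equal(prev["untreated", null_prog], prev["CRT", null_prog])
  expect_equal(prev["CRT", null_prog], prev["CRTL", null_prog])
})

test_that("dose and modality stratification is deterministic and valid", {
  sim <- small_sim()$sim
  md <- unique(sim$metadata[, c("patient_id", "arm", "dose_group", "modality")])
  expect_true(all(md$dose_group[md$arm == "untreated"] == "none"))
  treated <- md[md$arm != "untreated", ]
  expect_true(all(treated$dose_group %in% c("low", "high")))
  expect_true(all(treated$modality[treated$dose_group == "high"] == "photon"))
  expect_true(any(treated$modality == "proton"))
})

test_that("bulk simulator degenerates to the pure profile without noise", {
  bc <- bulk_config(n_samples = 15, cell_types = "endothelial",
                    noise_sd = 0, cohorts = "one", cohort_scale = 1, seed = 2)
  suppressWarnings(bk <- simulate_bulk_cohort(bc))
  # single type, no noise: every sample is exactly the profile
  expect_true(all(abs(sweep(bk$expression, 2, bk$expression[1, ])) < 1e-12))
  expect_true(all(bk$expression >= 0))
  expect_equal(unname(rowSums(bk$true_proportions)), rep(1, 15))
})

test_that("bulk survival times respond to the planted hazard", {
  sigs <- list(pA = sprintf("A%02d", 1:25), pB = sprintf("B%02d", 1:25))
  bc <- bulk_config(n_samples = 250, program_signatures = sigs,
                    survival_beta = c(pA = log(3)), censoring_rate = 0,
                    seed = 8)
  bk <- simulate_bulk_cohort(bc)
  hi <- bk$true_program_z[, "pA"] > 0
  expect_lt(median(bk$clinical$OS_time[hi]), median(bk$clinical$OS_time[!hi]))
  expect_true(all(bk$clinical$OS_time > 0))
  expect_true(all(bk$clinical$OS_event %in% 0:1))
})

test_that("panel simulator plants additive condition effects", {
  sigs <- list(s1 = sprintf("X%02d", 1:15), s2 = sprintf("Y%02d", 1:15))
  pn <- simulate_huvec_panel(sigs, effect_sizes = c(s1 = 1), n_pairs = 24,
                             seed = 3)
  expect_equal(nrow(pn$expression), 48)
  irr <- pn$info$condition == "irradiated"
  d1 <- mean(pn$expression[irr, sigs$s1]) - mean(pn$expression[!irr, sigs$s1])
  d2 <- mean(pn$expression[irr, sigs$s2]) - mean(pn$expression[!irr, sigs$s2])
  expect_lt(abs(d1 - 1), 0.2)
  expect_lt(abs(d2), 0.2)
  expect_error(simulate_huvec_panel(sigs, effect_sizes = c(zz = 1)), "zz")
})

test_that("planted effect size monotonically increases detection power", {
  sigs <- list(s1 = sprintf("X%02d", 1:15), s2 = sprintf("Y%02d", 1:15))
  power_at <- function(effect) {
    mean(vapply(1:25, function(r) {
      pn <- simulate_huvec_panel(sigs, effect_sizes = c(s1 = effect),
                                 n_pairs = 12, noise_sd = 1, pair_sd = 0.5,
                                 seed = 1000 + r)
      sp <- score_panel(pn, sigs)
      sp$tests$p_adj[sp$tests$signature == "s1"] < 0.05
    }, TRUE))
  }
  pw <- vapply(c(0, 0.6, 1.5), power_at, 0)
  expect_true(all(diff(pw) >= 0))
  expect_lt(pw[1], 0.2)
  expect_gt(pw[3], 0.8)
})

test_that("simulation bundles round-trip through disk and YAML", {
  fx <- small_sim()
  dir <- tempfile()
  write_simulation(fx$sim, dir)
  back <- read_count_matrix(file.path(dir, "matrix.mtx"))
  expect_equal(as.matrix(back$counts), as.matrix(fx$sim$counts$counts),
               check.attributes = FALSE)
  md <- read.delim(file.path(dir, "metadata.tsv"))
  expect_equal(nrow(md), nrow(fx$sim$metadata))
  gmt <- read_gmt(file.path(dir, "planted_programs.gmt"))
  expect_identical(gmt$program_1, fx$sim$truth$planted_gene_sets$program_1)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("n_patients: {untreated: 3, CRT: 2, CRTL: 1}",
               "n_nuclei_per_patient: [20, 30]",
               "n_genes: 150", "k_true: 3", "n_lineage: 2",
               "shifted_program: 2", "complement_program: 1",
               "markers_per_program: 10", "seed: 4"), yml)
  cfg <- sim_config_from_yaml(yml)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$k_true, 3)
  expect_identical(as.matrix(simulate_snrnaseq(cfg)$counts$counts),
                   as.matrix(simulate_snrnaseq(cfg)$counts$counts))
  writeLines(c("k_true: 3", "bogus_key: 1"), yml)
  expect_error(sim_config_from_yaml(yml), "bogus_key")
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(k_true = 1), "k_true")
  expect_error(sim_config(k_true = 300, n_genes = 200,
                          markers_per_program = 0), "k_true > n_genes")
  expect_error(sim_config(n_nuclei_per_patient = c(0, 10)), "positive")
  expect_error(bulk_config(cell_types = "unicorn"), "unicorn")
  expect_error(sim_config(other_cell_types = "fibroblast"),
               "frac_endothelial")
})
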