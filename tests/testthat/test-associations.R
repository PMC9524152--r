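make_assignments <- function(meta, lineage, state = NULL) {
  data.frame(barcode = meta$barcode, lineage_program = lineage,
             state_program = state %||% lineage, lineage_tie = FALSE,
             state_tie = FALSE, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

toy_meta <- function(n_per = 10, n_pat = 8) {
  arms <- rep(c("untreated", "CRT"), length.out = n_pat)
  data.frame(
    barcode = sprintf("b%03d", seq_len(n_per * n_pat)),
    patient_id = rep(sprintf("P%02d", seq_len(n_pat)), each = n_per),
    arm = rep(arms, each = n_per),
    dose_group = rep(ifelse(arms == "CRT", "low", "none"), each = n_per),
    modality = rep(ifelse(arms == "CRT", "photon", "none"), each = n_per),
    sex = "F", cell_type = "endothelial", stringsAsFactors = FALSE)
}

test_that("program proportions are patient-level simplexes", {
  meta <- toy_meta()
  asn <- make_assignments(meta, "program_1")
  pp <- program_proportions(asn, meta)
  expect_true(all(pp$program_1 == 1))
  expect_equal(pp$n_ec_nuclei, rep(10, 8))

  set.seed(21)
  for (i in 1:20) {
    labs <- sample(paste0("program_", 1:4), nrow(meta), replace = TRUE)
    pp <- program_proportions(make_assignments(meta, labs), meta)
    cols <- attr(pp, "programs")$lineage
    expect_equal(unname(rowSums(pp[, cols])), rep(1, 8), tolerance = 1e-9)
  }

  # a patient with zero assigned nuclei is excluded with a warning
  meta2 <- rbind(meta, data.frame(barcode = "extra", patient_id = "P99",
                                  arm = "untreated", dose_group = "none",
                                  modality = "none", sex = "F",
                                  cell_type = "endothelial"))
  expect_warning(pp2 <- program_proportions(make_assignments(meta, "program_1"),
                                            meta2), "P99")
  expect_false("P99" %in% pp2$patient_id)
})

test_that("planted arm prevalences show up in patient proportions", {
  fx <- small_sim()
  sim <- fx$sim
  asn <- data.frame(barcode = sim$metadata$barcode,
                    lineage_program = paste0("program_",
                                             sim$truth$nucleus_program_label),
                    state_program = NA_character_,
                    lineage_tie = FALSE, state_tie = FALSE)
  pp <- program_proportions(asn, sim$metadata)
  prev <- fx$cfg$program_prevalence_by_arm
  # truth labels cover all programs; proportions are over all k programs here
  for (a in c("untreated", "CRT")) {
    got <- colMeans(pp[pp$arm == a, paste0("program_", 1:4)])
    expect_lt(max(abs(got - prev[a, ])), 0.05)
  }
})

test_that("stratum comparisons control the family and respect symmetry", {
  meta <- toy_meta()
  # identical proportions in every patient: all-ties, p = 1
  pp <- program_proportions(make_assignments(meta, "program_1"), meta)
  pp$program_1 <- 0.5
  attr(pp, "programs") <- list(lineage = "program_1", state = character())
  cs <- compare_strata(pp, "arm", programs = "program_1")
  expect_equal(cs$p, 1)

  set.seed(4)
  pp$program_1 <- runif(8)
  c1 <- compare_strata(pp, "arm", pairs = list(c("untreated", "CRT")),
                       programs = "program_1")
  c2 <- compare_strata(pp, "arm", pairs = list(c("CRT", "untreated")),
                       programs = "program_1")
  expect_equal(c1$p, c2$p)

  # singleton stratum is skipped with a warning
  pp$arm[1] <- "CRTL"
  expect_warning(compare_strata(pp, "arm", programs = "program_1"), "skipped")
})

test_that("quartile association detects planted fold changes", {
  set.seed(10)
  scores <- setNames(seq_len(20) + runif(20, 0, 0.1), sprintf("P%02d", 1:20))
  base <- rlnorm(20, 0, 0.1)
  top5 <- names(sort(scores, decreasing = TRUE))[1:5]
  resp <- data.frame(hit = base * ifelse(names(scores) %in% top5, 4, 1),
                     null = rlnorm(20, 0, 0.1),
                     row.names = names(scores))
  qa <- quartile_association(scores, resp)
  hit <- qa[qa$response_name == "hit", ]
  expect_gte(hit$fold_change, 3)
  expect_lte(hit$fold_change, 5)
  expect_true(hit$significant)
  expect_false(qa$significant[qa$response_name == "null"])

  # identical responses: fold change 1, p = 1
  qa2 <- quartile_association(scores, data.frame(flat = rep(2, 20),
                                                 row.names = names(scores)))
  expect_equal(qa2$fold_change, 1)
  expect_equal(qa2$p, 1)

  # zero bottom mean yields the NA sentinel with a warning
  resp0 <- data.frame(z = ifelse(names(scores) %in% top5, 1, 0),
                      row.names = names(scores))
  expect_warning(qa3 <- quartile_association(scores, resp0), "zero")
  expect_true(is.na(qa3$fold_change))

  expect_error(quartile_association(scores[1:6], resp[1:6, , drop = FALSE]),
               ">= 8")
  expect_error(quartile_association(setNames(rep(1, 20), names(scores)), resp),
               "constant")
})

test_that("stromal-to-EC ratios are computed per patient and tested", {
  md <- data.frame(
    patient_id = rep(sprintf("P%02d", 1:12), each = 20),
    cell_type = rep(c(rep("endothelial", 10), rep("macrophage", 10)), 12))
  rr <- stromal_to_ec_ratio(md)
  expect_equal(rr$ratios$macrophage, rep(1, 12))
  expect_true(all(rr$ratios >= 0))

  # planted macrophage excess in high-scoring patients is detected
  md2 <- do.call(rbind, lapply(1:12, function(i) {
    n_mac <- if (i > 9) 30 else 10
    data.frame(patient_id = sprintf("P%02d", i),
               cell_type = c(rep("endothelial", 10), rep("macrophage", n_mac)))
  }))
  scores <- setNames(1:12 + 0.0, sprintf("P%02d", 1:12))
  rr2 <- stromal_to_ec_ratio(md2, ec_scores = scores)
  expect_true(rr2$tests$significant[rr2$tests$response_name == "macrophage"])

  # zero-EC patient excluded with warning
  md3 <- rbind(md, data.frame(patient_id = "P99", cell_type = "macrophage"))
  expect_warning(stromal_to_ec_ratio(md3), "P99")
})

test_that("panel scoring averages overlapping genes and tests pairs", {
  sigs <- list(single = "X01", wide = sprintf("X%02d", 1:10),
               off_panel = c("NOPE1", "NOPE2"))
  pn <- simulate_huvec_panel(sigs[1:2], effect_sizes = c(wide = 1.2),
                             n_pairs = 24, seed = 6)
  expect_warning(sp <- score_panel(pn, sigs), "off_panel")
  # singleton signature score equals that gene's expression
  s1 <- sp$scores[sp$scores$signature == "single", ]
  expect_equal(s1$score, unname(pn$expression[s1$sample_id, "X01"]))
  # only the planted signature survives Bonferroni
  expect_true(sp$tests$significant[sp$tests$signature == "wide"])
  expect_equal(sp$tests$procedure, rep("bonferroni", 2))
})

test_that("leave-one-patient-out strata reruns never error", {
  fx <- small_sim()
  sim <- fx$sim
  asn <- data.frame(barcode = sim$metadata$barcode,
                    lineage_program = paste0("program_",
                                             sim$truth$nucleus_program_label),
                    state_program = NA_character_,
                    lineage_tie = FALSE, state_tie = FALSE)
  for (drop_pat in unique(sim$metadata$patient_id)) {
    keep <- sim$metadata$patient_id != drop_pat
    md <- sim$metadata[keep, ]
    pp <- program_proportions(asn[keep, ], md)
    expect_no_error(compare_strata(pp, "arm",
                                   programs = paste0("program_", 1:4)))
  }
})
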