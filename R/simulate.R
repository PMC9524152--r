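#' Simulation configuration for single-nucleus data
#'
#' Defines the planted-truth generative model used by [simulate_snrnaseq()]:
#' nuclei carry mixtures of `k_true` nonnegative gene programs, program
#' prevalence depends on treatment arm, patients contribute a lognormal random
#' effect, and counts are Poisson. Defaults describe a three-arm cohort: 18
#' untreated, 14 chemoradiation (CRT) and 5 chemoradiation + losartan (CRTL)
#' patients, with one designated program shifted from prevalence 0.10
#' (untreated) to 0.35 (treated arms).
#'
#' @param n_patients named counts per arm (`untreated`, `CRT`, `CRTL`).
#' @param n_nuclei_per_patient length-2 integer range; per-patient totals are
#'   drawn uniformly from it.
#' @param n_genes number of genes.
#' @param k_true number of planted programs (>= 2).
#' @param n_lineage how many programs are lineage-like; the remainder are
#'   state-like (annotation carried in the ground truth).
#' @param shifted_program index of the treatment-responsive program.
#' @param complement_program index of the program that absorbs the prevalence
#'   shift (depleted under treatment, mirroring capillary loss alongside the
#'   treatment-enriched program); must differ from `shifted_program` and, for
#'   family-wise proportions to stay interpretable, belong to the same
#'   (lineage) family. All remaining programs keep identical prevalence in
#'   every arm, so they are genuinely null for treatment-association tests.
#' @param prevalence_baseline,prevalence_treated prevalence of the shifted
#'   program in untreated vs treated arms; the complement program absorbs the
#'   difference and the other programs share the remainder equally across all
#'   arms.
#' @param program_prevalence_by_arm optional arm x program matrix overriding
#'   the two-parameter default; rows must sum to 1.
#' @param usage_concentration length-2 Dirichlet parameters
#'   `(dominant, background)`: a nucleus's usage is Dirichlet with the
#'   dominant mass on its drawn primary program.
#' @param spectra_shape gamma shape for baseline spectra weights.
#' @param markers_per_program,marker_boost size and fold-elevation of each
#'   program's planted marker block.
#' @param patient_effect_sd SD of the patient-level log-rate random effect.
#' @param library_size_log_mean,library_size_log_sd lognormal library sizes.
#' @param frac_endothelial fraction of each patient's nuclei that are
#'   endothelial; the rest are split among `other_cell_types`.
#' @param other_cell_types character vector of non-endothelial types (must be
#'   names in [bulk_deconvolution_markers()]); when nonempty, real marker
#'   symbols are planted in the gene list so marker scoring is exercised.
#' @param seed integer seed; simulators are pure functions of (config, seed).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = c(untreated = 18, CRT = 14, CRTL = 5),
                       n_nuclei_per_patient = c(300, 500),
                       n_genes = 2000,
                       k_true = 7,
                       n_lineage = 5,
                       shifted_program = 5,
                       complement_program = 1,
                       prevalence_baseline = 0.10,
                       prevalence_treated = 0.35,
                       program_prevalence_by_arm = NULL,
                       usage_concentration = c(dominant = 8, background = 0.4),
                       spectra_shape = 0.3,
                       markers_per_program = 40,
                       marker_boost = 10,
                       patient_effect_sd = 0.25,
                       library_size_log_mean = log(2000),
                       library_size_log_sd = 0.4,
                       frac_endothelial = 1,
                       other_cell_types = NULL,
                       seed = 1L) {
  if (k_true < 2) stop("k_true must be >= 2")
  if (k_true > n_genes) stop("degenerate config: k_true > n_genes")
  if (n_lineage < 1 || n_lineage > k_true) stop("n_lineage must be in 1..k_true")
  if (any(n_patients < 1) || any(n_nuclei_per_patient < 1))
    stop("all counts must be positive")
  if (!all(c("untreated", "CRT", "CRTL") %in% names(n_patients)))
    stop("n_patients must be named untreated, CRT, CRTL")
  if (k_true * markers_per_program > n_genes)
    stop("marker blocks exceed n_genes; reduce markers_per_program")
  arms <- c("untreated", "CRT", "CRTL")
  if (shifted_program < 1 || shifted_program > k_true ||
      complement_program < 1 || complement_program > k_true)
    stop("shifted_program and complement_program must lie in 1..k_true")
  if (is.null(program_prevalence_by_arm)) {
    if (complement_program == shifted_program)
      stop("complement_program must differ from shifted_program")
    # null programs share a constant prevalence across arms; the complement
    # program absorbs the treatment shift so the rows stay on the simplex
    p_null <- (1 - prevalence_treated - 0.05) / (k_true - 2)
    if (p_null <= 0) stop("prevalence_treated too large for k_true")
    prev <- matrix(p_null, 3, k_true, dimnames = list(arms, NULL))
    for (a in arms) {
      p_shift <- if (a == "untreated") prevalence_baseline else prevalence_treated
      prev[a, shifted_program] <- p_shift
      prev[a, complement_program] <- 1 - p_shift - (k_true - 2) * p_null
    }
    program_prevalence_by_arm <- prev
  }
  if (any(abs(rowSums(program_prevalence_by_arm) - 1) > 1e-9))
    stop("program_prevalence_by_arm rows must sum to 1")
  if (!is.null(other_cell_types)) {
    unknown <- setdiff(other_cell_types, names(bulk_deconvolution_markers()))
    if (length(unknown))
      stop("unknown other_cell_types: ", paste(unknown, collapse = ", "))
    if (frac_endothelial >= 1)
      stop("frac_endothelial must be < 1 when other_cell_types are requested")
  }
  structure(list(
    n_patients = n_patients, n_nuclei_per_patient = n_nuclei_per_patient,
    n_genes = n_genes, k_true = k_true, n_lineage = n_lineage,
    shifted_program = shifted_program, complement_program = complement_program,
    program_prevalence_by_arm = program_prevalence_by_arm,
    usage_concentration = usage_concentration, spectra_shape = spectra_shape,
    markers_per_program = markers_per_program, marker_boost = marker_boost,
    patient_effect_sd = patient_effect_sd,
    library_size_log_mean = library_size_log_mean,
    library_size_log_sd = library_size_log_sd,
    frac_endothelial = frac_endothelial, other_cell_types = other_cell_types,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Build a simulation configuration from a YAML file
#'
#' The YAML keys mirror the arguments of [sim_config()] one-to-one (e.g.
#' `n_patients: {untreated: 18, CRT: 14, CRTL: 5}`,
#' `n_nuclei_per_patient: [300, 500]`, `k_true: 7`, `seed: 1`);
#' `program_prevalence_by_arm`, if given, is a list of per-arm numeric
#' vectors. Unknown keys are an error.
#'
#' @param path YAML file path.
#' @return A `sim_config`.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configs")
  cfg <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(cfg$n_patients)) cfg$n_patients <- unlist(cfg$n_patients)
  if (!is.null(cfg$usage_concentration))
    cfg$usage_concentration <- unlist(cfg$usage_concentration)
  if (!is.null(cfg$program_prevalence_by_arm))
    cfg$program_prevalence_by_arm <-
      do.call(rbind, cfg$program_prevalence_by_arm)
  do.call(sim_config, cfg)
}

#' Write a simulated single-nucleus dataset to disk
#'
#' Writes the standard file bundle: `matrix.mtx` + `genes.tsv` +
#' `barcodes.tsv` (via [write_count_matrix()]), `metadata.tsv`, and
#' `planted_programs.gmt` with the generator's program gene sets.
#'
#' @param sim output of [simulate_snrnaseq()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  write_count_matrix(sim$counts, dir)
  write.table(sim$metadata, file.path(dir, "metadata.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_gmt(sim$truth$planted_gene_sets, file.path(dir, "planted_programs.gmt"),
            description = unname(sim$truth$program_classes))
  invisible(dir)
}

rdirichlet <- function(n, alpha) {
  x <- matrix(rgamma(n * length(alpha), shape = alpha, scale = 1),
              nrow = n, byrow = TRUE)
  zero <- rowSums(x) == 0
  if (any(zero)) x[zero, which.max(alpha)] <- 1
  x / rowSums(x)
}

# deterministic dose/modality stratification of treated patients:
# low:high in the cohort's 11:8 proportion; within low, photon:proton 7:4.
stratify_treated <- function(n_treated) {
  n_low <- round(n_treated * 11 / 19)
  n_high <- n_treated - n_low
  n_low_photon <- round(n_low * 7 / 11)
  dose <- c(rep("low", n_low), rep("high", n_high))
  modality <- c(rep("photon", n_low_photon),
                rep("proton", n_low - n_low_photon),
                rep("photon", n_high))
  data.frame(dose_group = dose, modality = modality)
}

#' Simulate a single-nucleus count matrix with planted programs
#'
#' Counts for nucleus \eqn{c} and gene \eqn{g} are Poisson with mean
#' \eqn{L_c e^{b_{p(c)}} \sum_k u_{ck} h_{kg}} where the spectra rows
#' \eqn{h_k} lie on the simplex, usages \eqn{u_c} are Dirichlet draws whose
#' dominant component is sampled from the arm's program prevalence, and
#' \eqn{b_p} is a patient-level Gaussian log-rate effect. Each program owns a
#' disjoint block of elevated marker genes. Optionally a fraction of nuclei
#' are drawn from non-endothelial cell-type profiles carrying real marker
#' symbols, so extraction can be tested.
#'
#' @param config a [sim_config()].
#' @return A list with `counts` (a [count_matrix()]), `metadata` (per-nucleus
#'   data.frame), and `truth` (spectra, usages, labels, planted gene sets,
#'   program classes, patient arms).
#' @export
simulate_snrnaseq <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  k <- config$k_true
  G <- config$n_genes
  arms <- rep(c("untreated", "CRT", "CRTL"),
              config$n_patients[c("untreated", "CRT", "CRTL")])
  n_pat <- length(arms)
  patient_id <- sprintf("P%02d", seq_len(n_pat))

  # gene identifiers; plant real marker symbols when mixed cell types requested
  gene_ids <- sprintf("G%05d", seq_len(G))
  ec_panel <- unlist(ec_marker_panel(), use.names = FALSE)
  other <- config$other_cell_types
  other_markers <- list()
  if (!is.null(other)) {
    tab <- bulk_deconvolution_markers()
    other_markers <- tab[other]
    real <- unique(c(ec_panel, unlist(other_markers, use.names = FALSE)))
    if (length(real) > G) stop("n_genes too small for requested marker symbols")
    # marker symbols occupy the tail so program marker blocks (head) are untouched
    gene_ids[(G - length(real) + 1):G] <- real
  }

  # spectra: gamma baseline + per-program elevated marker block
  spectra <- matrix(rgamma(k * G, shape = config$spectra_shape, scale = 1), k, G)
  planted_sets <- vector("list", k)
  m <- config$markers_per_program
  for (j in seq_len(k)) {
    block <- ((j - 1) * m + 1):(j * m)
    spectra[j, block] <- spectra[j, block] + config$marker_boost *
      mean(spectra[j, ])
    # markers are program-specific: damp their baseline weight elsewhere
    spectra[-j, block] <- spectra[-j, block] * 0.1
    planted_sets[[j]] <- gene_ids[block]
  }
  if (!is.null(other)) {
    # endothelial nuclei must express the endothelial panel
    ec_idx <- match(ec_panel, gene_ids)
    spectra[, ec_idx] <- spectra[, ec_idx] + config$marker_boost * rowMeans(spectra)
  }
  spectra <- spectra / rowSums(spectra)
  names(planted_sets) <- sprintf("program_%d", seq_len(k))

  # non-endothelial cell-type profiles
  other_profiles <- NULL
  if (!is.null(other)) {
    other_profiles <- matrix(rgamma(length(other) * G,
                                    shape = config$spectra_shape, scale = 1),
                             length(other), G)
    for (i in seq_along(other)) {
      oi <- match(toupper(other_markers[[i]]), gene_ids)
      oi <- oi[!is.na(oi)]
      other_profiles[i, oi] <- other_profiles[i, oi] +
        config$marker_boost * mean(other_profiles[i, ])
    }
    other_profiles <- other_profiles / rowSums(other_profiles)
    rownames(other_profiles) <- other
  }

  b_pat <- rnorm(n_pat, 0, config$patient_effect_sd)
  strat <- stratify_treated(sum(arms != "untreated"))
  dose_group <- rep("none", n_pat)
  modality <- rep("none", n_pat)
  treated_idx <- which(arms != "untreated")
  dose_group[treated_idx] <- strat$dose_group
  modality[treated_idx] <- strat$modality
  sex <- rep(c("F", "M"), length.out = n_pat)

  rng <- config$n_nuclei_per_patient
  n_nuc <- if (rng[1] == rng[2]) rep(rng[1], n_pat) else
    sample(rng[1]:rng[2], n_pat, replace = TRUE)

  conc <- config$usage_concentration
  counts_list <- vector("list", n_pat)
  meta_list <- vector("list", n_pat)
  usage_list <- vector("list", n_pat)
  label_list <- vector("list", n_pat)

  for (p in seq_len(n_pat)) {
    nc <- n_nuc[p]
    n_ec <- if (is.null(other)) nc else max(1L, round(nc * config$frac_endothelial))
    n_oth <- nc - n_ec
    prev <- config$program_prevalence_by_arm[arms[p], ]
    z <- sample.int(k, n_ec, replace = TRUE, prob = prev)
    alpha_mat <- matrix(conc[["background"]], n_ec, k)
    alpha_mat[cbind(seq_len(n_ec), z)] <- conc[["dominant"]]
    u <- matrix(rgamma(n_ec * k, shape = as.vector(alpha_mat), scale = 1), n_ec, k)
    u <- u / rowSums(u)
    L <- rlnorm(nc, config$library_size_log_mean, config$library_size_log_sd)
    mu_ec <- (u %*% spectra) * (L[seq_len(n_ec)] * exp(b_pat[p]))
    y <- matrix(rpois(length(mu_ec), as.vector(mu_ec)), n_ec, G)
    ctype <- rep("endothelial", n_ec)
    if (n_oth > 0) {
      ti <- rep_len(seq_along(other), n_oth)
      mu_o <- other_profiles[ti, , drop = FALSE] *
        (L[n_ec + seq_len(n_oth)] * exp(b_pat[p]))
      y <- rbind(y, matrix(rpois(length(mu_o), as.vector(mu_o)), n_oth, G))
      ctype <- c(ctype, other[ti])
    }
    counts_list[[p]] <- y
    usage_list[[p]] <- u
    label_list[[p]] <- apply(u, 1, which.max)
    meta_list[[p]] <- data.frame(
      barcode = sprintf("%s_N%04d", patient_id[p], seq_len(nc)),
      patient_id = patient_id[p], arm = arms[p], dose_group = dose_group[p],
      modality = modality[p], sex = sex[p], cell_type = ctype,
      stringsAsFactors = FALSE
    )
  }

  counts <- do.call(rbind, counts_list)          # nuclei x genes
  metadata <- do.call(rbind, meta_list)
  rownames(metadata) <- NULL
  # untreated carry no dose/modality by construction; enforce the contract
  metadata <- validate_metadata(metadata)
  cm <- count_matrix(Matrix::t(methods::as(counts, "CsparseMatrix")),
                     gene_ids, metadata$barcode)
  usage_true <- do.call(rbind, usage_list)
  dimnames(usage_true) <- list(
    metadata$barcode[metadata$cell_type == "endothelial"],
    names(planted_sets))
  label <- unlist(label_list, use.names = FALSE)
  classes <- c(rep("lineage", config$n_lineage),
               rep("state", k - config$n_lineage))
  truth <- list(
    spectra_true = `dimnames<-`(spectra,
                                list(names(planted_sets), gene_ids)),
    usage_true = usage_true,
    nucleus_program_label = label,
    ec_barcodes = metadata$barcode[metadata$cell_type == "endothelial"],
    patient_arm = setNames(arms, patient_id),
    planted_gene_sets = planted_sets,
    program_classes = setNames(classes, names(planted_sets)),
    shifted_program = config$shifted_program,
    complement_program = config$complement_program,
    prevalence = config$program_prevalence_by_arm
  )
  list(counts = cm, metadata = metadata, truth = truth)
}

#' Configuration for the synthetic bulk cohort
#'
#' @param n_samples number of bulk samples.
#' @param cell_types names from [bulk_deconvolution_markers()] to mix.
#' @param mixing_alpha Dirichlet concentration for the mixing proportions
#'   (scalar or one per type).
#' @param n_background_genes non-marker genes added to the panel.
#' @param program_signatures named list of gene sets acting as the programs
#'   scored in bulk; when NULL, taken from `truth$planted_gene_sets`.
#' @param program_effect_scale log-fold modulation of a program's signature
#'   genes per unit of its latent z-score.
#' @param survival_beta named log-hazard coefficients per program (recycled to
#'   0 for unnamed programs).
#' @param baseline_hazard exponential baseline hazard.
#' @param censoring_rate target fraction of censored observations.
#' @param noise_sd lognormal expression noise SD (0 disables noise).
#' @param cohorts,cohort_scale cohort labels (samples split evenly) and the
#'   global expression scale per cohort, for testing within-cohort z-scoring.
#' @param node_program,node_z_shift program whose latent z is shifted by
#'   `node_z_shift` in node-positive samples; `prob_node_positive` sets the
#'   N+ fraction.
#' @param prob_node_positive probability a sample is node-positive.
#' @param seed integer seed.
#' @return A `bulk_config` list.
#' @export
bulk_config <- function(n_samples = 200,
                        cell_types = names(bulk_deconvolution_markers()),
                        mixing_alpha = 1.5,
                        n_background_genes = 300,
                        program_signatures = NULL,
                        program_effect_scale = 0.5,
                        survival_beta = c(),
                        baseline_hazard = 0.1,
                        censoring_rate = 0.2,
                        noise_sd = 0.1,
                        cohorts = c("cohortA", "cohortB"),
                        cohort_scale = c(1, 1.6),
                        node_program = NULL,
                        node_z_shift = 0.5,
                        prob_node_positive = 0.75,
                        seed = 1L) {
  unknown <- setdiff(cell_types, names(bulk_deconvolution_markers()))
  if (length(unknown))
    stop("cell_types absent from the marker table: ",
         paste(unknown, collapse = ", "))
  if (!"endothelial" %in% cell_types && length(cell_types) > 1)
    warning("cell_types does not include 'endothelial'")
  structure(list(
    n_samples = n_samples, cell_types = cell_types,
    mixing_alpha = mixing_alpha, n_background_genes = n_background_genes,
    program_signatures = program_signatures,
    program_effect_scale = program_effect_scale,
    survival_beta = survival_beta, baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate, noise_sd = noise_sd,
    cohorts = cohorts, cohort_scale = cohort_scale,
    node_program = node_program, node_z_shift = node_z_shift,
    prob_node_positive = prob_node_positive, seed = as.integer(seed)
  ), class = "bulk_config")
}

#' Simulate a bulk expression cohort with survival driven by program scores
#'
#' Each sample's expression is a proportion-weighted mixture of cell-type
#' profiles (Dirichlet proportions over the marker-defined types); latent
#' per-sample program z-scores modulate the program signature genes
#' multiplicatively and drive exponential survival times through a
#' proportional-hazards model with independent exponential censoring. Two
#' cohort labels with different global scales exercise within-cohort
#' z-normalization.
#'
#' @param config a [bulk_config()].
#' @param truth optional ground truth from [simulate_snrnaseq()]; supplies the
#'   program signatures when `config$program_signatures` is NULL.
#' @return A list with `expression` (samples x genes), `clinical`
#'   (data.frame incl. OS/TTP endpoints and N status), `true_proportions`,
#'   `true_program_z`, `signatures`.
#' @export
simulate_bulk_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "bulk_config"))
  set.seed(config$seed)
  sigs <- config$program_signatures
  if (is.null(sigs) && !is.null(truth)) sigs <- truth$planted_gene_sets
  if (is.null(sigs)) sigs <- list()

  markers <- bulk_deconvolution_markers()[config$cell_types]
  genes <- unique(c(unlist(markers, use.names = FALSE),
                    unlist(sigs, use.names = FALSE),
                    sprintf("BG%05d", seq_len(config$n_background_genes))))
  G <- length(genes)
  n_t <- length(config$cell_types)

  profiles <- matrix(rgamma(n_t * G, shape = 0.4, scale = 1), n_t, G,
                     dimnames = list(config$cell_types, genes))
  for (t in config$cell_types) {
    mi <- match(toupper(markers[[t]]), genes)
    mi <- mi[!is.na(mi)]
    profiles[t, mi] <- profiles[t, mi] + 8 * mean(profiles[t, ])
  }
  # program signature genes live in the endothelial compartment
  if (length(sigs) && "endothelial" %in% config$cell_types) {
    si <- match(unique(unlist(sigs)), genes)
    profiles["endothelial", si] <- profiles["endothelial", si] +
      4 * mean(profiles["endothelial", ])
  }

  alpha <- rep_len(config$mixing_alpha, n_t)
  props <- rdirichlet(config$n_samples, alpha)
  colnames(props) <- config$cell_types

  kp <- length(sigs)
  z <- if (kp) matrix(rnorm(config$n_samples * kp), config$n_samples, kp,
                      dimnames = list(NULL, names(sigs)))
       else matrix(0, config$n_samples, 0)
  n_pos <- rbinom(config$n_samples, 1, config$prob_node_positive)
  if (!is.null(config$node_program) && kp) {
    z[n_pos == 1, config$node_program] <-
      z[n_pos == 1, config$node_program] + config$node_z_shift
  }

  expr <- props %*% profiles
  if (kp) {
    for (j in seq_len(kp)) {
      si <- match(sigs[[j]], genes)
      si <- si[!is.na(si)]
      expr[, si] <- expr[, si] * exp(config$program_effect_scale * z[, j])
    }
  }
  if (config$noise_sd > 0)
    expr <- expr * matrix(rlnorm(length(expr), 0, config$noise_sd),
                          nrow(expr), ncol(expr))
  cohort <- sort(rep_len(config$cohorts, config$n_samples))
  scale_by <- setNames(rep_len(config$cohort_scale, length(config$cohorts)),
                       config$cohorts)
  expr <- expr * scale_by[cohort]
  rownames(expr) <- sprintf("S%04d", seq_len(config$n_samples))

  beta <- setNames(rep(0, kp), names(sigs))
  if (length(config$survival_beta)) {
    unknown <- setdiff(names(config$survival_beta), names(sigs))
    if (length(unknown)) stop("survival_beta names not among programs: ",
                              paste(unknown, collapse = ", "))
    beta[names(config$survival_beta)] <- config$survival_beta
  }
  lp <- if (kp) as.vector(z %*% beta) else rep(0, config$n_samples)
  haz <- config$baseline_hazard * exp(lp)
  sim_endpoint <- function(scale) {
    t_event <- rexp(config$n_samples, haz * scale)
    cr <- config$censoring_rate
    c_rate <- mean(haz * scale) * cr / max(1 - cr, 1e-6)
    t_cens <- if (cr > 0) rexp(config$n_samples, c_rate) else rep(Inf, config$n_samples)
    list(time = pmin(t_event, t_cens), event = as.integer(t_event <= t_cens))
  }
  os <- sim_endpoint(1)
  ttp <- sim_endpoint(1.4)

  clinical <- data.frame(
    sample_id = rownames(expr),
    age = round(rnorm(config$n_samples, 65, 8)),
    sex = rep(c("F", "M"), length.out = config$n_samples),
    grade = sample(1:3, config$n_samples, replace = TRUE),
    stage = sample(1:4, config$n_samples, replace = TRUE),
    N_status = ifelse(n_pos == 1, "N+", "N0"),
    OS_time = os$time, OS_event = os$event,
    TTP_time = ttp$time, TTP_event = ttp$event,
    cohort = cohort, metastatic = FALSE,
    stringsAsFactors = FALSE
  )
  list(expression = expr, clinical = clinical, true_proportions = props,
       true_program_z = z, signatures = sigs)
}

#' Simulate a paired targeted-transcriptome panel
#'
#' Emulates an in-vitro paired design (e.g., irradiated vs non-irradiated
#' endothelial cultures, 24 pairs): per-gene baselines, a per-pair random
#' intercept, an additive condition effect on the genes of designated
#' signatures, and Gaussian noise.
#'
#' @param signatures named list of gene sets scored on the panel.
#' @param effect_sizes named numeric vector of additive condition effects per
#'   signature (unnamed signatures get 0).
#' @param n_pairs number of paired samples per condition.
#' @param n_background_genes extra unaffected panel genes.
#' @param noise_sd residual Gaussian SD.
#' @param pair_sd SD of the per-pair random intercept.
#' @param seed integer seed.
#' @return A list with `expression` (samples x genes) and `info`
#'   (sample_id, pair_id, condition).
#' @export
simulate_huvec_panel <- function(signatures,
                                 effect_sizes = c(),
                                 n_pairs = 24,
                                 n_background_genes = 100,
                                 noise_sd = 0.5,
                                 pair_sd = 0.5,
                                 seed = 1L) {
  if (length(effect_sizes)) {
    unknown <- setdiff(names(effect_sizes), names(signatures))
    if (length(unknown))
      stop("effect_sizes name(s) not among signatures: ",
           paste(unknown, collapse = ", "))
  }
  set.seed(as.integer(seed))
  genes <- unique(c(unlist(signatures, use.names = FALSE),
                    sprintf("PBG%04d", seq_len(n_background_genes))))
  G <- length(genes)
  gene_effect <- setNames(rep(0, G), genes)
  for (s in names(effect_sizes))
    gene_effect[intersect(signatures[[s]], genes)] <- effect_sizes[[s]]

  base <- rnorm(G, 5, 1)
  pair_int <- rnorm(n_pairs, 0, pair_sd)
  make_cond <- function(cond) {
    eff <- if (cond == "irradiated") gene_effect else 0
    t(vapply(seq_len(n_pairs), function(i)
      base + pair_int[i] + eff + rnorm(G, 0, noise_sd), numeric(G)))
  }
  expr <- rbind(make_cond("control"), make_cond("irradiated"))
  colnames(expr) <- genes
  info <- data.frame(
    sample_id = c(sprintf("H%02d_ctrl", seq_len(n_pairs)),
                  sprintf("H%02d_irr", seq_len(n_pairs))),
    pair_id = rep(sprintf("H%02d", seq_len(n_pairs)), 2),
    condition = rep(c("control", "irradiated"), each = n_pairs),
    stringsAsFactors = FALSE
  )
  rownames(expr) <- info$sample_id
  list(expression = expr, info = info)
}

#' Simulate per-gene counts for the mixed-effects Poisson model
#'
#' Dedicated generator for differential-expression benchmarking: nuclei are
#' split between an in-program group and the rest, patients contribute a
#' Gaussian log-rate intercept, library sizes are lognormal, and the first
#' `n_effect_genes` genes carry a log-rate group effect `beta_group`.
#'
#' @param n_patients,nuclei_per_patient cohort dimensions.
#' @param n_genes total genes; the first `n_effect_genes` carry the effect.
#' @param n_effect_genes number of non-null genes.
#' @param beta_group planted log-rate effect of group membership.
#' @param patient_sd SD of the patient random intercept.
#' @param base_rate expected counts per nucleus at library size 1e4... scaled
#'   so typical per-gene counts are small, as in single-nucleus data.
#' @param group_fraction fraction of nuclei in the program group.
#' @param seed integer seed.
#' @return list with `counts` (genes x nuclei sparse), `metadata` (group,
#'   patient_id, arm, sex, total_umis), `beta_true`.
#' @export
simulate_pglmm_counts <- function(n_patients = 40, nuclei_per_patient = 200,
                                  n_genes = 50, n_effect_genes = n_genes,
                                  beta_group = 0.8, patient_sd = 0.3,
                                  base_rate = 0.2, group_fraction = 0.5,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  n <- n_patients * nuclei_per_patient
  patient <- rep(sprintf("P%02d", seq_len(n_patients)), each = nuclei_per_patient)
  group <- as.integer(runif(n) < group_fraction)
  b_pat <- rnorm(n_patients, 0, patient_sd)
  L <- rlnorm(n, log(2000), 0.3)
  size_factor <- L / median(L)
  beta_true <- c(rep(beta_group, min(n_effect_genes, n_genes)),
                 rep(0, max(0, n_genes - n_effect_genes)))
  eta0 <- log(base_rate) + b_pat[as.integer(factor(patient))] + log(size_factor)
  counts <- vapply(seq_len(n_genes), function(g)
    rpois(n, exp(eta0 + beta_true[g] * group)), numeric(n))
  counts <- Matrix::t(methods::as(counts, "CsparseMatrix"))  # genes x nuclei
  rownames(counts) <- sprintf("G%04d", seq_len(n_genes))
  colnames(counts) <- sprintf("N%05d", seq_len(n))
  pat_arm <- rep(c("untreated", "CRT"), length.out = n_patients)
  pat_sex <- rep(c("F", "M", "M", "F"), length.out = n_patients)
  pidx <- rep(seq_len(n_patients), each = nuclei_per_patient)
  metadata <- data.frame(
    barcode = colnames(counts), patient_id = patient,
    arm = pat_arm[pidx], sex = pat_sex[pidx],
    group = group, total_umis = L, stringsAsFactors = FALSE
  )
  list(counts = counts, metadata = metadata, beta_true = beta_true)
}
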