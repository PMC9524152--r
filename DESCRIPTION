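Package: ecprograms
Title: Consensus NMF Discovery of Endothelial Expression Programs and
    Treatment Associations in Tumor Single-Nucleus RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers recurrent endothelial-cell gene expression programs
    from single-nucleus RNA-seq count matrices by consensus non-negative
    matrix factorization (repeated factorizations, outlier filtering,
    component clustering, stability/error model selection), annotates
    programs by hypergeometric overlap of their top-weighted genes against
    reference signatures, tests per-gene differential expression between a
    program's nuclei and other endothelial nuclei with a mixed-effects
    Poisson model (patient random intercept, library-size offset), and
    carries the programs to patient-level treatment associations
    (Mann-Whitney U with Benjamini-Hochberg control), paired targeted-panel
    scoring (Wilcoxon signed-rank with Bonferroni control), and bulk-cohort
    prognostic analysis (marker-based deconvolution, within-cohort z-scored
    program scores, multivariable Cox regression). Ships simulators for
    every input so the whole pipeline is testable against planted ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    survival,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    jsonlite,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
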