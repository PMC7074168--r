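Package: wintergwas
Title: Weighted Single-Step GWAS for Pedigreed Populations with Partial Genotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the weighted single-step genomic BLUP association
    workflow (wssGWAS) for populations in which many animals have phenotypes
    and pedigree records but only a subset is genotyped. Provides pedigree
    (A), genomic (G) and blended single-step (H) relationship matrices,
    EM/AI-REML variance-component estimation for the single-trait animal
    model, iterative SNP-variance reweighting with back-solved marker
    effects, sliding 20-SNP window decomposition of additive genetic
    variance, positional candidate-gene lookup and pairwise LD. A gene-drop
    simulator generates multi-generation pedigrees, linked genotypes and
    phenotypes with known architecture so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    rtracklayer,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
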