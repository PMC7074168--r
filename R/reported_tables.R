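#' Published Simmental growth-trait summary statistics
#'
#' Descriptive statistics and REML variance components reported for a
#' Chinese Simmental beef cattle population (6022 animals with phenotypes
#' and pedigree, 744 genotyped) for birth weight (BW, kg), yearling weight
#' (YW, kg), birth-to-yearling average daily gain (BYADG, kg/day) and
#' 18-month weight (18MW, kg). Shipped as a plain-text input so the
#' package's summary arithmetic (CV%, phenotypic variance, heritability)
#' can be checked against the printed values.
#'
#' @return data.frame: `trait`, `n`, `mean`, `sd`, `min`, `max`,
#'   `cv_percent`, `sigma_a2`, `sigma_e2`, `sigma_p2`, `h2`, `h2_se`.
#' @export
reported_trait_summary <- function() {
  path <- system.file("extdata", "simmental_trait_summary.tsv",
                      package = "wintergwas", mustWork = TRUE)
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Published candidate windows for the Simmental growth traits
#'
#' The 20-SNP windows reported to explain more than 1% of the additive
#' genetic variance per trait in the Simmental population, with their
#' genomic spans, variance shares, top SNPs and nearest candidate genes
#' (`/` in the source = none reported, stored as `NA`).
#'
#' @param trait one of `"BW"`, `"YW"`, `"BYADG"`, `"18MW"`, or `"all"`
#'   (default) for the union with a `trait` column.
#' @return data.frame: `trait`, `chr`, `start_bp`, `end_bp`,
#'   `gvar_percent`, `top_snp`, `candidate_gene`, `distance` (bp as
#'   character, `"within"`, or `NA`).
#' @export
reported_growth_windows <- function(trait = "all") {
  traits <- c("BW", "YW", "BYADG", "18MW")
  trait <- match.arg(trait, c("all", traits))
  want <- if (trait == "all") traits else trait
  out <- do.call(rbind, lapply(want, function(tr) {
    path <- system.file("extdata",
                        sprintf("simmental_windows_%s.tsv", tolower(tr)),
                        package = "wintergwas", mustWork = TRUE)
    df <- read.table(path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE,
                     colClasses = c(chr = "integer", start_bp = "integer",
                                    end_bp = "integer",
                                    gvar_percent = "numeric",
                                    top_snp = "character",
                                    candidate_gene = "character",
                                    distance = "character"))
    cbind(trait = tr, df, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
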