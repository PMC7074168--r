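#' Simulation configuration
#'
#' Describes the synthetic breeding population used to exercise the pipeline:
#' a multi-generation pedigree with discrete non-overlapping generations,
#' linked biallelic SNPs on autosomes, and phenotypes built from fixed
#' effects, QTL plus polygenic additive values, and a residual. Defaults
#' emulate a beef-cattle design in which several thousand animals are
#' phenotyped and recorded in the pedigree but only roughly 12% are
#' genotyped, with trait heritabilities in the 0.2-0.45 range.
#'
#' Phenotypes are generated on a unit-phenotypic-variance scale: additive
#' variance equals `heritability`, residual variance `1 - heritability`.
#' A fraction `qtl_variance_fraction` of the additive variance is carried by
#' `n_qtl` marker loci, the remainder by a pedigree-transmitted polygenic
#' term.
#'
#' @param n_founders number of base-population animals (even; half each sex).
#' @param n_generations number of discrete offspring generations.
#' @param offspring_per_mating offspring produced by each mating pair.
#' @param n_chromosomes,snps_per_chromosome marker panel dimensions.
#' @param chromosome_length_cM map length per chromosome (recycled).
#' @param founder_maf_range interval in (0, 0.5] for founder allele
#'   frequencies of the counted allele.
#' @param n_qtl number of causal loci drawn from the simulated SNPs.
#' @param qtl_variance_fraction fraction of additive variance at QTL, in
#'   \[0, 1\]; the rest is polygenic.
#' @param heritability target narrow-sense h2, strictly in (0, 1).
#' @param genotyped_fraction fraction of animals retained by
#'   [mask_genotypes()], in (0, 1\].
#' @param qtl_on_panel logical; keep the causal loci on the analyzed panel
#'   (`TRUE`) or mask them from it.
#' @param fixed_effect_spec list of fixed-effect settings; see Details.
#' @param trait_name column name for the simulated trait.
#' @param seed integer seed; the whole simulation is reproducible from it.
#'
#' @details `fixed_effect_spec` accepts: `intercept`, `sex_effect` (added to
#' males), `n_farms`/`farm_sd`, `year_sd` (birth-year shifts, one level per
#' generation), `use_type_effect` (added to the second use type), `age_slope`
#' (per day, applied to age centred at `age_mean`), `age_mean`, `age_sd`.
#' All effects are on the unit-variance trait scale.
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 80L,
                       n_generations = 3L,
                       offspring_per_mating = 2L,
                       n_chromosomes = 3L,
                       snps_per_chromosome = 100L,
                       chromosome_length_cM = 100,
                       founder_maf_range = c(0.1, 0.5),
                       n_qtl = 5L,
                       qtl_variance_fraction = 0.5,
                       heritability = 0.42,
                       genotyped_fraction = 0.1235,
                       qtl_on_panel = TRUE,
                       fixed_effect_spec = list(),
                       trait_name = "trait",
                       seed = 1L) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              offspring_per_mating = as.integer(offspring_per_mating),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length_cM = as.numeric(chromosome_length_cM),
              founder_maf_range = as.numeric(founder_maf_range),
              n_qtl = as.integer(n_qtl),
              qtl_variance_fraction = as.numeric(qtl_variance_fraction),
              heritability = as.numeric(heritability),
              genotyped_fraction = as.numeric(genotyped_fraction),
              qtl_on_panel = isTRUE(qtl_on_panel),
              fixed_effect_spec = fe_defaults(fixed_effect_spec),
              trait_name = as.character(trait_name),
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

fe_defaults <- function(spec) {
  def <- list(intercept = 0, sex_effect = 0.5, n_farms = 4L, farm_sd = 0.3,
              year_sd = 0.2, use_type_effect = 0.3, age_slope = 0.01,
              age_mean = 360, age_sd = 15)
  bad <- setdiff(names(spec), names(def))
  if (length(bad))
    stopf("unknown fixed_effect_spec field(s): %s", paste(bad, collapse = ", "))
  utils::modifyList(def, spec)
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, field, what)
    if (!ok) stopf("invalid sim_config field '%s': %s", field, what)
  chk(is_count(cfg$n_founders, 1) && cfg$n_founders %% 2 == 0,
      "n_founders", "must be a positive even count")
  chk(is_count(cfg$n_generations, 0), "n_generations", "must be a count >= 0")
  chk(is_count(cfg$offspring_per_mating), "offspring_per_mating",
      "must be a count >= 1")
  chk(is_count(cfg$n_chromosomes), "n_chromosomes", "must be a count >= 1")
  chk(is_count(cfg$snps_per_chromosome), "snps_per_chromosome",
      "must be a count >= 1")
  chk(all(cfg$chromosome_length_cM > 0), "chromosome_length_cM",
      "must be positive")
  r <- cfg$founder_maf_range
  chk(length(r) == 2 && r[1] > 0 && r[2] <= 0.5 && r[1] <= r[2],
      "founder_maf_range", "must be an interval within (0, 0.5]")
  chk(is_count(cfg$n_qtl, 0), "n_qtl", "must be a count >= 0")
  chk(is_fraction(cfg$qtl_variance_fraction, 0, 1, FALSE, FALSE),
      "qtl_variance_fraction", "must lie in [0, 1]")
  chk(is_fraction(cfg$heritability, 0, 1), "heritability",
      "must lie strictly in (0, 1)")
  chk(is_fraction(cfg$genotyped_fraction, 0, 1, TRUE, FALSE),
      "genotyped_fraction", "must lie in (0, 1]")
  chk(cfg$n_qtl <= cfg$n_chromosomes * cfg$snps_per_chromosome, "n_qtl",
      "cannot exceed the number of simulated SNPs")
  chk(is_count(cfg$seed, 0) || is_count(-cfg$seed, 0), "seed",
      "must be an integer")
  invisible(cfg)
}

#' Simulate a multi-generation pedigree
#'
#' Founders form generation 0 with alternating sexes. Each later generation
#' mates randomly paired males and females of the previous generation
#' (non-overlapping generations, no selection); every pair produces
#' `offspring_per_mating` offspring with alternating sexes.
#'
#' @param config a [sim_config()].
#' @return A [pedigree] with `sex` and `generation` columns; total size is
#'   `n_founders + sum over generations of matings x offspring_per_mating`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    id <- sprintf("F%04d", seq_len(config$n_founders))
    sire <- rep("0", config$n_founders); dam <- rep("0", config$n_founders)
    sex <- rep(c("M", "F"), length.out = config$n_founders)
    gen <- rep(0L, config$n_founders)
    prev <- data.frame(id = id, sex = sex, stringsAsFactors = FALSE)
    if (config$n_generations > 0) for (g in seq_len(config$n_generations)) {
      males <- sample(prev$id[prev$sex == "M"])
      females <- sample(prev$id[prev$sex == "F"])
      n_mat <- min(length(males), length(females))
      if (n_mat == 0)
        stopf("generation %d has no mating pairs; increase n_founders", g)
      k <- config$offspring_per_mating
      off_sire <- rep(males[seq_len(n_mat)], each = k)
      off_dam <- rep(females[seq_len(n_mat)], each = k)
      off_id <- sprintf("G%d_%04d", g, seq_len(n_mat * k))
      off_sex <- rep(c("M", "F"), length.out = n_mat * k)
      id <- c(id, off_id); sire <- c(sire, off_sire); dam <- c(dam, off_dam)
      sex <- c(sex, off_sex); gen <- c(gen, rep(g, n_mat * k))
      prev <- data.frame(id = off_id, sex = off_sex, stringsAsFactors = FALSE)
    }
    pedigree(id, sire, dam, sex = sex, generation = gen)
  })
}

# marker map: evenly spaced loci; 1 cM is mapped to 1 Mb of physical position
sim_marker_map <- function(config) {
  m <- config$snps_per_chromosome
  len <- rep_len(config$chromosome_length_cM, config$n_chromosomes)
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(c) {
    cm <- seq(0, len[c], length.out = m + 1L)[-1L]  # avoid 0 position
    data.frame(snp = sprintf("chr%d_snp%04d", c, seq_len(m)),
               chr = c, pos = as.integer(round(cm * 1e6)), cM = cm,
               a1 = "A", a2 = "B", stringsAsFactors = FALSE)
  }))
}

# per-interval recombination fractions; 0.5 at chromosome starts so
# chromosomes segregate independently. Haldane: r = (1 - exp(-2d))/2, d in M.
recomb_fractions <- function(map) {
  d_cM <- c(0, diff(map$cM))
  r <- 0.5 * (1 - exp(-2 * d_cM / 100))
  r[c(TRUE, diff(map$chr) != 0)] <- 0.5
  r
}

# one gamete from a parent's two haplotype rows (0/1 integer vectors)
meiose <- function(h1, h2, r) {
  phase <- cumsum(stats::rbinom(length(r), 1L, r)) %% 2L
  ifelse(phase == 0L, h1, h2)
}

#' Drop founder haplotypes through a pedigree
#'
#' Founder allele frequencies are drawn uniformly from
#' `founder_maf_range` and founder haplotypes sampled at linkage
#' equilibrium; gametes then descend through the pedigree with recombination
#' between adjacent markers at the Haldane map-distance fraction
#' `r = (1 - exp(-2d))/2`. Chromosomes segregate independently.
#'
#' @param ped a [pedigree] ordered parents-first (as from
#'   [simulate_pedigree()]).
#' @param config a [sim_config()].
#' @return A [genotype_matrix] for all pedigree animals, with the phased
#'   haplotypes in `attr(, "haplotypes")` (list `h1`, `h2`) and founder
#'   allele frequencies in `attr(, "founder_freq")`.
#' @export
gene_drop_genotypes <- function(ped, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  map <- sim_marker_map(config)
  M <- nrow(map)
  n <- nrow(ped)
  pi <- parent_index(ped)
  with_seed(config$seed + 1L, {
    p <- runif(M, config$founder_maf_range[1], config$founder_maf_range[2])
    r <- recomb_fractions(map)
    h1 <- matrix(0L, n, M); h2 <- matrix(0L, n, M)
    for (i in seq_len(n)) {
      s <- pi[i, 1]; d <- pi[i, 2]
      h1[i, ] <- if (s == 0) stats::rbinom(M, 1L, p) else meiose(h1[s, ], h2[s, ], r)
      h2[i, ] <- if (d == 0) stats::rbinom(M, 1L, p) else meiose(h1[d, ], h2[d, ], r)
    }
    g <- genotype_matrix(h1 + h2, map, ids = ped$id)
    attr(g, "haplotypes") <- list(h1 = h1, h2 = h2)
    attr(g, "founder_freq") <- p
    g
  })
}

#' Simulate phenotypes over a pedigree and its genotypes
#'
#' Builds `y = fixed effects + QTL value + polygenic value + residual` on a
#' unit-phenotypic-variance scale. QTL allele-substitution effects are drawn
#' normal and rescaled so the realized QTL variance across animals equals
#' `heritability * qtl_variance_fraction`; the polygenic term descends
#' through the pedigree (midparent plus Mendelian sampling, inbreeding-
#' adjusted) and is rescaled to the complementary share, so the expected
#' additive:total ratio equals the configured heritability.
#'
#' @param ped a [pedigree].
#' @param genotypes a [genotype_matrix] covering every pedigree animal
#'   (QTL dosages must exist for all animals, even those later masked).
#' @param config a [sim_config()].
#' @return A list with `phenotypes` (data.frame: id, trait, sex, birth_year,
#'   use_type, farm, age_days) and `truth` (class `sim_truth`:
#'   `true_breeding_values`, `qtl_positions`, `qtl_effects`, `realized_h2`
#'   and the realized variance components).
#' @export
simulate_phenotypes <- function(ped, genotypes, config) {
  stopifnot(inherits(ped, "pedigree"), inherits(config, "sim_config"))
  if (!is_fraction(config$heritability, 0, 1))
    stopf("heritability must lie strictly in (0, 1)")
  if (!all(ped$id %in% genotypes$ids))
    stopf("genotypes must cover every pedigree animal")
  n <- nrow(ped)
  h2 <- config$heritability
  var_qtl_target <- h2 * config$qtl_variance_fraction
  var_poly_target <- h2 * (1 - config$qtl_variance_fraction)
  Z <- genotypes$dosages[ped$id, , drop = FALSE]
  with_seed(config$seed + 2L, {
    # QTL component, rescaled to its exact variance share
    if (config$n_qtl > 0 && var_qtl_target > 0) {
      qtl_pos <- sort(sample(ncol(Z), config$n_qtl))
      eff <- rnorm(config$n_qtl)
      q <- drop(Z[, qtl_pos, drop = FALSE] %*% eff)
      vq <- var(q)
      if (vq < .Machine$double.eps)
        stopf("QTL loci are monomorphic; widen founder_maf_range")
      scl <- sqrt(var_qtl_target / vq)
      eff <- eff * scl
      q <- (q - mean(q)) * scl
    } else {
      qtl_pos <- integer(0); eff <- numeric(0); q <- numeric(n)
      var_qtl_target <- 0
    }
    # polygenic component bred down the pedigree, then rescaled
    if (var_poly_target > 0) {
      pi <- parent_index(ped)
      Fc <- inbreeding_coefficients(ped)
      u <- numeric(n)
      for (i in seq_len(n)) {
        s <- pi[i, 1]; d <- pi[i, 2]
        if (s == 0 && d == 0) {
          u[i] <- rnorm(1, 0, sqrt(var_poly_target))
        } else {
          mp <- 0.5 * ((if (s > 0) u[s] else 0) + (if (d > 0) u[d] else 0))
          fbar <- 0.5 * ((if (s > 0) Fc[s] else 0) + (if (d > 0) Fc[d] else 0))
          nseg <- if (s > 0 && d > 0) 0.5 else 0.75
          u[i] <- mp + rnorm(1, 0, sqrt(nseg * var_poly_target * (1 - fbar)))
        }
      }
      u <- (u - mean(u)) * sqrt(var_poly_target / var(u))
    } else u <- numeric(n)
    tbv <- q + u
    e <- rnorm(n, 0, sqrt(1 - h2))
    fe <- config$fixed_effect_spec
    sex <- ped$sex %||% rep(c("M", "F"), length.out = n)
    gen <- ped$generation %||% rep(0L, n)
    farm <- sample(sprintf("farm%02d", seq_len(fe$n_farms)), n, replace = TRUE)
    farm_eff <- rnorm(fe$n_farms, 0, fe$farm_sd)
    names(farm_eff) <- sprintf("farm%02d", seq_len(fe$n_farms))
    year <- 2001L + gen
    year_eff <- rnorm(length(unique(year)), 0, fe$year_sd)
    names(year_eff) <- sort(unique(year))
    use_type <- sample(c("meat", "dual"), n, replace = TRUE)
    age <- as.integer(round(rnorm(n, fe$age_mean, fe$age_sd)))
    fx <- fe$intercept +
      fe$sex_effect * (sex == "M") +
      farm_eff[farm] +
      year_eff[as.character(year)] +
      fe$use_type_effect * (use_type == "dual") +
      fe$age_slope * (age - fe$age_mean)
    y <- drop(fx + tbv + e)
    phen <- data.frame(id = ped$id, trait = y, sex = sex, birth_year = year,
                       use_type = use_type, farm = farm, age_days = age,
                       stringsAsFactors = FALSE)
    names(phen)[names(phen) == "trait"] <- config$trait_name
    truth <- structure(list(
      true_breeding_values = stats::setNames(tbv, ped$id),
      qtl_positions = qtl_pos,
      qtl_effects = eff,
      var_qtl = var_qtl_target,
      var_poly = if (length(u) && var_poly_target > 0) var_poly_target else 0,
      var_e = var(e),
      realized_h2 = var(tbv) / var(tbv + e)), class = "sim_truth")
    list(phenotypes = phen, truth = truth)
  })
}

#' Mask genotypes down to a genotyped subset
#'
#' Emulates a population in which only a fraction of recorded animals is
#' genotyped: returns the genotype records of a random subset of the given
#' size (rounded to the nearest animal); all other animals carry no genotype
#' record.
#'
#' @param genotypes a [genotype_matrix].
#' @param fraction fraction of animals to keep, in (0, 1]. `1` returns the
#'   input unchanged.
#' @param seed integer seed for the subset draw.
#' @return A [genotype_matrix] over the sampled animals (pedigree order
#'   preserved).
#' @export
mask_genotypes <- function(genotypes, fraction, seed = 1L) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  if (!is_fraction(fraction, 0, 1, TRUE, FALSE))
    stopf("fraction must lie in (0, 1]")
  if (fraction == 1) return(genotypes)
  n <- length(genotypes$ids)
  n_keep <- max(1L, as.integer(round(fraction * n)))
  keep <- with_seed(seed, sort(sample(n, n_keep)))
  out <- subset_animals(genotypes, genotypes$ids[keep])
  hap <- attr(genotypes, "haplotypes")
  if (!is.null(hap))
    attr(out, "haplotypes") <- list(h1 = hap$h1[keep, , drop = FALSE],
                                    h2 = hap$h2[keep, , drop = FALSE])
  attr(out, "founder_freq") <- attr(genotypes, "founder_freq")
  out
}
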