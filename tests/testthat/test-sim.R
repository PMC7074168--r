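test_that("pedigree simulation respects counts, ordering and determinism", {
  # no matings
  cfg0 <- sim_config(n_founders = 2, n_generations = 0, seed = 4)
  p0 <- simulate_pedigree(cfg0)
  expect_equal(nrow(p0), 2L)
  expect_true(all(p0$sire == "0" & p0$dam == "0"))
  # 4 founders, 1 generation, 2 offspring per mating -> 4 + 2*2 = 8
  cfg1 <- sim_config(n_founders = 4, n_generations = 1,
                     offspring_per_mating = 2, seed = 4)
  p1 <- simulate_pedigree(cfg1)
  expect_equal(nrow(p1), 8L)
  founders <- p1$id[p1$generation == 0]
  off <- p1[p1$generation == 1, ]
  expect_true(all(off$sire %in% founders) && all(off$dam %in% founders))
  # brute-force scan: every known parent appears earlier
  pos <- seq_len(nrow(p1)); names(pos) <- p1$id
  for (i in seq_len(nrow(p1))) {
    if (p1$sire[i] != "0") expect_lt(pos[p1$sire[i]], i)
    if (p1$dam[i] != "0") expect_lt(pos[p1$dam[i]], i)
  }
  expect_identical(simulate_pedigree(cfg1), simulate_pedigree(cfg1))
  expect_error(sim_config(n_founders = 3), "n_founders")
  expect_error(sim_config(heritability = 1), "heritability")
  expect_error(sim_config(genotyped_fraction = 0), "genotyped_fraction")
})

test_that("recombination follows the Haldane map function", {
  n_mei <- 1e4
  h1 <- c(0L, 0L); h2 <- c(1L, 1L)
  recomb_at <- function(d_cM) {
    r <- c(0.5, 0.5 * (1 - exp(-2 * d_cM / 100)))
    hits <- replicate(n_mei, {
      g <- wintergwas:::meiose(h1, h2, r)
      g[1] != g[2]
    })
    mean(hits)
  }
  set.seed(99)
  # 0 cM: adjacent SNPs never recombine
  expect_equal(recomb_at(0), 0)
  # 50 cM: r = (1 - e^-1)/2 ~ 0.316, within 4 binomial SDs
  r50 <- recomb_at(50)
  expected <- (1 - exp(-1)) / 2
  expect_lt(abs(r50 - expected), 4 * sqrt(expected * (1 - expected) / n_mei))
})

test_that("gene drop is Mendelian-consistent and matches founder frequencies", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_chromosomes = 2,
                    snps_per_chromosome = 50, founder_maf_range = c(0.2, 0.4),
                    seed = 17)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  expect_true(all(g$dosages %in% 0:2))
  hap <- attr(g, "haplotypes")
  pos <- seq_len(nrow(ped)); names(pos) <- ped$id
  # each transmitted haplotype allele must exist in the parent at that locus
  for (i in which(ped$sire != "0")) {
    s <- pos[ped$sire[i]]; d <- pos[ped$dam[i]]
    expect_true(all(hap$h1[i, ] == hap$h1[s, ] | hap$h1[i, ] == hap$h2[s, ]))
    expect_true(all(hap$h2[i, ] == hap$h1[d, ] | hap$h2[i, ] == hap$h2[d, ]))
  }
  # founder allele frequencies track the configured draws (binomial error)
  p_cfg <- attr(g, "founder_freq")
  founders <- ped$generation == 0
  p_obs <- colMeans(g$dosages[founders, ]) / 2
  n_al <- 2 * sum(founders)
  expect_true(all(abs(p_obs - p_cfg) < 5 * sqrt(p_cfg * (1 - p_cfg) / n_al)))
  # determinism
  expect_identical(g$dosages, gene_drop_genotypes(ped, cfg)$dosages)
})

test_that("phenotype generator hits the target heritability without bias", {
  n_rep <- 50
  h2 <- vapply(seq_len(n_rep), function(r) {
    cfg <- sim_config(n_founders = 400, n_generations = 4,
                      n_chromosomes = 2, snps_per_chromosome = 30,
                      n_qtl = 5, qtl_variance_fraction = 0.5,
                      heritability = 0.42, seed = 1000 + r)
    ped <- simulate_pedigree(cfg)        # 2000 animals
    g <- gene_drop_genotypes(ped, cfg)
    simulate_phenotypes(ped, g, cfg)$truth$realized_h2
  }, numeric(1))
  expect_lt(abs(mean(h2) - 0.42), 0.03)
})

test_that("phenotypes decompose as the additive model prescribes", {
  # no fixed effects: regression of phenotype on true breeding value ~ 1
  fe0 <- list(intercept = 0, sex_effect = 0, farm_sd = 0, year_sd = 0,
              use_type_effect = 0, age_slope = 0)
  cfg <- sim_config(n_founders = 300, n_generations = 3, n_chromosomes = 2,
                    snps_per_chromosome = 40, heritability = 0.5,
                    fixed_effect_spec = fe0, seed = 21)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  sp <- simulate_phenotypes(ped, g, cfg)
  slope <- coef(lm(sp$phenotypes$trait ~ sp$truth$true_breeding_values))[2]
  expect_lt(abs(slope - 1), 0.15)
  # near-zero additive variance: phenotypic variance ~ residual variance
  cfg0 <- sim_config(n_founders = 300, n_generations = 3, n_chromosomes = 2,
                     snps_per_chromosome = 40, n_qtl = 0,
                     qtl_variance_fraction = 0, heritability = 1e-3,
                     fixed_effect_spec = fe0, seed = 22)
  ped0 <- simulate_pedigree(cfg0)
  g0 <- gene_drop_genotypes(ped0, cfg0)
  sp0 <- simulate_phenotypes(ped0, g0, cfg0)
  expect_lt(abs(var(sp0$phenotypes$trait) / sp0$truth$var_e - 1), 0.1)
})

test_that("genotype masking samples the stated fraction deterministically", {
  dos <- matrix(rbinom(6022, 2, 0.3), ncol = 1)
  g <- toy_genotypes(dos)
  expect_identical(mask_genotypes(g, 1), g)
  # 12.35% of 6022 animals -> 744 genotyped
  m <- mask_genotypes(g, 0.1235, seed = 3)
  expect_equal(length(m$ids), 744L)
  expect_identical(m$ids, mask_genotypes(g, 0.1235, seed = 3)$ids)
  expect_error(mask_genotypes(g, 0), "fraction")
})
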