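test_that("trait summaries reproduce the published descriptive arithmetic", {
  expect_equal(round(cv_percent(44.96, 5.38), 2), 11.97)   # BW
  expect_equal(round(cv_percent(1.03, 0.19), 2), 18.45)    # BYADG
  s <- summarize_trait(c(5, 5, 5))
  expect_equal(s$sd, 0); expect_equal(s$cv_percent, 0)
  expect_error(summarize_trait(c(-1, 1)), "mean")
  x <- rnorm(100, 50, 5)
  s2 <- summarize_trait(x)
  expect_equal(s2$cv_percent, sd(x) / mean(x) * 100)
})

test_that("heritability arithmetic matches the published components", {
  expect_equal(round(heritability(variance_components(10.165, 14.150)), 2), 0.42)
  expect_equal(round(heritability(variance_components(1193.4, 1598.0)), 2), 0.43)
  expect_equal(heritability(variance_components(3, 3)), 0.5)
})

test_that("MME solutions equal a dense textbook pedigree BLUP", {
  set.seed(53)
  ped <- random_pedigree(120, n_founders = 30)
  phen <- data.frame(id = ped$id, y = rnorm(120, 10),
                     grp = sample(c("u", "v"), 120, replace = TRUE))
  A_inv <- build_A_inverse(ped)
  vc <- variance_components(1, 2)
  spec <- model_spec("y", fixed_factors = "grp")
  sys <- assemble_mme(spec, phen, A_inv, vc)
  sol <- solve_mme(sys)
  X <- cbind(1, as.numeric(phen$grp == "v"))
  oracle <- dense_blup_oracle(phen$y, X, diag(120), as.matrix(build_A_inverse(ped)), 2)
  expect_equal(unname(sol$a), unname(oracle$a), tolerance = 1e-8)
  expect_equal(unname(sol$b), unname(oracle$b), tolerance = 1e-8)
  # permuting animal order permutes the predictions identically
  perm <- sample(120)
  sysp <- assemble_mme(spec, phen[perm, ], A_inv, vc)
  solp <- solve_mme(sysp)
  expect_equal(solp$a[names(sol$a)], sol$a, tolerance = 1e-8)
})

test_that("MME degenerate limits behave", {
  ped <- pedigree("only", "0", "0")
  phen <- data.frame(id = "only", y = 3.7)
  sys <- assemble_mme(model_spec("y"), phen, build_A_inverse(ped),
                      variance_components(1, 1))
  sol <- solve_mme(sys)
  # confounded single record: mean absorbs the record, a is fully shrunk
  expect_equal(unname(sol$b[1]), 3.7, tolerance = 1e-8)
  expect_equal(sol$a[["only"]], 0, tolerance = 1e-8)
  # vanishing additive variance: a -> 0
  set.seed(3)
  ped2 <- random_pedigree(50)
  phen2 <- data.frame(id = ped2$id, y = rnorm(50))
  sys2 <- assemble_mme(model_spec("y"), phen2, build_A_inverse(ped2),
                       variance_components(1e-10, 1))
  expect_lt(max(abs(solve_mme(sys2)$a)), 1e-6)
  # phenotyped animal missing from pedigree is reported by id
  phen3 <- data.frame(id = c(ped2$id[1], "ghost"), y = c(1, 2))
  expect_error(assemble_mme(model_spec("y"), phen3, build_A_inverse(ped2),
                            variance_components(1, 1)), "ghost")
})

test_that("REML matches a direct dense REML optimisation", {
  cfg <- sim_config(n_founders = 40, n_generations = 2, n_qtl = 0,
                    qtl_variance_fraction = 0, heritability = 0.4, seed = 7)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  sp <- simulate_phenotypes(ped, g, cfg)
  spec <- model_spec("trait", fixed_factors = c("sex", "farm"),
                     covariates = "age_days")
  A <- build_A(ped)
  vc <- reml_estimate(spec, sp$phenotypes, build_A_inverse(ped), tol = 1e-10)
  y <- sp$phenotypes$trait
  X <- wintergwas:::fixed_design(spec, sp$phenotypes)
  n <- length(y)
  negll <- function(th) {
    V <- th[1] * A + th[2] * diag(n)
    cV <- chol(V); Vi <- chol2inv(cV)
    XtVX <- t(X) %*% Vi %*% X
    P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
    0.5 * (2 * sum(log(diag(cV))) +
             as.numeric(determinant(XtVX)$modulus) + drop(t(y) %*% P %*% y))
  }
  opt <- optim(c(0.3, 0.7), negll, method = "L-BFGS-B",
               lower = c(1e-6, 1e-6), control = list(factr = 1e4))
  expect_equal(c(vc$sigma_a2, vc$sigma_e2), opt$par, tolerance = 1e-4)
  expect_equal(vc$sigma_p2, vc$sigma_a2 + vc$sigma_e2)
})

test_that("REML is invariant to starts, ordering and location shifts", {
  cfg <- sim_config(n_founders = 60, n_generations = 2, heritability = 0.35,
                    seed = 29)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  sp <- simulate_phenotypes(ped, g, cfg)
  spec <- model_spec("trait", fixed_factors = "sex")
  A_inv <- build_A_inverse(ped)
  tol <- 1e-8
  vy <- var(sp$phenotypes$trait)
  v1 <- reml_estimate(spec, sp$phenotypes, A_inv, tol = tol,
                      start = variance_components(0.1 * vy, 0.9 * vy))
  v2 <- reml_estimate(spec, sp$phenotypes, A_inv, tol = tol,
                      start = variance_components(0.8 * vy, 0.2 * vy))
  expect_equal(v1$h2, v2$h2, tolerance = tol * 10 + 1e-6)
  shifted <- sp$phenotypes; shifted$trait <- shifted$trait + 100
  v3 <- reml_estimate(spec, shifted, A_inv, tol = tol)
  expect_equal(v3$sigma_a2, v1$sigma_a2, tolerance = 1e-5)
  perm <- sample(nrow(sp$phenotypes))
  v4 <- reml_estimate(spec, sp$phenotypes[perm, ], A_inv, tol = tol)
  expect_equal(v4$h2, v1$h2, tolerance = 1e-6)
})

test_that("REML shrinks to the boundary when there is no additive variance", {
  set.seed(61)
  h2_null <- vapply(1:5, function(r) {
    ped <- random_pedigree(600, n_founders = 120)
    phen <- data.frame(id = ped$id, y = rnorm(600))   # pure noise
    reml_estimate(model_spec("y"), phen, build_A_inverse(ped),
                  tol = 1e-6, max_iter = 200)$h2
  }, numeric(1))
  expect_lt(mean(h2_null), 0.02)
})

test_that("prediction accuracy rises with heritability and genotyping", {
  n_rep <- 20
  h2s <- c(0.1, 0.42, 0.8)
  fracs <- c(0, 0.5, 1.0)
  acc <- array(NA_real_, c(length(h2s), length(fracs), n_rep))
  for (r in seq_len(n_rep)) {
    for (ih in seq_along(h2s)) {
      cfg <- sim_config(n_founders = 60, n_generations = 2,
                        n_chromosomes = 2, snps_per_chromosome = 75,
                        n_qtl = 8, qtl_variance_fraction = 0.6,
                        heritability = h2s[ih], seed = 7000 + r)
      ped <- simulate_pedigree(cfg)
      g <- gene_drop_genotypes(ped, cfg)
      sp <- simulate_phenotypes(ped, g, cfg)
      spec <- model_spec("trait", fixed_factors = "sex")
      vc <- variance_components(h2s[ih], 1 - h2s[ih])
      A_inv <- build_A_inverse(ped)
      for (jf in seq_along(fracs)) {
        H_inv <- if (fracs[jf] == 0) A_inv else {
          gm <- if (fracs[jf] == 1) g else mask_genotypes(g, fracs[jf], seed = r)
          fr <- compute_allele_freqs(gm)
          A22 <- build_A22(ped, gm$ids)
          Gb <- blend_G(build_G(gm, fr), A22, 0.95)
          build_H_inverse(A_inv, A22, Gb, gm$ids)
        }
        sol <- solve_mme(assemble_mme(spec, sp$phenotypes, H_inv, vc))
        acc[ih, jf, r] <- cor(sol$a, sp$truth$true_breeding_values)
      }
    }
  }
  m <- apply(acc, c(1, 2), mean)
  # monotone in h2 at every genotyping fraction
  for (jf in seq_along(fracs)) expect_true(all(diff(m[, jf]) > 0))
  # monotone in genotyping fraction at every h2
  for (ih in seq_along(h2s)) expect_true(all(diff(m[ih, ]) > 0))
})
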