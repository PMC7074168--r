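test_that("SNP-effect backsolve satisfies its algebraic identities", {
  set.seed(71)
  # invertible G (more SNPs than animals, reference frequencies -- observed
  # ones centre the columns exactly and make G singular): Z u = a_g exactly
  p_true <- runif(30, 0.2, 0.5)
  dos <- sapply(p_true, function(p) rbinom(8, 2, p))
  g <- toy_genotypes(dos)
  fr <- allele_freqs(p_true)
  Z <- center_dosages(g, fr)
  G <- build_G(g, fr)
  lam <- compute_lambda(fr)
  a_g <- rnorm(8)
  u <- backsolve_snp_effects(a_g, Z, NULL, G, lam)
  expect_equal(as.numeric(Z %*% u), a_g, tolerance = 1e-8)
  # zero GEBVs give zero effects
  expect_equal(unname(backsolve_snp_effects(rep(0, 8), Z, NULL, G, lam)),
               rep(0, 30))
  # random weighted instance matches the direct dense formula
  d <- runif(30, 0.1, 3)
  Gw <- build_G(g, fr, d)
  uw <- backsolve_snp_effects(a_g, Z, d, Gw, lam)
  direct <- lam * diag(d) %*% t(Z) %*% solve(Gw) %*% a_g
  expect_equal(unname(uw), drop(direct), tolerance = 1e-10)
})

test_that("weight updates and trace normalisation follow the scheme", {
  expect_equal(update_weights(c(0, 1), allele_freqs(c(0.3, 0.5)))$d, c(0, 0.5))
  expect_equal(update_weights(0.3, allele_freqs(0.1))$d, 0.0162)
  # raw weights with trace 2M over M SNPs are halved
  w <- normalize_weights(rep(2, 10), snp_weights(rep(1, 10)))
  expect_equal(w$d, rep(1, 10)); expect_equal(w$iteration, 2L)
  # already-normalised weights are a fixed point
  expect_equal(normalize_weights(w$d, 10)$d, w$d)
  expect_equal(normalize_weights(c(1, 3), 2)$d, c(0.5, 1.5))
  expect_error(normalize_weights(c(0, 0), 2), "zero")
})

test_that("window variances match the brute-force animal-level oracle", {
  set.seed(73)
  n <- 25
  dos <- sapply(runif(60, 0.2, 0.5), function(p) rbinom(n, 2, p))
  g <- toy_genotypes(dos)
  fr <- compute_allele_freqs(g)
  Z <- center_dosages(g, fr)
  u <- rnorm(60, 0, 0.1)
  res <- window_variances(u, Z, g$map, sigma_a2 = 0.4, window_size = 20)
  expect_equal(nrow(res), 41L)       # 60 SNPs, 20-SNP windows, step 1
  for (i in seq_len(nrow(res))) {
    j <- res$start_idx[i]:res$end_idx[i]
    val <- drop(Z[, j] %*% u[j])     # per-animal window genetic value
    expect_equal(res$gvar_percent[i], var(val) / 0.4 * 100, tolerance = 1e-6)
  }
  # zero effects give a flat zero profile
  z0 <- window_variances(rep(0, 60), Z, g$map, 0.4)
  expect_true(all(z0$gvar_percent == 0))
  # a single nonzero effect contributes exactly to the windows containing it
  u1 <- rep(0, 60); u1[30] <- 0.5
  r1 <- window_variances(u1, Z, g$map, 0.4)
  hit <- r1$start_idx <= 30 & r1$end_idx >= 30
  expect_equal(r1$gvar_percent[hit],
               rep(var(Z[, 30] * 0.5) / 0.4 * 100, sum(hit)), tolerance = 1e-10)
  expect_true(all(r1$gvar_percent[!hit] == 0))
})

test_that("orthogonal SNP columns make window variance additive", {
  n <- 40
  Zo <- stats::poly(seq_len(n), degree = 25)        # zero-mean, orthogonal
  Z <- unclass(Zo) * sqrt(n)
  map <- data.frame(snp = sprintf("s%02d", 1:25), chr = 1L,
                    pos = seq_len(25) * 1000L)
  u <- rnorm(25)
  res <- window_variances(u, Z, map, sigma_a2 = 1, window_size = 20)
  per_snp <- vapply(seq_len(25), function(j) var(Z[, j] * u[j]), numeric(1))
  for (i in seq_len(nrow(res))) {
    j <- res$start_idx[i]:res$end_idx[i]
    expect_equal(res$gvar_percent[i], sum(per_snp[j]) * 100, tolerance = 1e-6)
  }
})

test_that("window selection keeps isolated peaks and collapses plateaus", {
  idx <- c(1:4, 40:42)                   # plateau well clear of the peak
  prof <- data.frame(chr = 1L, start_bp = idx * 1000L,
                     end_bp = idx * 1000L + 900L,
                     gvar_percent = c(0.5, 0.5, 7.89, 0.5, 1.2, 1.5, 1.3),
                     start_idx = idx, end_idx = idx + 19L, n_snps = 20L)
  # all sub-threshold -> empty
  expect_equal(nrow(select_windows(transform(prof, gvar_percent = 0.5))), 0L)
  sel <- select_windows(prof)
  # the isolated 7.89% window survives alone; the (1.2, 1.5, 1.3) plateau
  # collapses to its 1.5% local maximum
  expect_equal(sel$gvar_percent, c(7.89, 1.5))
  # overlapping selected windows on different chromosomes never merge
  prof2 <- prof; prof2$chr <- c(1L, 1L, 1L, 1L, 2L, 2L, 2L)
  prof2$start_idx <- c(1:4, 5:7); prof2$end_idx <- prof2$start_idx + 19L
  sel2 <- select_windows(prof2)
  expect_equal(sort(sel2$gvar_percent), c(1.5, 7.89))
})

test_that("top SNP is the largest variance contributor, ties to lower bp", {
  map <- data.frame(snp = sprintf("s%02d", 1:20), chr = 1L,
                    pos = seq_len(20) * 100L)
  win <- data.frame(start_idx = 1L, end_idx = 20L)
  u <- rep(0, 20); u[7] <- 1
  fr <- allele_freqs(rep(0.5, 20))
  expect_equal(top_snp(win, u, fr, map), "s07")
  u2 <- rep(0, 20); u2[c(4, 11)] <- 1       # equal contributions
  expect_equal(top_snp(win, u2, fr, map), "s04")
  set.seed(79)
  u3 <- rnorm(20); p3 <- runif(20, 0.05, 0.5)
  contrib <- u3^2 * 2 * p3 * (1 - p3)
  expect_equal(top_snp(win, u3, allele_freqs(p3), map),
               map$snp[which.max(contrib)])
})

test_that("nonredundant union counts identical regions once", {
  w <- function(chr, s, g) data.frame(chr = chr, start_bp = s,
                                      end_bp = s + 500L, gvar_percent = g)
  t1 <- rbind(w(1, 100, 5), w(2, 200, 3))
  t2 <- rbind(w(3, 300, 4), w(4, 400, 2), w(5, 500, 1.5))
  expect_equal(nrow(nonredundant_union(t1, t2)), 5L)
  expect_equal(nrow(nonredundant_union(t1, t1)), nrow(t1))
  # a region shared between two traits counts once
  shared <- rbind(t1, w(3, 300, 4))
  expect_equal(nrow(nonredundant_union(shared, t2)), 5L)
})

test_that("the weighting loop is deterministic and sharpens a major QTL", {
  cfg <- sim_config(n_founders = 150, n_generations = 2, n_chromosomes = 3,
                    snps_per_chromosome = 120, n_qtl = 1,
                    qtl_variance_fraction = 0.3, heritability = 0.42,
                    seed = 83)
  ped <- simulate_pedigree(cfg)
  g <- gene_drop_genotypes(ped, cfg)
  sp <- simulate_phenotypes(ped, g, cfg)
  gm <- mask_genotypes(g, 0.6, seed = 2)
  spec <- model_spec("trait", fixed_factors = "sex")
  vc <- variance_components(0.42, 0.58)
  run <- run_wssgwas(sp$phenotypes, ped, gm, vc, spec, iterations = 2)
  # trace conservation at every iteration
  M <- nrow(gm$map)
  for (it in run$iterations) expect_equal(sum(it$weights$d), M, tolerance = 1e-8)
  # one iteration with D = I is a plain (unweighted) single-step backsolve
  run1 <- run_wssgwas(sp$phenotypes, ped, gm, vc, spec, iterations = 1)
  expect_equal(run1$effects, run$iterations[[1]]$effects, tolerance = 1e-12)
  expect_true(all(run1$iterations[[1]]$weights$d == 1))
  # determinism end to end
  run_b <- run_wssgwas(sp$phenotypes, ped, gm, vc, spec, iterations = 2)
  expect_identical(run$effects, run_b$effects)
  # the QTL window's variance share grows under reweighting
  qtl <- sp$truth$qtl_positions
  gv <- vapply(run$iterations, function(it) {
    w <- it$windows
    max(w$gvar_percent[w$start_idx <= qtl & w$end_idx >= qtl])
  }, numeric(1))
  expect_gt(gv[2], gv[1])
})
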