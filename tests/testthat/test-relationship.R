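test_that("tabular A reproduces textbook relationships", {
  # unrelated founders -> identity
  pf <- pedigree(c("a", "b", "c"), rep("0", 3), rep("0", 3))
  expect_equal(unname(build_A(pf)), diag(3), ignore_attr = TRUE)
  # parent-offspring 0.5, full sibs 0.5, half sibs 0.25
  ped <- pedigree(c("s", "d1", "d2", "o1", "o2", "o3"),
                  c("0", "0", "0", "s", "s", "s"),
                  c("0", "0", "0", "d1", "d1", "d2"))
  A <- build_A(ped)
  expect_equal(A["s", "o1"], 0.5)
  expect_equal(A["o1", "o2"], 0.5)   # full sibs
  expect_equal(A["o1", "o3"], 0.25)  # half sibs
  # offspring of full sibs: diagonal 1.25 (F = 0.25)
  ped2 <- pedigree(c("a", "b", "x", "y", "z"), c("0", "0", "a", "a", "x"),
                   c("0", "0", "b", "b", "y"))
  expect_equal(build_A(ped2)["z", "z"], 1.25)
})

test_that("tabular A equals the path-counting oracle on small pedigrees", {
  set.seed(31)
  for (rep in 1:25) {
    ped <- random_pedigree(sample(4:12, 1))
    expect_equal(unname(build_A(ped)), unname(kinship_oracle_A(ped)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("Henderson A-inverse inverts the tabular A", {
  # single founder
  p1 <- pedigree("x", "0", "0")
  expect_equal(as.matrix(build_A_inverse(p1)), matrix(1, 1, 1),
               ignore_attr = TRUE)
  # sire-dam-offspring trio: known 3x3 pattern
  trio <- pedigree(c("s", "d", "o"), c("0", "0", "s"), c("0", "0", "d"))
  Ai <- as.matrix(build_A_inverse(trio))
  expect_equal(unname(Ai),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)
  # matches a numerical inverse of tabular A
  expect_equal(Ai, solve(build_A(trio)), ignore_attr = TRUE, tolerance = 1e-10)
  # random 200-animal pedigree: A^-1 A = I to 1e-8 (inbred loops included)
  set.seed(7)
  ped <- random_pedigree(200)
  prod <- as.matrix(build_A_inverse(ped) %*% build_A(ped))
  expect_lt(max(abs(prod - diag(200))), 1e-8)
})

test_that("allele frequencies come from non-missing calls of genotyped animals", {
  g <- toy_genotypes(matrix(c(0, 1, 2), ncol = 1))
  expect_equal(unname(compute_allele_freqs(g)$p), 0.5)
  g2 <- toy_genotypes(matrix(c(0, 0, 1, 2, NA), ncol = 1))
  expect_equal(unname(compute_allele_freqs(g2)$p), 3 / 8)
  g3 <- toy_genotypes(matrix(c(2, 2, 2), ncol = 1))
  expect_error(compute_allele_freqs(g3), "monomorphic")
})

test_that("weighted G matches the VanRaden formula and its symmetries", {
  # one SNP, p = 0.5, dosages (0, 1, 2): Z = (-1, 0, 1), denominator 0.5
  g <- toy_genotypes(matrix(c(0, 1, 2), ncol = 1))
  G <- build_G(g, allele_freqs(0.5))
  expect_equal(unname(G), matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3),
               ignore_attr = TRUE)
  # scaling weights then trace-normalising leaves G unchanged
  set.seed(19)
  dos <- sapply(runif(40, 0.2, 0.5), function(p) rbinom(30, 2, p))
  gg <- toy_genotypes(dos)
  fr <- compute_allele_freqs(gg)
  w <- runif(40, 0.5, 2)
  G1 <- build_G(gg, fr, normalize_weights(w, 40))
  G2 <- build_G(gg, fr, normalize_weights(2 * w, 40))
  expect_equal(G1, G2, tolerance = 1e-12)
  # mean diagonal ~ 1 with observed frequencies
  expect_lt(abs(mean(diag(build_G(gg, fr))) - 1), 5 / sqrt(40))
  # invariance to allele relabelling: x -> 2 - x, p -> 1 - p
  gflip <- toy_genotypes(2 - dos)
  Gflip <- build_G(gflip, allele_freqs(1 - fr$p))
  expect_equal(unname(build_G(gg, fr)), unname(Gflip), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("lambda is the reciprocal summed marker variance", {
  expect_equal(compute_lambda(allele_freqs(0.5)), 2)
  expect_equal(compute_lambda(allele_freqs(rep(0.5, 10))), 0.2)
  expect_equal(compute_lambda(allele_freqs(c(0.1, 0.3))), 1 / 0.6)
})

test_that("blending restores invertibility and has the stated fixed points", {
  G <- diag(4); A22 <- diag(4)
  expect_equal(unname(blend_G(G, A22, 1)), G, ignore_attr = TRUE)
  expect_equal(unname(blend_G(G, A22, 0.95)), diag(4), ignore_attr = TRUE)
  # duplicate animals make G singular; blending fixes the conditioning
  set.seed(23)
  dos <- sapply(runif(30, 0.2, 0.5), function(p) rbinom(10, 2, p))
  dos <- rbind(dos, dos[1, ])                     # duplicated animal
  gg <- toy_genotypes(dos)
  fr <- compute_allele_freqs(gg)
  G2 <- build_G(gg, fr)
  expect_lt(min(abs(eigen(G2, symmetric = TRUE)$values)), 1e-10)
  A22b <- diag(nrow(dos))
  Gb <- blend_G(G2, A22b, 0.95)
  ev <- eigen(Gb, symmetric = TRUE)$values
  expect_gt(min(ev), 1e-4)
  expect_lt(max(ev) / min(ev), 1e6)
})

test_that("H-inverse reduces to its limiting cases and matches the dense oracle", {
  set.seed(41)
  ped <- random_pedigree(20, n_founders = 8)
  A_inv <- build_A_inverse(ped)
  # no genotyped animals: H^-1 = A^-1
  H0 <- build_H_inverse(A_inv, matrix(0, 0, 0), matrix(0, 0, 0), character(0))
  expect_equal(as.matrix(H0), as.matrix(A_inv), ignore_attr = TRUE)
  # all genotyped with A22 = A: H^-1 = G^-1
  dos <- sapply(runif(60, 0.2, 0.5), function(p) rbinom(20, 2, p))
  rownames(dos) <- ped$id
  gg <- toy_genotypes(dos)
  fr <- compute_allele_freqs(gg)
  A <- build_A(ped)
  G <- blend_G(build_G(gg, fr), A, 0.95)
  Hall <- build_H_inverse(A_inv, A, G, ped$id)
  expect_equal(as.matrix(Hall), solve(G), ignore_attr = TRUE,
               tolerance = 1e-8)
  # 8 genotyped of 20: compare with inverting the closed-form dense H
  gids <- ped$id[c(3, 5, 8, 11, 14, 16, 18, 20)]
  A22 <- build_A22(ped, gids)
  Gg <- blend_G(build_G(subset_animals(gg, gids), compute_allele_freqs(subset_animals(gg, gids))),
                A22, 0.95)
  Hinv <- build_H_inverse(A_inv, A22, Gg, gids)
  H_dense <- dense_H_oracle(A, Gg, gids)
  expect_lt(max(abs(as.matrix(Hinv) - solve(H_dense))), 1e-6)
})
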