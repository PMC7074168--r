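#' Numerator relationship matrix (tabular method)
#'
#' Builds the pedigree-based additive relationship matrix A by the tabular
#' method: `a_ii = 1 + F_i` with `F_i` half the relationship of the parents,
#' and `a_ij` the mean of j's relationships with i's parents.
#'
#' @param ped a [pedigree] (ordered parents-first; the constructor enforces
#'   acyclicity).
#' @return Dense symmetric matrix with animal ids as dimnames and
#'   `attr(, "kind") == "A"`.
#' @export
build_A <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- pi[i, 1]; d <- pi[i, 2]
    if (i > 1) {
      j <- seq_len(i - 1L)
      as_ <- if (s > 0) A[j, s] else 0
      ad_ <- if (d > 0) A[j, d] else 0
      A[j, i] <- A[i, j] <- 0.5 * (as_ + ad_)
    }
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
  }
  attr(A, "kind") <- "A"
  A
}

#' Pedigree relationship matrix among the genotyped animals
#'
#' A22: the block of A for a subset of animals, computed on the pedigree
#' pruned to that subset and its ancestors (so cost scales with the relevant
#' paths, not the whole pedigree).
#'
#' @param ped a [pedigree].
#' @param ids the genotyped animals, a subset of `ped$id`.
#' @return Dense symmetric matrix over `ids` (in pedigree order), kind
#'   `"A22"`.
#' @export
build_A22 <- function(ped, ids) {
  ids <- as.character(ids)
  sub <- prune_pedigree(ped, ids)
  A <- build_A(sub)
  keep <- sub$id[sub$id %in% ids]
  out <- A[keep, keep, drop = FALSE]
  attr(out, "kind") <- "A22"
  out
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with Mendelian-sampling variances from the
#' Meuwissen-Luo inbreeding recursion, exact for inbred pedigrees: for
#' animal i with parents s, d, `alpha_i = 1/d_i` where
#' `d_i = 0.5 - 0.25 (F_s + F_d)` (unknown parents contribute F = -1).
#'
#' @param ped a [pedigree].
#' @return Sparse symmetric `Matrix` with animal ids as dimnames, kind
#'   `"A_inverse"`.
#' @export
build_A_inverse <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  pi <- parent_index(ped)
  F <- unname(inbreeding_coefficients(ped))
  s <- pi[, 1]; d <- pi[, 2]
  Fs <- ifelse(s > 0, F[pmax(s, 1)], -1)
  Fd <- ifelse(d > 0, F[pmax(d, 1)], -1)
  alpha <- 1 / (0.5 - 0.25 * (Fs + Fd))
  ks <- which(s > 0); kd <- which(d > 0); kb <- which(s > 0 & d > 0)
  ii <- c(seq_len(n), ks, s[ks], kd, d[kd], s[ks], d[kd], s[kb], d[kb])
  jj <- c(seq_len(n), s[ks], ks, d[kd], kd, s[ks], d[kd], d[kb], s[kb])
  xx <- c(alpha,
          -alpha[ks] / 2, -alpha[ks] / 2, -alpha[kd] / 2, -alpha[kd] / 2,
          alpha[ks] / 4, alpha[kd] / 4, alpha[kb] / 4, alpha[kb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(ped$id, ped$id))
  Ainv <- Matrix::forceSymmetric((Ainv + Matrix::t(Ainv)) / 2)
  attr(Ainv, "kind") <- "A_inverse"
  Ainv
}

#' Observed allele frequencies
#'
#' Frequency of the counted (A1) allele per SNP: mean dosage over non-missing
#' calls divided by 2.
#'
#' @param genotypes a [genotype_matrix] (typically the genotyped subset after
#'   QC).
#' @return An object of class `allele_freqs`: list with `p` (named numeric in
#'   (0,1)) and `source = "observed"`.
#' @export
compute_allele_freqs <- function(genotypes) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  dos <- genotypes$dosages
  ncall <- colSums(!is.na(dos))
  if (any(ncall == 0))
    stopf("SNP(s) with no non-missing calls: %s",
          paste(head(genotypes$map$snp[ncall == 0], 5), collapse = ", "))
  p <- colMeans(dos, na.rm = TRUE) / 2
  if (any(p <= 0 | p >= 1))
    stopf("monomorphic SNP(s) (p = 0 or 1): %s; apply the MAF filter first",
          paste(head(genotypes$map$snp[p <= 0 | p >= 1], 5), collapse = ", "))
  structure(list(p = p, source = "observed"), class = "allele_freqs")
}

#' Supplied allele frequencies
#'
#' Wraps externally provided frequencies (e.g. base-population estimates) in
#' the container used by [build_G()] and [compute_lambda()].
#'
#' @param p named numeric vector of A1 frequencies, strictly in (0, 1).
#' @return An `allele_freqs` object with `source = "supplied"`.
#' @export
allele_freqs <- function(p) {
  if (any(p <= 0 | p >= 1)) stopf("allele frequencies must lie strictly in (0, 1)")
  structure(list(p = p, source = "supplied"), class = "allele_freqs")
}

freq_vector <- function(freqs) {
  if (inherits(freqs, "allele_freqs")) freqs$p else as.numeric(freqs)
}

#' Centered dosage matrix
#'
#' Columns centered by `2 p_i`; missing dosages are mean-imputed to `2 p_i`
#' (centered value 0), the convention that leaves G unbiased in expectation.
#'
#' @param genotypes a [genotype_matrix].
#' @param freqs [allele_freqs] aligned with the SNP map.
#' @return Numeric matrix Z (animals x SNPs).
#' @export
center_dosages <- function(genotypes, freqs) {
  p <- freq_vector(freqs)
  dos <- genotypes$dosages
  if (length(p) != ncol(dos)) stopf("freqs length != SNP count")
  Z <- sweep(dos, 2L, 2 * p)
  Z[is.na(Z)] <- 0
  Z
}

#' Weighted genomic relationship matrix
#'
#' VanRaden's marker-based relationship matrix with per-SNP variance
#' weights: `G = Z diag(d) Z' / sum_i 2 p_i (1 - p_i)` where Z is the
#' dosage matrix column-centered by `2 p_i`.
#'
#' @param genotypes a [genotype_matrix] of the genotyped animals.
#' @param freqs [allele_freqs].
#' @param weights per-SNP weights (numeric vector or [snp_weights]); `NULL`
#'   means unit weights (unweighted G).
#' @return Dense symmetric matrix over the genotyped animals, kind `"G"`.
#' @export
build_G <- function(genotypes, freqs, weights = NULL) {
  p <- freq_vector(freqs)
  Z <- center_dosages(genotypes, freqs)
  d <- weight_vector(weights, ncol(Z))
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0) stopf("sum 2p(1-p) must be positive")
  G <- tcrossprod(sweep(Z, 2L, sqrt(d), `*`)) / denom
  G <- (G + t(G)) / 2
  dimnames(G) <- list(genotypes$ids, genotypes$ids)
  attr(G, "kind") <- "G"
  G
}

#' Marker-variance scaling constant
#'
#' `lambda = 1 / sum_i 2 p_i (1 - p_i)`, the factor relating SNP-effect
#' variance to the additive genetic variance on the G scale.
#'
#' @param freqs [allele_freqs].
#' @return Scalar lambda.
#' @export
compute_lambda <- function(freqs) {
  p <- freq_vector(freqs)
  if (length(p) == 0) stopf("empty SNP panel")
  1 / sum(2 * p * (1 - p))
}

#' Blend G with the pedigree relationship of the genotyped animals
#'
#' `beta G + (1 - beta) A22`. Guarantees invertibility of G when the number
#' of genotyped animals exceeds the effective marker rank or when animals
#' are duplicated; `beta = 1` disables blending.
#'
#' @param G,A22 matching square matrices over the same animals.
#' @param beta weight on G, in (0, 1].
#' @return Blended matrix, kind `"G"`, with `attr(, "beta")` recording the
#'   weight.
#' @export
blend_G <- function(G, A22, beta = 0.95) {
  if (!all(dim(G) == dim(A22))) stopf("G and A22 dimensions differ")
  if (!is_fraction(beta, 0, 1, TRUE, FALSE)) stopf("beta must lie in (0, 1]")
  out <- if (beta == 1) G else beta * G + (1 - beta) * A22
  attr(out, "kind") <- "G"
  attr(out, "beta") <- beta
  out
}

#' Single-step relationship matrix inverse
#'
#' `H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]`: the genomic information enters as
#' a correction to the genotyped-by-genotyped block of the pedigree inverse.
#'
#' @param A_inv sparse pedigree inverse from [build_A_inverse()] (all
#'   animals).
#' @param A22 pedigree relationships among the genotyped animals.
#' @param G_blended (blended) genomic relationship matrix, same animals and
#'   order as `A22`.
#' @param genotyped_ids ids of the genotyped animals (subset of the
#'   pedigree).
#' @return Sparse symmetric `Matrix` over all pedigree animals, kind
#'   `"H_inverse"`.
#' @export
build_H_inverse <- function(A_inv, A22, G_blended, genotyped_ids) {
  ids <- rownames(A_inv)
  genotyped_ids <- as.character(genotyped_ids)
  if (!all(genotyped_ids %in% ids))
    stopf("genotyped ids missing from pedigree inverse")
  if (length(genotyped_ids) == 0) {
    H <- A_inv
    attr(H, "kind") <- "H_inverse"
    return(H)
  }
  stopifnot(all(dim(A22) == length(genotyped_ids)),
            all(dim(G_blended) == length(genotyped_ids)))
  Ginv <- tryCatch(solve(G_blended), error = function(e)
    stopf("G is singular; blend it with A22 (see blend_G)"))
  corr <- Ginv - solve(A22)
  idx <- match(genotyped_ids, ids)
  n <- length(ids)
  C <- Matrix::sparseMatrix(i = rep(idx, times = length(idx)),
                            j = rep(idx, each = length(idx)),
                            x = as.numeric(corr), dims = c(n, n))
  H <- Matrix::forceSymmetric(A_inv + (C + Matrix::t(C)) / 2)
  dimnames(H) <- list(ids, ids)
  attr(H, "kind") <- "H_inverse"
  H
}
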