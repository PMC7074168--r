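# Independent oracles used across the suite. These deliberately avoid the
# package's own algorithms (tabular A, Henderson A-inverse, MME backsolve).

# recursive path-counting kinship: phi(i,i) = 0.5 (1 + phi(s,d)),
# phi(i,j) = 0.5 (phi(s_i, j) + phi(d_i, j)) with the later-born animal
# expanded; unknown parents contribute 0. A = 2 phi.
kinship_oracle_A <- function(ped) {
  n <- nrow(ped)
  pos <- seq_len(n); names(pos) <- ped$id
  si <- ifelse(ped$sire == "0", 0L, pos[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, pos[ped$dam])
  memo <- new.env(parent = emptyenv())
  phi <- function(i, j) {
    if (i == 0L || j == 0L) return(0)
    if (i < j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, "_", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) 0.5 * (1 + phi(si[i], di[i]))
           else 0.5 * (phi(si[i], j) + phi(di[i], j))
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in seq_len(i)) A[i, j] <- A[j, i] <- 2 * phi(i, j)
  A
}

# random valid pedigree: each non-founder draws parents uniformly from
# earlier animals (sires from odd indices, dams from even, so sexes stay
# consistent)
random_pedigree <- function(n, n_founders = max(2L, n %/% 3L)) {
  id <- sprintf("a%03d", seq_len(n))
  sire <- rep("0", n); dam <- rep("0", n)
  for (i in seq(n_founders + 1L, length.out = max(0L, n - n_founders))) {
    earlier <- seq_len(i - 1L)
    males <- earlier[earlier %% 2L == 1L]
    females <- earlier[earlier %% 2L == 0L]
    if (length(males)) sire[i] <- id[males[sample.int(length(males), 1L)]]
    if (length(females)) dam[i] <- id[females[sample.int(length(females), 1L)]]
  }
  pedigree(id, sire, dam)
}

# exact HWE conditional distribution built from dmultinom (a code path the
# package's test does not use): P(n_Aa | n, allele count) by conditioning
# the HWE multinomial on the rare-allele count
hwe_oracle_p <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  na <- n_Aa + 2 * n_aa
  if (na > n) na <- 2 * n - na
  if (na == 0) return(1)
  p <- na / (2 * n)
  het <- seq(na %% 2, min(na, 2 * n - na), by = 2)
  pr <- vapply(het, function(h) {
    aa <- (na - h) / 2
    dmultinom(c(n - h - aa, h, aa), prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
  }, numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# dense single-step H built from its closed form, for checking H^-1:
# H11 = A11 + A12 A22^-1 (G - A22) A22^-1 A21, H12 = A12 A22^-1 G, H22 = G
dense_H_oracle <- function(A, G, genotyped_ids) {
  ids <- rownames(A)
  g <- match(genotyped_ids, ids); ng <- setdiff(seq_along(ids), g)
  A22i <- solve(A[g, g])
  H <- A
  H[ng, ng] <- A[ng, ng] +
    A[ng, g] %*% A22i %*% (G - A[g, g]) %*% A22i %*% A[g, ng]
  H[ng, g] <- A[ng, g] %*% A22i %*% G
  H[g, ng] <- t(H[ng, g])
  H[g, g] <- G
  H
}

# dense textbook pedigree-BLUP: direct solve of the full MME built with
# base-R linear algebra only
dense_blup_oracle <- function(y, X, Zmat, Ainv_dense, ratio) {
  C <- rbind(cbind(t(X) %*% X, t(X) %*% Zmat),
             cbind(t(Zmat) %*% X, t(Zmat) %*% Zmat + ratio * Ainv_dense))
  rhs <- c(t(X) %*% y, t(Zmat) %*% y)
  sol <- solve(C, rhs)
  list(b = sol[seq_len(ncol(X))], a = sol[-seq_len(ncol(X))])
}

# small genotype matrix straight from a dosage matrix
toy_genotypes <- function(dos, chr = NULL, pos = NULL) {
  M <- ncol(dos)
  map <- data.frame(snp = sprintf("s%03d", seq_len(M)),
                    chr = chr %||% rep(1L, M),
                    pos = pos %||% seq_len(M) * 1000L,
                    a1 = "A", a2 = "B")
  if (is.null(rownames(dos))) rownames(dos) <- sprintf("an%03d", seq_len(nrow(dos)))
  genotype_matrix(dos, map)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
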