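#' Average daily gain from birth to yearling
#'
#' `(yw - bw) / days`, the pre-analysis derivation of the BYADG trait from
#' birth weight and yearling weight. Vectorized; missing inputs give missing
#' output.
#'
#' @param bw birth weight (kg), non-negative.
#' @param yw yearling weight (kg), at least `bw`.
#' @param days days between the two weighings, strictly positive.
#' @return Average daily gain in kg/day.
#' @export
derive_byadg <- function(bw, yw, days) {
  n <- max(length(bw), length(yw), length(days))
  bw <- rep_len(bw, n); yw <- rep_len(yw, n); days <- rep_len(days, n)
  if (any(days <= 0, na.rm = TRUE)) stopf("days must be strictly positive")
  if (any(bw < 0, na.rm = TRUE)) stopf("birth weight must be non-negative")
  if (any(yw < bw, na.rm = TRUE)) stopf("yearling weight below birth weight")
  (yw - bw) / days
}

#' Remove phenotypic outliers beyond three standard deviations
#'
#' Single-pass screen: mean and SD are computed once on the non-missing
#' input, and values with `|x - mean| > k * SD` are removed. No
#' re-iteration after removal.
#'
#' @param values numeric trait vector (may contain `NA`).
#' @param k SD multiplier (default 3).
#' @return List with `kept` (values with outliers set to `NA` removed from
#'   the non-missing set; original `NA`s preserved), `kept_idx`,
#'   `removed_idx`, `mean`, `sd`.
#' @export
remove_outliers <- function(values, k = 3) {
  ok <- !is.na(values)
  if (sum(ok) < 2) stopf("need at least 2 non-missing values")
  m <- mean(values[ok]); s <- sd(values[ok])
  out <- ok & abs(values - m) > k * s
  out[is.na(out)] <- FALSE
  list(kept = values[!out & ok], kept_idx = which(!out & ok),
       removed_idx = which(out), mean = m, sd = s)
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count
#' (the "no more probable" rule).
#'
#' @param n_AA,n_Aa,n_aa genotype counts.
#' @return The exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  cnt <- c(n_AA, n_Aa, n_aa)
  if (any(cnt < 0) || any(cnt != round(cnt))) stopf("counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) stopf("total genotype count is zero")
  n_a <- n_Aa + 2 * n_aa         # rare-allele count (relabel if needed)
  if (n_a > n) n_a <- 2 * n - n_a
  if (n_a == 0) return(1)        # monomorphic: single configuration
  # feasible heterozygote counts share the parity of n_a
  het <- seq(n_a %% 2, min(n_a, 2 * n - n_a), by = 2)
  # log P(n_Aa = h | n, n_a) up to a constant (Levene / Haldane distribution)
  logp <- lfactorial(n) - lfactorial((n_a - het) / 2) - lfactorial(het) -
    lfactorial(n - (n_a + het) / 2) + het * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp); pr <- pr / sum(pr)
  obs <- pr[match(n_Aa, het)]
  if (is.na(obs)) stopf("inconsistent genotype counts")
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

observed_maf <- function(dos) {
  p <- colMeans(dos, na.rm = TRUE) / 2
  pmin(p, 1 - p)
}

#' Genotype quality control
#'
#' Applies the standard GWAS marker filters in a fixed order: (1) individual
#' call rate, (2) SNP call rate, (3) minor allele frequency, (4) exact HWE
#' test, (5) non-autosomal or unmapped SNPs. SNP statistics (call rate, MAF,
#' HWE) are recomputed after individual removal. Thresholds follow the
#' usual conventions: individuals/SNPs with call rate *below* the threshold
#' are removed, SNPs with MAF strictly below `maf_min` are removed, SNPs
#' with HWE p strictly below `hwe_p_min` are removed.
#'
#' @param genotypes a [genotype_matrix].
#' @param ind_call_rate,snp_call_rate minimum call rates (default 0.95).
#' @param maf_min minimum minor allele frequency (default 0.05, strict `<`
#'   removal).
#' @param hwe_p_min minimum exact HWE p-value (default 1e-6).
#' @param autosome_max largest autosome number; SNPs with `chr` outside
#'   `1..autosome_max` or missing position are dropped. Default keeps all
#'   numeric chromosomes present.
#' @return List with `genotypes` (filtered [genotype_matrix]) and `report`
#'   (class `qc_report`): removal counts per filter and the thresholds used.
#' @export
apply_genotype_qc <- function(genotypes, ind_call_rate = 0.95,
                              snp_call_rate = 0.95, maf_min = 0.05,
                              hwe_p_min = 1e-6, autosome_max = NULL) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  for (thr in c(ind_call_rate, snp_call_rate, maf_min))
    if (!is_fraction(thr, 0, 1, FALSE, FALSE)) stopf("thresholds must lie in [0, 1]")
  dos <- genotypes$dosages
  map <- genotypes$map
  # (1) individual call rate
  icr <- rowMeans(!is.na(dos))
  drop_ind <- icr < ind_call_rate
  dos <- dos[!drop_ind, , drop = FALSE]
  if (nrow(dos) == 0) stopf("QC removed every individual (call rate < %g)", ind_call_rate)
  # (2) SNP call rate, recomputed on retained individuals
  scr <- colMeans(!is.na(dos))
  rm_call <- scr < snp_call_rate
  # (3) MAF on non-missing calls
  maf <- observed_maf(dos)
  rm_maf <- !rm_call & maf < maf_min
  # (4) exact HWE on surviving SNPs
  rm_hwe <- logical(ncol(dos))
  cand <- which(!rm_call & !rm_maf)
  for (j in cand) {
    x <- dos[, j]; x <- x[!is.na(x)]
    p <- hwe_exact_test(sum(x == 0), sum(x == 1), sum(x == 2))
    rm_hwe[j] <- p < hwe_p_min
  }
  # (5) non-autosomal / unmapped
  chr_num <- suppressWarnings(as.numeric(map$chr))
  auto_ok <- !is.na(chr_num) & chr_num >= 1 &
    (if (is.null(autosome_max)) TRUE else chr_num <= autosome_max) &
    !is.na(map$pos)
  rm_auto <- !rm_call & !rm_maf & !rm_hwe & !auto_ok
  keep <- !(rm_call | rm_maf | rm_hwe | rm_auto)
  if (!any(keep)) stopf("QC removed every SNP; check thresholds")
  out <- genotype_matrix(dos[, keep, drop = FALSE], map[keep, , drop = FALSE],
                         rownames(dos))
  report <- structure(list(
    n_individuals_in = length(genotypes$ids),
    n_individuals_removed = sum(drop_ind),
    n_snps_in = ncol(genotypes$dosages),
    n_snps_removed_call_rate = sum(rm_call),
    n_snps_removed_maf = sum(rm_maf),
    n_snps_removed_hwe = sum(rm_hwe),
    n_snps_removed_nonautosomal = sum(rm_auto),
    n_snps_out = sum(keep),
    thresholds = list(ind_call_rate = ind_call_rate,
                      snp_call_rate = snp_call_rate, maf_min = maf_min,
                      hwe_p_min = hwe_p_min, autosome_max = autosome_max),
    filter_order = c("individual_call_rate", "snp_call_rate", "maf", "hwe",
                     "non_autosomal")), class = "qc_report")
  list(genotypes = out, report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("genotype QC report\n")
  cat(sprintf("  individuals: %d in, %d removed (call rate)\n",
              x$n_individuals_in, x$n_individuals_removed))
  cat(sprintf("  SNPs: %d in -> %d out\n", x$n_snps_in, x$n_snps_out))
  cat(sprintf("    removed: call rate %d, MAF %d, HWE %d, non-autosomal %d\n",
              x$n_snps_removed_call_rate, x$n_snps_removed_maf,
              x$n_snps_removed_hwe, x$n_snps_removed_nonautosomal))
  invisible(x)
}
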