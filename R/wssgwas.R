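#' Per-SNP variance weights
#'
#' The diagonal D of SNP variance weights used in the weighted genomic
#' relationship matrix. The first iteration uses `D = I`; later iterations
#' derive weights from squared back-solved SNP effects and are trace-
#' normalised so `tr(D)` stays equal to the SNP count.
#'
#' @param d non-negative numeric weights, one per SNP.
#' @param iteration iteration index the weights belong to.
#' @return List of class `snp_weights`.
#' @export
snp_weights <- function(d, iteration = 1L) {
  if (any(d < 0)) stopf("SNP weights must be non-negative")
  structure(list(d = as.numeric(d), iteration = as.integer(iteration)),
            class = "snp_weights")
}

weight_vector <- function(weights, M) {
  if (is.null(weights)) return(rep(1, M))
  d <- if (inherits(weights, "snp_weights")) weights$d else as.numeric(weights)
  if (length(d) != M) stopf("weight length [%d] != SNP count [%d]", length(d), M)
  d
}

#' Back-solve SNP effects from genomic breeding values
#'
#' `u = lambda D Z' G^-1 a_g`: converts the GEBVs of the genotyped animals
#' into per-SNP allele-substitution effects.
#'
#' @param gebv_g GEBVs of the genotyped animals, ordered as the rows of
#'   `Z_centered`.
#' @param Z_centered centered dosage matrix ([center_dosages()]).
#' @param weights SNP weights (`NULL` = unit).
#' @param G the genomic relationship matrix used in the solve (blended if
#'   blending was applied upstream).
#' @param lambda scaling constant from [compute_lambda()].
#' @return Named numeric vector of SNP effects (trait units per allele
#'   copy).
#' @export
backsolve_snp_effects <- function(gebv_g, Z_centered, weights = NULL, G, lambda) {
  M <- ncol(Z_centered)
  if (length(gebv_g) != nrow(Z_centered))
    stopf("gebv length [%d] != genotyped animals [%d]", length(gebv_g), nrow(Z_centered))
  d <- weight_vector(weights, M)
  Ga <- tryCatch(solve(G, gebv_g), error = function(e)
    stopf("G is singular; blend it with A22 before back-solving"))
  u <- lambda * d * as.numeric(crossprod(Z_centered, Ga))
  stats::setNames(u, colnames(Z_centered))
}

#' Update SNP weights from estimated effects
#'
#' `d_i = u_i^2 * 2 p_i (1 - p_i)`: the variance attributed to each SNP by
#' its current effect estimate.
#'
#' @param effects SNP effect vector (from [backsolve_snp_effects()]).
#' @param freqs [allele_freqs] aligned with the effects.
#' @return Unnormalised [snp_weights].
#' @export
update_weights <- function(effects, freqs) {
  p <- freq_vector(freqs)
  if (length(effects) != length(p)) stopf("effects and freqs lengths differ")
  snp_weights(as.numeric(effects)^2 * 2 * p * (1 - p))
}

#' Trace-normalise SNP weights
#'
#' Rescales weights so their trace (sum) equals the previous iteration's
#' trace, keeping the total genetic variance constant across iterations.
#' The starting trace is the SNP count M (unit weights).
#'
#' @param weights new (unnormalised) [snp_weights] or numeric vector.
#' @param previous previous [snp_weights], numeric vector, or a single
#'   number giving the target trace.
#' @return Normalised [snp_weights] with the iteration index advanced.
#' @export
normalize_weights <- function(weights, previous) {
  d <- if (inherits(weights, "snp_weights")) weights$d else as.numeric(weights)
  target <- if (length(previous) == 1 && is.numeric(previous)) previous
            else sum(if (inherits(previous, "snp_weights")) previous$d
                     else as.numeric(previous))
  tr <- sum(d)
  if (tr <= 0) stopf("all SNP weights are zero; no signal to normalise")
  it <- if (inherits(previous, "snp_weights")) previous$iteration + 1L else 1L
  snp_weights(d * target / tr, iteration = it)
}

#' Sliding-window decomposition of additive genetic variance
#'
#' For each window of `window_size` successive SNPs (step 1, never spanning
#' a chromosome boundary) the genetic value of animal k is
#' `sum_j z_kj u_j` over the window's SNPs; the window's share of additive
#' variance is the empirical variance (n-1 denominator) of that value
#' across genotyped animals divided by `sigma_a2`, times 100.
#'
#' @param effects SNP effect vector aligned with `snp_map`.
#' @param Z_centered centered dosage matrix of the genotyped animals.
#' @param snp_map data.frame with `snp`, `chr`, `pos` aligned with
#'   `effects`.
#' @param sigma_a2 total additive genetic variance.
#' @param window_size SNPs per window (default 20).
#' @return data.frame of class `window_results`: `chr`, `start_bp`,
#'   `end_bp`, `gvar_percent`, `start_idx`, `end_idx` (global SNP indices),
#'   `n_snps`. Chromosomes shorter than the window are skipped with a
#'   warning.
#' @export
window_variances <- function(effects, Z_centered, snp_map, sigma_a2,
                             window_size = 20L) {
  stopifnot(length(effects) == nrow(snp_map), ncol(Z_centered) == nrow(snp_map))
  if (sigma_a2 <= 0) stopf("sigma_a2 must be positive")
  out <- list()
  for (ch in unique(snp_map$chr)) {
    idx <- which(snp_map$chr == ch)
    m <- length(idx)
    if (m < window_size) {
      warnf("chromosome %s has %d SNPs (< window %d); skipped", ch, m, window_size)
      next
    }
    W <- sweep(Z_centered[, idx, drop = FALSE], 2L, effects[idx], `*`)
    CS <- cbind(0, t(apply(W, 1L, cumsum)))
    starts <- seq_len(m - window_size + 1L)
    g <- vapply(starts, function(i) {
      v <- CS[, i + window_size] - CS[, i]
      var(v)
    }, numeric(1))
    out[[length(out) + 1L]] <- data.frame(
      chr = ch,
      start_bp = snp_map$pos[idx[starts]],
      end_bp = snp_map$pos[idx[starts + window_size - 1L]],
      gvar_percent = g / sigma_a2 * 100,
      start_idx = idx[starts],
      end_idx = idx[starts + window_size - 1L],
      n_snps = window_size, stringsAsFactors = FALSE)
  }
  if (!length(out)) stopf("no chromosome long enough for the window size")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("window_results", "data.frame")
  res
}

#' Top SNP of a window
#'
#' The SNP within the window maximising the individual variance
#' contribution `u_j^2 * 2 p_j (1 - p_j)`; ties are broken by the lowest bp
#' position.
#'
#' @param window one row of a [window_variances()] result.
#' @param effects SNP effect vector aligned with `snp_map`.
#' @param freqs [allele_freqs] aligned with `snp_map`.
#' @param snp_map the marker map the indices refer to.
#' @return The top SNP id (character).
#' @export
top_snp <- function(window, effects, freqs, snp_map) {
  j <- window$start_idx:window$end_idx
  p <- freq_vector(freqs)[j]
  contrib <- as.numeric(effects[j])^2 * 2 * p * (1 - p)
  ord <- order(-contrib, snp_map$pos[j])
  snp_map$snp[j[ord[1]]]
}

#' Select and collapse QTL candidate windows
#'
#' Keeps windows explaining more than `threshold_percent` of the additive
#' genetic variance and collapses each contiguous run of overlapping
#' selected windows to the single window with the locally maximal share,
#' yielding one nonredundant region per peak. Output is sorted by
#' `gvar_percent`, descending.
#'
#' @param results a [window_variances()] data.frame (genome-ordered).
#' @param threshold_percent selection threshold (default 1.0, strict `>`).
#' @return Subset of `results`, possibly empty.
#' @export
select_windows <- function(results, threshold_percent = 1.0) {
  sel <- results[results$gvar_percent > threshold_percent, , drop = FALSE]
  if (nrow(sel) == 0) return(sel)
  # runs of overlapping windows: same chromosome and SNP spans intersecting
  new_run <- c(TRUE, sel$chr[-1] != sel$chr[-nrow(sel)] |
                 sel$start_idx[-1] > sel$end_idx[-nrow(sel)])
  run <- cumsum(new_run)
  keep <- unlist(lapply(split(seq_len(nrow(sel)), run), function(ix) {
    ix[which.max(sel$gvar_percent[ix])]
  }), use.names = FALSE)
  out <- sel[keep, , drop = FALSE]
  out <- out[order(-out$gvar_percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nonredundant union of per-trait window selections
#'
#' Windows with identical (chromosome, start, end) count once across
#' traits; overlapping but unequal windows count separately.
#'
#' @param ... per-trait window data.frames (as from [select_windows()]),
#'   or a single list of them.
#' @return Deduplicated data.frame sorted by `gvar_percent`, descending.
#' @export
nonredundant_union <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.list(args[[1]]) && !is.data.frame(args[[1]]))
    args <- args[[1]]
  all <- do.call(rbind, args)
  if (is.null(all) || nrow(all) == 0) return(all)
  key <- paste(all$chr, all$start_bp, all$end_bp, sep = ":")
  out <- all[!duplicated(key), , drop = FALSE]
  out <- out[order(-out$gvar_percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Iterative weighted single-step GWAS
#'
#' Runs the weighting loop: iteration 1 uses unit weights (`D = I`); each
#' iteration builds the weighted genomic relationship matrix, blends it
#' with A22, forms `H^-1`, solves the mixed-model equations for GEBVs at
#' fixed variance components, back-solves SNP effects, then derives and
#' trace-normalises the next iteration's weights. Window variance profiles
#' are computed from each iteration's effects.
#'
#' @param phenotypes phenotype data.frame (`id`, trait, fixed-effect
#'   columns).
#' @param ped a [pedigree] covering all phenotyped animals.
#' @param genotypes a [genotype_matrix] of the genotyped subset (post-QC).
#' @param vc [variance_components()], estimated once and held fixed across
#'   iterations.
#' @param spec a [model_spec()].
#' @param iterations number of weighting iterations (default 3).
#' @param window_size SNPs per window (default 20).
#' @param beta blending weight on G (default 0.95; 1 disables blending).
#' @param threshold_percent selection threshold for candidate windows.
#' @return List of class `wssgwas_run`: per-iteration records (`weights`,
#'   `effects`, `gebv_g`, `windows`), the final `windows` profile and
#'   `selected` windows (top SNPs filled in), `freqs`, `lambda`, `map` and
#'   the settings used.
#' @export
run_wssgwas <- function(phenotypes, ped, genotypes, vc, spec,
                        iterations = 3L, window_size = 20L, beta = 0.95,
                        threshold_percent = 1.0) {
  stopifnot(inherits(ped, "pedigree"), inherits(genotypes, "genotype_matrix"),
            inherits(vc, "variance_components"), inherits(spec, "model_spec"))
  if (!is_count(iterations)) stopf("iterations must be a positive count")
  gids <- genotypes$ids
  if (!all(gids %in% ped$id)) stopf("genotyped animals missing from pedigree")
  freqs <- compute_allele_freqs(genotypes)
  Z <- center_dosages(genotypes, freqs)
  lambda <- compute_lambda(freqs)
  A_inv <- build_A_inverse(ped)
  A22 <- build_A22(ped, gids)
  M <- ncol(Z)
  D <- snp_weights(rep(1, M), iteration = 1L)
  iters <- vector("list", iterations)
  for (t in seq_len(iterations)) {
    G <- build_G(genotypes, freqs, D)
    Gb <- blend_G(G, A22, beta)
    H_inv <- build_H_inverse(A_inv, A22, Gb, gids)
    sys <- assemble_mme(spec, phenotypes, H_inv, vc, genotyped_ids = gids)
    sol <- solve_mme(sys)
    u <- backsolve_snp_effects(sol$a_g, Z, D, Gb, lambda)
    win <- window_variances(u, Z, genotypes$map, vc$sigma_a2, window_size)
    iters[[t]] <- list(weights = D, effects = u, gebv_g = sol$a_g,
                       windows = win)
    if (t < iterations)
      D <- normalize_weights(update_weights(u, freqs), D)
  }
  final <- iters[[iterations]]
  sel <- select_windows(final$windows, threshold_percent)
  if (nrow(sel))
    sel$top_snp <- vapply(seq_len(nrow(sel)), function(i)
      top_snp(sel[i, ], final$effects, freqs, genotypes$map), character(1))
  structure(list(iterations = iters, windows = final$windows, selected = sel,
                 effects = final$effects, freqs = freqs, lambda = lambda,
                 map = genotypes$map,
                 settings = list(iterations = iterations,
                                 window_size = window_size, beta = beta,
                                 threshold_percent = threshold_percent,
                                 sigma_a2 = vc$sigma_a2, trait = spec$trait)),
            class = "wssgwas_run")
}

#' @export
print.wssgwas_run <- function(x, ...) {
  s <- x$settings
  cat(sprintf("wssGWAS run: trait '%s', %d iteration(s), %d-SNP windows\n",
              s$trait, s$iterations, s$window_size))
  cat(sprintf("  %d windows scanned; %d selected above %.2f%% gVar\n",
              nrow(x$windows), nrow(x$selected), s$threshold_percent))
  if (nrow(x$selected)) {
    cat("  top regions:\n")
    print.data.frame(head(x$selected[, c("chr", "start_bp", "end_bp",
                                         "gvar_percent", "top_snp")], 5))
  }
  invisible(x)
}
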