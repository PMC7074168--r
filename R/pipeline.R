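#' Load an analysis configuration
#'
#' Reads a YAML configuration (or accepts an equivalent list) describing
#' one full analysis: input paths, per-trait model specifications, QC
#' thresholds and wssGWAS settings. Referenced paths are checked at load
#' time.
#'
#' @param config path to a YAML file, or a list with elements `paths`
#'   (`pedigree`, `genotypes` (PLINK prefix), `phenotypes`, optional
#'   `genes`), `traits` (named list: each with `fixed_factors`,
#'   `covariates`), optional `qc`, `wssgwas` (`iterations`, `window_size`,
#'   `threshold_percent`, `beta`), `seed`, `out_dir`.
#' @return Validated list of class `analysis_config`.
#' @export
analysis_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  for (key in c("paths", "traits", "out_dir"))
    if (is.null(config[[key]])) stopf("config lacks required entry '%s'", key)
  p <- config$paths
  for (key in c("pedigree", "phenotypes"))
    if (is.null(p[[key]]) || !file.exists(p[[key]]))
      stopf("config path '%s' missing or nonexistent: %s", key, p[[key]] %||% "<unset>")
  if (is.null(p$genotypes) ||
      !(file.exists(paste0(p$genotypes, ".ped")) ||
        file.exists(paste0(p$genotypes, ".bed"))))
    stopf("no PLINK fileset at config genotype prefix '%s'", p$genotypes %||% "<unset>")
  if (!is.null(p$genes) && !file.exists(p$genes))
    stopf("gene annotation file not found: %s", p$genes)
  config$qc <- utils::modifyList(
    list(ind_call_rate = 0.95, snp_call_rate = 0.95, maf_min = 0.05,
         hwe_p_min = 1e-6), config$qc %||% list())
  config$wssgwas <- utils::modifyList(
    list(iterations = 3L, window_size = 20L, threshold_percent = 1.0,
         beta = 0.95), config$wssgwas %||% list())
  w <- config$wssgwas
  if (!is_count(w$iterations) || !is_count(w$window_size) ||
      !is_fraction(w$beta, 0, 1, TRUE, FALSE))
    stopf("wssgwas settings out of range (iterations/window_size counts, beta in (0,1])")
  config$seed <- as.integer(config$seed %||% 1L)
  structure(config, class = "analysis_config")
}

#' Run the full weighted single-step GWAS pipeline
#'
#' Executes, per trait: genotype QC, relationship construction, REML
#' variance components on `H^-1` (unit SNP weights), the iterative
#' weighting loop with window decomposition, window selection, and (when
#' annotation is configured) candidate-gene lookup. All intermediate tables
#' are written under `out_dir` as TSV; a manifest summarises versions,
#' checksums and per-stage counts.
#'
#' @param config an [analysis_config()] (list or YAML path accepted).
#' @return The run manifest (class `run_manifest`), invisibly; side effect
#'   is the populated output directory.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "analysis_config")) config <- analysis_config(config)
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ped <- read_pedigree_csv(config$paths$pedigree)
  phen <- utils::read.csv(config$paths$phenotypes, stringsAsFactors = FALSE)
  phen$id <- as.character(phen$id)
  geno_raw <- read_plink(config$paths$genotypes)
  qc <- do.call(apply_genotype_qc, c(list(geno_raw), config$qc))
  geno <- qc$genotypes
  write_qc_report(qc$report, file.path(out_dir, "qc_report.tsv"))
  genes <- if (!is.null(config$paths$genes))
    read_gene_intervals(config$paths$genes) else NULL
  manifest <- list(
    tool = sprintf("wintergwas %s", as.character(utils::packageVersion("wintergwas"))),
    config_hash = config_hash(config),
    input_checksums = input_checksums(config$paths),
    seed = config$seed,
    stages = list(pedigree = nrow(ped),
                  phenotype_records = nrow(phen),
                  genotyped_in = qc$report$n_individuals_in,
                  genotyped_out = length(geno$ids),
                  snps_in = qc$report$n_snps_in,
                  snps_out = qc$report$n_snps_out),
    traits = list(),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  for (tr in names(config$traits)) {
    tc <- config$traits[[tr]]
    spec <- model_spec(tr, fixed_factors = tc$fixed_factors %||% character(0),
                       covariates = tc$covariates %||% character(0))
    stage <- sprintf("trait '%s'", tr)
    res <- tryCatch(
      run_trait(spec, phen, ped, geno, config, genes, out_dir),
      error = function(e) stopf("pipeline failed at %s: %s", stage,
                                conditionMessage(e)))
    manifest$traits[[tr]] <- res$counts
  }
  write_manifest(manifest, file.path(out_dir, "manifest.tsv"))
  class(manifest) <- "run_manifest"
  invisible(manifest)
}

run_trait <- function(spec, phen, ped, geno, config, genes, out_dir) {
  w <- config$wssgwas
  A_inv <- build_A_inverse(ped)
  freqs <- compute_allele_freqs(geno)
  A22 <- build_A22(ped, geno$ids)
  G0 <- blend_G(build_G(geno, freqs), A22, w$beta)
  H_inv <- build_H_inverse(A_inv, A22, G0, geno$ids)
  vc <- reml_estimate(spec, phen, H_inv)
  run <- run_wssgwas(phen, ped, geno, vc, spec,
                     iterations = w$iterations, window_size = w$window_size,
                     beta = w$beta, threshold_percent = w$threshold_percent)
  ts <- summarize_trait(phen[[spec$trait]])
  vc_row <- data.frame(trait = spec$trait, n = ts$n, mean = ts$mean,
                       sd = ts$sd, min = ts$min, max = ts$max,
                       cv_percent = ts$cv_percent, sigma_a2 = vc$sigma_a2,
                       sigma_e2 = vc$sigma_e2, sigma_p2 = vc$sigma_p2,
                       h2 = vc$h2,
                       h2_se = unname((vc$se %||% c(h2 = NA_real_))["h2"]))
  write.table(vc_row, file.path(out_dir, sprintf("vc_%s.tsv", spec$trait)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sysol <- data.frame(id = names(run$iterations[[w$iterations]]$gebv_g),
                      gebv = as.numeric(run$iterations[[w$iterations]]$gebv_g))
  write.table(sysol, file.path(out_dir, sprintf("gebv_%s.tsv", spec$trait)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  prof <- run$windows
  write.table(prof, file.path(out_dir, sprintf("windows_%s.tsv", spec$trait)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sel <- run$selected
  if (!is.null(genes) && nrow(sel)) {
    ann <- lapply(seq_len(nrow(sel)), function(i) {
      snp_row <- run$map[run$map$snp == sel$top_snp[i], ]
      nearest_gene(snp_row$chr[1], snp_row$pos[1], genes)
    })
    sel$candidate_gene <- vapply(ann, `[[`, character(1), "gene")
    sel$distance <- vapply(ann, function(a)
      if (is.na(a$gene)) NA_character_
      else if (a$within) "within" else as.character(a$distance), character(1))
  }
  write.table(sel, file.path(out_dir, sprintf("selected_%s.tsv", spec$trait)),
              sep = "\t", quote = FALSE, row.names = FALSE)
  for (t in seq_along(run$iterations)) {
    it <- run$iterations[[t]]
    write.table(data.frame(snp = run$map$snp, weight = it$weights$d,
                           effect = as.numeric(it$effects)),
                file.path(out_dir, sprintf("snp_iter%d_%s.tsv", t, spec$trait)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(counts = list(records = sum(!is.na(phen[[spec$trait]])),
                     windows = nrow(prof), selected = nrow(sel),
                     h2 = vc$h2))
}

write_qc_report <- function(report, path) {
  df <- data.frame(metric = c("individuals_in", "individuals_removed",
                              "snps_in", "snps_removed_call_rate",
                              "snps_removed_maf", "snps_removed_hwe",
                              "snps_removed_nonautosomal", "snps_out"),
                   value = c(report$n_individuals_in,
                             report$n_individuals_removed, report$n_snps_in,
                             report$n_snps_removed_call_rate,
                             report$n_snps_removed_maf,
                             report$n_snps_removed_hwe,
                             report$n_snps_removed_nonautosomal,
                             report$n_snps_out))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

config_hash <- function(config) {
  clean <- config
  clean$out_dir <- NULL
  tmp <- tempfile()
  on.exit(unlink(tmp))
  dput(clean[order(names(clean))], file = tmp)
  unname(tools::md5sum(tmp))
}

input_checksums <- function(paths) {
  files <- c(paths$pedigree, paths$phenotypes, paths$genes,
             Filter(file.exists, paste0(paths$genotypes, c(".ped", ".map", ".bed", ".bim", ".fam"))))
  files <- files[!vapply(files, is.null, logical(1))]
  sums <- tools::md5sum(unlist(files))
  stats::setNames(unname(sums), basename(names(sums)))
}

write_manifest <- function(manifest, path) {
  flat <- c(tool = manifest$tool, config_hash = manifest$config_hash,
            seed = manifest$seed, timestamp = manifest$timestamp,
            stats::setNames(as.character(unlist(manifest$stages)),
                            paste0("stage_", names(unlist(manifest$stages)))),
            stats::setNames(as.character(unlist(manifest$traits)),
                            paste0("trait_", names(unlist(manifest$traits)))),
            stats::setNames(as.character(manifest$input_checksums),
                            paste0("md5_", names(manifest$input_checksums))))
  write.table(data.frame(key = names(flat), value = unname(flat)), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
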