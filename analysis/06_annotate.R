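#!/usr/bin/env Rscript
# Stage 6: positional candidate lookup and regional LD.
#
# Maps each selected window's top SNP to the nearest interval of the
# synthetic annotation written in stage 1 (distance 0 = "within"), and
# computes pairwise r2 around the strongest window for a region plot.

library(wintergwas)

`%||%` <- function(x, y) if (is.null(x)) y else x

dat <- file.path("results", "data")
geno <- read_plink(file.path(dat, "genotypes_qc"))
genes <- read_gene_intervals(file.path(dat, "synthetic_genes.bed"))
sel <- read.table(file.path("results", "selected_windows.tsv"), header = TRUE,
                  stringsAsFactors = FALSE)

ann <- lapply(seq_len(nrow(sel)), function(i) {
  snp <- geno$map[geno$map$snp == sel$top_snp[i], ]
  nearest_gene(snp$chr[1], snp$pos[1], genes)
})
sel$candidate_gene <- vapply(ann, function(a) a$gene %||% NA_character_,
                             character(1))
sel$distance <- vapply(ann, function(a)
  if (is.na(a$gene)) NA_character_
  else if (a$within) "within" else as.character(a$distance), character(1))
write.table(sel, file.path("results", "candidate_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("top window: chr %s, %d-%d bp, %.2f%% gVar, top SNP %s -> %s (%s)\n",
            sel$chr[1], sel$start_bp[1], sel$end_bp[1], sel$gvar_percent[1],
            sel$top_snp[1], sel$candidate_gene[1], sel$distance[1]))

# LD around the strongest region (plus 200 kb flanks)
ld <- ld_r2(geno, sel$chr[1], from = sel$start_bp[1] - 2e5,
            to = sel$end_bp[1] + 2e5)
ut <- which(upper.tri(ld, diag = TRUE), arr.ind = TRUE)
write.table(data.frame(snp_a = rownames(ld)[ut[, 1]],
                       snp_b = colnames(ld)[ut[, 2]],
                       r2 = ld[ut]),
            file.path("results", "ld_top_region.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("pairwise r2 for %d SNPs around the top region written to results/ld_top_region.tsv\n",
            nrow(ld)))
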