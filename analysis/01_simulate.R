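#!/usr/bin/env Rscript
# Stage 1: simulate the study population.
#
# Builds a breeding population shaped like the motivating beef-cattle
# design: a multi-generation pedigree (~5000 animals, all phenotyped for a
# unit-variance growth trait with h2 = 0.42), linked SNPs on 5 autosomes,
# and genotypes for only ~12% of animals. Writes pedigree/phenotype CSVs,
# a PLINK BED fileset for the genotyped subset, a synthetic gene annotation
# around the simulated QTLs, and the simulation truth.

library(wintergwas)

out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(n_founders = 1000, n_generations = 4,
                  offspring_per_mating = 2, n_chromosomes = 5,
                  snps_per_chromosome = 400, n_qtl = 10,
                  qtl_variance_fraction = 0.6, heritability = 0.42,
                  genotyped_fraction = 0.1235, seed = 20260919)
ped <- simulate_pedigree(cfg)
geno_all <- gene_drop_genotypes(ped, cfg)
sim <- simulate_phenotypes(ped, geno_all, cfg)
geno <- mask_genotypes(geno_all, cfg$genotyped_fraction, seed = cfg$seed)

cat(sprintf("simulated %d animals over %d generations; %d genotyped at %d SNPs\n",
            nrow(ped), cfg$n_generations, length(geno$ids), nrow(geno$map)))
cat(sprintf("realized h2 = %.3f (target %.2f), %d QTLs carrying %.0f%% of sigma_a2\n",
            sim$truth$realized_h2, cfg$heritability, cfg$n_qtl,
            100 * cfg$qtl_variance_fraction))

write_pedigree_csv(ped, file.path(out, "pedigree.csv"))
write.csv(sim$phenotypes, file.path(out, "phenotypes.csv"), row.names = FALSE)
write_plink(geno, file.path(out, "genotypes"), format = "bed", ped = ped)

# synthetic annotation: one interval per QTL plus decoys (clearly labelled
# synthetic -- there is no real genome here)
qtl <- sim$truth$qtl_positions
map <- geno_all$map
set.seed(cfg$seed)
decoy <- sample(setdiff(seq_len(nrow(map)), qtl), 30)
genes <- data.frame(chr = map$chr[c(qtl, decoy)],
                    start0 = pmax(0L, map$pos[c(qtl, decoy)] - 25000L),
                    end = map$pos[c(qtl, decoy)] + 25000L,
                    name = c(sprintf("SYNQTL%02d", seq_along(qtl)),
                             sprintf("SYNGENE%02d", seq_along(decoy))))
genes <- genes[order(genes$chr, genes$start0), ]
writeLines(sprintf("%s\t%d\t%d\t%s", genes$chr, genes$start0, genes$end,
                   genes$name), file.path(out, "synthetic_genes.bed"))

truth <- data.frame(id = names(sim$truth$true_breeding_values),
                    tbv = as.numeric(sim$truth$true_breeding_values))
write.table(truth, file.path(out, "truth_tbv.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(snp = map$snp[qtl], chr = map$chr[qtl],
                       pos = map$pos[qtl], effect = sim$truth$qtl_effects),
            file.path(out, "truth_qtl.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote inputs under", out, "\n")
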