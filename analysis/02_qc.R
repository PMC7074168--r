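#!/usr/bin/env Rscript
# Stage 2: genotype quality control.
#
# Reads the PLINK fileset written by 01_simulate.R and applies the standard
# marker filters (individual call rate >= 95%, SNP call rate >= 95%,
# MAF >= 0.05, exact HWE p >= 1e-6, autosomal mapped SNPs only), then
# writes the filtered fileset and the per-filter removal counts.

library(wintergwas)

dat <- file.path("results", "data")
geno_raw <- read_plink(file.path(dat, "genotypes"))
res <- apply_genotype_qc(geno_raw)
print(res$report)

write_plink(res$genotypes, file.path(dat, "genotypes_qc"), format = "bed")
rep <- res$report
write.table(data.frame(
  metric = c("individuals_in", "individuals_removed", "snps_in",
             "snps_removed_call_rate", "snps_removed_maf",
             "snps_removed_hwe", "snps_removed_nonautosomal", "snps_out"),
  value = c(rep$n_individuals_in, rep$n_individuals_removed, rep$n_snps_in,
            rep$n_snps_removed_call_rate, rep$n_snps_removed_maf,
            rep$n_snps_removed_hwe, rep$n_snps_removed_nonautosomal,
            rep$n_snps_out)),
  file.path("results", "qc_report.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("filtered genotypes written; report in results/qc_report.tsv\n")
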