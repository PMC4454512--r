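#!/usr/bin/env Rscript
# Stage 2: per-cohort SNP QC, merge, re-QC.
#
# Each cohort is filtered on imputation info (> 0.6), missing rate
# (<= 3%), MAF (>= 1%) and the exact Hardy-Weinberg test (p >= 1e-6);
# the cohorts are then merged on the SNP intersection (allele orientation
# reconciled, strand-ambiguous SNPs dropped) and the merged data are
# quality-controlled again with the same thresholds, so pooled
# missingness/MAF/HWE are re-checked.

library(gremlite)

th <- qc_thresholds() # the study defaults

uk <- read_plink("results/cohorts/uk",
                 info_file = "results/cohorts/uk.info.txt")
nl <- read_plink("results/cohorts/nl",
                 info_file = "results/cohorts/nl.info.txt")
uk$fam$cohort <- "UK"
nl$fam$cohort <- "NL"

qc_uk <- qc_filter(uk, th)
qc_nl <- qc_filter(nl, th)
cat("-- UK cohort --\n"); print(qc_uk$report)
cat("-- NL cohort --\n"); print(qc_nl$report)

merged <- merge_cohorts(qc_uk$genotypes, qc_nl$genotypes, th)
cat("-- merged (re-QC) --\n"); print(merged$report)
cat(sprintf("merge bookkeeping: %d intersecting, %d flipped, %d ambiguous dropped\n",
            attr(merged$report, "n_intersection"),
            attr(merged$report, "n_flipped"),
            attr(merged$report, "n_ambiguous_dropped")))

write_plink(merged$genotypes, "results/merged")
utils::write.table(
  data.frame(SNP = merged$genotypes$snps$id,
             INFO = merged$genotypes$snps$info),
  "results/merged.info.txt", sep = "\t", quote = FALSE, row.names = FALSE)
write.table(
  data.frame(iid = merged$genotypes$fam$iid,
             cohort = merged$genotypes$fam$cohort),
  "results/merged.cohort.txt", sep = "\t", quote = FALSE, row.names = FALSE)
write_qc_report(qc_uk$report, "results/qc_uk.tsv")
write_qc_report(qc_nl$report, "results/qc_nl.tsv")
write_qc_report(merged$report, "results/qc_merged.tsv")
cat("merged panel:", nrow(merged$genotypes$X), "women x",
    ncol(merged$genotypes$X), "SNPs\n")
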