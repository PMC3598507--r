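#!/usr/bin/env Rscript
# Stage 3: three-way gene-set comparison.
#
# Partitions genes into the mutually exclusive sets ADT (approved drug
# targets), ESS (essential non-targets) and ALL (background), then tests
# each pairwise rate difference with a two-sided Mann-Whitney U test and
# adjusts the p-values with the Benjamini-Yekutieli FDR across the family
# (both statistics' tests jointly here, mirroring the joint-family design
# of a multi-species run). Set means carry 95% bootstrap CIs.

suppressMessages(library(evorate))

estimates <- read.delim("results/estimates.tsv", stringsAsFactors = FALSE)
genes <- read_gene_table("results/study/genes.tsv")
partition <- partition_genes(genes)

set.seed(20240903L)
comparisons <- NULL
for (kind in c("polymorphism", "divergence")) {
  est <- estimates[estimates$stat_kind == kind, ]
  if (kind == "divergence") est <- est[!est$recombination_flagged, ]
  cmp <- compare_groups(est, partition, species = "sim", boot_R = 2000L)
  cmp$stat_kind <- kind
  comparisons <- rbind(comparisons, cmp)
}
comparisons <- adjust_comparisons(comparisons)

write.table(comparisons, "results/comparisons.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Set comparisons written to results/comparisons.tsv\n")
for (i in seq_len(nrow(comparisons))) {
  r <- comparisons[i, ]
  cat(sprintf("  [%s] %s (mean %.3f) vs %s (mean %.3f): U = %.0f, BY-adjusted p = %.3g\n",
              substr(r$stat_kind, 1, 4), r$group_a, r$mean_a, r$group_b,
              r$mean_b, r$u_statistic, r$p_adjusted))
}
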