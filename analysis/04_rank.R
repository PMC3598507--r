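#!/usr/bin/env Rscript
# Stage 4: genome-wide ranking and orthology-group summary.
#
# Ranks all usable genes by pN/pS (rank 1 = slowest = strongest purifying
# selection; percentiles use mid-ranks) and summarizes the drug-target KO
# orthology groups by mean +/- SD of the ratio across contributing
# genomes, slowest groups first — the evolutionary attractiveness ranking
# of the known target families.

suppressMessages(library(evorate))

estimates <- read.delim("results/estimates.tsv", stringsAsFactors = FALSE)
poly <- estimates[estimates$stat_kind == "polymorphism" & estimates$usable, ]

ranking <- percentile_rank(poly)
write.table(ranking, "results/ranking.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

ko <- read.delim("results/study/ko.tsv", stringsAsFactors = FALSE)
ko_summary <- summarize_ko_groups(ko, poly)
write.table(ko_summary, "results/ko_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

genes <- read_gene_table("results/study/genes.tsv")
adt <- genes$gene_id[genes$drug_target]
cat("Ranking written to results/ranking.tsv,",
    "KO summary to results/ko_summary.tsv\n")
cat(sprintf("  %d genes ranked; drug targets sit at median percentile %.1f\n",
            nrow(ranking),
            median(ranking$percentile[ranking$gene_id %in% adt])))
cat(sprintf("  slowest KO group: %s (mean %.4f, SD %.4f)\n",
            ko_summary$ko_id[1], ko_summary$mean[1], ko_summary$sd[1]))
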