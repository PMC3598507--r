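#!/usr/bin/env Rscript
# Stage 1: generate the ground-truthed study.
#
# One simulated bacterial species: per-gene clusters of closely related
# strain sequences evolved from a shared ancestor under class-specific
# purifying selection (true omega: drug targets 0.1 < essential 0.3 <
# background 0.6), plus the gene membership table, KO assignments for the
# target class, a toy GO ontology and annotations. Everything downstream
# reads the files written here, exactly as it would read real inputs.

suppressMessages(library(evorate))

out_dir <- "results/study"
cfg <- simulation_config(seed = 20240901L)
sim <- simulate_study(cfg, out_dir = out_dir)

cat("Simulated study written to", out_dir, "\n")
cat(sprintf("  genes: %d (ADT %d, ESS %d, background %d)\n",
            nrow(sim$gene_table), sum(sim$gene_table$drug_target),
            sum(sim$gene_table$essential & !sim$gene_table$drug_target),
            sum(!sim$gene_table$essential)))
cat(sprintf("  %d-codon genes, %d strains per cluster, %.2g proposed subs/codon\n",
            cfg$gene_length_codons, cfg$rows_per_cluster,
            cfg$expected_subs_per_codon))
cat(sprintf("  genes with >= 1 GO annotation: %d (%.0f%%)\n",
            length(sim$annotations),
            100 * length(sim$annotations) / nrow(sim$gene_table)))
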