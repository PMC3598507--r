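#!/usr/bin/env Rscript
# Stage 5: GO over-representation of the slowest-evolving genes.
#
# Selects the slowest decile of the pN/pS ranking as the study set, closes
# the GAF annotations upward through the ontology (true-path rule over
# is_a / part_of), and tests each term's over-representation against the
# full ranked population with a one-sided hypergeometric tail
# (term-for-term analysis). Raw p is the headline column; a BH column is
# emitted alongside.

suppressMessages(library(evorate))

ranking <- read.delim("results/ranking.tsv", stringsAsFactors = FALSE)
dag <- read_obo("results/study/go.obo")
gaf <- read_gaf("results/study/annotations.gaf", dag)

propagated <- propagate_annotations(gaf$annotations, dag)
study <- select_slowest(ranking, 0.10)
enrichment <- term_for_term(study, ranking$gene_id, propagated, dag = dag)

write.table(enrichment, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Enrichment written to results/enrichment.tsv\n")
cat(sprintf("  study set: %d genes (slowest decile of %d)\n",
            length(study), nrow(ranking)))
top <- enrichment[1:min(3, nrow(enrichment)), ]
for (i in seq_len(nrow(top))) {
  cat(sprintf("  %s  p = %.3g  study %d/%d vs population %d/%d  (%s)\n",
              top$term_id[i], top$p_value[i], top$study_count[i],
              top$study_n[i], top$pop_count[i], top$pop_n[i],
              top$description[i]))
}
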