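# Fixture builders shared across test files.

make_aln <- function(rows, genomes = paste0("G", seq_along(rows)),
                     gene = "g1", ref = 1L) {
  codon_alignment(gene, genomes, rows, ref)
}

write_fasta <- function(headers, seqs, path = tempfile(fileext = ".fasta")) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# a random gap/stop-free codon alignment with a few substitutions
random_pair_aln <- function(n_codons = 50, n_sub = 5) {
  anc <- random_cds(n_codons)
  ev <- evolve(anc, 1, n_sub / n_codons)
  make_aln(c(anc, ev$seq))
}
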