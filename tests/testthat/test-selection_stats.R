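test_that("codon translation follows the standard code and rejects bad input", {
  expect_equal(translate_codon("ATG"), "M")
  expect_equal(translate_codon("TAA"), "*")
  expect_equal(translate_codon("TTT"), "F")
  expect_error(translate_codon("ATN"), "illegal")
  expect_error(translate_codon("AT"), "3-letter")
})

test_that("substitution classification handles single and multi-hit codons", {
  expect_equal(classify_substitution("TTT", "TTC"),
               list(n_frac = 0, s_frac = 1))
  expect_equal(classify_substitution("ATG", "ATA"),
               list(n_frac = 1, s_frac = 0))
  # two minimal pathways, TTT->GTT(N)->GTA(S) and TTT->TTA(N)->GTA(N)
  expect_equal(classify_substitution("TTT", "GTA"),
               list(n_frac = 1.5, s_frac = 0.5))
  expect_equal(classify_substitution("AAA", "AAA"),
               list(n_frac = 0, s_frac = 0))
  expect_error(classify_substitution("TAA", "TTA"), "stop")
})

test_that("classification agrees with the pathway-enumeration oracle on random pairs", {
  set.seed(4)
  sense <- all_sense_codons()
  for (i in 1:120) {
    pair <- sample(sense, 2L)
    got <- classify_substitution(pair[1L], pair[2L])
    want <- oracle_classify(pair[1L], pair[2L])
    expect_equal(got$n_frac, unname(want["n"]), info = paste(pair, collapse = "-"))
    expect_equal(got$s_frac, unname(want["s"]), info = paste(pair, collapse = "-"))
    # counts sum to the Hamming distance (or distance over used pathways)
    expect_equal(got$n_frac + got$s_frac,
                 sum(strsplit(pair[1L], "")[[1]] != strsplit(pair[2L], "")[[1]]))
  }
})

test_that("pS->1 correction fires exactly when the synonymous count is zero", {
  expect_equal(pnps(3, 0), list(ratio = 3, s_corrected = TRUE))
  expect_equal(pnps(0, 5), list(ratio = 0, s_corrected = FALSE))
  expect_equal(pnps(2, 4), list(ratio = 0.5, s_corrected = FALSE))
  expect_error(pnps(-1, 2), "non-negative")
})

test_that("polymorphism counting: pairs, majority rule, and column filtering", {
  # no polymorphism -> unusable
  est <- count_gene_polymorphisms(make_aln(c("ATGAAA", "ATGAAA")))
  expect_equal(est$n_count + est$s_count, 0)
  expect_false(est$usable)

  # single synonymous SNP
  est <- count_gene_polymorphisms(make_aln(c("ATGTTT", "ATGTTC")))
  expect_equal(est$s_count, 1)
  expect_equal(est$n_count, 0)
  expect_equal(est$ratio, 0)

  # majority-base allele counting on a 3-row column
  est <- count_gene_polymorphisms(make_aln(c("TTT", "TTT", "TTA")))
  expect_equal(est$n_count, 1)
  expect_equal(est$s_count, 0)

  # columns with gaps, N, or stops are wholly excluded
  est <- count_gene_polymorphisms(make_aln(c("ATG---TTTTAA", "ATGAAATTCNAA")))
  expect_equal(est$n_codons_used, 2L)  # ATG and TTT/TTC survive
  expect_equal(est$s_count, 1)

  expect_error(count_gene_polymorphisms(
    structure(list(rows = "ATG"), class = "codon_alignment")), "2 rows")
})

test_that("duplicating a row never changes polymorphism counts (allele counting)", {
  set.seed(7)
  for (i in 1:25) {
    n_rows <- sample(2:5, 1)
    anc <- random_cds(30)
    rows <- vapply(seq_len(n_rows),
                   function(r) evolve(anc, 1, 0.1)$seq, "")
    aln <- make_aln(rows)
    base <- count_gene_polymorphisms(aln)
    dup_row <- sample(n_rows, 1)
    aln2 <- make_aln(c(rows, rows[dup_row]),
                     genomes = paste0("G", seq_len(n_rows + 1L)))
    dup <- count_gene_polymorphisms(aln2)
    expect_equal(dup$n_count, base$n_count)
    expect_equal(dup$s_count, base$s_count)
    expect_equal(dup$ratio, base$ratio)
  }
})

test_that("NG86 site counts match single-base mutant enumeration", {
  # TTT: only T->C at position 3 is synonymous among the 9 changes
  pair <- make_aln(c("TTT", "TTT"))
  est <- dnds_ng86(pair)
  expect_equal(attr(est, "S_sites"), 1 / 3)
  expect_equal(attr(est, "N_sites"), 8 / 3)

  set.seed(11)
  for (i in 1:10) {
    aln <- random_pair_aln(20, 2)
    est <- dnds_ng86(aln)
    o1 <- oracle_opportunity_ratio(aln$rows[1])
    o2 <- oracle_opportunity_ratio(aln$rows[2])
    expect_equal(attr(est, "N_sites"), mean(c(o1$n, o2$n)) / 3)
    expect_equal(attr(est, "S_sites"), mean(c(o1$s, o2$s)) / 3)
    # N + S == 3 * codons minus the weight of stop-creating changes
    expect_lte(attr(est, "N_sites") + attr(est, "S_sites"),
               3 * est$n_codons_used + 1e-9)
  }
})

test_that("dN/dS behaves at the boundaries and is monotone in nonsynonymous load", {
  est <- dnds_ng86(make_aln(c("ATGAAA", "ATGAAA")))
  expect_false(est$usable)
  expect_equal(est$ratio, 0)

  # only synonymous differences -> ratio 0
  est <- dnds_ng86(make_aln(c(strrep("CTT", 30), paste0(strrep("CTT", 28), "CTCCTC"))))
  expect_equal(attr(est, "Nd"), 0)
  expect_equal(est$ratio, 0)

  # only nonsynonymous differences -> pS->1-style fallback flag
  est <- dnds_ng86(make_aln(c(strrep("CTT", 30), paste0(strrep("CTT", 28), "ATTATT"))))
  expect_equal(attr(est, "Sd"), 0)
  expect_true(est$s_corrected)

  # at fixed total differences the ratio rises with the nonsynonymous share
  base <- strrep("CTT", 60)
  mk <- function(n_non, n_syn) {
    codons <- rep("CTT", 60)
    if (n_non > 0) codons[seq_len(n_non)] <- "ATT"          # Leu -> Ile
    if (n_syn > 0) codons[60 - seq_len(n_syn) + 1] <- "CTC" # Leu -> Leu
    dnds_ng86(make_aln(c(base, paste(codons, collapse = ""))))$ratio
  }
  r <- c(mk(2, 8), mk(5, 5), mk(8, 2))
  expect_true(all(diff(r) > 0))
})

test_that("four-gamete screen detects recombinant patterns only", {
  expect_equal(four_gamete_screen(make_aln(c("ATGAAA", "ATGAAG"))),
               list(violating_pairs = 0L, flagged = FALSE))

  # canonical violation: haplotypes AB / Ab / aB / ab at two sites
  rows <- c("AAATTT", "AAATTC", "AACTTT", "AACTTC")
  scr <- four_gamete_screen(make_aln(rows))
  expect_true(scr$flagged)
  expect_equal(scr$violating_pairs, 1L)

  # mutations accumulated along a single lineage are tree-compatible
  anc <- random_cds(40)
  lineage <- anc
  rows <- character(6)
  set.seed(3)
  for (i in 1:6) {
    lineage <- evolve(lineage, 1, 0.02)$seq
    rows[i] <- lineage
  }
  scr <- four_gamete_screen(make_aln(rows))
  expect_false(scr$flagged)
})
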