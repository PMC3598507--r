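test_that("random coding sequences start with ATG and avoid internal stops", {
  expect_equal(random_cds(1), "ATG")
  set.seed(16)
  for (i in 1:10) {
    s <- random_cds(40)
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    expect_false(any(vapply(codons, translate_codon, "") == "*"))
    expect_equal(codons[1], "ATG")
  }
  expect_identical(random_cds(30, seed = 99), random_cds(30, seed = 99))
})

test_that("the evolver respects omega and is deterministic under a seed", {
  anc <- random_cds(80, seed = 17)
  ev0 <- evolve(anc, 0, 2, seed = 1)
  expect_equal(ev0$n_accepted, 0L)

  ev_none <- evolve(anc, 1, 0, seed = 1)
  expect_identical(ev_none$seq, anc)
  expect_equal(ev_none$proposals, 0L)

  expect_identical(evolve(anc, 0.5, 0.3, seed = 5),
                   evolve(anc, 0.5, 0.3, seed = 5))

  # derived sequences never contain internal stops
  ev <- evolve(anc, 1, 1, seed = 6)
  codons <- substring(ev$seq, seq(1, nchar(ev$seq), 3),
                      seq(3, nchar(ev$seq), 3))
  expect_false(any(vapply(codons, translate_codon, "") == "*"))
})

test_that("truth-table tallies reconcile with re-classified ancestor/derived diffs", {
  # single-hit regime: with <= 0.05 proposals per codon nearly every codon
  # takes at most one hit, where pathway classification is exact
  cfg <- simulation_config(n_background = 25, n_essential = 10,
                           n_targets = 5, gene_length_codons = 60L,
                           expected_subs_per_codon = 0.03, seed = 18L)
  sim <- simulate_study(cfg)
  checked <- 0L
  for (g in sim$truth$gene_id) {
    aln <- sim$alignments[[g]]
    anc <- sim$ancestors[[g]]
    tot_n <- 0
    tot_s <- 0
    hamming <- 0L
    multi_hit <- FALSE
    for (row in aln$rows) {
      av <- strsplit(anc, "")[[1]]
      rv <- strsplit(row, "")[[1]]
      hamming <- hamming + sum(av != rv)
      starts <- seq(1, nchar(anc), 3)
      for (cs in starts) {
        ca <- substr(anc, cs, cs + 2)
        cr <- substr(row, cs, cs + 2)
        if (ca == cr) next
        if (sum(strsplit(ca, "")[[1]] != strsplit(cr, "")[[1]]) > 1) {
          multi_hit <- TRUE
          next
        }
        cl <- classify_substitution(ca, cr)
        tot_n <- tot_n + cl$n_frac
        tot_s <- tot_s + cl$s_frac
      }
    }
    tr <- sim$truth[sim$truth$gene_id == g, ]
    accepted <- tr$n_accepted + tr$s_accepted
    if (!multi_hit && hamming == accepted) {
      expect_equal(tot_n, tr$n_accepted)
      expect_equal(tot_s, tr$s_accepted)
      checked <- checked + 1L
    }
  }
  # the single-hit regime must cover the vast majority of genes
  expect_gt(checked / nrow(sim$truth), 0.8)
})

test_that("counted pN/pS per class is monotone in the configured omega", {
  set.seed(19)
  mean_ratio <- vapply(c(0.1, 0.3, 0.6, 1.0), function(om) {
    ratios <- replicate(50, {
      anc <- random_cds(100)
      pair <- codon_alignment("g", c("G1", "G2"),
                              c(evolve(anc, om, 0.2)$seq,
                                evolve(anc, om, 0.2)$seq))
      count_gene_polymorphisms(pair)$ratio
    })
    mean(ratios)
  }, numeric(1))
  expect_true(all(diff(mean_ratio) > 0))
})

test_that("simulated studies are deterministic, correctly shaped, and re-parse", {
  cfg <- simulation_config(n_background = 15, n_essential = 8, n_targets = 0,
                           gene_length_codons = 30L, seed = 20L)
  sim <- simulate_study(cfg)
  expect_equal(sum(sim$gene_table$drug_target), 0L)
  expect_equal(nrow(sim$gene_table), 23L)

  sim2 <- simulate_study(cfg)
  expect_identical(sim$truth, sim2$truth)
  expect_identical(sim$alignments[[1]]$rows, sim2$alignments[[1]]$rows)
  expect_identical(sim$annotations, sim2$annotations)

  # emitted files re-parse through the readers (round-trip contract)
  dir <- tempfile("sim")
  cfg3 <- simulation_config(n_background = 6, n_essential = 4, n_targets = 3,
                            gene_length_codons = 20L, seed = 21L)
  sim3 <- simulate_study(cfg3, out_dir = dir)
  files <- list.files(file.path(dir, "alignments"), full.names = TRUE)
  expect_length(files, 13L)
  for (f in files) {
    aln <- read_codon_alignment(f, "G1")
    expect_identical(aln$rows, sim3$alignments[[aln$gene_id]]$rows)
  }
  tab <- read_gene_table(file.path(dir, "genes.tsv"))
  expect_equal(tab, sim3$gene_table, ignore_attr = TRUE)
  dag <- read_obo(file.path(dir, "go.obo"))
  expect_setequal(names(dag$terms), names(sim3$dag$terms))
  gaf <- read_gaf(file.path(dir, "annotations.gaf"), dag)
  expect_equal(gaf$n_skipped, 0L)
  expect_setequal(names(gaf$annotations), names(sim3$annotations))
})
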