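test_that("percentile ranking uses mid-ranks and is permutation invariant", {
  set.seed(13)
  est <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    ratio = sample(seq(0.01, 1, length.out = 100)),
                    stringsAsFactors = FALSE)
  rk <- percentile_rank(est)
  expect_equal(sort(rk$rank), 1:100)
  # the 32nd smallest unique ratio sits at the 32nd percentile
  expect_equal(rk$percentile[rk$rank == 32], 32)

  # all tied, n = 4 -> shared mid-rank percentile 62.5
  rk4 <- percentile_rank(data.frame(gene_id = letters[1:4], ratio = 0.2))
  expect_equal(rk4$percentile, rep(62.5, 4))

  # smallest of two
  rk2 <- percentile_rank(data.frame(gene_id = c("a", "b"), ratio = c(1, 2)))
  expect_equal(rk2$percentile, c(50, 100))

  # permutation invariance
  perm <- est[sample(nrow(est)), ]
  rk_perm <- percentile_rank(perm)
  expect_equal(rk_perm, rk)

  # appending the fastest gene preserves existing order
  est2 <- rbind(est, data.frame(gene_id = "zzz", ratio = 99))
  rk_plus <- percentile_rank(est2)
  expect_equal(rk_plus$gene_id[1:100], rk$gene_id)

  expect_error(percentile_rank(est[0, ]), "no usable")
})

test_that("KO group summaries average per genome with the single-contributor SD-0 convention", {
  assign <- data.frame(gene_id = c("g1", "g2", "g3"),
                       ko_id = c("ko:K1", "ko:K1", "ko:K2"),
                       gene_name = c("a", "a", "pbp1B"),
                       stringsAsFactors = FALSE)
  est <- data.frame(gene_id = c("g1", "g2", "g3"),
                    genome_id = c("E1", "E2", "E1"),
                    ratio = c(0.2, 0.3, 0.4693),
                    usable = TRUE, stringsAsFactors = FALSE)
  ko <- summarize_ko_groups(assign, est)
  k1 <- ko[ko$ko_id == "ko:K1", ]
  expect_equal(k1$mean, 0.25)
  expect_equal(k1$sd, sd(c(0.2, 0.3)))
  # single contributing genome -> SD 0
  k2 <- ko[ko$ko_id == "ko:K2", ]
  expect_equal(k2$mean, 0.4693)
  expect_equal(k2$sd, 0)
  # ascending by mean: slowest first
  expect_equal(ko$ko_id, c("ko:K1", "ko:K2"))

  # mean equals brute-force arithmetic mean on a random fixture
  set.seed(14)
  n <- 40
  assign <- data.frame(gene_id = sprintf("g%02d", 1:n),
                       ko_id = sample(paste0("ko:K", 1:6), n, replace = TRUE))
  est <- data.frame(gene_id = assign$gene_id,
                    genome_id = sample(paste0("G", 1:4), n, replace = TRUE),
                    ratio = runif(n), usable = runif(n) > 0.2)
  ko <- summarize_ko_groups(assign, est)
  for (i in seq_len(nrow(ko))) {
    d <- merge(assign[assign$ko_id == ko$ko_id[i], ], est[est$usable, ],
               by = "gene_id")
    expect_equal(ko$mean[i], mean(tapply(d$ratio, d$genome_id, mean)))
  }
  expect_false(is.unsorted(ko$mean))
})

test_that("slowest-decile selection floors the count and keeps only slow genes", {
  est <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    ratio = seq(0.01, 1, length.out = 100))
  rk <- percentile_rank(est)
  slow <- select_slowest(rk, 0.10)
  expect_length(slow, 10L)
  expect_true(all(est$ratio[est$gene_id %in% slow] <=
                  min(est$ratio[!est$gene_id %in% slow])))
  expect_length(select_slowest(rk, 1.0), 100L)
  expect_length(select_slowest(percentile_rank(est[1:25, ]), 0.10), 2L)
  expect_error(select_slowest(rk, 0), "fraction")
  expect_error(select_slowest(rk, 1.5), "fraction")
})
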