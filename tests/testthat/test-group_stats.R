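test_that("gene-set partition is mutually exclusive with ADT precedence", {
  tab <- data.frame(
    gene_id = c("g1", "g2", "g3", "g4"), genome_id = "G1",
    essential = c(TRUE, TRUE, FALSE, FALSE),
    drug_target = c(TRUE, FALSE, FALSE, TRUE),
    ko_id = NA_character_, stringsAsFactors = FALSE)
  part <- partition_genes(tab)
  expect_equal(as.character(part$set), c("ADT", "ESS", "ALL", "ADT"))
  expect_equal(sum(attr(part, "counts")), nrow(tab))
  expect_error(partition_genes(rbind(tab, tab[1, ])), "duplicate")
})

test_that("Mann-Whitney wrapper reproduces exact and symmetric behavior", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$u, 0)
  expect_equal(res$p, 0.1)

  # same multiset -> exact symmetry gives p = 1
  expect_equal(mann_whitney_u(c(1, 2, 3), c(3, 1, 2))$p, 1)

  # two-sided symmetry under argument swap
  set.seed(8)
  for (i in 1:10) {
    x <- rnorm(sample(3:9, 1))
    y <- rnorm(sample(3:9, 1))
    expect_equal(mann_whitney_u(x, y)$p, mann_whitney_u(y, x)$p)
    expect_gte(mann_whitney_u(x, y)$u, 0)
    expect_lte(mann_whitney_u(x, y)$u, length(x) * length(y))
  }
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("exact p-values match full permutation enumeration on small samples", {
  set.seed(9)
  for (i in 1:20) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    v <- sample(seq_len(40), nx + ny)  # unique -> no ties
    x <- v[seq_len(nx)]
    y <- v[-seq_len(nx)]
    expect_equal(mann_whitney_u(x, y)$p, oracle_mw(x, y))
  }
})

test_that("BY adjustment matches the closed form and dominates raw p", {
  expect_equal(benjamini_yekutieli(c(0.01, 0.02, 0.03)),
               c(0.055, 0.055, 0.055))
  expect_equal(benjamini_yekutieli(1), 1)
  expect_error(benjamini_yekutieli(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(10)
  for (i in 1:25) {
    p <- runif(sample(1:30, 1))
    adj <- benjamini_yekutieli(p)
    expect_equal(adj, oracle_by(p))
    expect_true(all(adj >= p))
    expect_true(all(adj <= 1))
  }
})

test_that("group comparison reports exact tails, means, CIs and skips tiny sets", {
  # ADT ratios all below every ALL ratio -> exact two-sided tail at U = 0
  est <- data.frame(
    gene_id = sprintf("g%02d", 1:25),
    ratio = c(seq(0.01, 0.05, length.out = 5), seq(0.5, 2, length.out = 20)),
    usable = TRUE, stringsAsFactors = FALSE)
  part <- data.frame(gene_id = est$gene_id,
                     set = factor(rep(c("ADT", "ALL"), c(5, 20)),
                                  levels = c("ADT", "ESS", "ALL")))
  set.seed(1)
  cmp <- suppressMessages(compare_groups(est, part, boot_R = 200))
  row <- cmp[cmp$group_a == "ADT" & cmp$group_b == "ALL", ]
  expect_equal(row$u_statistic, 0)
  expect_equal(row$p_raw, 2 / choose(25, 5))  # enumeration tail, doubled
  expect_equal(row$mean_a, mean(est$ratio[1:5]))
  expect_true(row$ci_a_low <= row$mean_a && row$mean_a <= row$ci_a_high)

  # ESS has <2 usable genes: its comparisons are skipped with a message
  expect_message(compare_groups(est, part, boot_R = 50), "skipping")
  expect_equal(nrow(cmp), 1L)

  adj <- adjust_comparisons(rbind(cmp, cmp, cmp))
  expect_equal(nrow(adj), 3L)
  expect_true(all(adj$p_adjusted >= adj$p_raw))
})

test_that("the test is calibrated under a simulated null", {
  set.seed(12)
  p <- replicate(500, mann_whitney_u(rnorm(15), rnorm(15))$p)
  frac <- mean(p < 0.05)
  # binomial 99% bounds around 0.05 at 500 replicates
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / 500)
  expect_gte(frac, 0.05 - half)
  expect_lte(frac, 0.05 + half)
  expect_gt(median(p), 0.3)
  expect_lt(median(p), 0.7)
})
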