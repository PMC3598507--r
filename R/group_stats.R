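#' Partition genes into mutually exclusive ADT / ESS / ALL sets
#'
#' Approved drug targets (ADT) take precedence: a gene flagged as a drug
#' target is ADT regardless of essentiality. Essential non-targets are ESS.
#' Everything else is the background set ALL. The three sets are therefore
#' pairwise disjoint and cover the input — removing drug targets from the
#' essential set and both from the background avoids biasing the pairwise
#' tests.
#'
#' @param table gene table (one genome), as from [read_gene_table()].
#' @return data.frame `gene_id`, `set` (factor ADT/ESS/ALL), with per-set
#'   counts in attribute `counts`.
#' @export
partition_genes <- function(table) {
  if (anyDuplicated(table$gene_id)) {
    stop("duplicate gene_id in gene table", call. = FALSE)
  }
  set <- ifelse(table$drug_target, "ADT",
                ifelse(table$essential, "ESS", "ALL"))
  out <- data.frame(gene_id = table$gene_id,
                    set = factor(set, levels = c("ADT", "ESS", "ALL")),
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- table(out$set)
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Thin wrapper around [stats::wilcox.test()], the implementation the
#' original analysis used: the exact null distribution when both samples
#' have fewer than 50 observations and no ties are present, otherwise the
#' normal approximation with tie and continuity correction.
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `u` (the U statistic for `x` vs `y`, in
#'   `[0, n_x * n_y]`) and `p` (two-sided p-value).
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  w <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(u = unname(w$statistic), p = w$p.value)
}

#' Benjamini-Yekutieli FDR adjustment
#'
#' Step-up adjustment valid under arbitrary dependence:
#' `adj_(i) = min_(j >= i) min(1, m * c(m) * p_(j) / j)` with
#' `c(m) = sum_(k=1..m) 1/k`, mapped back to input order. Delegates to
#' [stats::p.adjust()].
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
#' @examples
#' benjamini_yekutieli(c(0.01, 0.02, 0.03))  # all 0.055
benjamini_yekutieli <- function(p_values) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_values, method = "BY")
}

#' Percentile bootstrap confidence interval for a mean
#' @param x numeric vector.
#' @param level confidence level.
#' @param R resamples.
#' @return c(low, high).
#' @export
boot_ci_mean <- function(x, level = 0.95, R = 2000L) {
  if (length(x) < 2L) return(c(NA_real_, NA_real_))
  means <- vapply(seq_len(R), function(i) {
    mean(x[sample.int(length(x), replace = TRUE)])
  }, numeric(1))
  a <- (1 - level) / 2
  unname(stats::quantile(means, c(a, 1 - a), names = FALSE))
}

#' Compare per-gene rate ratios between the three gene sets
#'
#' Runs the three pairwise two-sided Mann-Whitney tests (ADT vs ALL, ADT vs
#' ESS, ESS vs ALL) on usable estimates, with percentile-bootstrap 95%
#' confidence intervals for each set mean. `p_adjusted` is left `NA`; apply
#' [adjust_comparisons()] across the full family of tests (24 in the
#' original eight-species design, 3 in a single-species run) afterwards.
#' Comparisons where either set has fewer than 2 usable genes are skipped
#' with a message.
#'
#' @param estimates data.frame with `gene_id`, `ratio`, `usable` for one
#'   species.
#' @param partition result of [partition_genes()].
#' @param species species label carried into the output.
#' @param boot_R bootstrap resamples for the CIs.
#' @return data.frame, one row per performed comparison.
#' @export
compare_groups <- function(estimates, partition, species = "sim",
                           boot_R = 2000L) {
  usable <- estimates[estimates$usable, , drop = FALSE]
  lab <- partition$set[match(usable$gene_id, partition$gene_id)]
  vals <- split(usable$ratio, lab)
  pairs <- list(c("ADT", "ALL"), c("ADT", "ESS"), c("ESS", "ALL"))
  rows <- list()
  for (pr in pairs) {
    a <- vals[[pr[1L]]]
    b <- vals[[pr[2L]]]
    if (length(a) < 2L || length(b) < 2L) {
      message("skipping ", pr[1L], " vs ", pr[2L], " for ", species,
              ": fewer than 2 usable genes in a set")
      next
    }
    mw <- mann_whitney_u(a, b)
    ci_a <- boot_ci_mean(a, R = boot_R)
    ci_b <- boot_ci_mean(b, R = boot_R)
    rows[[length(rows) + 1L]] <- data.frame(
      species = species, group_a = pr[1L], group_b = pr[2L],
      n_a = length(a), n_b = length(b),
      u_statistic = mw$u, p_raw = mw$p, p_adjusted = NA_real_,
      mean_a = mean(a), ci_a_low = ci_a[1L], ci_a_high = ci_a[2L],
      mean_b = mean(b), ci_b_low = ci_b[1L], ci_b_high = ci_b[2L],
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Apply BY-FDR across a family of group comparisons
#'
#' @param comparisons one or several [compare_groups()] results bound
#'   together (the hypothesis family; across all species in a multi-species
#'   design).
#' @return the same data.frame with `p_adjusted` filled in.
#' @export
adjust_comparisons <- function(comparisons) {
  comparisons$p_adjusted <- benjamini_yekutieli(comparisons$p_raw)
  comparisons
}
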