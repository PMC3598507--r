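#' Rank genes genome-wide by evolutionary rate
#'
#' Ascending sort by ratio: slow evolution = low ratio = rank 1. Integer
#' ranks are a permutation of `1..n` (ties broken by gene_id for
#' reproducibility); percentiles use mid-ranks, `100 * midrank / n`, so
#' tied genes share a percentile.
#'
#' @param estimates data.frame with `gene_id` and `ratio` (usable genes
#'   only).
#' @return data.frame `gene_id`, `ratio`, `rank`, `percentile`, sorted by
#'   rank.
#' @export
percentile_rank <- function(estimates) {
  if (nrow(estimates) == 0L) stop("no usable estimates to rank",
                                  call. = FALSE)
  ord <- order(estimates$ratio, estimates$gene_id)
  out <- estimates[ord, c("gene_id", "ratio"), drop = FALSE]
  n <- nrow(out)
  out$rank <- seq_len(n)
  out$percentile <- 100 * rank(out$ratio, ties.method = "average") / n
  rownames(out) <- NULL
  out
}

#' Summarize orthology (KO) groups across genomes
#'
#' For each KO group: the mean and sample standard deviation of the
#' per-genome rate ratios of its member genes, computed over genomes that
#' contribute a usable ortholog only. A group represented in a single
#' genome gets SD 0 by convention. Output is sorted ascending by mean —
#' the slowest-evolving (most evolutionarily attractive) groups first.
#'
#' @param assignments data.frame `gene_id`, `ko_id` (and optional
#'   `gene_name` passed through).
#' @param estimates data.frame with `gene_id`, `genome_id`, `ratio`,
#'   `usable` across genomes/species.
#' @return data.frame `ko_id`, `gene_name`, `n_genomes`, `mean`, `sd`.
#' @export
summarize_ko_groups <- function(assignments, estimates) {
  usable <- estimates[estimates$usable, , drop = FALSE]
  merged <- merge(assignments, usable, by = "gene_id")
  if (nrow(merged) == 0L) {
    return(data.frame(ko_id = character(0), gene_name = character(0),
                      n_genomes = integer(0), mean = numeric(0),
                      sd = numeric(0), stringsAsFactors = FALSE))
  }
  has_name <- "gene_name" %in% names(merged)
  rows <- lapply(split(merged, merged$ko_id), function(d) {
    # one value per contributing genome
    per_genome <- tapply(d$ratio, d$genome_id, mean)
    data.frame(
      ko_id = d$ko_id[1L],
      gene_name = if (has_name) d$gene_name[1L] else NA_character_,
      n_genomes = length(per_genome),
      mean = mean(per_genome),
      sd = if (length(per_genome) > 1L) stats::sd(per_genome) else 0,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean, out$ko_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the slowest-evolving fraction of genes as a study set
#'
#' Takes the `floor(fraction * n)` genes with the smallest ratios (ties at
#' the boundary broken by gene_id, deterministically).
#'
#' @param ranked result of [percentile_rank()].
#' @param fraction fraction of genes to keep, in `(0, 1]`; default 0.10,
#'   the slowest decile.
#' @return character vector of gene_ids.
#' @export
select_slowest <- function(ranked, fraction = 0.10) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]", call. = FALSE)
  }
  k <- floor(fraction * nrow(ranked))
  ord <- order(ranked$ratio, ranked$gene_id)
  ranked$gene_id[ord][seq_len(k)]
}
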