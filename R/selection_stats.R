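#' Translate a codon under the standard genetic code
#'
#' The standard code is used throughout; for the 61 sense codons it is
#' identical to the bacterial translation table 11.
#'
#' @param codon three-letter DNA string over `{A,C,G,T}`.
#' @return a one-letter amino-acid code, or `"*"` for a stop codon.
#' @export
#' @examples
#' translate_codon("ATG")  # "M"
#' translate_codon("TAA")  # "*"
translate_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L) {
    stop("codon must be a single 3-letter string", call. = FALSE)
  }
  b <- dna_to_int(codon)
  if (anyNA(b)) {
    stop("illegal or ambiguous base in codon '", codon, "'", call. = FALSE)
  }
  aa_by_index()[codon_index(b[1], b[2], b[3])]
}

#' Classify the mutational path between two sense codons
#'
#' Counts how many of the single-base steps separating two codons are
#' nonsynonymous vs synonymous. For codons differing at one position the
#' single change is classified by amino-acid identity. For two or three
#' differences, all minimal mutational pathways (orderings of the differing
#' positions) are enumerated; pathways passing through a stop codon at an
#' intermediate step are discarded and counts are averaged over the
#' remainder. If every pathway transits a stop, all pathways are used
#' (steps into or out of a stop count as nonsynonymous). This is the
#' pathway-averaging convention of Nei and Gojobori (1986).
#'
#' @param codon_a,codon_b sense codons (3-letter DNA strings, no stops).
#' @return list with `n_frac` and `s_frac`, the (possibly fractional)
#'   nonsynonymous and synonymous mutation counts; they sum to the Hamming
#'   distance between the codons.
#' @export
#' @examples
#' classify_substitution("TTT", "TTC")  # n = 0, s = 1
#' classify_substitution("TTT", "GTA")  # n = 1.5, s = 0.5
classify_substitution <- function(codon_a, codon_b) {
  aa <- aa_by_index()
  ba <- dna_to_int(codon_a)
  bb <- dna_to_int(codon_b)
  if (length(ba) != 3L || length(bb) != 3L || anyNA(ba) || anyNA(bb)) {
    stop("codons must be 3-letter strings over A/C/G/T", call. = FALSE)
  }
  ia <- codon_index(ba[1], ba[2], ba[3])
  ib <- codon_index(bb[1], bb[2], bb[3])
  if (aa[ia] == "*" || aa[ib] == "*") {
    stop("stop codons are not classified", call. = FALSE)
  }
  diffs <- which(ba != bb)
  k <- length(diffs)
  if (k == 0L) {
    return(list(n_frac = 0, s_frac = 0))
  }
  orders <- perms(diffs)
  n_tot <- numeric(nrow(orders))
  s_tot <- numeric(nrow(orders))
  via_stop <- logical(nrow(orders))
  for (p in seq_len(nrow(orders))) {
    cur <- ba
    for (step in seq_len(k)) {
      pos <- orders[p, step]
      nxt <- cur
      nxt[pos] <- bb[pos]
      aa_cur <- aa[codon_index(cur[1], cur[2], cur[3])]
      aa_nxt <- aa[codon_index(nxt[1], nxt[2], nxt[3])]
      if (step < k && aa_nxt == "*") via_stop[p] <- TRUE
      if (aa_cur == aa_nxt) {
        s_tot[p] <- s_tot[p] + 1
      } else {
        n_tot[p] <- n_tot[p] + 1
      }
      cur <- nxt
    }
  }
  keep <- if (all(via_stop)) rep(TRUE, length(via_stop)) else !via_stop
  list(n_frac = mean(n_tot[keep]), s_frac = mean(s_tot[keep]))
}

# all permutations of a small vector, one per row
perms <- function(v) {
  k <- length(v)
  if (k == 1L) return(matrix(v, 1L))
  out <- NULL
  for (i in seq_len(k)) {
    sub <- perms(v[-i])
    out <- rbind(out, cbind(v[i], sub))
  }
  out
}

#' Form a pN/pS (or dN/dS-style) ratio with the pS -> 1 correction
#'
#' Genes of closely related strains frequently show only nonsynonymous
#' polymorphisms; with a zero synonymous count the ratio is undefined. The
#' correction replaces a zero denominator by 1 and flags the estimate.
#'
#' @param n_count,s_count nonsynonymous and synonymous mutation counts
#'   (non-negative reals).
#' @return list with `ratio` and logical `s_corrected` (TRUE iff
#'   `s_count == 0`).
#' @export
#' @examples
#' pnps(3, 0)  # ratio 3, corrected
#' pnps(2, 4)  # ratio 0.5
pnps <- function(n_count, s_count) {
  if (!is.numeric(n_count) || !is.numeric(s_count) ||
      n_count < 0 || s_count < 0) {
    stop("counts must be non-negative numbers", call. = FALSE)
  }
  if (s_count == 0) {
    list(ratio = n_count / 1, s_corrected = TRUE)
  } else {
    list(ratio = n_count / s_count, s_corrected = FALSE)
  }
}

# selection_estimate record shared by the polymorphism and divergence paths
new_selection_estimate <- function(gene_id, stat_kind, n_count, s_count,
                                   s_corrected, ratio, n_codons_used, n_rows,
                                   usable, recombination_flagged = FALSE) {
  structure(list(
    gene_id = gene_id, stat_kind = stat_kind,
    n_count = n_count, s_count = s_count,
    s_corrected = s_corrected, ratio = ratio,
    n_codons_used = n_codons_used, n_rows = n_rows,
    usable = usable, recombination_flagged = recombination_flagged
  ), class = "selection_estimate")
}

#' @export
print.selection_estimate <- function(x, ...) {
  cat(sprintf(
    "<selection_estimate %s> %s: N=%.3g S=%.3g ratio=%.4g%s (%d codons, %d rows%s)\n",
    x$stat_kind, x$gene_id, x$n_count, x$s_count, x$ratio,
    if (x$s_corrected) " [pS->1]" else "",
    x$n_codons_used, x$n_rows,
    if (x$usable) "" else ", unusable"))
  invisible(x)
}

# which codon columns survive filtering: no gap/N and no stop in any row
retained_columns <- function(ci) {
  aa <- aa_by_index()
  ok <- colSums(is.na(ci)) == 0L
  if (any(ok)) {
    sub <- ci[, ok, drop = FALSE]
    has_stop <- colSums(matrix(aa[sub] == "*", nrow = nrow(sub))) > 0L
    ok[ok] <- !has_stop
  }
  ok
}

#' Count within-cluster polymorphisms and form pN/pS for one gene
#'
#' Iterates codon columns of a strain-cluster alignment. Columns containing
#' a gap, an `N`, or a stop codon in any row are excluded. For a two-row
#' cluster every differing codon pair is classified with
#' [classify_substitution()]. For larger clusters, identical row sequences
#' are first collapsed (alleles are counted once, however many strains carry
#' them); the per-column base state is the majority codon among the distinct
#' rows, ties resolved to the reference row's codon, and each distinct
#' non-base codon contributes one classified variant.
#'
#' @param aln a [codon_alignment()] object.
#' @return a `selection_estimate` with `stat_kind = "polymorphism"`. When no
#'   columns survive filtering or no polymorphism is observed the estimate
#'   has zero counts and `usable = FALSE`.
#' @export
count_gene_polymorphisms <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$rows) < 2L) stop("need at least 2 rows", call. = FALSE)
  n_rows_orig <- length(aln$rows)

  # collapse identical sequences; keep the reference row's copy identifiable
  rows <- aln$rows
  ref_seq <- rows[aln$reference_row]
  uniq <- !duplicated(rows)
  rows <- rows[uniq]
  ref_u <- match(ref_seq, rows)

  m <- base_matrix(rows)
  ci <- codon_index_matrix(m)
  ok <- retained_columns(ci)
  n_used <- sum(ok)

  n_count <- 0
  s_count <- 0
  if (n_used > 0L && nrow(ci) >= 2L) {
    tabs <- pair_tables()
    sub <- ci[, ok, drop = FALSE]
    if (nrow(sub) == 2L) {
      d <- sub[1L, ] != sub[2L, ]
      if (any(d)) {
        n_count <- sum(tabs$N[cbind(sub[1L, d], sub[2L, d])])
        s_count <- sum(tabs$S[cbind(sub[1L, d], sub[2L, d])])
      }
    } else {
      for (j in seq_len(ncol(sub))) {
        col <- sub[, j]
        if (all(col == col[1L])) next
        tab <- tabulate(col, nbins = 64L)
        top <- max(tab)
        cands <- which(tab == top)
        base <- if (length(cands) == 1L) cands else {
          if (col[ref_u] %in% cands) col[ref_u] else min(cands)
        }
        for (v in setdiff(unique(col), base)) {
          n_count <- n_count + tabs$N[base, v]
          s_count <- s_count + tabs$S[base, v]
        }
      }
    }
  }

  pr <- pnps(n_count, s_count)
  usable <- n_used > 0L && (n_count + s_count) > 0
  new_selection_estimate(aln$gene_id, "polymorphism", n_count, s_count,
                         pr$s_corrected, pr$ratio, n_used, n_rows_orig,
                         usable)
}

#' Nei-Gojobori (1986) dN/dS for a two-sequence codon alignment
#'
#' Counting estimator: per retained codon the nine single-base changes are
#' enumerated to give synonymous/nonsynonymous site (opportunity) counts
#' (changes creating stops excluded from opportunity, each remaining change
#' weighted 1/3); site counts are averaged over the two rows. Observed
#' differences are classified by [classify_substitution()] pathway
#' averaging. The per-site proportions `pN* = Nd/N`, `pS* = Sd/S` receive
#' the Jukes-Cantor correction `d = -(3/4) log(1 - (4/3) p)`. A proportion
#' at or beyond the 3/4 saturation bound marks the estimate unusable. When
#' no synonymous difference is observed the ratio falls back to the
#' uncorrected `pN*` over a denominator of 1, with the corrected flag set.
#'
#' @param aln a [codon_alignment()] with exactly 2 rows.
#' @return a `selection_estimate` with `stat_kind = "divergence"`; `n_count`
#'   and `s_count` carry dN and dS, with the observed difference counts in
#'   attributes `Nd`/`Sd` and site counts in `N_sites`/`S_sites`.
#' @export
dnds_ng86 <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (length(aln$rows) != 2L) {
    stop("dnds_ng86 requires exactly 2 rows", call. = FALSE)
  }
  m <- base_matrix(aln$rows)
  ci <- codon_index_matrix(m)
  ok <- retained_columns(ci)
  n_used <- sum(ok)
  st <- site_tables()
  tabs <- pair_tables()

  if (n_used == 0L) {
    est <- new_selection_estimate(aln$gene_id, "divergence", 0, 0, FALSE, 0,
                                  0L, 2L, FALSE)
    return(est)
  }
  sub <- ci[, ok, drop = FALSE]
  N_sites <- mean(c(sum(st$N[sub[1L, ]]), sum(st$N[sub[2L, ]])))
  S_sites <- mean(c(sum(st$S[sub[1L, ]]), sum(st$S[sub[2L, ]])))
  d <- sub[1L, ] != sub[2L, ]
  Nd <- if (any(d)) sum(tabs$N[cbind(sub[1L, d], sub[2L, d])]) else 0
  Sd <- if (any(d)) sum(tabs$S[cbind(sub[1L, d], sub[2L, d])]) else 0

  pN <- if (N_sites > 0) Nd / N_sites else 0
  pS <- if (S_sites > 0) Sd / S_sites else 0

  saturated <- pN >= 0.75 || pS >= 0.75
  jc <- function(p) -0.75 * log(1 - (4 / 3) * p)

  if (saturated) {
    est <- new_selection_estimate(aln$gene_id, "divergence", NA_real_,
                                  NA_real_, FALSE, NA_real_, n_used, 2L,
                                  FALSE)
    attr(est, "saturated") <- TRUE
  } else {
    dN <- jc(pN)
    dS <- jc(pS)
    if (Nd + Sd == 0) {
      est <- new_selection_estimate(aln$gene_id, "divergence", 0, 0, FALSE,
                                    0, n_used, 2L, FALSE)
    } else if (dS == 0) {
      est <- new_selection_estimate(aln$gene_id, "divergence", dN, 0, TRUE,
                                    pN / 1, n_used, 2L, TRUE)
    } else {
      est <- new_selection_estimate(aln$gene_id, "divergence", dN, dS, FALSE,
                                    dN / dS, n_used, 2L, TRUE)
    }
    attr(est, "saturated") <- FALSE
  }
  attr(est, "Nd") <- Nd
  attr(est, "Sd") <- Sd
  attr(est, "N_sites") <- N_sites
  attr(est, "S_sites") <- S_sites
  est
}

#' Four-gamete screen for intragenic recombination
#'
#' Over all pairs of biallelic nucleotide sites (sites where every row is an
#' unambiguous base and exactly two alleles segregate), counts pairs
#' exhibiting all four haplotypes. Under infinite-sites evolution on a
#' single tree at most three gametes can occur, so a violating pair implies
#' recombination (or recurrent mutation). Flagged genes are excluded from
#' dN/dS summaries (divergence estimates are sensitive to recombination)
#' but retained for pN/pS.
#'
#' @param aln a [codon_alignment()].
#' @return list with integer `violating_pairs` and logical `flagged`.
#'   Alignments with fewer than 4 rows return `(0, FALSE)` since four
#'   gametes cannot be observed.
#' @export
four_gamete_screen <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  n <- length(aln$rows)
  if (n < 4L) return(list(violating_pairs = 0L, flagged = FALSE))
  m <- base_matrix(aln$rows)
  complete <- colSums(is.na(m)) == 0L
  m <- m[, complete, drop = FALSE]
  nallele <- apply(m, 2L, function(col) length(unique(col)))
  bi <- which(nallele == 2L)
  if (length(bi) < 2L) return(list(violating_pairs = 0L, flagged = FALSE))
  # binary encoding: 1 where the allele equals the site's first-row allele
  B <- m[, bi, drop = FALSE]
  B <- sweep(B, 2L, B[1L, ], `==`) * 1L
  c11 <- crossprod(B)
  c00 <- crossprod(1L - B)
  c10 <- crossprod(B, 1L - B)
  c01 <- t(c10)
  viol <- (c11 > 0L) & (c00 > 0L) & (c10 > 0L) & (c01 > 0L)
  n_viol <- sum(viol[upper.tri(viol)])
  list(violating_pairs = as.integer(n_viol), flagged = n_viol > 0L)
}

# tidy one-row data.frame for a selection_estimate (used by report writers)
estimate_row <- function(est, genome_id = NA_character_) {
  data.frame(
    gene_id = est$gene_id, genome_id = genome_id,
    stat_kind = est$stat_kind,
    n_count = est$n_count, s_count = est$s_count,
    s_corrected = est$s_corrected, ratio = est$ratio,
    n_codons_used = est$n_codons_used, n_rows = est$n_rows,
    usable = est$usable,
    recombination_flagged = est$recombination_flagged,
    stringsAsFactors = FALSE
  )
}
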