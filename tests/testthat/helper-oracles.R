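# Independent oracles used to check the package's computations. These are
# deliberately written with different algorithms/code paths than the
# implementations they verify.

GENCODE <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(GENCODE[[codon]])

# Brute-force minimal-pathway classification between two sense codons:
# recursive depth-first enumeration over which differing position mutates
# next, tracking stop transits.
oracle_classify <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  paths <- list()
  walk <- function(cur, remaining, n, s, via_stop) {
    if (length(remaining) == 0L) {
      paths[[length(paths) + 1L]] <<- list(n = n, s = s, via_stop = via_stop)
      return(invisible())
    }
    for (pos in remaining) {
      nxt <- cur
      nxt[pos] <- bv[pos]
      aa1 <- oracle_translate(paste(cur, collapse = ""))
      aa2 <- oracle_translate(paste(nxt, collapse = ""))
      syn <- aa1 == aa2
      stop_here <- aa2 == "*" && length(remaining) > 1L
      walk(nxt, setdiff(remaining, pos),
           n + !syn, s + syn, via_stop || stop_here)
    }
  }
  walk(av, which(av != bv), 0L, 0L, FALSE)
  if (length(paths) == 0L) return(c(n = 0, s = 0))
  ok <- Filter(function(p) !p$via_stop, paths)
  if (length(ok) == 0L) ok <- paths
  c(n = mean(vapply(ok, `[[`, 0, "n")),
    s = mean(vapply(ok, `[[`, 0, "s")))
}

all_sense_codons <- function() {
  codons <- names(GENCODE)
  codons[GENCODE != "*"]
}

# Exact two-sided Mann-Whitney p by enumerating every assignment of the
# pooled values to the two groups.
oracle_mw <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  idx <- utils::combn(length(pooled), nx)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(x, y)
  us <- apply(idx, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# Closed-form BY step-up
oracle_by <- function(p) {
  m <- length(p)
  cm <- sum(1 / seq_len(m))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1, m * cm * ps / seq_len(m))
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- adj
  out
}

# Hypergeometric upper tail by direct summation of binomial coefficients
oracle_hyper_tail <- function(pop_n, pop_count, study_n, study_count) {
  ks <- study_count:min(study_n, pop_count)
  ks <- ks[study_n - ks <= pop_n - pop_count]
  sum(choose(pop_count, ks) * choose(pop_n - pop_count, study_n - ks)) /
    choose(pop_n, study_n)
}

# Mutational-opportunity ratio of a sequence: enumerate all single-base
# mutants, count nonsynonymous vs synonymous among non-stop proposals.
oracle_opportunity_ratio <- function(seq) {
  v <- strsplit(seq, "")[[1]]
  n_non <- 0L
  n_syn <- 0L
  for (p in seq_along(v)) {
    for (nb in setdiff(c("A", "C", "G", "T"), v[p])) {
      w <- v
      w[p] <- nb
      c0 <- p - ((p - 1) %% 3)
      aa_old <- oracle_translate(paste(v[c0:(c0 + 2)], collapse = ""))
      aa_new <- oracle_translate(paste(w[c0:(c0 + 2)], collapse = ""))
      if (aa_new == "*") next
      if (aa_new == aa_old) n_syn <- n_syn + 1L else n_non <- n_non + 1L
    }
  }
  list(n = n_non, s = n_syn, ratio = n_non / n_syn)
}
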