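# Internal codon machinery: integer encodings of bases and codons plus
# cached lookup tables used by the counting statistics. Bases are encoded
# A=1, C=2, G=3, T=4; a codon (b1,b2,b3) maps to index (b1-1)*16+(b2-1)*4+b3
# in 1..64. Gap ('-') and ambiguous ('N') positions are encoded NA.

BASES <- c("A", "C", "G", "T")

.evorate_cache <- new.env(parent = emptyenv())

dna_to_int <- function(seq) {
  match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], BASES)
}

int_to_dna <- function(b) {
  paste(BASES[b], collapse = "")
}

codon_index <- function(b1, b2, b3) {
  (b1 - 1L) * 16L + (b2 - 1L) * 4L + b3
}

#' @return character vector of length 64: one-letter amino acid per codon
#'   index, "*" for the three stop codons. Standard genetic code (identical
#'   to bacterial table 11 on all 61 sense codons).
#' @noRd
aa_by_index <- function() {
  if (is.null(.evorate_cache$aa)) {
    gc_tab <- Biostrings::GENETIC_CODE
    aa <- character(64)
    for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
      codon <- paste0(BASES[i1], BASES[i2], BASES[i3])
      aa[codon_index(i1, i2, i3)] <- unname(gc_tab[[codon]])
    }
    .evorate_cache$aa <- aa
  }
  .evorate_cache$aa
}

codon_string_by_index <- function() {
  if (is.null(.evorate_cache$codon_str)) {
    s <- character(64)
    for (i1 in 1:4) for (i2 in 1:4) for (i3 in 1:4) {
      s[codon_index(i1, i2, i3)] <- paste0(BASES[i1], BASES[i2], BASES[i3])
    }
    .evorate_cache$codon_str <- s
  }
  .evorate_cache$codon_str
}

sense_codon_indices <- function() {
  which(aa_by_index() != "*")
}

# 64x64 matrices of pathway-averaged nonsynonymous / synonymous mutation
# fractions between sense codon pairs (NA where either codon is a stop).
# Built lazily once per session from classify_substitution().
pair_tables <- function() {
  if (is.null(.evorate_cache$pairN)) {
    codons <- codon_string_by_index()
    sense <- sense_codon_indices()
    N <- matrix(NA_real_, 64, 64)
    S <- matrix(NA_real_, 64, 64)
    for (i in sense) for (j in sense) {
      cl <- classify_substitution(codons[i], codons[j])
      N[i, j] <- cl$n_frac
      S[i, j] <- cl$s_frac
    }
    .evorate_cache$pairN <- N
    .evorate_cache$pairS <- S
  }
  list(N = .evorate_cache$pairN, S = .evorate_cache$pairS)
}

# Per-codon NG86 mutational-opportunity site counts: each of the nine
# single-base changes carries weight 1/3; changes creating a stop codon are
# excluded from both counts, so N + S = 3 - (stop changes)/3 per codon.
site_tables <- function() {
  if (is.null(.evorate_cache$siteN)) {
    aa <- aa_by_index()
    sN <- rep(NA_real_, 64)
    sS <- rep(NA_real_, 64)
    for (idx in sense_codon_indices()) {
      b <- index_to_bases(idx)
      nsyn <- 0; nnon <- 0
      for (pos in 1:3) for (nb in (1:4)[-b[pos]]) {
        mut <- b
        mut[pos] <- nb
        aam <- aa[codon_index(mut[1], mut[2], mut[3])]
        if (aam == "*") next
        if (aam == aa[idx]) nsyn <- nsyn + 1 else nnon <- nnon + 1
      }
      sS[idx] <- nsyn / 3
      sN[idx] <- nnon / 3
    }
    .evorate_cache$siteN <- sN
    .evorate_cache$siteS <- sS
  }
  list(N = .evorate_cache$siteN, S = .evorate_cache$siteS)
}

index_to_bases <- function(idx) {
  i0 <- idx - 1L
  c(i0 %/% 16L + 1L, (i0 %/% 4L) %% 4L + 1L, i0 %% 4L + 1L)
}

# rows of an alignment as an n_rows x L integer base matrix (NA for -/N)
base_matrix <- function(rows) {
  n <- length(rows)
  m <- matrix(match(unlist(strsplit(toupper(rows), "", fixed = TRUE)), BASES),
              nrow = n, byrow = TRUE)
  m
}

# n_rows x n_codons codon-index matrix; NA wherever any base of the codon
# is NA
codon_index_matrix <- function(m) {
  L <- ncol(m)
  s1 <- seq(1L, L, by = 3L)
  ci <- (m[, s1, drop = FALSE] - 1L) * 16L +
    (m[, s1 + 1L, drop = FALSE] - 1L) * 4L + m[, s1 + 2L, drop = FALSE]
  ci
}
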