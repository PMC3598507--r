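#' Configuration for the synthetic study generator
#'
#' Defaults mirror the scale of a single bacterial species in the study
#' design this package targets: three mutually exclusive gene classes
#' (background, essential, approved drug target) whose true nonsynonymous
#' acceptance rates omega are ordered ADT < ESS < background, clusters of
#' closely related strain sequences per gene, and a toy GO ontology whose
#' designated "slow" term is preferentially annotated to the two
#' constrained classes.
#'
#' @param n_background,n_essential,n_targets genes per class.
#' @param omega_background,omega_essential,omega_targets acceptance
#'   probability of a proposed nonsynonymous change per class.
#' @param expected_subs_per_codon expected proposed substitutions per codon
#'   on each branch (ancestor -> strain).
#' @param gene_length_codons gene length; a scalar or `c(min, max)` range.
#' @param rows_per_cluster strain sequences per gene cluster (>= 2).
#' @param slow_term_enrichment odds multiplier tying the designated slow GO
#'   term to the ADT and ESS classes (>= 1).
#' @param seed integer seed driving all randomness of the simulation.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_background = 1000L, n_essential = 300L,
                              n_targets = 35L,
                              omega_background = 0.6,
                              omega_essential = 0.3,
                              omega_targets = 0.1,
                              expected_subs_per_codon = 0.2,
                              gene_length_codons = 300L,
                              rows_per_cluster = 2L,
                              slow_term_enrichment = 8,
                              seed = 1L) {
  stopifnot(n_background >= 0, n_essential >= 0, n_targets >= 0,
            omega_background > 0, omega_essential > 0, omega_targets > 0,
            expected_subs_per_codon >= 0, rows_per_cluster >= 2,
            slow_term_enrichment >= 1,
            length(gene_length_codons) %in% c(1L, 2L),
            all(gene_length_codons >= 1))
  if (sum(c(n_background, n_essential, n_targets) > 0) < 2) {
    stop("at least two classes must be non-empty", call. = FALSE)
  }
  structure(list(
    n_background = as.integer(n_background),
    n_essential = as.integer(n_essential),
    n_targets = as.integer(n_targets),
    omega_background = omega_background,
    omega_essential = omega_essential,
    omega_targets = omega_targets,
    expected_subs_per_codon = expected_subs_per_codon,
    gene_length_codons = as.integer(gene_length_codons),
    rows_per_cluster = as.integer(rows_per_cluster),
    slow_term_enrichment = slow_term_enrichment,
    seed = as.integer(seed)), class = "simulation_config")
}

#' Draw a random coding sequence
#'
#' Starts with ATG, then uniform sense codons: no internal stop by
#' construction.
#'
#' @param length_codons number of codons (>= 1).
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @return DNA string of `3 * length_codons` letters.
#' @export
random_cds <- function(length_codons, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length_codons >= 1)
  codons <- codon_string_by_index()
  sense <- sense_codon_indices()
  body <- if (length_codons > 1L) {
    sample(sense, length_codons - 1L, replace = TRUE)
  } else integer(0)
  paste0("ATG", paste(codons[body], collapse = ""))
}

#' Evolve a coding sequence under purifying selection
#'
#' Proposes `Poisson(expected_subs_per_codon * n_codons)` single-base
#' changes at uniform random sites (uniform among the three alternative
#' bases), applied sequentially. Proposals creating a stop codon are
#' rejected; synonymous proposals are always accepted; nonsynonymous
#' proposals are accepted with probability `min(1, omega)`. This acceptance
#' thinning is the simplest mechanism making the counted pN/pS of derived
#' sequences approximately proportional to omega.
#'
#' @param seq sense-codon DNA string (length a multiple of 3, no internal
#'   stops).
#' @param omega nonsynonymous acceptance probability.
#' @param expected_subs_per_codon expected proposals per codon.
#' @param seed optional seed.
#' @return list with `seq` (derived sequence), `n_accepted`, `s_accepted`
#'   (exact accepted mutation tallies) and `proposals`.
#' @export
evolve <- function(seq, omega, expected_subs_per_codon, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- dna_to_int(seq)
  if (anyNA(b)) stop("sequence must be over A/C/G/T", call. = FALSE)
  L <- length(b)
  if (L %% 3L != 0L) stop("length must be a multiple of 3", call. = FALSE)
  nc <- L %/% 3L
  aa <- aa_by_index()
  n_prop <- stats::rpois(1L, expected_subs_per_codon * nc)
  nN <- 0L
  nS <- 0L
  if (n_prop > 0L) {
    pos <- sample.int(L, n_prop, replace = TRUE)
    delta <- sample.int(3L, n_prop, replace = TRUE)
    u <- stats::runif(n_prop)
    for (i in seq_len(n_prop)) {
      p <- pos[i]
      new <- ((b[p] - 1L + delta[i]) %% 4L) + 1L
      c0 <- p - ((p - 1L) %% 3L)
      i1 <- b[c0]; i2 <- b[c0 + 1L]; i3 <- b[c0 + 2L]
      old_idx <- (i1 - 1L) * 16L + (i2 - 1L) * 4L + i3
      off <- p - c0
      new_idx <- if (off == 0L) (new - 1L) * 16L + (i2 - 1L) * 4L + i3
      else if (off == 1L) (i1 - 1L) * 16L + (new - 1L) * 4L + i3
      else (i1 - 1L) * 16L + (i2 - 1L) * 4L + new
      aa_new <- aa[new_idx]
      if (aa_new == "*") next
      if (aa[old_idx] == aa_new) {
        b[p] <- new
        nS <- nS + 1L
      } else if (u[i] < omega) {
        b[p] <- new
        nN <- nN + 1L
      }
    }
  }
  list(seq = int_to_dna(b), n_accepted = nN, s_accepted = nS,
       proposals = n_prop)
}

# toy molecular-function ontology used by the generator; GO:0005198 is the
# designated "slow" term
toy_go_dag <- function() {
  terms <- list(
    "GO:0003674" = list(name = "molecular_function",
                        namespace = "molecular_function", parents = character(0)),
    "GO:0005198" = list(name = "structural molecule activity",
                        namespace = "molecular_function", parents = "GO:0003674"),
    "GO:0005488" = list(name = "binding",
                        namespace = "molecular_function", parents = "GO:0003674"),
    "GO:0003676" = list(name = "nucleic acid binding",
                        namespace = "molecular_function", parents = "GO:0005488"),
    "GO:0019843" = list(name = "rRNA binding",
                        namespace = "molecular_function",
                        parents = c("GO:0003676", "GO:0005488")),
    "GO:0046872" = list(name = "metal ion binding",
                        namespace = "molecular_function", parents = "GO:0005488"),
    "GO:0003824" = list(name = "catalytic activity",
                        namespace = "molecular_function", parents = "GO:0003674"),
    "GO:0016740" = list(name = "transferase activity",
                        namespace = "molecular_function", parents = "GO:0003824")
  )
  structure(list(
    terms = lapply(terms, function(t) list(name = t$name,
                                           namespace = t$namespace,
                                           obsolete = FALSE)),
    parents = lapply(terms, `[[`, "parents")), class = "go_dag")
}

#' Serialize a GO DAG as OBO 1.2
#' @param dag a `go_dag`.
#' @param path output file.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "")
  for (id in names(dag$terms)) {
    t <- dag$terms[[id]]
    lines <- c(lines, "[Term]", paste0("id: ", id), paste0("name: ", t$name),
               paste0("namespace: ", t$namespace))
    for (p in dag$parents[[id]]) {
      lines <- c(lines, paste0("is_a: ", p, " ! ", dag$terms[[p]]$name))
    }
    if (isTRUE(t$obsolete)) lines <- c(lines, "is_obsolete: true")
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize direct annotations as GAF 2.1
#' @param annotations named list `gene -> term ids`.
#' @param path output file.
#' @export
write_gaf <- function(annotations, path) {
  lines <- "!gaf-version: 2.1"
  for (g in names(annotations)) {
    for (t in annotations[[g]]) {
      lines <- c(lines, paste("SIM", g, g, "", t, "SIM:1", "IEA", "", "F",
                              g, "", "protein", "taxon:0", "20120101",
                              "SIM", "", "", sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate a complete ground-truthed study
#'
#' Per gene: a random ancestral CDS from which each strain sequence is
#' independently evolved (star topology — the closely-related-strains
#' polymorphism setting) under the class omega. Also emits the gene
#' membership table, KO assignments for the drug-target class, a toy GO
#' ontology with a designated slow term annotated preferentially to the
#' constrained classes, and the exact accepted-mutation bookkeeping.
#'
#' @param config a [simulation_config()].
#' @param out_dir if non-NULL, all inputs are additionally written in the
#'   formats the readers consume (`alignments/*.fasta`, `genes.tsv`,
#'   `ko.tsv`, `go.obo`, `annotations.gaf`, `truth.tsv`).
#' @return list with `alignments` (named list of [codon_alignment()]),
#'   `ancestors` (named character vector of ancestral sequences),
#'   `gene_table`, `ko` (data.frame `gene_id`, `ko_id`, `gene_name`),
#'   `dag`, `annotations` (direct, gene -> terms), `truth` (data.frame
#'   `gene_id`, `class`, `omega`, `n_accepted`, `s_accepted`) and `config`.
#' @export
simulate_study <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  classes <- c(rep("ADT", config$n_targets),
               rep("ESS", config$n_essential),
               rep("ALL", config$n_background))
  n_genes <- length(classes)
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  omegas <- c(ADT = config$omega_targets, ESS = config$omega_essential,
              ALL = config$omega_background)[classes]
  genomes <- paste0("G", seq_len(config$rows_per_cluster))

  lens <- if (length(config$gene_length_codons) == 2L) {
    sample(config$gene_length_codons[1L]:config$gene_length_codons[2L],
           n_genes, replace = TRUE)
  } else rep(config$gene_length_codons, n_genes)

  alignments <- vector("list", n_genes)
  ancestors <- character(n_genes)
  nA <- integer(n_genes)
  sA <- integer(n_genes)
  for (i in seq_len(n_genes)) {
    anc <- random_cds(lens[i])
    ancestors[i] <- anc
    rows <- character(config$rows_per_cluster)
    ni <- 0L
    si <- 0L
    for (r in seq_len(config$rows_per_cluster)) {
      ev <- evolve(anc, omegas[i], config$expected_subs_per_codon)
      rows[r] <- ev$seq
      ni <- ni + ev$n_accepted
      si <- si + ev$s_accepted
    }
    alignments[[i]] <- codon_alignment(gene_ids[i], genomes, rows, 1L)
    nA[i] <- ni
    sA[i] <- si
  }
  names(alignments) <- gene_ids

  gene_table <- data.frame(
    gene_id = gene_ids, genome_id = genomes[1L],
    essential = classes %in% c("ESS", "ADT"),
    drug_target = classes == "ADT",
    ko_id = ifelse(classes == "ADT",
                   sprintf("ko:K%05d", seq_len(n_genes)), NA_character_),
    stringsAsFactors = FALSE)

  ko <- gene_table[!is.na(gene_table$ko_id),
                   c("gene_id", "ko_id"), drop = FALSE]
  if (nrow(ko) > 0L) ko$gene_name <- paste0("target_", ko$gene_id)
  rownames(ko) <- NULL

  dag <- toy_go_dag()
  slow_term <- "GO:0005198"
  other_terms <- c("GO:0019843", "GO:0046872", "GO:0016740", "GO:0003676")
  p0 <- 0.08
  odds0 <- p0 / (1 - p0)
  odds_slow <- odds0 * config$slow_term_enrichment
  p_slow_constrained <- odds_slow / (1 + odds_slow)
  annotations <- list()
  for (i in seq_len(n_genes)) {
    if (stats::runif(1) > 0.7) next  # ~30% of genes carry no GO term
    p_slow <- if (classes[i] %in% c("ADT", "ESS")) p_slow_constrained else p0
    terms <- character(0)
    if (stats::runif(1) < p_slow) terms <- slow_term
    terms <- c(terms,
               sample(other_terms, stats::rbinom(1L, 2L, 0.5)))
    if (length(terms) == 0L) terms <- sample(other_terms, 1L)
    annotations[[gene_ids[i]]] <- unique(terms)
  }

  truth <- data.frame(gene_id = gene_ids, class = classes,
                      omega = unname(omegas), n_accepted = nA,
                      s_accepted = sA, stringsAsFactors = FALSE)

  names(ancestors) <- gene_ids
  out <- list(alignments = alignments, ancestors = ancestors,
              gene_table = gene_table, ko = ko,
              dag = dag, annotations = annotations, truth = truth,
              config = config)

  if (!is.null(out_dir)) {
    adir <- file.path(out_dir, "alignments")
    if (!dir.exists(adir)) dir.create(adir, recursive = TRUE)
    for (g in gene_ids) {
      write_codon_alignment(alignments[[g]],
                            file.path(adir, paste0(g, ".fasta")))
    }
    write_gene_table(gene_table, file.path(out_dir, "genes.tsv"))
    utils::write.table(ko, file.path(out_dir, "ko.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_obo(dag, file.path(out_dir, "go.obo"))
    write_gaf(annotations, file.path(out_dir, "annotations.gaf"))
    utils::write.table(truth, file.path(out_dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}
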