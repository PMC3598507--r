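#' Configuration for an end-to-end pipeline run
#'
#' Exactly one input source: either a [simulation_config()] (the study is
#' generated) or paths to real inputs (alignment directory, gene table,
#' ontology, annotations).
#'
#' @param simulation a [simulation_config()], or NULL.
#' @param alignments_dir directory of per-gene FASTA cluster alignments.
#' @param genes_file gene membership TSV (see [read_gene_table()]).
#' @param obo_file GO ontology (OBO 1.2).
#' @param gaf_file GO annotations (GAF 2.x).
#' @param reference_genome reference genome id for file inputs.
#' @param species species label used in output tables.
#' @param statistic `"pnps"`, `"dnds"` or `"both"`.
#' @param slow_fraction fraction of slowest genes forming the GO study set.
#' @param boot_R bootstrap resamples for set-mean confidence intervals.
#' @param seed seed for the run's own randomness (bootstrap).
#' @param out_dir if non-NULL, report tables are written there.
#' @return a `run_config` list.
#' @export
run_config <- function(simulation = NULL, alignments_dir = NULL,
                       genes_file = NULL, obo_file = NULL, gaf_file = NULL,
                       reference_genome = "G1", species = "sim",
                       statistic = c("pnps", "dnds", "both"),
                       slow_fraction = 0.10, boot_R = 2000L, seed = 1L,
                       out_dir = NULL) {
  statistic <- match.arg(statistic)
  has_sim <- !is.null(simulation)
  has_files <- !is.null(alignments_dir)
  if (has_sim == has_files) {
    stop("supply exactly one of `simulation` or file inputs", call. = FALSE)
  }
  if (has_files && (is.null(genes_file))) {
    stop("file inputs require `genes_file`", call. = FALSE)
  }
  structure(list(simulation = simulation, alignments_dir = alignments_dir,
                 genes_file = genes_file, obo_file = obo_file,
                 gaf_file = gaf_file, reference_genome = reference_genome,
                 species = species, statistic = statistic,
                 slow_fraction = slow_fraction, boot_R = as.integer(boot_R),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

# per-gene estimate tables for a set of alignments
estimate_alignments <- function(alignments, statistic, species) {
  do_pnps <- statistic %in% c("pnps", "both")
  do_dnds <- statistic %in% c("dnds", "both")
  rows <- vector("list", length(alignments) * (do_pnps + do_dnds))
  k <- 0L
  for (aln in alignments) {
    genome <- aln$genome_ids[aln$reference_row]
    if (do_pnps) {
      est <- count_gene_polymorphisms(aln)
      k <- k + 1L
      rows[[k]] <- estimate_row(est, genome)
    }
    if (do_dnds) {
      # the divergence estimator is pairwise: reference row vs the first
      # other row; the recombination screen uses the full cluster
      other <- setdiff(seq_along(aln$rows), aln$reference_row)[1L]
      pair <- codon_alignment(aln$gene_id,
                              aln$genome_ids[c(aln$reference_row, other)],
                              aln$rows[c(aln$reference_row, other)], 1L)
      est <- dnds_ng86(pair)
      fg <- four_gamete_screen(aln)
      est$recombination_flagged <- fg$flagged
      k <- k + 1L
      rows[[k]] <- estimate_row(est, genome)
    }
  }
  out <- do.call(rbind, rows[seq_len(k)])
  out$species <- species
  out
}

#' Run the full analysis pipeline
#'
#' simulate (or read) -> estimate per-gene rates -> three-way set
#' comparison with BY-FDR -> genome-wide ranking and KO-group summary ->
#' GO over-representation of the slowest decile. The divergence (dN/dS)
#' path excludes genes flagged by the four-gamete recombination screen
#' from its comparisons; the polymorphism path keeps them.
#'
#' @param config a [run_config()].
#' @return a run report: list of data.frames `estimates`, `comparisons`,
#'   `ranking`, `ko_summary`, `enrichment` plus a `provenance` list
#'   (config echo, seed, filter-step counts, package version).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))

  if (!is.null(config$simulation)) {
    sim <- simulate_study(config$simulation)
    alignments <- sim$alignments
    gene_table <- sim$gene_table
    ko <- sim$ko
    dag <- sim$dag
    direct <- sim$annotations
  } else {
    files <- list.files(config$alignments_dir,
                        pattern = "\\.(fa|fasta)$", full.names = TRUE)
    alignments <- lapply(files, read_codon_alignment,
                         reference_genome = config$reference_genome)
    names(alignments) <- vapply(alignments, `[[`, "", "gene_id")
    gene_table <- read_gene_table(config$genes_file)
    ko <- gene_table[!is.na(gene_table$ko_id),
                     c("gene_id", "ko_id"), drop = FALSE]
    dag <- if (!is.null(config$obo_file)) read_obo(config$obo_file) else NULL
    direct <- if (!is.null(config$gaf_file)) {
      read_gaf(config$gaf_file, dag)$annotations
    } else NULL
  }

  set.seed(config$seed)
  estimates <- estimate_alignments(alignments, config$statistic,
                                   config$species)
  partition <- partition_genes(gene_table)

  primary_kind <- if (config$statistic == "dnds") "divergence" else
    "polymorphism"
  primary <- estimates[estimates$stat_kind == primary_kind, , drop = FALSE]

  comparisons <- NULL
  for (kind in unique(estimates$stat_kind)) {
    est_k <- estimates[estimates$stat_kind == kind, , drop = FALSE]
    if (kind == "divergence") {
      est_k <- est_k[!est_k$recombination_flagged, , drop = FALSE]
    }
    cmp <- compare_groups(est_k, partition, species = config$species,
                          boot_R = config$boot_R)
    if (!is.null(cmp)) {
      cmp$stat_kind <- kind
      # single-species run: the family is this statistic's 3 tests
      cmp <- adjust_comparisons(cmp)
      comparisons <- rbind(comparisons, cmp)
    }
  }

  usable <- primary[primary$usable, , drop = FALSE]
  ranking <- percentile_rank(usable)
  ko_summary <- summarize_ko_groups(ko, primary)

  enrichment <- NULL
  slow_set <- select_slowest(ranking, config$slow_fraction)
  if (!is.null(dag) && !is.null(direct)) {
    propagated <- propagate_annotations(direct, dag)
    enrichment <- term_for_term(slow_set, ranking$gene_id, propagated,
                                dag = dag)
  }

  provenance <- list(
    package_version = as.character(utils::packageVersion("evorate")),
    seed = config$seed,
    statistic = config$statistic,
    species = config$species,
    slow_fraction = config$slow_fraction,
    boot_R = config$boot_R,
    simulated = !is.null(config$simulation),
    simulation = if (!is.null(config$simulation)) {
      unclass(config$simulation)
    } else NULL,
    counts = list(
      genes_in = length(alignments),
      estimates = nrow(estimates),
      usable_primary = nrow(usable),
      recombination_flagged = sum(estimates$recombination_flagged),
      study_set = length(slow_set),
      sets = as.list(table(partition$set))
    )
  )

  report <- list(estimates = estimates, comparisons = comparisons,
                 ranking = ranking, ko_summary = ko_summary,
                 enrichment = enrichment, provenance = provenance)
  if (!is.null(config$out_dir)) {
    write_report(Filter(Negate(is.null), report), config$out_dir)
  }
  report
}
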