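#' Construct a validated codon alignment
#'
#' The unit of rate estimation: one gene's aligned coding sequences across
#' the strains of a cluster. Rows are equal-length strings over
#' `{A,C,G,T,-,N}` whose common length is a multiple of 3. Gap and `N`
#' symbols are legal here; their treatment (column exclusion) happens in the
#' counting statistics.
#'
#' @param gene_id gene identifier (by convention the reference genome's
#'   gene).
#' @param genome_ids character vector, one unique genome per row.
#' @param rows character vector of aligned sequences.
#' @param reference_row index of the reference genome's row.
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(gene_id, genome_ids, rows, reference_row = 1L) {
  stopifnot(is.character(rows), is.character(genome_ids))
  if (length(rows) < 2L) stop("alignment needs at least 2 rows", call. = FALSE)
  if (length(genome_ids) != length(rows)) {
    stop("one genome_id per row required", call. = FALSE)
  }
  if (anyDuplicated(genome_ids)) {
    stop("genome_ids must be unique within an alignment", call. = FALSE)
  }
  w <- nchar(rows)
  if (length(unique(w)) != 1L) {
    stop("format error: rows have unequal lengths (ragged alignment)",
         call. = FALSE)
  }
  if (w[1L] %% 3L != 0L) {
    stop("frame error: alignment length ", w[1L], " is not a multiple of 3",
         call. = FALSE)
  }
  bad <- grepl("[^ACGTN-]", toupper(rows))
  if (any(bad)) {
    stop("illegal characters in alignment row(s) ",
         paste(which(bad), collapse = ", "), call. = FALSE)
  }
  reference_row <- as.integer(reference_row)
  if (is.na(reference_row) || reference_row < 1L ||
      reference_row > length(rows)) {
    stop("reference_row out of range", call. = FALSE)
  }
  structure(list(gene_id = unname(gene_id), genome_ids = unname(genome_ids),
                 rows = unname(toupper(rows)),
                 reference_row = reference_row),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %s: %d rows x %d codons (reference: %s)\n",
              x$gene_id, length(x$rows), nchar(x$rows[1L]) / 3L,
              x$genome_ids[x$reference_row]))
  invisible(x)
}

#' Read one gene's cluster alignment from FASTA
#'
#' Headers follow the grammar `genome|gene` (first `|` splits the two
#' fields). The alignment's `gene_id` is the reference genome's gene.
#'
#' @param path FASTA file of aligned CDS (gaps as `-`).
#' @param reference_genome genome_id that must be present; its row becomes
#'   the reference row.
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(path, reference_genome) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("empty FASTA: ", path, call. = FALSE)
  headers <- names(seqs)
  parts <- regmatches(headers, regexpr("|", headers, fixed = TRUE),
                      invert = TRUE)
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) {
    stop("header(s) without 'genome|gene' grammar: ",
         paste(headers[bad], collapse = ", "), call. = FALSE)
  }
  genome_ids <- vapply(parts, `[`, "", 1L)
  gene_ids <- vapply(parts, `[`, "", 2L)
  ref <- match(reference_genome, genome_ids)
  if (is.na(ref)) {
    stop("lookup error: reference genome '", reference_genome,
         "' absent from ", path, call. = FALSE)
  }
  codon_alignment(gene_id = gene_ids[ref], genome_ids = genome_ids,
                  rows = as.character(seqs), reference_row = ref)
}

#' Write a codon alignment back to FASTA (round-trip of
#' [read_codon_alignment()])
#' @param aln a [codon_alignment()].
#' @param path output file.
#' @param gene_ids optional per-row gene ids; defaults to the cluster gene.
#' @export
write_codon_alignment <- function(aln, path, gene_ids = NULL) {
  if (is.null(gene_ids)) gene_ids <- rep(aln$gene_id, length(aln$rows))
  lines <- character(0)
  for (i in seq_along(aln$rows)) {
    lines <- c(lines, paste0(">", aln$genome_ids[i], "|", gene_ids[i]),
               aln$rows[i])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Score a protein pair by global alignment
#'
#' Deterministic stand-in for a BLAST bit score in reciprocal-best-hit
#' orthology resolution: Needleman-Wunsch global alignment under BLOSUM62
#' with affine gaps (opening 10, extension 0.5). The score is symmetric and
#' maximal for self-alignment.
#'
#' @param a,b protein sequences (strings over the 20 amino-acid letters).
#' @return numeric alignment score.
#' @export
score_protein_pair <- function(a, b) {
  if (!is.character(a) || !is.character(b) || nchar(a) == 0L ||
      nchar(b) == 0L) {
    stop("protein sequences must be non-empty strings", call. = FALSE)
  }
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = blosum62(), gapOpening = 10, gapExtension = 0.5,
    scoreOnly = TRUE)
}

blosum62 <- function() {
  if (is.null(.evorate_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .evorate_cache$blosum62 <- e$BLOSUM62
  }
  .evorate_cache$blosum62
}

#' Construct an ortholog cluster
#'
#' @param cluster_id cluster identifier.
#' @param members named list: `genome_id -> named character vector` of
#'   protein sequences, names being gene_ids.
#' @return an `ortholog_cluster` object.
#' @export
ortholog_cluster <- function(cluster_id, members) {
  stopifnot(is.list(members), !is.null(names(members)))
  if (any(vapply(members, length, 1L) < 1L)) {
    stop("every genome needs at least one member", call. = FALSE)
  }
  structure(list(cluster_id = cluster_id, members = members),
            class = "ortholog_cluster")
}

#' Resolve many-to-one ortholog duplications by reciprocal best hit
#'
#' The reference genome must hold exactly one member. For each other
#' genome, the member kept is the one that (a) scores best against the
#' reference member among its genome's members and (b) has the reference
#' member as its own best hit among all members outside its genome. Ties in
#' score are broken lexicographically by gene_id. Genomes whose best member
#' fails the reciprocity check are dropped (reported in the
#' `dropped_genomes` attribute).
#'
#' @param cluster an [ortholog_cluster()].
#' @param reference_genome genome_id with the single reference member.
#' @return named character vector `genome_id -> gene_id` (one-to-one),
#'   with attribute `dropped_genomes`.
#' @export
resolve_duplicates <- function(cluster, reference_genome) {
  stopifnot(inherits(cluster, "ortholog_cluster"))
  members <- cluster$members
  if (!reference_genome %in% names(members)) {
    stop("reference genome absent from cluster", call. = FALSE)
  }
  if (length(members[[reference_genome]]) != 1L) {
    stop("ambiguity error: reference genome must have exactly 1 member",
         call. = FALSE)
  }
  ref_gene <- names(members[[reference_genome]])
  ref_seq <- unname(members[[reference_genome]][[1L]])

  # flat view of all members for the reciprocal back-search
  flat_genome <- rep(names(members), vapply(members, length, 1L))
  flat_gene <- unlist(lapply(members, names), use.names = FALSE)
  flat_seq <- unlist(members, use.names = FALSE)

  best_in <- function(target_seq, candidate_idx) {
    sc <- vapply(candidate_idx,
                 function(i) score_protein_pair(target_seq, flat_seq[i]),
                 numeric(1))
    top <- candidate_idx[sc == max(sc)]
    top[order(flat_gene[top])][1L]  # lexicographic tie-break
  }

  out <- stats::setNames(ref_gene, reference_genome)
  dropped <- character(0)
  for (g in setdiff(names(members), reference_genome)) {
    idx_g <- which(flat_genome == g)
    fwd <- best_in(ref_seq, idx_g)
    # reciprocity: is the reference member the candidate's best hit among
    # everything outside its own genome?
    idx_out <- which(flat_genome != g)
    back <- best_in(flat_seq[fwd], idx_out)
    if (flat_genome[back] == reference_genome &&
        flat_gene[back] == ref_gene) {
      out[g] <- flat_gene[fwd]
    } else {
      dropped <- c(dropped, g)
    }
  }
  attr(out, "dropped_genomes") <- dropped
  out
}

#' Read / write the gene membership table
#'
#' Tab-separated with header `gene_id genome_id essential drug_target
#' ko_id`; flags are 0/1, `ko_id` may be empty.
#'
#' @param path TSV file.
#' @return data.frame with logical `essential`/`drug_target` and `ko_id`
#'   (`NA` when empty).
#' @export
read_gene_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty gene table: ", path, call. = FALSE)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  expected <- c("gene_id", "genome_id", "essential", "drug_target", "ko_id")
  if (!identical(header, expected)) {
    stop("line 1: expected header ", paste(expected, collapse = "\t"),
         call. = FALSE)
  }
  recs <- vector("list", length(lines) - 1L)
  for (i in seq_along(recs)) {
    f <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 4L || length(f) > 5L) {
      stop("line ", i + 1L, ": expected 5 tab-separated fields",
           call. = FALSE)
    }
    if (!f[3L] %in% c("0", "1") || !f[4L] %in% c("0", "1")) {
      stop("line ", i + 1L, ": flags must be 0 or 1", call. = FALSE)
    }
    recs[[i]] <- data.frame(
      gene_id = f[1L], genome_id = f[2L],
      essential = f[3L] == "1", drug_target = f[4L] == "1",
      ko_id = if (length(f) == 5L && nzchar(f[5L])) f[5L] else NA_character_,
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, recs)
  dup <- duplicated(tab[, c("gene_id", "genome_id")])
  if (any(dup)) {
    stop("duplicate gene_id within genome at line(s) ",
         paste(which(dup) + 1L, collapse = ", "), call. = FALSE)
  }
  tab
}

#' @rdname read_gene_table
#' @param table data.frame as returned by `read_gene_table`.
#' @export
write_gene_table <- function(table, path) {
  out <- data.frame(
    gene_id = table$gene_id, genome_id = table$genome_id,
    essential = as.integer(table$essential),
    drug_target = as.integer(table$drug_target),
    ko_id = ifelse(is.na(table$ko_id), "", table$ko_id),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Parse a Gene Ontology OBO 1.2 file
#'
#' Reads `[Term]` stanzas, keeping id, name, namespace, obsolete flag and
#' the `is_a` plus `relationship: part_of` parent edges (the edges used for
#' true-path propagation). Obsolete terms keep no edges. The edge graph is
#' checked for acyclicity.
#'
#' @param path OBO file.
#' @return object of class `go_dag`: list with `terms` (named list of
#'   `name`, `namespace`, `obsolete`) and `parents` (named list of parent
#'   term ids).
#' @export
read_obo <- function(path) {
  lines <- readLines(path)
  terms <- list()
  parents <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !is.null(cur$id)) {
      terms[[cur$id]] <<- list(name = cur$name %||% "",
                               namespace = cur$namespace %||% "",
                               obsolete = isTRUE(cur$obsolete))
      parents[[cur$id]] <<- if (isTRUE(cur$obsolete)) character(0) else
        unique(cur$parents)
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      flush()
      cur <- list(parents = character(0))
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      flush()
      cur <- NULL
      in_term <- FALSE
    } else if (in_term && nzchar(ln)) {
      kv <- regmatches(ln, regexpr(":", ln, fixed = TRUE), invert = TRUE)[[1]]
      if (length(kv) != 2L) next
      key <- kv[1L]
      val <- trimws(sub("!.*$", "", kv[2L]))
      if (key == "id") cur$id <- val
      else if (key == "name") cur$name <- trimws(kv[2L])
      else if (key == "namespace") cur$namespace <- val
      else if (key == "is_obsolete") cur$obsolete <- val == "true"
      else if (key == "is_a") cur$parents <- c(cur$parents, val)
      else if (key == "relationship") {
        rel <- strsplit(val, "[[:space:]]+")[[1L]]
        if (length(rel) >= 2L && rel[1L] == "part_of") {
          cur$parents <- c(cur$parents, rel[2L])
        }
      }
    }
  }
  flush()
  dag <- structure(list(terms = terms, parents = parents), class = "go_dag")
  check_acyclic(dag)
  dag
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_acyclic <- function(dag) {
  state <- new.env(parent = emptyenv())  # 1 = in stack, 2 = done
  visit <- function(id) {
    s <- state[[id]] %||% 0L
    if (s == 1L) stop("cycle error: is_a/part_of cycle at term ", id,
                      call. = FALSE)
    if (s == 2L) return(invisible())
    assign(id, 1L, envir = state)
    for (p in dag$parents[[id]]) {
      if (!is.null(dag$parents[[p]])) visit(p)
    }
    assign(id, 2L, envir = state)
  }
  for (id in names(dag$parents)) visit(id)
  invisible(dag)
}

#' Read direct GO annotations from a GAF 2.x file
#'
#' Comment lines (`!`) are skipped; only columns 2 (object id) and 5 (GO
#' id) are used. When a DAG is supplied, annotations to unknown terms are
#' skipped with a warning and counted.
#'
#' @param path GAF file.
#' @param dag optional [read_obo()] result used to validate term ids.
#' @return list with `annotations` (named list `gene -> character vector` of
#'   direct term ids) and integer `n_skipped`.
#' @export
read_gaf <- function(path, dag = NULL) {
  lines <- readLines(path)
  ann <- list()
  n_skipped <- 0L
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "!")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L) {
      stop("line ", i, ": malformed GAF line (fewer than 5 columns)",
           call. = FALSE)
    }
    gene <- f[2L]
    term <- f[5L]
    if (!is.null(dag) && is.null(dag$terms[[term]])) {
      n_skipped <- n_skipped + 1L
      next
    }
    ann[[gene]] <- unique(c(ann[[gene]], term))
  }
  if (n_skipped > 0L) {
    warning(n_skipped, " annotation line(s) referenced unknown GO terms ",
            "and were skipped", call. = FALSE)
  }
  list(annotations = ann, n_skipped = n_skipped)
}

#' Write pipeline result tables
#'
#' Each data.frame in `results` is written as `<name>.tsv`; any
#' non-data.frame element (e.g. the provenance block) is written as
#' `<name>.json`.
#'
#' @param results named list of data.frames / lists.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(results)) {
    x <- results[[nm]]
    if (is.data.frame(x)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    } else {
      p <- file.path(dir, paste0(nm, ".json"))
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
    }
    paths <- c(paths, p)
  }
  invisible(paths)
}
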