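#' Propagate GO annotations up the ontology (true-path rule)
#'
#' A gene annotated to a term is implicitly annotated to every ancestor of
#' that term via `is_a` and `part_of` edges. Annotations to terms absent
#' from the DAG are skipped and tallied. The closure is idempotent.
#'
#' @param direct named list `gene -> character vector` of direct term ids.
#' @param dag a [read_obo()] result.
#' @return named list `gene -> character vector` of terms closed upward,
#'   with attribute `n_skipped`.
#' @export
propagate_annotations <- function(direct, dag) {
  anc_cache <- new.env(parent = emptyenv())
  ancestors <- function(term) {
    hit <- anc_cache[[term]]
    if (!is.null(hit)) return(hit)
    ps <- dag$parents[[term]]
    ps <- ps[vapply(ps, function(p) !is.null(dag$terms[[p]]), logical(1))]
    res <- unique(c(term, unlist(lapply(ps, ancestors), use.names = FALSE)))
    assign(term, res, envir = anc_cache)
    res
  }
  n_skipped <- 0L
  out <- lapply(direct, function(terms) {
    known <- terms[vapply(terms, function(t) !is.null(dag$terms[[t]]),
                          logical(1))]
    n_skipped <<- n_skipped + (length(terms) - length(known))
    unique(unlist(lapply(known, ancestors), use.names = FALSE))
  })
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Term-for-term GO over-representation of a study set
#'
#' For every term annotated to at least one population gene, tests
#' over-representation in the study set with a one-sided hypergeometric
#' tail: `p = P(X >= study_count)` for
#' `X ~ Hypergeom(pop_n, pop_count, study_n)`. Raw p-values are reported
#' (the convention of term-for-term analyses); a Benjamini-Hochberg column
#' is emitted alongside. Genes without any annotation stay in the
#' denominators unless `annotated_only = TRUE`.
#'
#' @param study character vector of study gene ids (must be a subset of
#'   `population`).
#' @param population character vector of population gene ids.
#' @param annotations propagated annotations from
#'   [propagate_annotations()].
#' @param dag optional DAG supplying term descriptions.
#' @param annotated_only if TRUE, restrict both sets to genes with at least
#'   one annotation before counting.
#' @return data.frame sorted ascending by p: `term_id`, `p_value`, `p_bh`,
#'   `study_count`, `study_n`, `pop_count`, `pop_n`, `study_fraction`,
#'   `population_fraction`, `description`.
#' @export
term_for_term <- function(study, population, annotations, dag = NULL,
                          annotated_only = FALSE) {
  study <- unique(study)
  population <- unique(population)
  if (!all(study %in% population)) {
    stop("study set must be a subset of the population", call. = FALSE)
  }
  if (length(population) == 0L) stop("empty population", call. = FALSE)
  if (annotated_only) {
    has_ann <- names(annotations)[vapply(annotations, length, 1L) > 0L]
    population <- intersect(population, has_ann)
    study <- intersect(study, has_ann)
  }
  pop_n <- length(population)
  study_n <- length(study)

  count_terms <- function(genes) {
    t <- unlist(annotations[intersect(genes, names(annotations))],
                use.names = FALSE)
    if (is.null(t)) return(integer(0))
    table(t)
  }
  pop_tab <- count_terms(population)
  study_tab <- count_terms(study)
  terms <- names(pop_tab)
  if (length(terms) == 0L) {
    return(data.frame(term_id = character(0), p_value = numeric(0),
                      p_bh = numeric(0), study_count = integer(0),
                      study_n = integer(0), pop_count = integer(0),
                      pop_n = integer(0), study_fraction = numeric(0),
                      population_fraction = numeric(0),
                      description = character(0), stringsAsFactors = FALSE))
  }
  pop_count <- as.integer(pop_tab[terms])
  study_count <- as.integer(ifelse(terms %in% names(study_tab),
                                   study_tab[terms], 0L))
  p <- stats::phyper(study_count - 1L, pop_count, pop_n - pop_count,
                     study_n, lower.tail = FALSE)
  desc <- if (!is.null(dag)) {
    vapply(terms, function(t) dag$terms[[t]]$name %||% "", character(1))
  } else rep(NA_character_, length(terms))
  out <- data.frame(
    term_id = terms, p_value = p,
    p_bh = stats::p.adjust(p, method = "BH"),
    study_count = study_count, study_n = study_n,
    pop_count = pop_count, pop_n = pop_n,
    study_fraction = if (study_n > 0) study_count / study_n else NA_real_,
    population_fraction = pop_count / pop_n,
    description = desc, stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
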