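# Seeded synthetic-data generation: random DAG ontologies, gene
# annotations, and miRNA target sets with planted clusters, so every stage
# of the pipeline can be exercised without external downloads.

#' Specification for synthetic data
#'
#' The defaults describe the conditions under which planted-cluster
#' recovery is assessed: 4 groups of miRNAs whose targets are annotated in
#' 4 disjoint branches of a 60-term ontology. Terms in different branches
#' share only the root, so between-group miRNA similarity is exactly 0 and
#' the planted block structure is the situation the clustering method
#' assumes.
#'
#' @param n_terms Total ontology terms, root included (default 60).
#' @param max_children Maximum children per term in the random DAG
#'   (default 4).
#' @param part_of_fraction Probability that a generated edge is `part_of`
#'   rather than `is_a` (default 0.2).
#' @param n_genes Number of annotated genes (default 40, split evenly over
#'   clusters).
#' @param terms_per_gene Integer range of directly annotated terms per gene
#'   (default `2:4`).
#' @param n_mirnas Number of miRNAs (default 40, split evenly).
#' @param n_clusters Number of planted clusters (default 4).
#' @param targets_per_mirna Integer range of target genes per miRNA
#'   (default `3:6`).
#' @param within_cluster_target_overlap Fraction of each miRNA's targets
#'   drawn from its cluster's shared core gene set (default 0.5).
#' @param labeled_fraction Fraction of miRNAs per cluster given a disease
#'   label (default 0.9).
#' @param seed Random seed (default 1).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_terms = 60, max_children = 4,
                           part_of_fraction = 0.2,
                           n_genes = 40, terms_per_gene = 2:4,
                           n_mirnas = 40, n_clusters = 4,
                           targets_per_mirna = 3:6,
                           within_cluster_target_overlap = 0.5,
                           labeled_fraction = 0.9, seed = 1) {
  stopifnot(n_terms >= 2, max_children >= 1,
            part_of_fraction >= 0, part_of_fraction <= 1,
            n_genes >= 1, all(terms_per_gene >= 1),
            n_mirnas >= 1, n_clusters >= 1, all(targets_per_mirna >= 1),
            within_cluster_target_overlap >= 0,
            within_cluster_target_overlap <= 1,
            labeled_fraction >= 0, labeled_fraction <= 1)
  structure(
    list(n_terms = n_terms, max_children = max_children,
         part_of_fraction = part_of_fraction, n_genes = n_genes,
         terms_per_gene = terms_per_gene, n_mirnas = n_mirnas,
         n_clusters = n_clusters, targets_per_mirna = targets_per_mirna,
         within_cluster_target_overlap = within_cluster_target_overlap,
         labeled_fraction = labeled_fraction, seed = seed),
    class = "synthetic_spec"
  )
}

synthetic_term_ids <- function(n) sprintf("GO:%07d", seq_len(n))

#' Generate a random rooted DAG ontology
#'
#' Terms are added one at a time; each new term attaches to 1-2 existing
#' terms with spare child capacity, so the result is acyclic, connected,
#' and has the first term as its unique root. Relationship labels are
#' drawn `part_of` with probability `part_of_fraction`. Deterministic per
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @param namespace Namespace assigned to every term (default
#'   `"molecular_function"`).
#' @return A `go_ontology`.
#' @export
generate_synthetic_ontology <- function(spec = synthetic_spec(),
                                        namespace = "molecular_function") {
  withr::with_seed(spec$seed, {
    ids <- synthetic_term_ids(spec$n_terms)
    edges <- random_dag_edges(ids, spec$max_children, spec$part_of_fraction)
    make_ontology(ids, edges, namespace)
  })
}

# Attach each term (beyond the first) to 1-2 earlier terms with capacity.
random_dag_edges <- function(ids, max_children, part_of_fraction,
                             offset = 0L) {
  n <- length(ids)
  if (n == 1) {
    return(tibble(child = character(0), parent = character(0),
                  relationship = character(0)))
  }
  child_count <- stats::setNames(integer(n), ids)
  rows <- vector("list", n - 1)
  for (i in seq(2, n)) {
    open <- ids[seq_len(i - 1)][child_count[seq_len(i - 1)] < max_children]
    if (length(open) == 0) {
      abort("infeasible spec: max_children too small for n_terms")
    }
    n_parents <- min(length(open), sample(c(1L, 1L, 2L), 1))
    parents <- sample(open, n_parents)
    child_count[parents] <- child_count[parents] + 1L
    rows[[i - 1]] <- tibble(
      child = ids[[i]], parent = parents,
      relationship = ifelse(stats::runif(n_parents) < part_of_fraction,
                            "part_of", "is_a")
    )
  }
  bind_rows(rows)
}

make_ontology <- function(ids, edges, namespace) {
  structure(
    list(terms = ids,
         edges = arrange(edges, .data$child, .data$parent),
         namespace = stats::setNames(rep(namespace, length(ids)), ids),
         obsolete = character(0), alt_id = character(0),
         n_dropped_edges = 0L),
    class = "go_ontology"
  )
}

#' Generate a miRNA dataset with planted clusters
#'
#' Builds an ontology whose non-root terms fall into `n_clusters` disjoint
#' branches hanging off the root; each cluster's genes are annotated with
#' terms of its branch only, and each cluster's miRNAs target that
#' cluster's genes, sharing a core target set controlled by
#' `within_cluster_target_overlap`. A fraction of miRNAs per cluster
#' carries the disease label `"disease_<cluster>"`; the rest stay
#' unannotated. Deterministic per seed.
#'
#' @param spec A [synthetic_spec()].
#' @param namespace Namespace for the generated terms.
#' @return A list with `dataset` (a [mirna_dataset()]), `truth` (tibble
#'   `mirna_id`, `cluster`), `ontology`, `annotations`, `targets`,
#'   `diseases` (the raw tables, reusable through the file writers).
#' @examples
#' sim <- generate_planted_mirna_dataset(synthetic_spec(
#'   n_terms = 21, n_genes = 8, n_mirnas = 8, n_clusters = 2, seed = 7
#' ))
#' sim$truth
#' @export
generate_planted_mirna_dataset <- function(spec = synthetic_spec(),
                                           namespace = "molecular_function") {
  n_branch_terms <- (spec$n_terms - 1) %/% spec$n_clusters
  genes_per_cluster <- spec$n_genes %/% spec$n_clusters
  mirnas_per_cluster <- spec$n_mirnas %/% spec$n_clusters
  if (n_branch_terms < max(spec$terms_per_gene)) {
    abort("infeasible spec: branches too small for terms_per_gene")
  }
  if (genes_per_cluster < max(spec$targets_per_mirna)) {
    abort("infeasible spec: too few genes per cluster for targets_per_mirna")
  }
  if (n_branch_terms < 1 || genes_per_cluster < 1 || mirnas_per_cluster < 1) {
    abort("infeasible spec: n_clusters larger than terms, genes, or miRNAs")
  }

  withr::with_seed(spec$seed, {
    ids <- synthetic_term_ids(1 + n_branch_terms * spec$n_clusters)
    root <- ids[[1]]
    branch_terms <- split(ids[-1],
                          rep(seq_len(spec$n_clusters), each = n_branch_terms))
    edges <- bind_rows(map(branch_terms, function(terms) {
      inner <- random_dag_edges(terms, spec$max_children, spec$part_of_fraction)
      bind_rows(
        tibble(child = terms[[1]], parent = root, relationship = "is_a"),
        inner
      )
    }))
    ontology <- make_ontology(ids, edges, namespace)

    annotations <- bind_rows(map(seq_len(spec$n_clusters), function(c) {
      pool <- branch_terms[[c]]
      bind_rows(map(seq_len(genes_per_cluster), function(g) {
        k <- sample_range(spec$terms_per_gene)
        tibble(
          gene_id = sprintf("gene_c%d_%02d", c, g),
          term = sample(pool, min(k, length(pool)))
        )
      }))
    }))

    cluster_genes <- map(seq_len(spec$n_clusters), function(c)
      sprintf("gene_c%d_%02d", c, seq_len(genes_per_cluster)))

    targets <- bind_rows(map(seq_len(spec$n_clusters), function(c) {
      pool <- cluster_genes[[c]]
      core_size <- max(1, round(spec$within_cluster_target_overlap *
                                  mean(spec$targets_per_mirna)))
      core <- sample(pool, min(core_size, length(pool)))
      bind_rows(map(seq_len(mirnas_per_cluster), function(m) {
        n_t <- sample_range(spec$targets_per_mirna)
        n_core <- min(length(core), round(spec$within_cluster_target_overlap * n_t))
        picked <- c(
          if (n_core > 0) sample(core, n_core) else character(0),
          sample(setdiff(pool, core), min(n_t - n_core, length(pool) - length(core)))
        )
        tibble(mirna_id = sprintf("mir_c%d_%02d", c, m), gene_id = unique(picked))
      }))
    }))

    truth <- distinct(tibble(
      mirna_id = targets$mirna_id,
      cluster = as.integer(sub("^mir_c(\\d+)_.*$", "\\1", targets$mirna_id))
    ))

    diseases <- truth |>
      group_by(.data$cluster) |>
      filter(dplyr::row_number() <= ceiling(spec$labeled_fraction * n())) |>
      ungroup() |>
      mutate(disease = sprintf("disease_%d", .data$cluster)) |>
      select("mirna_id", "disease")

    dataset <- mirna_dataset(ontology, annotations, targets,
                             diseases = diseases, namespace = namespace)
    list(dataset = dataset, truth = truth, ontology = ontology,
         annotations = annotations, targets = targets, diseases = diseases)
  })
}

sample_range <- function(range) {
  if (length(range) == 1) range else sample(range, 1)
}

#' Write synthetic (or any) inputs in the standard file formats
#'
#' These writers emit the same formats the readers consume, so generated
#' data can exercise the full file-based pipeline: OBO for the ontology,
#' 2-column TSVs for annotations, targets and diseases.
#'
#' @param ontology A `go_ontology`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_obo <- function(ontology, path) {
  stopifnot(inherits(ontology, "go_ontology"))
  by_child <- split(ontology$edges, ontology$edges$child)
  stanzas <- map_chr(ontology$terms, function(t) {
    lines <- c("[Term]", paste0("id: ", t))
    ns <- ontology$namespace[[t]]
    if (!is.na(ns)) lines <- c(lines, paste0("namespace: ", ns))
    e <- by_child[[t]]
    if (!is.null(e)) {
      lines <- c(lines,
                 paste0("is_a: ", e$parent[e$relationship == "is_a"]),
                 if (any(e$relationship == "part_of"))
                   paste0("relationship: part_of ",
                          e$parent[e$relationship == "part_of"]))
    }
    paste(lines, collapse = "\n")
  })
  readr::write_lines(c("format-version: 1.2", "", paste(stanzas, collapse = "\n\n")),
                     path)
  invisible(path)
}

#' @rdname write_obo
#' @param annotations Tibble with columns `gene_id`, `term`.
#' @export
write_annotations_tsv <- function(annotations, path) {
  readr::write_tsv(annotations[, c("gene_id", "term")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_obo
#' @param targets Tibble with columns `mirna_id`, `gene_id`.
#' @export
write_targets_tsv <- function(targets, path) {
  readr::write_tsv(targets[, c("mirna_id", "gene_id")], path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_obo
#' @param diseases Tibble with columns `mirna_id`, `disease`.
#' @export
write_diseases_tsv <- function(diseases, path) {
  readr::write_tsv(diseases[, c("mirna_id", "disease")], path, col_names = FALSE)
  invisible(path)
}
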