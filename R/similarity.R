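# The similarity cascade: term-graph pair -> gene pair -> gene set vs gene
# -> miRNA pair -> distance matrix.

#' Similarity of two term graphs
#'
#' The similarity is the weighted-IC mass of the common terms relative to
#' all terms of the merged graph:
#' `sum(wIC(common)) / (sum(wIC(common)) + sum(wIC(uncommon)))`.
#' When the MICA of the two leaves is the root, the similarity is 0 (this
#' also covers the degenerate case of two bare-root graphs); identical term
#' graphs have similarity 1.
#'
#' @param tg_a,tg_b `term_graph` objects with the same root.
#' @param weights Output of [relationship_weights()].
#' @param log_base Logarithm base for information content.
#' @return Numeric in `[0, 1]`.
#' @examples
#' we <- load_worked_example()
#' term_graph_similarity(we$tg_a, we$tg_b)  # ~0.306
#' @export
term_graph_similarity <- function(tg_a, tg_b, weights = relationship_weights(),
                                  log_base = 10) {
  core_similarity(context_core(tg_a, tg_b, weights, log_base))
}

#' Similarity of two genes
#'
#' Averages, over the leaf term graphs of both genes, the best-matching
#' term-graph similarity against the other gene:
#' `(sum_i max_j s(tg1_i, tg2_j) + sum_j max_i s(tg1_i, tg2_j)) / (n1 + n2)`.
#'
#' @param g1,g2 `go_graph` objects in the same namespace.
#' @inheritParams term_graph_similarity
#' @return Numeric in `[0, 1]`; 1 when the graphs are identical.
#' @export
gene_similarity <- function(g1, g2, weights = relationship_weights(),
                            log_base = 10) {
  tgs1 <- extract_leaf_term_graphs(g1)
  tgs2 <- extract_leaf_term_graphs(g2)
  pair_sim <- function(a, b) term_graph_similarity(a, b, weights, log_base)
  gene_similarity_impl(g1$leaf_terms, g2$leaf_terms,
                       stats::setNames(tgs1, g1$leaf_terms),
                       stats::setNames(tgs2, g2$leaf_terms),
                       pair_sim)
}

# Shared Eq-5 core over precomputed term graphs and a pairwise term-graph
# similarity function (possibly memoised).
gene_similarity_impl <- function(leaves1, leaves2, tg1, tg2, pair_sim) {
  if (length(leaves1) == 0 || length(leaves2) == 0) {
    abort("a gene GO graph must have at least one leaf term")
  }
  smat <- matrix(0, length(leaves1), length(leaves2))
  for (i in seq_along(leaves1)) {
    for (j in seq_along(leaves2)) {
      smat[i, j] <- pair_sim(tg1[[leaves1[[i]]]], tg2[[leaves2[[j]]]])
    }
  }
  (sum(apply(smat, 1, max)) + sum(apply(smat, 2, max))) /
    (length(leaves1) + length(leaves2))
}

#' Similarity between a gene set and a gene
#'
#' The maximum of the pairwise gene similarities between the set members
#' and the gene. The maximum (not the average) is used because averaging
#' underestimates the similarity a set owes to its single best-matching
#' member.
#'
#' @param gene_set Non-empty list of `go_graph` objects.
#' @param g A `go_graph`.
#' @inheritParams term_graph_similarity
#' @return Numeric in `[0, 1]`.
#' @export
geneset_gene_similarity <- function(gene_set, g, weights = relationship_weights(),
                                    log_base = 10) {
  if (length(gene_set) == 0) abort("gene_set must be non-empty")
  max(map_dbl(gene_set, gene_similarity, g2 = g, weights = weights,
              log_base = log_base))
}

#' Similarity of two miRNAs from their target-gene sets
#'
#' With target sets `GS1` (s genes) and `GS2` (k genes):
#' `(sum_i sim(GS1, g2_i) + sum_j sim(GS2, g1_j)) / (s + k)`, where each
#' term is a gene-set-versus-gene similarity.
#'
#' @param targets_1,targets_2 Non-empty lists of `go_graph` objects, the GO
#'   graphs of the two miRNAs' target genes.
#' @inheritParams term_graph_similarity
#' @return Numeric in `[0, 1]`.
#' @export
mirna_pair_similarity <- function(targets_1, targets_2,
                                  weights = relationship_weights(),
                                  log_base = 10) {
  if (length(targets_1) == 0 || length(targets_2) == 0) {
    abort("both miRNAs must have at least one annotated target gene")
  }
  s1 <- map_dbl(targets_2, function(g) geneset_gene_similarity(targets_1, g, weights, log_base))
  s2 <- map_dbl(targets_1, function(g) geneset_gene_similarity(targets_2, g, weights, log_base))
  (sum(s1) + sum(s2)) / (length(targets_1) + length(targets_2))
}

#' miRNA distance from similarity
#'
#' `dsim = 1 - sim`.
#'
#' @param sim Numeric vector of similarities in `[0, 1]`.
#' @return `1 - sim`.
#' @export
mirna_distance <- function(sim) {
  if (any(!is.finite(sim)) || any(sim < 0 | sim > 1)) {
    abort("similarities must lie in [0, 1]")
  }
  1 - sim
}

#' Assemble a miRNA dataset
#'
#' Joins an ontology, gene annotations and a miRNA-to-target-gene table
#' (plus optional disease labels) into the object consumed by
#' [build_distance_matrix()]. Annotations are restricted to one namespace;
#' genes without a usable annotation and miRNAs left with no annotated
#' target are dropped with a warning. Repeated miRNA-gene rows (one per
#' evidence line in target databases) collapse to one target per gene.
#'
#' @param ontology A `go_ontology`.
#' @param annotations Tibble/data frame with columns `gene_id`, `term`.
#' @param targets Tibble/data frame with columns `mirna_id`, `gene_id`.
#' @param diseases Optional tibble with columns `mirna_id`, `disease`
#'   (normalized via [disease_labels()]).
#' @param namespace Namespace of the analysis (default
#'   `"molecular_function"`).
#' @return An object of class `mirna_dataset`.
#' @export
mirna_dataset <- function(ontology, annotations, targets, diseases = NULL,
                          namespace = "molecular_function") {
  stopifnot(inherits(ontology, "go_ontology"))
  annotations <- as_tibble(annotations)
  targets <- distinct(as_tibble(targets)[, c("mirna_id", "gene_id")])
  stopifnot(all(c("gene_id", "term") %in% names(annotations)))

  keep <- annotations$term %in% ontology$terms &
    !is.na(ontology$namespace[annotations$term]) &
    ontology$namespace[annotations$term] == namespace
  dropped_ann <- sum(!keep)
  if (dropped_ann > 0) {
    warn(sprintf("mirna_dataset: dropped %d annotation row(s) outside namespace '%s' or unknown",
                 dropped_ann, namespace))
  }
  annotations <- annotations[keep, ]
  if (nrow(annotations) == 0) abort("no usable annotations in the chosen namespace")

  gene_terms <- split(annotations$term, annotations$gene_id)
  gene_graphs <- purrr::imap(gene_terms, function(ts, g)
    build_gene_go_graph(ontology, unique(ts), gene_id = g))

  annotated_genes <- names(gene_graphs)
  targets_ok <- filter(targets, .data$gene_id %in% annotated_genes)
  mirna_ids <- unique(targets$mirna_id)
  usable <- unique(targets_ok$mirna_id)
  dropped_mirnas <- setdiff(mirna_ids, usable)
  if (length(dropped_mirnas) > 0) {
    warn(sprintf("mirna_dataset: dropped %d miRNA(s) with no annotated target: %s",
                 length(dropped_mirnas), paste(dropped_mirnas, collapse = ", ")))
  }
  structure(
    list(ontology = ontology,
         namespace = namespace,
         gene_graphs = gene_graphs,
         targets = split(targets_ok$gene_id, factor(targets_ok$mirna_id, levels = usable)),
         mirna_ids = mirna_ids[mirna_ids %in% usable],
         diseases = if (is.null(diseases)) NULL else disease_labels(diseases)),
    class = "mirna_dataset"
  )
}

#' @export
print.mirna_dataset <- function(x, ...) {
  cat(sprintf("<mirna_dataset> %d miRNAs, %d annotated genes, namespace %s%s\n",
              length(x$mirna_ids), length(x$gene_graphs), x$namespace,
              if (is.null(x$diseases)) "" else sprintf(", %d disease rows", nrow(x$diseases))))
  invisible(x)
}

#' Pairwise miRNA distance matrix
#'
#' Computes the symmetric h-by-h matrix of miRNA distances
#' `dsim = 1 - sim` over the dataset's miRNAs, in input order. Gene-pair
#' and term-pair similarities are cached so each unordered pair is computed
#' once.
#'
#' @param dataset A [mirna_dataset()].
#' @param weights Output of [relationship_weights()].
#' @param log_base Logarithm base for information content.
#' @param cache Use the pair caches (default `TRUE`; `FALSE` recomputes
#'   every pair, for verification).
#' @return An object of class `mirna_dist`: list with `ids`, `values`
#'   (matrix, zero diagonal), `kind = "distance"`.
#' @export
build_distance_matrix <- function(dataset, weights = relationship_weights(),
                                  log_base = 10, cache = TRUE) {
  stopifnot(inherits(dataset, "mirna_dataset"))
  ids <- dataset$mirna_ids
  if (length(ids) < 2) abort("need at least 2 miRNAs with usable targets")

  tg_cache <- new.env(parent = emptyenv())
  term_graph_for <- function(leaf) {
    tg <- tg_cache[[leaf]]
    if (is.null(tg)) {
      g <- build_gene_go_graph(dataset$ontology, leaf)
      tg <- term_graph_of(g, leaf)
      tg_cache[[leaf]] <- tg
    }
    tg
  }

  ts_cache <- new.env(parent = emptyenv())
  term_sim <- function(a, b) {
    if (!cache) return(term_graph_similarity(a, b, weights, log_base))
    key <- paste(sort(c(a$leaf, b$leaf)), collapse = "|")
    val <- ts_cache[[key]]
    if (is.null(val)) {
      val <- term_graph_similarity(a, b, weights, log_base)
      ts_cache[[key]] <- val
    }
    val
  }

  gs_cache <- new.env(parent = emptyenv())
  gene_sim <- function(ga, gb) {
    key <- paste(sort(c(ga, gb)), collapse = "|")
    if (cache && !is.null(val <- gs_cache[[key]])) return(val)
    g1 <- dataset$gene_graphs[[ga]]
    g2 <- dataset$gene_graphs[[gb]]
    tg1 <- stats::setNames(lapply(g1$leaf_terms, term_graph_for), g1$leaf_terms)
    tg2 <- stats::setNames(lapply(g2$leaf_terms, term_graph_for), g2$leaf_terms)
    val <- gene_similarity_impl(g1$leaf_terms, g2$leaf_terms, tg1, tg2, term_sim)
    if (cache) gs_cache[[key]] <- val
    val
  }

  h <- length(ids)
  d <- matrix(0, h, h, dimnames = list(ids, ids))
  for (i in seq_len(h - 1)) {
    gs1 <- dataset$targets[[ids[[i]]]]
    for (j in seq((i + 1), h)) {
      gs2 <- dataset$targets[[ids[[j]]]]
      # Eq-6 terms through the gene-pair cache
      set_vs_gene <- function(set, g) max(vapply(set, gene_sim, numeric(1), gb = g))
      sim <- (sum(vapply(gs2, function(g) set_vs_gene(gs1, g), numeric(1))) +
                sum(vapply(gs1, function(g) set_vs_gene(gs2, g), numeric(1)))) /
        (length(gs1) + length(gs2))
      d[i, j] <- d[j, i] <- mirna_distance(sim)
    }
  }
  structure(list(ids = ids, values = d, kind = "distance"), class = "mirna_dist")
}

#' @export
print.mirna_dist <- function(x, ...) {
  cat(sprintf("<mirna_dist> %d miRNAs (kind: %s)\n", length(x$ids), x$kind))
  print(head(round(x$values, 3), 6))
  invisible(x)
}

#' @export
as.matrix.mirna_dist <- function(x, ...) x$values

#' @rdname tidy
#' @param x A `mirna_dist` object.
#' @param ... Unused.
#' @return For `mirna_dist`: a long tibble with columns `mirna_1`,
#'   `mirna_2`, `distance` (each unordered pair once).
#' @method tidy mirna_dist
#' @export
tidy.mirna_dist <- function(x, ...) {
  idx <- which(upper.tri(x$values), arr.ind = TRUE)
  tibble(
    mirna_1 = x$ids[idx[, 1]],
    mirna_2 = x$ids[idx[, 2]],
    distance = x$values[idx]
  )
}

#' Write / read a distance matrix as TSV
#'
#' The matrix is written with an id header row and an id first column;
#' `#`-prefixed provenance lines are allowed at the top and skipped on read.
#'
#' @param x A `mirna_dist`.
#' @param path Output path.
#' @param header Optional character vector of provenance lines (written
#'   `#`-prefixed).
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` returns a `mirna_dist`.
#' @export
write_distance_matrix <- function(x, path, header = NULL) {
  stopifnot(inherits(x, "mirna_dist"))
  lines <- character(0)
  if (!is.null(header)) lines <- paste0("# ", header)
  body <- c(
    paste(c("mirna_id", x$ids), collapse = "\t"),
    vapply(seq_along(x$ids), function(i)
      paste(c(x$ids[[i]], sprintf("%.17g", x$values[i, ])), collapse = "\t"),
      character(1))
  )
  readr::write_lines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  tab <- readr::read_tsv(path, comment = "#",
                         col_types = readr::cols(mirna_id = readr::col_character(),
                                                 .default = readr::col_double()),
                         progress = FALSE)
  ids <- tab$mirna_id
  m <- as.matrix(tab[, -1])
  rownames(m) <- ids
  structure(list(ids = ids, values = m, kind = "distance"), class = "mirna_dist")
}

#' Read a miRNA-to-target-gene table
#'
#' Accepts either a 2-column TSV `mirna_id<TAB>gene_id` (header optional) or
#' a miRTarBase-style export with named columns `miRNA` and `Target Gene`.
#' Repeated evidence rows are deduplicated.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `mirna_id`, `gene_id`.
#' @export
read_mirna_targets <- function(path) {
  first <- readr::read_lines(path, n_max = 50)
  first <- first[!grepl("^#", first) & nzchar(first)]
  if (length(first) == 0) abort("empty targets file", class = "mirgosim_empty_error")
  header <- strsplit(first[[1]], "\t", fixed = TRUE)[[1]]
  if (all(c("miRNA", "Target Gene") %in% header)) {
    raw <- readr::read_tsv(path, comment = "#",
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    out <- tibble(mirna_id = raw[["miRNA"]], gene_id = raw[["Target Gene"]])
  } else {
    raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (ncol(raw) < 2) abort("targets TSV must have two columns: mirna_id, gene_id")
    out <- tibble(mirna_id = raw[[1]], gene_id = raw[[2]])
    if (nrow(out) > 0 && tolower(out$mirna_id[[1]]) %in% c("mirna_id", "mirna")) {
      out <- out[-1, ]
    }
  }
  out <- distinct(filter(out, !is.na(.data$mirna_id), !is.na(.data$gene_id)))
  if (nrow(out) == 0) abort("no usable miRNA-target rows", class = "mirgosim_empty_error")
  out
}
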