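# Ontology parsing and per-gene GO graph construction.

#' Parse an OBO ontology file
#'
#' Reads an OBO 1.2/1.4 file into an ontology object. Only `is_a` and
#' `relationship: part_of` edges are ingested; every other relationship type
#' (`regulates`, `occurs_in`, ...) is dropped and the dropped count reported.
#' Obsolete terms are flagged and excluded from graph construction; `alt_id`
#' identifiers are recorded so annotations using them can be mapped to the
#' primary id.
#'
#' Edges are stored child -> parent, following the direction of the OBO
#' `is_a` statement itself. Under this convention the namespace root is the
#' unique term with out-degree 0 (it only receives edges when viewed from its
#' children).
#'
#' @param path Path to an OBO file.
#' @param namespace Optional namespace filter, one of
#'   `"biological_process"`, `"molecular_function"`,
#'   `"cellular_component"`. When given, only terms of that namespace (and
#'   edges among them) are kept.
#' @return An object of class `go_ontology`: a list with `terms` (character),
#'   `edges` (tibble with columns `child`, `parent`, `relationship`),
#'   `namespace` (named character), `obsolete` (character), `alt_id`
#'   (named character mapping alternate to primary ids), and
#'   `n_dropped_edges` (count of non-is_a/part_of relationships skipped).
#' @examples
#' obo <- system.file("extdata", "worked_example.obo", package = "mirgosim")
#' onto <- parse_obo(obo)
#' onto$edges
#' @export
parse_obo <- function(path, namespace = NULL) {
  lines <- readr::read_lines(path)
  in_term <- FALSE
  in_other_stanza <- FALSE
  cur <- NULL
  terms <- list()
  flush <- function() if (!is.null(cur) && !is.null(cur$id)) terms[[length(terms) + 1L]] <<- cur

  for (i in seq_along(lines)) {
    line <- sub("!.*$", "", lines[[i]])
    line <- trimws(line)
    if (line == "") next
    if (line == "[Term]") {
      flush()
      cur <- list(is_a = character(0), part_of = character(0),
                  alt_id = character(0), obsolete = FALSE,
                  n_dropped = 0L)
      in_term <- TRUE
      in_other_stanza <- FALSE
      next
    }
    if (grepl("^\\[.*\\]$", line)) {
      flush()
      cur <- NULL
      in_term <- FALSE
      in_other_stanza <- TRUE
      next
    }
    if (!grepl("^[A-Za-z_-]+\\s*:", line)) {
      abort(sprintf("malformed OBO line %d: '%s'", i, lines[[i]]),
            class = "mirgosim_parse_error")
    }
    if (!in_term) next
    key <- sub(":.*$", "", line)
    val <- trimws(sub("^[A-Za-z_-]+\\s*:\\s*", "", line))
    if (key == "id") cur$id <- val
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "is_a") cur$is_a <- c(cur$is_a, strsplit(val, "\\s+")[[1]][1])
    else if (key == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2) {
        abort(sprintf("malformed relationship at OBO line %d: '%s'", i, lines[[i]]),
              class = "mirgosim_parse_error")
      }
      if (parts[[1]] == "part_of") cur$part_of <- c(cur$part_of, parts[[2]])
      else cur$n_dropped <- cur$n_dropped + 1L
    }
  }
  flush()
  if (length(terms) == 0) {
    abort("no [Term] stanzas found", class = "mirgosim_parse_error")
  }

  ids <- map_chr(terms, "id")
  obsolete <- ids[map_lgl_safe(terms, "obsolete")]
  ns <- map_chr(terms, function(t) t$namespace %||% NA_character_)
  names(ns) <- ids
  alt <- unlist(map(terms, function(t) {
    if (length(t$alt_id) == 0) return(NULL)
    stats::setNames(rep(t$id, length(t$alt_id)), t$alt_id)
  }))
  n_dropped <- sum(map_int(terms, "n_dropped"))
  if (n_dropped > 0) {
    inform(sprintf("parse_obo: dropped %d edge(s) with relationships other than is_a/part_of",
                   n_dropped))
  }

  active <- setdiff(ids, obsolete)
  edges <- bind_rows(map(terms, function(t) {
    if (t$obsolete) return(NULL)
    tibble(
      child = t$id,
      parent = c(t$is_a, t$part_of),
      relationship = c(rep("is_a", length(t$is_a)), rep("part_of", length(t$part_of)))
    )
  }))
  if (nrow(edges) == 0) {
    edges <- tibble(child = character(0), parent = character(0),
                    relationship = character(0))
  }
  edges <- filter(edges, .data$parent %in% active)

  if (!is.null(namespace)) {
    keep <- active[!is.na(ns[active]) & ns[active] == namespace]
    active <- keep
    edges <- filter(edges, .data$child %in% keep, .data$parent %in% keep)
  } else {
    # never connect terms across namespaces
    same_ns <- is.na(ns[edges$child]) | is.na(ns[edges$parent]) |
      ns[edges$child] == ns[edges$parent]
    edges <- edges[same_ns, ]
  }
  edges <- distinct(edges)
  for (nsp in unique(stats::na.omit(ns[active]))) {
    in_ns <- active[!is.na(ns[active]) & ns[active] == nsp]
    stop_if_cyclic(in_ns, filter(edges, .data$child %in% in_ns),
                   context = sprintf("namespace '%s'", nsp))
  }
  if (is.null(namespace)) {
    # a namespace-less OBO (e.g. a toy fixture) must still be acyclic
    stop_if_cyclic(active, edges, context = "ontology")
  }

  structure(
    list(terms = active, edges = edges, namespace = ns[active],
         obsolete = obsolete,
         alt_id = if (is.null(alt)) character(0) else alt,
         n_dropped_edges = n_dropped),
    class = "go_ontology"
  )
}

map_lgl_safe <- function(x, field) vapply(x, function(t) isTRUE(t[[field]]), logical(1))

#' @export
print.go_ontology <- function(x, ...) {
  cat(sprintf("<go_ontology> %d terms, %d edges, %d obsolete\n",
              length(x$terms), nrow(x$edges), length(x$obsolete)))
  invisible(x)
}

#' Read gene-to-GO annotations
#'
#' Reads either a GAF 2.x file (columns 2 = gene symbol, 4 = qualifier,
#' 5 = GO id; rows with a `NOT` qualifier are skipped) or a two-column TSV
#' `gene_id<TAB>go_id` (header optional, `#` comment lines skipped). Unknown
#' and obsolete terms are dropped with a warning count; `alt_id`s are mapped
#' to their primary id; duplicate rows collapse to set semantics.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @param ontology Optional `go_ontology`; when supplied, term ids are
#'   validated against it (alt ids remapped, unknown/obsolete dropped).
#' @return A tibble with columns `gene_id`, `term` (one row per distinct
#'   pair).
#' @export
read_gene_annotations <- function(path, format = c("tsv", "gaf"), ontology = NULL) {
  format <- match.arg(format)
  if (format == "gaf") {
    raw <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (ncol(raw) < 5) abort("GAF file must have at least 5 columns")
    qual <- raw[[4]] %||% ""
    not_rows <- !is.na(qual) & grepl("(^|\\|)NOT($|\\|)", qual)
    ann <- tibble(gene_id = raw[[2]], term = raw[[5]])[!not_rows, ]
  } else {
    raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    if (nrow(raw) == 0) {
      abort("no usable annotations found", class = "mirgosim_empty_error")
    }
    if (ncol(raw) < 2) abort("annotation TSV must have two columns: gene_id, go_id")
    ann <- tibble(gene_id = raw[[1]], term = raw[[2]])
    # tolerate a header row
    if (nrow(ann) > 0 && !grepl("^GO:", ann$term[[1]]) && grepl("^GO:", ann$term)[-1][1] %in% TRUE) {
      ann <- ann[-1, ]
    }
  }
  ann <- distinct(filter(ann, !is.na(.data$gene_id), !is.na(.data$term)))
  if (!is.null(ontology)) {
    remap <- ann$term %in% names(ontology$alt_id)
    ann$term[remap] <- unname(ontology$alt_id[ann$term[remap]])
    known <- ann$term %in% ontology$terms
    if (any(!known)) {
      warn(sprintf("read_gene_annotations: dropped %d row(s) with unknown or obsolete terms",
                   sum(!known)))
      ann <- ann[known, ]
    }
    ann <- distinct(ann)
  }
  if (nrow(ann) == 0) abort("no usable annotations found", class = "mirgosim_empty_error")
  arrange(ann, .data$gene_id, .data$term)
}

#' Build the GO graph of a gene
#'
#' The GO graph of a gene is the union of all child -> parent paths from each
#' directly annotated term up to the namespace root. Its leaf terms are the
#' terms with no incoming child edge *inside the induced graph*, so an
#' annotated term that is an ancestor of another annotated term is not a
#' leaf.
#'
#' @param ontology A `go_ontology`.
#' @param annotated_terms Character vector of GO term ids, all in one
#'   namespace.
#' @param gene_id Identifier stored on the result (informational).
#' @return An object of class `go_graph`: list with `gene_id`, `terms`,
#'   `edges`, `root`, `leaf_terms`.
#' @examples
#' we <- load_worked_example()
#' g <- build_gene_go_graph(we$ontology, c("GO:0048513", "GO:0072358"))
#' g$leaf_terms
#' @export
build_gene_go_graph <- function(ontology, annotated_terms, gene_id = NA_character_) {
  stopifnot(inherits(ontology, "go_ontology"))
  annotated_terms <- unique(annotated_terms)
  if (length(annotated_terms) == 0) abort("annotated_terms is empty")
  missing <- setdiff(annotated_terms, ontology$terms)
  if (length(missing) > 0) {
    abort(sprintf("unknown term(s): %s", paste(missing, collapse = ", ")))
  }
  nss <- unique(stats::na.omit(unname(ontology$namespace[annotated_terms])))
  if (length(nss) > 1) {
    abort(sprintf("annotated terms span multiple namespaces: %s",
                  paste(nss, collapse = ", ")))
  }

  closure <- annotated_terms
  for (t in annotated_terms) {
    closure <- union(closure, ancestor_set(ontology$terms, ontology$edges, t))
  }
  edges <- ontology$edges[ontology$edges$child %in% closure, ]
  # child in closure implies parent in closure (ancestor sets are closed)
  out_deg <- table(factor(edges$child, levels = closure))
  roots <- closure[out_deg == 0]
  if (length(roots) != 1) {
    abort(sprintf(
      "gene GO graph must have exactly one root; found %d (%s): an annotated term cannot reach the namespace root",
      length(roots), paste(roots, collapse = ", ")
    ))
  }
  in_deg <- table(factor(edges$parent, levels = closure))
  leaves <- sort(closure[in_deg == 0])
  structure(
    list(gene_id = gene_id,
         terms = sort(closure),
         edges = edges[order(edges$child, edges$parent), ],
         root = roots,
         leaf_terms = leaves),
    class = "go_graph"
  )
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("<go_graph%s> %d terms, %d edges, root %s, leaves: %s\n",
              if (is.na(x$gene_id)) "" else paste0(" ", x$gene_id),
              length(x$terms), nrow(x$edges), x$root,
              paste(x$leaf_terms, collapse = ", ")))
  invisible(x)
}

#' Extract the leaf term graphs of a GO graph
#'
#' A term graph is the sub-DAG made of one leaf term plus every term and edge
#' on any path from that leaf to the root. A GO graph yields one term graph
#' per leaf, in `leaf_terms` order.
#'
#' @param graph A `go_graph`.
#' @return A list of `term_graph` objects (fields `leaf`, `terms`, `edges`,
#'   `root`).
#' @export
extract_leaf_term_graphs <- function(graph) {
  stopifnot(inherits(graph, "go_graph") || inherits(graph, "term_graph"))
  map(graph$leaf_terms, function(leaf) term_graph_of(graph, leaf))
}

# Term graph of any term of `graph` (leaf term graphs are the usual case).
term_graph_of <- function(graph, term) {
  terms <- c(term, ancestor_set(graph$terms, graph$edges, term))
  edges <- graph$edges[graph$edges$child %in% terms, ]
  edges <- edges[order(edges$child, edges$parent), ]
  structure(
    list(leaf = term, terms = sort(terms), edges = edges, root = graph$root),
    class = "term_graph"
  )
}

#' @export
print.term_graph <- function(x, ...) {
  cat(sprintf("<term_graph> leaf %s, %d terms, root %s\n",
              x$leaf, length(x$terms), x$root))
  invisible(x)
}

#' Depth of a term
#'
#' The depth of a term is the number of edges in the *longest* directed
#' child -> parent path from the term to the root of the graph; the root has
#' depth 0.
#'
#' @param graph A `go_graph`, `term_graph`, or merged graph.
#' @param term A term id present in the graph.
#' @return A non-negative integer.
#' @examples
#' we <- load_worked_example()
#' term_depth(we$tg_a, "GO:0048513")  # 4
#' @export
term_depth <- function(graph, term) {
  check_term(graph, term)
  lp <- longest_path_to(graph$terms, graph$edges, term, graph$root,
                        c(is_a = 1, part_of = 1))
  if (is.null(lp)) abort(sprintf("term %s cannot reach root %s", term, graph$root))
  lp$length
}

#' Number of descendants of a term
#'
#' Counts the distinct terms having a directed path to `term` (the term
#' itself excluded).
#'
#' @inheritParams term_depth
#' @return A non-negative integer.
#' @export
descendant_count <- function(graph, term) {
  check_term(graph, term)
  length(descendant_set(graph$terms, graph$edges, term))
}

check_term <- function(graph, term) {
  if (!term %in% graph$terms) {
    abort(sprintf("term %s is not in the graph", term), class = "mirgosim_term_error")
  }
  invisible(TRUE)
}
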