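# Shared fixtures and independent brute-force oracles.
# The oracles deliberately use naive enumeration (all simple paths, transpose
# reachability) so they share no code with the package's dynamic programming.

# Build a go_ontology directly from an edge data frame.
toy_ontology <- function(edges, namespace = "biological_process") {
  terms <- sort(unique(c(edges$child, edges$parent)))
  mirgosim:::make_ontology(terms, tibble::as_tibble(edges), namespace)
}

edge_df <- function(child, parent, relationship = "is_a") {
  tibble::tibble(child = child, parent = parent, relationship = relationship)
}

# Random rooted DAG edge list on n terms: term i (>= 2) attaches to 1-2
# earlier terms. Independent of the package's generator.
rand_dag_edges <- function(n, part_of_prob = 0.3) {
  ids <- sprintf("GO:%07d", seq_len(n))
  rows <- list()
  for (i in seq(2, n)) {
    k <- sample(1:min(2, i - 1), 1)
    parents <- sample(ids[seq_len(i - 1)], k)
    rows[[i]] <- tibble::tibble(
      child = ids[[i]], parent = parents,
      relationship = ifelse(stats::runif(k) < part_of_prob, "part_of", "is_a")
    )
  }
  dplyr::bind_rows(rows)
}

# All simple child->parent paths between two terms, as lists of edge indices.
all_paths <- function(edges, from, to) {
  out <- list()
  walk <- function(node, used) {
    if (node == to) {
      out[[length(out) + 1]] <<- used
      return(invisible())
    }
    idx <- which(edges$child == node)
    for (i in idx) walk(edges$parent[[i]], c(used, i))
  }
  walk(from, integer(0))
  out
}

# Longest-path length and max weight product among longest paths, by
# exhaustive enumeration.
oracle_longest <- function(edges, from, to, weights = c(is_a = 0.9, part_of = 0.7)) {
  paths <- all_paths(edges, from, to)
  if (length(paths) == 0) return(NULL)
  lens <- vapply(paths, length, integer(1))
  longest <- paths[lens == max(lens)]
  prods <- vapply(longest, function(p) prod(weights[edges$relationship[p]]), numeric(1))
  list(length = max(lens), product = max(prods))
}

# Descendant count by transpose reachability: s is a descendant of t iff t is
# reachable from s.
oracle_descendant_count <- function(edges, term) {
  terms <- unique(c(edges$child, edges$parent))
  sum(vapply(setdiff(terms, term), function(s)
    length(all_paths(edges, s, term)) > 0, logical(1)))
}

# Ontology + gene graphs for a random pair of annotated genes, for the
# cascade property suite.
random_gene_pair <- function(n_terms = 8, n_annot = 2) {
  edges <- rand_dag_edges(n_terms)
  onto <- toy_ontology(edges)
  pick <- function() sample(onto$terms, sample(seq_len(n_annot), 1))
  g1 <- build_gene_go_graph(onto, pick(), gene_id = "g1")
  g2 <- build_gene_go_graph(onto, pick(), gene_id = "g2")
  list(onto = onto, g1 = g1, g2 = g2)
}

worked <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_worked_example()
    cache
  }
})

# Reference per-term table of the packaged worked example (printed to 3
# decimals).
worked_reference <- tibble::tribble(
  ~term,         ~ic,   ~depth_weight, ~edge_weight, ~weighted_ic,
  "GO:0008150",  0,     1,             0,            0,
  "GO:0032502",  0.067, 0.9,           0.533,        0.189,
  "GO:0048856",  0.146, 0.81,          0.567,        0.288,
  "GO:0048731",  0.243, 0.729,         0.599,        0.382,
  "GO:0072359",  0.544, 0.9,           0.533,        0.538,
  "GO:0048513",  0.845, 0.9,           0.533,        0.671,
  "GO:0072358",  0.845, 0.63,          0.642,        0.737
)

map_int_ <- function(x, f) vapply(x, f, integer(1))
map_dbl_ <- function(x, f) vapply(x, f, numeric(1))
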