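# Packaged worked example: the 7-term developmental-process subgraph used
# throughout the documentation and tests.
#
# The edge set (child -> parent):
#   GO:0032502 -> GO:0008150  is_a
#   GO:0048856 -> GO:0032502  is_a
#   GO:0048731 -> GO:0048856  is_a
#   GO:0072359 -> GO:0048731  is_a
#   GO:0048513 -> GO:0048731  is_a
#   GO:0072358 -> GO:0072359  part_of
#
# The relationship labels are forced by the reference table's arithmetic:
# omega_depth(GO:0072358) = 0.63 = 0.9 * 0.7 puts exactly one part_of edge on
# the GO:0072358 path, and depth(GO:0048513) = 4 fixes its chain of is_a
# edges to the root.

#' Load the packaged worked example
#'
#' Parses the packaged 7-term OBO fixture and returns the ontology together
#' with the two leaf term graphs of GO:0048513 and GO:0072358. Their merged
#' graph reproduces the reference per-term table (IC, omega_depth,
#' omega_edge, weighted IC) under the default weights is_a = 0.9,
#' part_of = 0.7 and log base 10.
#'
#' @return A list with elements `ontology` (`go_ontology`), `tg_a`
#'   (`term_graph` of GO:0048513), `tg_b` (`term_graph` of GO:0072358), and
#'   `gene_graph` (the `go_graph` annotated with both leaves).
#' @examples
#' we <- load_worked_example()
#' ctx <- build_comparison_context(we$tg_a, we$tg_b)
#' ctx$table
#' @export
load_worked_example <- function() {
  path <- system.file("extdata", "worked_example.obo", package = "mirgosim")
  ontology <- parse_obo(path)
  gene_graph <- build_gene_go_graph(ontology, c("GO:0048513", "GO:0072358"),
                                    gene_id = "worked_example")
  tgs <- extract_leaf_term_graphs(gene_graph)
  list(ontology = ontology,
       tg_a = tgs[[match("GO:0048513", gene_graph$leaf_terms)]],
       tg_b = tgs[[match("GO:0072358", gene_graph$leaf_terms)]],
       gene_graph = gene_graph)
}
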