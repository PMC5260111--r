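# Weighted information content on the merged graph of two term graphs.
#
# The information content used here is purely structural: for a term t of the
# merged graph G with n terms,
#
#   IC(t) = -log10( (1 + |descendants(t)|) / n )
#
# so the root has IC 0 and leaves share the maximal IC. The IC is then
# adjusted by a path weight relative to the most informative common ancestor
# (MICA) of the two leaves:
#
#   omega_depth(t) = product of relationship weights (is_a = 0.9,
#                    part_of = 0.7 by default) along the longest path from t
#                    to the root (when t is the MICA or one of its ancestors)
#                    or to the MICA (otherwise); 1 for the root
#   omega_edge(t)  = (2/pi) * atan(1 / omega_depth(t)), 0 for the root
#   wIC(t)         = sqrt( IC(t) * omega_edge(t) )
#
# The root's omega_edge is fixed at 0 rather than the formula's 0.5: since
# IC(root) = 0 this never changes wIC, but it keeps the per-term tables
# identical to the worked reference values.

#' Relationship weights for GO edges
#'
#' `is_a` is considered the stronger relationship and gets the larger weight.
#' Both weights must lie in (0, 1].
#'
#' @param is_a Weight of `is_a` edges (default 0.9).
#' @param part_of Weight of `part_of` edges (default 0.7).
#' @return A named numeric vector usable wherever `weights` is accepted.
#' @export
relationship_weights <- function(is_a = 0.9, part_of = 0.7) {
  stopifnot(is.numeric(is_a), is.numeric(part_of),
            is_a > 0, is_a <= 1, part_of > 0, part_of <= 1)
  c(is_a = is_a, part_of = part_of)
}

#' Merge two term graphs
#'
#' Union of the term sets and edge sets of two term graphs sharing the same
#' root. The result is the universe over which information content and path
#' weights are evaluated.
#'
#' @param tg_a,tg_b `term_graph` objects with the same root.
#' @return A `merged_graph` (list with `terms`, `edges`, `root`, `leaves`).
#' @export
merge_term_graphs <- function(tg_a, tg_b) {
  stopifnot(inherits(tg_a, "term_graph"), inherits(tg_b, "term_graph"))
  if (!identical(tg_a$root, tg_b$root)) {
    abort(sprintf("term graphs have different roots (%s vs %s)", tg_a$root, tg_b$root))
  }
  terms <- sort(union(tg_a$terms, tg_b$terms))
  edges <- distinct(bind_rows(tg_a$edges, tg_b$edges))
  structure(
    list(terms = terms,
         edges = arrange(edges, .data$child, .data$parent),
         root = tg_a$root,
         leaves = unique(c(tg_a$leaf, tg_b$leaf))),
    class = c("merged_graph", "go_graph")
  )
}

#' Structural information content of a term
#'
#' `-log((1 + descendant count) / n terms)` evaluated on the merged graph,
#' base-10 logarithm by default. The root always has IC 0 and a parent's IC
#' is strictly smaller than any of its children's.
#'
#' @param merged A `merged_graph` (or any graph object with `terms`/`edges`).
#' @param term Term id.
#' @param log_base Base of the logarithm (default 10, matching the worked
#'   reference values).
#' @return Non-negative numeric.
#' @examples
#' we <- load_worked_example()
#' m <- merge_term_graphs(we$tg_a, we$tg_b)
#' information_content(m, "GO:0048731")  # 0.243
#' @export
information_content <- function(merged, term, log_base = 10) {
  check_term(merged, term)
  n <- length(merged$terms)
  -log((1 + descendant_count(merged, term)) / n, base = log_base)
}

#' Most informative common ancestor of two term graphs
#'
#' Among the terms present in both term graphs (each such term is an
#' ancestor of both leaves), returns the one with maximal information
#' content on the merged graph. Ties are broken by greater depth, then by
#' lexicographically smaller id.
#'
#' @inheritParams merge_term_graphs
#' @param merged Optional pre-computed merged graph.
#' @param log_base Logarithm base for IC.
#' @return A term id.
#' @export
find_mica <- function(tg_a, tg_b, merged = NULL, log_base = 10) {
  merged <- merged %||% merge_term_graphs(tg_a, tg_b)
  common <- intersect(tg_a$terms, tg_b$terms)
  ic <- map_dbl(common, information_content, merged = merged, log_base = log_base)
  depth <- map_int(common, function(t) term_depth(merged, t))
  ord <- order(-ic, -depth, common)
  common[ord[[1]]]
}

#' Relationship-weight product along the longest path (omega_depth)
#'
#' For the root, 1. For the MICA or any of its ancestors, the product of
#' relationship weights along the longest (by edge count) path from the term
#' to the root; for every other term, along the longest path from the term
#' to the MICA. Among multiple longest paths the one with the largest weight
#' product is taken. A term incomparable to the MICA (possible in DAGs with
#' multiple parents) falls back to its root path, with a message.
#'
#' @param merged A `merged_graph`.
#' @param mica The MICA term id.
#' @param term Term id to evaluate.
#' @param weights Output of [relationship_weights()].
#' @return Numeric in (0, 1].
#' @export
depth_weight <- function(merged, mica, term, weights = relationship_weights()) {
  check_term(merged, term)
  if (term == merged$root) return(1)
  mica_up <- c(mica, ancestor_set(merged$terms, merged$edges, mica))
  if (term %in% mica_up) {
    lp <- longest_path_to(merged$terms, merged$edges, term, merged$root, weights)
  } else {
    lp <- longest_path_to(merged$terms, merged$edges, term, mica, weights)
    if (is.null(lp)) {
      inform(sprintf(
        "depth_weight: %s has no path to MICA %s; using its root path instead",
        term, mica
      ))
      lp <- longest_path_to(merged$terms, merged$edges, term, merged$root, weights)
    }
  }
  lp$product
}

#' Arctan-standardized edge weight (omega_edge)
#'
#' `(2/pi) * atan(1 / omega_depth)` for non-root terms; 0 for the root (the
#' table convention of the reference values; the root's weighted IC is 0
#' either way).
#'
#' @inheritParams depth_weight
#' @return Numeric in `[0, 1)`; in `[0.5, 1)` for non-root terms.
#' @export
edge_weight <- function(merged, mica, term, weights = relationship_weights()) {
  check_term(merged, term)
  if (term == merged$root) return(0)
  wd <- depth_weight(merged, mica, term, weights)
  (2 / pi) * atan(1 / wd)
}

#' Weighted information content (wIC)
#'
#' `sqrt(IC(t) * omega_edge(t))`; 0 exactly for the root.
#'
#' @inheritParams depth_weight
#' @param log_base Logarithm base for IC.
#' @return Non-negative numeric.
#' @export
weighted_information_content <- function(merged, mica, term,
                                         weights = relationship_weights(),
                                         log_base = 10) {
  sqrt(information_content(merged, term, log_base) *
         edge_weight(merged, mica, term, weights))
}

#' Build the full comparison context of two term graphs
#'
#' Merges the two term graphs, locates the MICA, partitions the merged terms
#' into common (in both term graphs) and uncommon (in exactly one), and
#' tabulates depth, IC, omega_depth, omega_edge and weighted IC for every
#' merged term.
#'
#' @inheritParams merge_term_graphs
#' @param weights Output of [relationship_weights()].
#' @param log_base Logarithm base for IC.
#' @return An object of class `comparison_context`: list with `merged`,
#'   `mica`, `common_terms`, `uncommon_terms`, `n_terms`, and `table` — a
#'   tibble with one row per merged term and columns `term`, `common`,
#'   `depth`, `ic`, `depth_weight`, `edge_weight`, `weighted_ic`.
#' @examples
#' we <- load_worked_example()
#' ctx <- build_comparison_context(we$tg_a, we$tg_b)
#' ctx$table
#' @export
build_comparison_context <- function(tg_a, tg_b,
                                     weights = relationship_weights(),
                                     log_base = 10) {
  merged <- merge_term_graphs(tg_a, tg_b)
  mica <- find_mica(tg_a, tg_b, merged, log_base)
  common <- sort(intersect(tg_a$terms, tg_b$terms))
  uncommon <- sort(setdiff(merged$terms, common))
  tab <- tibble(
    term = merged$terms,
    common = merged$terms %in% common,
    depth = map_int(merged$terms, function(t) term_depth(merged, t)),
    ic = map_dbl(merged$terms, information_content, merged = merged,
                 log_base = log_base),
    depth_weight = map_dbl(merged$terms, function(t)
      depth_weight(merged, mica, t, weights)),
    edge_weight = map_dbl(merged$terms, function(t)
      edge_weight(merged, mica, t, weights))
  )
  tab$weighted_ic <- sqrt(tab$ic * tab$edge_weight)
  structure(
    list(merged = merged, mica = mica, common_terms = common,
         uncommon_terms = uncommon, n_terms = length(merged$terms),
         table = tab),
    class = "comparison_context"
  )
}

#' @export
print.comparison_context <- function(x, ...) {
  cat(sprintf("<comparison_context> %d terms (%d common, %d uncommon), MICA %s\n",
              x$n_terms, length(x$common_terms), length(x$uncommon_terms), x$mica))
  print(x$table)
  invisible(x)
}
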