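# Internal directed-acyclic-graph primitives shared by every module.
#
# All graphs in this package store edges child -> parent, matching the way OBO
# files state `is_a`: the namespace root is the unique term with out-degree 0
# (it only *receives* edges, seen from the parents' side). Graphs are small
# (term graphs, merged graphs, per-gene closures), so adjacency lists are
# rebuilt on demand rather than cached.

# Adjacency lists from an edge tibble (child, parent, relationship).
graph_adjacency <- function(terms, edges) {
  parents <- rep(list(character(0)), length(terms))
  names(parents) <- terms
  children <- parents
  if (nrow(edges) > 0) {
    sp <- split(edges$parent, edges$child)
    sc <- split(edges$child, edges$parent)
    parents[names(sp)] <- sp
    children[names(sc)] <- sc
  }
  list(parents = parents, children = children)
}

# Kahn topological order, root(s) first (every node after all its parents).
# Returns NULL when a cycle prevents a full ordering.
topological_order <- function(terms, edges) {
  adj <- graph_adjacency(terms, edges)
  n_parents <- vapply(adj$parents, length, integer(1))
  queue <- terms[n_parents == 0L]
  order <- character(0)
  while (length(queue) > 0) {
    u <- queue[[1]]
    queue <- queue[-1]
    order <- c(order, u)
    for (child in adj$children[[u]]) {
      n_parents[[child]] <- n_parents[[child]] - 1L
      if (n_parents[[child]] == 0L) queue <- c(queue, child)
    }
  }
  if (length(order) < length(terms)) NULL else order
}

# Locate one directed cycle for error reporting: walk parent pointers from a
# node left over by Kahn's algorithm until a repeat closes the loop.
find_cycle <- function(terms, edges) {
  adj <- graph_adjacency(terms, edges)
  n_parents <- vapply(adj$parents, length, integer(1))
  ord <- topological_order(terms, edges)
  stuck <- setdiff(terms, ord)
  if (length(stuck) == 0) return(NULL)
  seen <- character(0)
  u <- stuck[[1]]
  repeat {
    if (u %in% seen) {
      i <- match(u, seen)
      return(c(seen[i:length(seen)], u))
    }
    seen <- c(seen, u)
    # stay inside the stuck set so the walk cannot escape the cycle
    nxt <- intersect(adj$parents[[u]], stuck)
    u <- nxt[[1]]
  }
}

stop_if_cyclic <- function(terms, edges, context = "graph") {
  if (is.null(topological_order(terms, edges))) {
    cyc <- find_cycle(terms, edges)
    abort(sprintf(
      "%s contains a relationship cycle: %s",
      context, paste(cyc, collapse = " -> ")
    ), class = "mirgosim_cycle_error")
  }
  invisible(TRUE)
}

# Ancestors of `term` (terms reachable by walking child -> parent edges),
# excluding `term` itself.
ancestor_set <- function(terms, edges, term) {
  adj <- graph_adjacency(terms, edges)
  reach_set(adj$parents, term)
}

# Descendants of `term` (terms that can reach it), excluding `term`.
descendant_set <- function(terms, edges, term) {
  adj <- graph_adjacency(terms, edges)
  reach_set(adj$children, term)
}

reach_set <- function(step, term) {
  seen <- character(0)
  frontier <- step[[term]]
  while (length(frontier) > 0) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(step[frontier], use.names = FALSE))
  }
  seen
}

# Longest child->parent path (edge count) from `from` to `to`, together with
# the maximal product of relationship weights among paths of that length
# ("if a term has multiple longest paths ... choose the one which provides the
# biggest edge weight"). Returns NULL when `to` is unreachable from `from`.
longest_path_to <- function(terms, edges, from, to, edge_weights) {
  if (from == to) return(list(length = 0L, product = 1))
  adj <- graph_adjacency(terms, edges)
  w <- edge_weights[edges$relationship]
  parent_edges <- split(
    data.frame(parent = edges$parent, w = w, stringsAsFactors = FALSE),
    edges$child
  )
  memo <- new.env(parent = emptyenv())
  rec <- function(u) {
    if (u == to) return(list(length = 0L, product = 1))
    if (!is.null(res <- memo[[u]])) return(if (isFALSE(res)) NULL else res)
    best <- NULL
    pe <- parent_edges[[u]]
    if (!is.null(pe)) {
      for (i in seq_len(nrow(pe))) {
        up <- rec(pe$parent[[i]])
        if (is.null(up)) next
        cand <- list(length = up$length + 1L, product = up$product * pe$w[[i]])
        if (is.null(best) ||
            cand$length > best$length ||
            (cand$length == best$length && cand$product > best$product)) {
          best <- cand
        }
      }
    }
    memo[[u]] <- if (is.null(best)) FALSE else best
    best
  }
  out <- rec(from)
  if (isFALSE(out)) NULL else out
}
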