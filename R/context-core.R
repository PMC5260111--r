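# Single-pass computation of everything the similarity cascade needs for one
# pair of term graphs. The exported per-term functions (information_content,
# depth_weight, ...) are convenient for inspection but rebuild adjacency per
# query; this core builds it once and fills all per-term tables by dynamic
# programming over one topological order. Tests assert the two routes agree.

context_core <- function(tg_a, tg_b, weights = relationship_weights(),
                         log_base = 10) {
  if (!identical(tg_a$root, tg_b$root)) {
    abort(sprintf("term graphs have different roots (%s vs %s)", tg_a$root, tg_b$root))
  }
  terms <- sort(union(tg_a$terms, tg_b$terms))
  edges <- rbind(as.data.frame(tg_a$edges), as.data.frame(tg_b$edges))
  edges <- edges[!duplicated(edges), ]
  root <- tg_a$root
  n <- length(terms)
  idx <- stats::setNames(seq_len(n), terms)

  e_child <- idx[edges$child]
  e_parent <- idx[edges$parent]
  e_w <- unname(weights[edges$relationship])

  parent_of <- vector("list", n)   # per child: parent indices
  pweight_of <- vector("list", n)  # per child: edge weights
  child_of <- vector("list", n)
  for (i in seq_along(e_child)) {
    c_ <- e_child[[i]]; p_ <- e_parent[[i]]
    parent_of[[c_]] <- c(parent_of[[c_]], p_)
    pweight_of[[c_]] <- c(pweight_of[[c_]], e_w[[i]])
    child_of[[p_]] <- c(child_of[[p_]], c_)
  }

  # topological order, root first (parents before children)
  n_par <- lengths(parent_of)
  queue <- which(n_par == 0L)
  topo <- integer(0)
  n_left <- n_par
  while (length(queue) > 0) {
    u <- queue[[1]]; queue <- queue[-1]
    topo <- c(topo, u)
    for (v in child_of[[u]]) {
      n_left[[v]] <- n_left[[v]] - 1L
      if (n_left[[v]] == 0L) queue <- c(queue, v)
    }
  }

  # depth and longest-path product to the root, one DP sweep
  depth <- rep(NA_integer_, n)
  prod_root <- rep(NA_real_, n)
  depth[[idx[[root]]]] <- 0L
  prod_root[[idx[[root]]]] <- 1
  for (u in topo) {
    if (u == idx[[root]]) next
    best_len <- -1L; best_prod <- -Inf
    ps <- parent_of[[u]]; ws <- pweight_of[[u]]
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (is.na(depth[[p]])) next
      len <- depth[[p]] + 1L
      pr <- prod_root[[p]] * ws[[k]]
      if (len > best_len || (len == best_len && pr > best_prod)) {
        best_len <- len; best_prod <- pr
      }
    }
    depth[[u]] <- best_len
    prod_root[[u]] <- best_prod
  }

  # descendant counts by reverse reachability (graphs are small)
  desc <- integer(n)
  for (u in seq_len(n)) {
    seen <- logical(n)
    frontier <- child_of[[u]]
    while (length(frontier) > 0) {
      frontier <- frontier[!seen[frontier]]
      seen[frontier] <- TRUE
      frontier <- unique(unlist(child_of[frontier], use.names = FALSE))
    }
    desc[[u]] <- sum(seen)
  }
  ic <- -log((1 + desc) / n, base = log_base)

  # MICA: max IC among common terms, ties by depth then id
  common <- terms %in% intersect(tg_a$terms, tg_b$terms)
  ci <- which(common)
  ord <- ci[order(-ic[ci], -depth[ci], terms[ci])]
  mica <- ord[[1]]

  # ancestors of the MICA
  mica_anc <- logical(n)
  frontier <- parent_of[[mica]]
  while (length(frontier) > 0) {
    frontier <- frontier[!mica_anc[frontier]]
    mica_anc[frontier] <- TRUE
    frontier <- unique(unlist(parent_of[frontier], use.names = FALSE))
  }

  # longest path (length, then product) to the MICA, same DP restricted to
  # terms that can reach it
  len_mica <- rep(NA_integer_, n)
  prod_mica <- rep(NA_real_, n)
  len_mica[[mica]] <- 0L
  prod_mica[[mica]] <- 1
  for (u in topo) {
    if (u == mica) next
    best_len <- NA_integer_; best_prod <- NA_real_
    ps <- parent_of[[u]]; ws <- pweight_of[[u]]
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (is.na(len_mica[[p]])) next
      len <- len_mica[[p]] + 1L
      pr <- prod_mica[[p]] * ws[[k]]
      if (is.na(best_len) || len > best_len ||
          (len == best_len && pr > best_prod)) {
        best_len <- len; best_prod <- pr
      }
    }
    len_mica[[u]] <- best_len
    prod_mica[[u]] <- best_prod
  }

  omega_depth <- numeric(n)
  fallback <- logical(n)
  for (u in seq_len(n)) {
    if (u == idx[[root]]) {
      omega_depth[[u]] <- 1
    } else if (u == mica || mica_anc[[u]]) {
      omega_depth[[u]] <- prod_root[[u]]
    } else if (!is.na(prod_mica[[u]])) {
      omega_depth[[u]] <- prod_mica[[u]]
    } else {
      omega_depth[[u]] <- prod_root[[u]]
      fallback[[u]] <- TRUE
    }
  }
  omega_edge <- (2 / pi) * atan(1 / omega_depth)
  omega_edge[[idx[[root]]]] <- 0
  wic <- sqrt(ic * omega_edge)

  list(terms = terms, root = root, n = n,
       edges = edges,
       depth = depth, desc = desc, ic = ic,
       common = common, mica = terms[[mica]],
       omega_depth = omega_depth, omega_edge = omega_edge,
       weighted_ic = wic, fallback = fallback)
}

# Fast Eq-4 similarity on a context core.
core_similarity <- function(core) {
  if (core$mica == core$root) return(0)
  total <- sum(core$weighted_ic)
  if (total == 0) return(0)
  sum(core$weighted_ic[core$common]) / total
}
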