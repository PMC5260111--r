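# Weighted information content: merged graphs, IC, MICA, path weights.

test_that("the full worked-example reference table is reproduced", {
  ctx <- build_comparison_context(worked()$tg_a, worked()$tg_b)
  expect_equal(ctx$mica, "GO:0048731")
  tab <- ctx$table[match(worked_reference$term, ctx$table$term), ]
  for (col in c("ic", "depth_weight", "edge_weight", "weighted_ic")) {
    expect_true(all(abs(tab[[col]] - worked_reference[[col]]) <= 1e-3),
                info = col)
  }
})

test_that("merging term graphs is a set union and idempotent", {
  m <- merge_term_graphs(worked()$tg_a, worked()$tg_b)
  expect_length(m$terms, 7)
  expect_equal(nrow(m$edges), 6)

  m2 <- merge_term_graphs(worked()$tg_a, worked()$tg_a)
  expect_setequal(m2$terms, worked()$tg_a$terms)
  expect_equal(nrow(m2$edges), nrow(worked()$tg_a$edges))

  # disjoint chains sharing only the root: |A| + |B| - 1 terms
  edges <- edge_df(c("B", "C", "X", "Y"), c("A", "B", "A", "X"))
  onto <- toy_ontology(edges)
  tg1 <- extract_leaf_term_graphs(build_gene_go_graph(onto, "C"))[[1]]
  tg2 <- extract_leaf_term_graphs(build_gene_go_graph(onto, "Y"))[[1]]
  m3 <- merge_term_graphs(tg1, tg2)
  expect_length(m3$terms, length(tg1$terms) + length(tg2$terms) - 1)

  tg_other <- tg2
  tg_other$root <- "Z"
  expect_error(merge_term_graphs(tg1, tg_other), "different roots")
})

test_that("information content matches the printed worked values and is monotone", {
  m <- merge_term_graphs(worked()$tg_a, worked()$tg_b)
  expect_equal(information_content(m, "GO:0048731"), -log10(4 / 7))
  expect_equal(round(information_content(m, "GO:0048731"), 3), 0.243)
  expect_equal(information_content(m, "GO:0008150"), 0)
  expect_equal(round(information_content(m, "GO:0072359"), 3), 0.544)

  # natural log would disagree with the printed value
  expect_equal(round(information_content(m, "GO:0048731", log_base = exp(1)), 3),
               0.560)

  # parent IC strictly below child IC along every edge, random DAGs
  withr::with_seed(3, {
    for (rep in 1:10) {
      edges <- rand_dag_edges(sample(4:10, 1))
      onto <- toy_ontology(edges)
      leaves <- setdiff(onto$terms, unique(edges$parent))
      g <- build_gene_go_graph(onto, leaves)
      tgs <- extract_leaf_term_graphs(g)
      mm <- if (length(tgs) > 1) merge_term_graphs(tgs[[1]], tgs[[2]]) else
        merge_term_graphs(tgs[[1]], tgs[[1]])
      for (i in seq_len(nrow(mm$edges))) {
        expect_lt(information_content(mm, mm$edges$parent[[i]]),
                  information_content(mm, mm$edges$child[[i]]))
      }
      # leaves of the merged graph share the maximal IC
      in_deg <- table(factor(mm$edges$parent, levels = mm$terms))
      mleaves <- mm$terms[in_deg == 0]
      ics <- map_dbl_(mleaves, function(t) information_content(mm, t))
      expect_true(all(abs(ics - (-log10(1 / length(mm$terms)))) < 1e-12))
    }
  })
})

test_that("MICA identification follows IC with depth then id tie-breaks", {
  expect_equal(find_mica(worked()$tg_a, worked()$tg_b), "GO:0048731")
  expect_equal(find_mica(worked()$tg_a, worked()$tg_a), "GO:0048513")

  # two leaves sharing only the root
  edges <- edge_df(c("B", "C"), c("A", "A"))
  onto <- toy_ontology(edges)
  tgb <- extract_leaf_term_graphs(build_gene_go_graph(onto, "B"))[[1]]
  tgc <- extract_leaf_term_graphs(build_gene_go_graph(onto, "C"))[[1]]
  expect_equal(find_mica(tgb, tgc), "A")
})

test_that("path weights reproduce the reference row and the root conventions", {
  m <- merge_term_graphs(worked()$tg_a, worked()$tg_b)
  mica <- "GO:0048731"
  expect_equal(depth_weight(m, mica, "GO:0008150"), 1)
  expect_equal(depth_weight(m, mica, "GO:0048731"), 0.9^3)
  expect_equal(depth_weight(m, mica, "GO:0072358"), 0.9 * 0.7)
  expect_equal(depth_weight(m, mica, "GO:0072359"), 0.9)

  expect_equal(edge_weight(m, mica, "GO:0008150"), 0)
  expect_equal(round(edge_weight(m, mica, "GO:0048856"), 3), 0.567)
  expect_equal(round(edge_weight(m, mica, "GO:0072358"), 3), 0.642)

  expect_equal(weighted_information_content(m, mica, "GO:0008150"), 0)
  expect_equal(round(weighted_information_content(m, mica, "GO:0048513"), 3), 0.671)
  expect_equal(round(weighted_information_content(m, mica, "GO:0048731"), 3), 0.382)
})

test_that("longest-path weight products agree with exhaustive enumeration", {
  w <- relationship_weights()
  withr::with_seed(19, {
    for (rep in 1:12) {
      edges <- rand_dag_edges(sample(5:12, 1))
      onto <- toy_ontology(edges)
      leaves <- setdiff(onto$terms, unique(edges$parent))
      g <- build_gene_go_graph(onto, leaves)
      tgs <- extract_leaf_term_graphs(g)
      i <- sample(length(tgs), 1); j <- sample(length(tgs), 1)
      mm <- merge_term_graphs(tgs[[i]], tgs[[j]])
      mica <- find_mica(tgs[[i]], tgs[[j]], mm)
      mica_up <- c(mica, mirgosim:::ancestor_set(mm$terms, mm$edges, mica))
      for (t in setdiff(mm$terms, mm$root)) {
        target <- if (t %in% mica_up) mm$root else mica
        want <- oracle_longest(mm$edges, t, target, w)
        if (is.null(want)) next  # incomparable fallback checked separately
        expect_equal(depth_weight(mm, mica, t, w), want$product)
      }
    }
  })
})

test_that("terms with no path to the MICA fall back to their root path", {
  # B and C are siblings under A; MICA forced to C by comparing leaves under C;
  # X hangs under B only, so X cannot reach C.
  edges <- edge_df(c("B", "C", "X", "L1", "L2"), c("A", "A", "B", "C", "C"))
  onto <- toy_ontology(edges)
  tg1 <- extract_leaf_term_graphs(build_gene_go_graph(onto, "L1"))[[1]]
  tg2 <- extract_leaf_term_graphs(build_gene_go_graph(onto, "L2"))[[1]]
  m <- merge_term_graphs(tg1, tg2)
  mica <- find_mica(tg1, tg2, m)
  expect_equal(mica, "C")
  # add X into the merged universe by hand to exercise the fallback
  m$terms <- sort(c(m$terms, "X", "B"))
  m$edges <- dplyr::bind_rows(m$edges, edge_df(c("B", "X"), c("A", "B")))
  expect_message(wd <- depth_weight(m, mica, "X"), "no path to MICA")
  expect_equal(wd, 0.9 * 0.9)
})

test_that("omega_edge lies in [0.5, 1) for non-root terms and decreases in omega_depth", {
  ctx <- build_comparison_context(worked()$tg_a, worked()$tg_b)
  non_root <- ctx$table[ctx$table$term != "GO:0008150", ]
  expect_true(all(non_root$edge_weight >= 0.5 & non_root$edge_weight < 1))

  wd <- seq(0.05, 1, by = 0.05)
  we <- (2 / pi) * atan(1 / wd)
  expect_true(all(diff(we) < 0))
})

test_that("the comparison context partitions terms as in the schematic", {
  ctx <- build_comparison_context(worked()$tg_a, worked()$tg_b)
  expect_setequal(ctx$common_terms,
                  c("GO:0008150", "GO:0032502", "GO:0048856", "GO:0048731"))
  expect_setequal(ctx$uncommon_terms,
                  c("GO:0072359", "GO:0048513", "GO:0072358"))
  expect_setequal(c(ctx$common_terms, ctx$uncommon_terms), ctx$merged$terms)

  # every ancestor of the MICA is a common term
  up <- mirgosim:::ancestor_set(ctx$merged$terms, ctx$merged$edges, ctx$mica)
  expect_true(all(up %in% ctx$common_terms))

  # identical graphs: no uncommon terms; root-only overlap: common = root
  ctx2 <- build_comparison_context(worked()$tg_a, worked()$tg_a)
  expect_length(ctx2$uncommon_terms, 0)
})
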