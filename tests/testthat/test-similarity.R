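# Similarity cascade: term-graph pair, gene pair, gene set, miRNA pair,
# distance matrix.

test_that("term-graph similarity reproduces the worked pair and its limits", {
  we <- worked()
  s <- term_graph_similarity(we$tg_a, we$tg_b)
  expect_equal(s, 0.306, tolerance = 2e-3)

  expect_equal(term_graph_similarity(we$tg_a, we$tg_a), 1)

  # leaves sharing only the root have similarity 0
  edges <- edge_df(c("B", "C"), c("A", "A"))
  onto <- toy_ontology(edges)
  tgb <- extract_leaf_term_graphs(build_gene_go_graph(onto, "B"))[[1]]
  tgc <- extract_leaf_term_graphs(build_gene_go_graph(onto, "C"))[[1]]
  expect_equal(term_graph_similarity(tgb, tgc), 0)

  # degenerate: both graphs are the bare root
  tg_root <- extract_leaf_term_graphs(build_gene_go_graph(onto, "A"))[[1]]
  expect_equal(term_graph_similarity(tg_root, tg_root), 0)
})

test_that("gene similarity averages best-matching leaf pairs", {
  we <- worked()
  g <- we$gene_graph
  expect_equal(gene_similarity(g, g), 1)

  # single-leaf genes reduce to the term-graph similarity
  onto <- we$ontology
  g1 <- build_gene_go_graph(onto, "GO:0048513", gene_id = "g1")
  g2 <- build_gene_go_graph(onto, "GO:0072358", gene_id = "g2")
  expect_equal(gene_similarity(g1, g2),
               term_graph_similarity(we$tg_a, we$tg_b))

  # two leaves vs one: brute-force the 2x1 pair table
  g12 <- build_gene_go_graph(onto, c("GO:0048513", "GO:0072359"), gene_id = "g12")
  tgs <- extract_leaf_term_graphs(g12)
  s_ac <- term_graph_similarity(tgs[[1]], we$tg_b)
  s_bc <- term_graph_similarity(tgs[[2]], we$tg_b)
  expect_equal(gene_similarity(g12, g2), (max(s_ac, s_bc) + s_ac + s_bc) / 3)
})

test_that("gene-set similarity is the max over members and bounds the mean", {
  we <- worked()
  onto <- we$ontology
  g1 <- build_gene_go_graph(onto, "GO:0048513", gene_id = "g1")
  g2 <- build_gene_go_graph(onto, "GO:0072358", gene_id = "g2")
  g3 <- build_gene_go_graph(onto, "GO:0072359", gene_id = "g3")

  expect_equal(geneset_gene_similarity(list(g1, g2), g1), 1)
  expect_equal(geneset_gene_similarity(list(g1), g2), gene_similarity(g1, g2))
  pair_vals <- c(gene_similarity(g1, g3), gene_similarity(g2, g3))
  expect_equal(geneset_gene_similarity(list(g1, g2), g3), max(pair_vals))
  expect_gte(geneset_gene_similarity(list(g1, g2), g3), mean(pair_vals))
  expect_error(geneset_gene_similarity(list(), g1), "non-empty")
})

test_that("miRNA pair similarity composes gene-set terms as specified", {
  we <- worked()
  onto <- we$ontology
  g1 <- build_gene_go_graph(onto, "GO:0048513", gene_id = "g1")
  g2 <- build_gene_go_graph(onto, "GO:0072358", gene_id = "g2")
  g3 <- build_gene_go_graph(onto, "GO:0072359", gene_id = "g3")

  expect_equal(mirna_pair_similarity(list(g1, g2), list(g1, g2)), 1)
  expect_equal(mirna_pair_similarity(list(g1), list(g2)),
               gene_similarity(g1, g2))

  # s = 2, k = 1: three gene-set terms evaluated exhaustively
  got <- mirna_pair_similarity(list(g1, g2), list(g3))
  want <- (max(gene_similarity(g1, g3), gene_similarity(g2, g3)) +
             gene_similarity(g3, g1) + gene_similarity(g3, g2)) / 3
  expect_equal(got, want)
})

test_that("similarity cascade properties hold on random graph pairs", {
  w <- relationship_weights()
  n_cases <- 220
  withr::with_seed(101, {
    for (case in seq_len(n_cases)) {
      rp <- random_gene_pair(n_terms = sample(5:9, 1), n_annot = 2)
      tg1 <- extract_leaf_term_graphs(rp$g1)[[1]]
      tg2 <- extract_leaf_term_graphs(rp$g2)[[1]]

      s_tg <- term_graph_similarity(tg1, tg2, w)
      expect_gte(s_tg, 0); expect_lte(s_tg, 1)
      expect_equal(s_tg, term_graph_similarity(tg2, tg1, w))

      s_g <- gene_similarity(rp$g1, rp$g2, w)
      expect_gte(s_g, 0); expect_lte(s_g, 1)
      expect_equal(s_g, gene_similarity(rp$g2, rp$g1, w))
      # identity holds unless the gene is annotated only with the root
      # (bare-root term graphs are defined to have similarity 0)
      if (!identical(rp$g1$terms, rp$g1$root)) {
        expect_equal(gene_similarity(rp$g1, rp$g1, w), 1)
      }

      s_m <- mirna_pair_similarity(list(rp$g1), list(rp$g2), w)
      expect_equal(s_m, mirna_pair_similarity(list(rp$g2), list(rp$g1), w))

      # identical-input identity at the term-graph level, unless bare root
      if (length(tg1$terms) > 1) {
        expect_equal(term_graph_similarity(tg1, tg1, w), 1)
      }

      # MICA at root implies 0
      m <- merge_term_graphs(tg1, tg2)
      if (find_mica(tg1, tg2, m) == m$root) expect_equal(s_tg, 0)

      # gene-set max dominates the member mean
      vals <- c(gene_similarity(rp$g1, rp$g2, w), gene_similarity(rp$g2, rp$g2, w))
      expect_gte(geneset_gene_similarity(list(rp$g1, rp$g2), rp$g2, w), mean(vals))
    }
  })
})

test_that("mirna_distance is 1 - sim with range checks", {
  expect_equal(mirna_distance(1), 0)
  expect_equal(mirna_distance(0), 1)
  expect_equal(mirna_distance(0.306), 0.694)
  expect_error(mirna_distance(1.2), "0, 1")
  expect_error(mirna_distance(NA_real_))
})

test_that("mirna_dataset drops unusable genes and miRNAs with warnings", {
  we <- worked()
  ann <- tibble::tibble(
    gene_id = c("g1", "g1", "g2", "g3"),
    term = c("GO:0048513", "GO:0072358", "GO:0072359", "GO:9999999")
  )
  targets <- tibble::tibble(
    mirna_id = c("mir-1", "mir-1", "mir-2", "mir-3"),
    gene_id = c("g1", "g2", "g2", "g3")
  )
  expect_warning(
    expect_warning(
      ds <- mirna_dataset(we$ontology, ann, targets,
                          namespace = "biological_process"),
      "annotation"
    ),
    "mir-3"
  )
  expect_setequal(ds$mirna_ids, c("mir-1", "mir-2"))
  expect_length(ds$gene_graphs, 2)
})

test_that("distance matrix is symmetric, zero-diagonal, and cache-invariant", {
  we <- worked()
  ann <- tibble::tibble(
    gene_id = c("ga", "ga", "gb", "gc", "gd"),
    term = c("GO:0048513", "GO:0072358", "GO:0072359", "GO:0048513", "GO:0048856")
  )
  targets <- tibble::tibble(
    mirna_id = c("mir-1", "mir-1", "mir-2", "mir-2", "mir-3"),
    gene_id = c("ga", "gb", "gb", "gc", "gd")
  )
  ds <- mirna_dataset(we$ontology, ann, targets, namespace = "biological_process")
  d <- build_distance_matrix(ds)
  expect_s3_class(d, "mirna_dist")
  expect_equal(d$values, t(d$values))
  expect_equal(unname(diag(d$values)), rep(0, 3))
  expect_true(all(d$values >= 0 & d$values <= 1))

  # the cache must be observationally invisible
  d_nocache <- build_distance_matrix(ds, cache = FALSE)
  expect_equal(d$values, d_nocache$values)

  # entry-by-entry recomputation through the public cascade
  graphs_of <- function(id) unname(purrr::map(ds$targets[[id]], ~ ds$gene_graphs[[.x]]))
  for (i in 1:2) for (j in (i + 1):3) {
    want <- mirna_distance(mirna_pair_similarity(
      graphs_of(d$ids[[i]]), graphs_of(d$ids[[j]])
    ))
    expect_equal(d$values[i, j], want)
  }

  # identical target sets give distance 0
  t2 <- tibble::tibble(mirna_id = c("m1", "m2"), gene_id = c("ga", "ga"))
  ds2 <- mirna_dataset(we$ontology, ann[1:2, ], t2, namespace = "biological_process")
  d2 <- build_distance_matrix(ds2)
  expect_equal(d2$values[1, 2], 0)

  expect_error(build_distance_matrix(ds2$ontology), "mirna_dataset")
})

test_that("distance matrix round-trips through TSV and tidies to long form", {
  we <- worked()
  ann <- tibble::tibble(gene_id = c("ga", "gb"),
                        term = c("GO:0048513", "GO:0072358"))
  targets <- tibble::tibble(mirna_id = c("m1", "m2"), gene_id = c("ga", "gb"))
  ds <- mirna_dataset(we$ontology, ann, targets, namespace = "biological_process")
  d <- build_distance_matrix(ds)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(d, path, header = "test")
  d2 <- read_distance_matrix(path)
  expect_equal(d2$ids, d$ids)
  expect_equal(unname(d2$values), unname(d$values))

  long <- tidy(d)
  expect_equal(nrow(long), 1)
  expect_equal(long$distance, d$values[1, 2])
})

test_that("miRTarBase-style and plain target tables are read identically", {
  plain <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mir-1\tGENE1", "mir-1\tGENE1", "mir-2\tGENE2"), plain)
  t1 <- read_mirna_targets(plain)
  expect_equal(nrow(t1), 2)

  mtb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    paste("miRTarBase ID", "miRNA", "Species (miRNA)", "Target Gene",
          "Target Gene (Entrez ID)", "Species (Target Gene)", "Experiments",
          "Support Type", "References (PMID)", sep = "\t"),
    paste("MIRT001", "mir-1", "hsa", "GENE1", "1", "hsa", "exp", "Functional", "1", sep = "\t"),
    paste("MIRT002", "mir-1", "hsa", "GENE1", "1", "hsa", "exp2", "Functional", "2", sep = "\t"),
    paste("MIRT003", "mir-2", "hsa", "GENE2", "2", "hsa", "exp", "Functional", "3", sep = "\t")
  ), mtb)
  t2 <- read_mirna_targets(mtb)
  expect_equal(t2, t1)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("# nothing", empty)
  expect_error(read_mirna_targets(empty), class = "mirgosim_empty_error")
})
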