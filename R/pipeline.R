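# File-to-file pipeline steps behind the command-line front-end
# (inst/cli/mirgosim). Each step is an ordinary function so scripts and
# tests can drive it directly; outputs are TSV/JSON with '#'-prefixed
# provenance headers, reproducible byte-for-byte given identical inputs and
# seeds.

provenance_header <- function(...) {
  c(sprintf("mirgosim %s", as.character(utils::packageVersion("mirgosim"))), ...)
}

#' Compute and write the miRNA distance matrix from input files
#'
#' Reads an OBO ontology, gene annotations and a miRNA-target table, builds
#' the dataset and writes the pairwise distance matrix as TSV.
#'
#' @param obo Path to the ontology (OBO).
#' @param annotations Path to gene annotations (TSV or GAF).
#' @param targets Path to the miRNA-target TSV.
#' @param out Output TSV path.
#' @param annotation_format `"tsv"` or `"gaf"`.
#' @param namespace Analysis namespace (default `"molecular_function"`).
#' @param weights Output of [relationship_weights()].
#' @param log_base Logarithm base for information content.
#' @return The `mirna_dist`, invisibly.
#' @export
run_similarity <- function(obo, annotations, targets, out,
                           annotation_format = "tsv",
                           namespace = "molecular_function",
                           weights = relationship_weights(), log_base = 10) {
  ontology <- parse_obo(obo)
  ann <- read_gene_annotations(annotations, format = annotation_format,
                               ontology = ontology)
  tg <- read_mirna_targets(targets)
  dataset <- mirna_dataset(ontology, ann, tg, namespace = namespace)
  dist <- build_distance_matrix(dataset, weights = weights, log_base = log_base)
  write_distance_matrix(dist, out, header = provenance_header(
    sprintf("weights: is_a=%g part_of=%g, log_base=%g, namespace=%s",
            weights[["is_a"]], weights[["part_of"]], log_base, namespace)
  ))
  invisible(dist)
}

#' Cluster a miRNA distance matrix and write the results
#'
#' @param dist A `mirna_dist` or a path to a distance-matrix TSV written by
#'   [write_distance_matrix()].
#' @param out_prefix Path prefix; writes `<prefix>_clusters.tsv` and
#'   `<prefix>_eigenvalues.tsv`.
#' @param config A [spectral_config()].
#' @return The `mirna_clustering` fit, invisibly.
#' @export
run_cluster <- function(dist, out_prefix, config = spectral_config()) {
  if (is.character(dist)) dist <- read_distance_matrix(dist)
  fit <- spectral_cluster(dist, config)
  readr::write_tsv(tidy(fit), paste0(out_prefix, "_clusters.tsv"))
  readr::write_tsv(
    tibble(index = seq_along(fit$eigenvalues), eigenvalue = fit$eigenvalues),
    paste0(out_prefix, "_eigenvalues.tsv")
  )
  invisible(fit)
}

#' Evaluate clusters against disease labels and write a JSON report
#'
#' @param fit A `mirna_clustering`, or a path to a `_clusters.tsv` file.
#' @param diseases Path to a miRNA-disease TSV, or a [disease_labels()]
#'   tibble.
#' @param out Output JSON path.
#' @param include_unannotated Passed to [cluster_accuracy()].
#' @return The per-cluster report tibble, invisibly.
#' @export
run_evaluate <- function(fit, diseases, out, include_unannotated = FALSE) {
  if (is.character(fit)) {
    fit <- readr::read_tsv(fit, comment = "#", show_col_types = FALSE)
  }
  labels <- if (is.character(diseases)) read_disease_labels(diseases) else
    disease_labels(diseases)
  report <- evaluate_clusters(fit, labels, include_unannotated)
  predictions <- annotate_unlabeled(fit, labels)
  members <- cluster_assignments(fit) |>
    group_by(.data$cluster) |>
    summarise(members = list(.data$mirna_id), .groups = "drop")
  payload <- list(
    clusters = purrr::pmap(
      left_join(report, members, by = "cluster"),
      function(cluster, n_members, disease, accuracy, n_matching, n_total, members) {
        list(cluster = cluster, n_members = n_members,
             prevailing_disease = disease, accuracy = accuracy,
             n_matching = n_matching, n_total = n_total, members = members)
      }
    ),
    predictions = predictions
  )
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' Generate synthetic input files
#'
#' Writes a planted-cluster synthetic dataset in the standard input formats
#' (OBO, annotation/target/disease TSVs) plus the planted truth labels.
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
run_simulate <- function(spec = synthetic_spec(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_planted_mirna_dataset(spec)
  paths <- c(
    obo = file.path(out_dir, "ontology.obo"),
    annotations = file.path(out_dir, "annotations.tsv"),
    targets = file.path(out_dir, "targets.tsv"),
    diseases = file.path(out_dir, "diseases.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )
  write_obo(sim$ontology, paths[["obo"]])
  write_annotations_tsv(sim$annotations, paths[["annotations"]])
  write_targets_tsv(sim$targets, paths[["targets"]])
  write_diseases_tsv(sim$diseases, paths[["diseases"]])
  readr::write_tsv(sim$truth, paths[["truth"]])
  invisible(paths)
}

#' Print the worked-example reference table and pair similarity
#'
#' Reproduces the per-term table (IC, omega_depth, omega_edge, weighted IC
#' for the 7 terms of the packaged example) and the similarity of the two
#' leaf term graphs, with the default weights is_a = 0.9, part_of = 0.7 and
#' log base 10.
#'
#' @param json Emit machine-readable JSON instead of a printed table.
#' @return Invisibly, a list with the context table and the pair
#'   similarity.
#' @export
run_demo <- function(json = FALSE) {
  we <- load_worked_example()
  ctx <- build_comparison_context(we$tg_a, we$tg_b)
  sim <- term_graph_similarity(we$tg_a, we$tg_b)
  out <- list(table = ctx$table, mica = ctx$mica, similarity = sim)
  if (json) {
    cat(jsonlite::toJSON(list(
      mica = ctx$mica,
      similarity = sim,
      terms = ctx$table
    ), auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
  } else {
    cat(sprintf("Worked example: merged graph of TG(%s) and TG(%s)\n",
                we$tg_a$leaf, we$tg_b$leaf))
    cat(sprintf("MICA: %s\n\n", ctx$mica))
    print(as.data.frame(mutate(ctx$table, dplyr::across(
      c("ic", "depth_weight", "edge_weight", "weighted_ic"),
      ~ round(.x, 3)
    ))), row.names = FALSE)
    cat(sprintf("\nterm-graph similarity: %.3f\n", sim))
  }
  invisible(out)
}
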