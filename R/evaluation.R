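# Prevailing-disease accuracy of clusters and annotation of unlabeled
# miRNAs by cluster membership.

#' Normalize miRNA disease labels
#'
#' Disease names are trimmed and case-folded; duplicate (miRNA, disease)
#' pairs collapse. miRNAs may carry several diseases (multi-label) or none
#' (unannotated).
#'
#' @param x Tibble/data frame with columns `mirna_id`, `disease`.
#' @return A normalized tibble of class `disease_labels`.
#' @export
disease_labels <- function(x) {
  x <- as_tibble(x)
  stopifnot(all(c("mirna_id", "disease") %in% names(x)))
  out <- x |>
    mutate(disease = tolower(trimws(.data$disease))) |>
    filter(!is.na(.data$disease), .data$disease != "") |>
    distinct(.data$mirna_id, .data$disease) |>
    arrange(.data$mirna_id, .data$disease)
  class(out) <- c("disease_labels", class(out))
  out
}

#' Read a miRNA-disease TSV
#'
#' Two columns `mirna_id<TAB>disease`, one pair per row, header optional,
#' `#` comments skipped.
#'
#' @param path Path to the TSV.
#' @return A [disease_labels()] tibble.
#' @export
read_disease_labels <- function(path) {
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) abort("disease TSV must have two columns: mirna_id, disease")
  out <- tibble(mirna_id = raw[[1]], disease = raw[[2]])
  if (nrow(out) > 0 && tolower(out$mirna_id[[1]]) %in% c("mirna_id", "mirna")) {
    out <- out[-1, ]
  }
  disease_labels(out)
}

#' Prevailing disease and accuracy of one cluster
#'
#' The prevailing disease is the one carried by the most cluster members
#' (ties broken lexicographically); the accuracy is its member count over
#' the cluster size. Multi-label miRNAs count toward every disease they
#' carry. By default unannotated members are excluded from the cluster size
#' (evaluation over annotated miRNAs only); set
#' `include_unannotated = TRUE` to count them in the denominator.
#'
#' @param cluster_members Character vector of miRNA ids.
#' @param labels A [disease_labels()] tibble.
#' @param include_unannotated Count unannotated members in the denominator
#'   (default `FALSE`).
#' @return A one-row tibble with `disease`, `accuracy`, `n_matching`,
#'   `n_total`. A cluster with no annotated member gets `NA` disease and
#'   accuracy with `n_total` 0 (or the member count when
#'   `include_unannotated = TRUE`).
#' @examples
#' labs <- disease_labels(tibble::tibble(
#'   mirna_id = c("a", "b", "c"),
#'   disease = c("Breast Neoplasms", "breast neoplasms", "Stomach Neoplasms")
#' ))
#' cluster_accuracy(c("a", "b", "c"), labs)
#' @export
cluster_accuracy <- function(cluster_members, labels,
                             include_unannotated = FALSE) {
  if (length(cluster_members) == 0) abort("cluster is empty")
  labels <- if (inherits(labels, "disease_labels")) labels else disease_labels(labels)
  member_rows <- filter(labels, .data$mirna_id %in% cluster_members)
  annotated <- unique(member_rows$mirna_id)
  n_total <- if (include_unannotated) length(unique(cluster_members)) else length(annotated)
  if (length(annotated) == 0) {
    return(tibble(disease = NA_character_, accuracy = NA_real_,
                  n_matching = 0L, n_total = as.integer(n_total)))
  }
  counts <- member_rows |>
    count_by_disease()
  top <- counts[order(-counts$n, counts$disease), ][1, ]
  tibble(disease = top$disease,
         accuracy = top$n / n_total,
         n_matching = as.integer(top$n),
         n_total = as.integer(n_total))
}

count_by_disease <- function(rows) {
  rows |>
    group_by(.data$disease) |>
    summarise(n = dplyr::n_distinct(.data$mirna_id), .groups = "drop")
}

#' Per-cluster prevailing-disease report
#'
#' Applies [cluster_accuracy()] to every cluster of a fit.
#'
#' @param result A `mirna_clustering` (or a named vector/tibble of labels
#'   as accepted by [tidy()]).
#' @inheritParams cluster_accuracy
#' @return A tibble with one row per cluster: `cluster`, `n_members`,
#'   `disease`, `accuracy`, `n_matching`, `n_total`.
#' @export
evaluate_clusters <- function(result, labels, include_unannotated = FALSE) {
  assign_tbl <- cluster_assignments(result)
  labels <- if (inherits(labels, "disease_labels")) labels else disease_labels(labels)
  assign_tbl |>
    group_by(.data$cluster) |>
    summarise(
      n_members = n(),
      cluster_accuracy(.data$mirna_id, labels, include_unannotated),
      .groups = "drop"
    ) |>
    arrange(.data$cluster)
}

cluster_assignments <- function(result) {
  if (inherits(result, "mirna_clustering")) return(tidy(result))
  tbl <- as_tibble(result)
  stopifnot(all(c("mirna_id", "cluster") %in% names(tbl)))
  tbl
}

#' Annotate unlabeled miRNAs by cluster membership
#'
#' Every miRNA without a disease label receives the prevailing disease of
#' its cluster; members of clusters with no annotated miRNA receive
#' `"unassigned"`.
#'
#' @inheritParams evaluate_clusters
#' @return A tibble with columns `mirna_id`, `cluster`,
#'   `predicted_disease`, one row per unannotated miRNA.
#' @export
annotate_unlabeled <- function(result, labels) {
  assign_tbl <- cluster_assignments(result)
  labels <- if (inherits(labels, "disease_labels")) labels else disease_labels(labels)
  prevailing <- evaluate_clusters(result, labels) |>
    select("cluster", "disease")
  assign_tbl |>
    filter(!.data$mirna_id %in% labels$mirna_id) |>
    left_join(prevailing, by = "cluster") |>
    mutate(predicted_disease = dplyr::coalesce(.data$disease, "unassigned")) |>
    select("mirna_id", "cluster", "predicted_disease")
}
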