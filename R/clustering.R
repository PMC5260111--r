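# Self-tuning spectral clustering of the miRNA distance matrix, with
# eigenvalue-based selection of the number of clusters.
#
# The affinity is a Gaussian kernel on the distances; in self-tuning mode the
# bandwidth is local, sigma_i = mean distance of miRNA i to all others, and
# the kernel uses sigma_i * sigma_j. The spectrum is taken from the
# symmetric normalized operator D^(-1/2) W D^(-1/2) and reported in
# descending order (so connected graphs lead with eigenvalue 1 and the k
# leading values flag k well-separated blocks); 1 - lambda gives the
# normalized-Laplacian view.

#' Spectral clustering configuration
#'
#' @param sigma_mode `"self_tuning"` (per-point bandwidths, the default) or
#'   `"fixed"`.
#' @param fixed_sigma Bandwidth used when `sigma_mode = "fixed"`.
#' @param k Number of clusters; `NULL` (default) selects it from the
#'   eigenvalue spectrum via [select_cluster_count()].
#' @param eigengap_epsilon Stability threshold on consecutive eigenvalue
#'   differences (default 0.01).
#' @param small_eig_delta Threshold under which an eigenvalue counts as
#'   "very small". `NULL` (default) uses `0.1 * lambda_1`.
#' @param window Number of leading eigenvalues inspected during selection
#'   (default 50).
#' @param kmeans_restarts Restarts of the k-means step (default 50).
#' @param random_seed Seed for the k-means step (default 0).
#' @param row_normalize Normalize embedding rows to unit length before
#'   k-means (default `TRUE`).
#' @return A list of class `spectral_config`.
#' @export
spectral_config <- function(sigma_mode = c("self_tuning", "fixed"),
                            fixed_sigma = NULL, k = NULL,
                            eigengap_epsilon = 0.01, small_eig_delta = NULL,
                            window = 50, kmeans_restarts = 50, random_seed = 0,
                            row_normalize = TRUE) {
  sigma_mode <- match.arg(sigma_mode)
  if (sigma_mode == "fixed" && (is.null(fixed_sigma) || fixed_sigma <= 0)) {
    abort("fixed sigma mode requires a positive fixed_sigma")
  }
  stopifnot(eigengap_epsilon > 0, is.null(small_eig_delta) || small_eig_delta > 0,
            window >= 1, kmeans_restarts >= 1)
  if (!is.null(k) && k < 1) abort("k must be a positive integer")
  structure(
    list(sigma_mode = sigma_mode, fixed_sigma = fixed_sigma, k = k,
         eigengap_epsilon = eigengap_epsilon, small_eig_delta = small_eig_delta,
         window = window, kmeans_restarts = kmeans_restarts,
         random_seed = random_seed, row_normalize = row_normalize),
    class = "spectral_config"
  )
}

#' Self-tuning bandwidths
#'
#' `sigma_i = sum_{j != i} d(i, j) / (h - 1)`: the mean distance of each
#' miRNA to all others.
#'
#' @param dist A `mirna_dist` or a symmetric numeric matrix of distances.
#' @return Named numeric vector of positive bandwidths.
#' @export
self_tuning_sigmas <- function(dist) {
  d <- dist_values(dist)
  h <- nrow(d)
  if (h < 2) abort("need at least 2 miRNAs")
  sig <- rowSums(d) / (h - 1)
  if (any(sig <= 0)) {
    abort(paste0(
      "some miRNAs are at distance 0 from every other miRNA; ",
      "self-tuning bandwidths are undefined - use fixed sigma mode"
    ))
  }
  sig
}

dist_values <- function(dist) {
  d <- if (inherits(dist, "mirna_dist")) dist$values else as.matrix(dist)
  if (!isSymmetric(unname(d))) abort("distance matrix must be symmetric")
  if (any(!is.finite(d))) abort("distance matrix has non-finite entries")
  d
}

#' Gaussian affinity matrix from distances
#'
#' Self-tuning mode: `W_ij = exp(-d_ij^2 / (2 sigma_i sigma_j))`; fixed
#' mode: `W_ij = exp(-d_ij^2 / (2 sigma^2))`. The diagonal is exactly 1.
#'
#' @inheritParams self_tuning_sigmas
#' @param config A [spectral_config()].
#' @return Symmetric matrix with unit diagonal, entries in (0, 1].
#' @export
affinity_matrix <- function(dist, config = spectral_config()) {
  d <- dist_values(dist)
  if (config$sigma_mode == "self_tuning") {
    sig <- self_tuning_sigmas(dist)
    denom <- 2 * outer(sig, sig)
  } else {
    denom <- 2 * config$fixed_sigma^2
  }
  w <- exp(-(d^2) / denom)
  diag(w) <- 1
  if (any(!is.finite(w))) abort("affinity matrix has non-finite entries")
  w
}

#' Spectrum of the normalized affinity operator
#'
#' Eigen-decomposition of `D^(-1/2) W D^(-1/2)` with `D = diag(rowSums(W))`,
#' eigenvalues in descending order. `1 - values` are the eigenvalues of the
#' symmetric normalized Laplacian, exposed as `laplacian_values`.
#'
#' @param affinity Symmetric non-negative matrix.
#' @return List with `values` (descending), `vectors` (columns aligned with
#'   `values`), `laplacian_values`.
#' @export
spectrum <- function(affinity) {
  w <- as.matrix(affinity)
  if (!isSymmetric(unname(w)) || any(w < 0)) {
    abort("affinity must be a symmetric non-negative matrix")
  }
  deg <- rowSums(w)
  if (any(deg <= 0)) abort("affinity matrix has a zero-degree row")
  s <- 1 / sqrt(deg)
  nw <- w * outer(s, s)
  nw <- (nw + t(nw)) / 2
  eig <- eigen(nw, symmetric = TRUE)
  list(values = eig$values, vectors = eig$vectors,
       laplacian_values = 1 - eig$values)
}

#' Select the number of clusters from the eigenvalue spectrum
#'
#' Returns the smallest `k >= 2` such that `lambda_{k+1}` is very small
#' (below `small_eig_delta`, default `0.1 * lambda_1`) and the trend of the
#' subsequent eigenvalues is stable: every consecutive difference in the
#' inspected window stays below `eigengap_epsilon`. If no `k` qualifies, the
#' position of the largest consecutive gap is used and a warning emitted.
#'
#' @param eigenvalues Numeric vector sorted in descending order (at least 3
#'   values).
#' @param config A [spectral_config()].
#' @return Integer `k >= 2`.
#' @export
select_cluster_count <- function(eigenvalues, config = spectral_config()) {
  ev <- as.numeric(eigenvalues)
  if (length(ev) < 3) abort("need at least 3 eigenvalues")
  if (is.unsorted(rev(ev), strictly = FALSE)) {
    abort("eigenvalues must be sorted in descending order")
  }
  delta <- config$small_eig_delta %||% (0.1 * ev[[1]])
  w_end <- min(length(ev), config$window)
  diffs <- -diff(ev)  # lambda_j - lambda_{j+1} >= 0
  for (k in 2:(length(ev) - 1)) {
    if (ev[[k + 1]] >= delta) next
    js <- if (k + 1 > w_end - 1) integer(0) else seq(k + 1, w_end - 1)
    if (length(js) == 0 || all(diffs[js] < config$eigengap_epsilon)) {
      return(as.integer(k))
    }
  }
  gap_k <- which.max(diffs[seq(2, length(diffs))]) + 1L
  warn(sprintf(
    "no k satisfied the small-eigenvalue/stability rule; falling back to the largest consecutive gap (k = %d)",
    gap_k
  ))
  as.integer(gap_k)
}

#' Spectral clustering of a miRNA distance matrix
#'
#' Builds the affinity matrix, takes the `k` leading eigenvectors of the
#' normalized operator as an embedding, optionally normalizes the embedding
#' rows to unit length, and runs seeded k-means. `k` comes from `config$k`
#' or from [select_cluster_count()]. Cluster indices are relabeled in order
#' of first appearance so the result is deterministic given the seed.
#'
#' @inheritParams self_tuning_sigmas
#' @param config A [spectral_config()].
#' @return Object of class `mirna_clustering`: list with `labels` (named
#'   integer), `k`, `k_selected` (logical: chosen from the spectrum),
#'   `eigenvalues`, `affinity`, `sigmas` (`NULL` in fixed mode), `ids`.
#' @examples
#' d <- matrix(0.9, 4, 4); d[1:2, 1:2] <- d[3:4, 3:4] <- 0.05; diag(d) <- 0
#' rownames(d) <- colnames(d) <- paste0("mir-", 1:4)
#' fit <- spectral_cluster(d, spectral_config(k = 2))
#' tidy(fit)
#' @export
spectral_cluster <- function(dist, config = spectral_config()) {
  d <- dist_values(dist)
  ids <- if (inherits(dist, "mirna_dist")) dist$ids else
    (rownames(d) %||% paste0("item_", seq_len(nrow(d))))
  h <- nrow(d)
  w <- affinity_matrix(dist, config)
  sp <- spectrum(w)
  k <- config$k
  if (is.null(k)) k <- select_cluster_count(sp$values, config)
  if (k > h) abort(sprintf("k = %d exceeds the number of miRNAs (%d)", k, h))
  if (k < 1) abort("k must be at least 1")

  u <- sp$vectors[, seq_len(k), drop = FALSE]
  if (config$row_normalize) {
    nrm <- sqrt(rowSums(u^2))
    nrm[nrm == 0] <- 1
    u <- u / nrm
  }
  if (k == h) {
    # one miRNA per cluster; k-means is degenerate here
    labels <- seq_len(h)
  } else {
    km <- withr::with_seed(
      config$random_seed,
      kmeans(u, centers = k, nstart = config$kmeans_restarts, iter.max = 100)
    )
    labels <- canonical_labels(km$cluster)
  }
  names(labels) <- ids
  structure(
    list(labels = labels, k = as.integer(k),
         k_selected = is.null(config$k),
         eigenvalues = sp$values,
         laplacian_values = sp$laplacian_values,
         affinity = w,
         sigmas = if (config$sigma_mode == "self_tuning") self_tuning_sigmas(dist) else NULL,
         ids = ids, config = config),
    class = "mirna_clustering"
  )
}

# Relabel clusters by order of first appearance (1, 2, ...).
canonical_labels <- function(labels) {
  as.integer(match(labels, unique(labels)))
}

#' @export
print.mirna_clustering <- function(x, ...) {
  cat(sprintf("<mirna_clustering> %d miRNAs in %d clusters (k %s)\n",
              length(x$labels), x$k,
              if (x$k_selected) "selected from spectrum" else "fixed"))
  print(table(cluster = x$labels))
  invisible(x)
}

#' @rdname tidy
#' @return For `mirna_clustering`: a tibble with columns `mirna_id`,
#'   `cluster`.
#' @method tidy mirna_clustering
#' @export
tidy.mirna_clustering <- function(x, ...) {
  tibble(mirna_id = names(x$labels), cluster = unname(x$labels))
}

#' @rdname glance
#' @param x A fitted object.
#' @param ... Unused.
#' @return For `mirna_clustering`: a one-row tibble with `n`, `k`,
#'   `k_selected`, `lambda_1`, `lambda_k`, `lambda_k1`, `eigengap`.
#' @method glance mirna_clustering
#' @export
glance.mirna_clustering <- function(x, ...) {
  ev <- x$eigenvalues
  tibble(
    n = length(x$labels), k = x$k, k_selected = x$k_selected,
    lambda_1 = ev[[1]], lambda_k = ev[[x$k]],
    lambda_k1 = if (x$k < length(ev)) ev[[x$k + 1]] else NA_real_,
    eigengap = if (x$k < length(ev)) ev[[x$k]] - ev[[x$k + 1]] else NA_real_
  )
}

#' Eigenvalue scree plot of a clustering fit
#'
#' Descending eigenvalues of the normalized affinity operator with the
#' selected cluster count marked.
#'
#' @param object A `mirna_clustering`.
#' @param n_values Number of leading eigenvalues to show (default 50).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mirna_clustering
#' @export
autoplot.mirna_clustering <- function(object, n_values = 50, ...) {
  n <- min(n_values, length(object$eigenvalues))
  df <- tibble(index = seq_len(n), eigenvalue = object$eigenvalues[seq_len(n)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$eigenvalue)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k + 0.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "eigenvalue index", y = "eigenvalue",
                  title = sprintf("Normalized-operator spectrum (k = %d)", object$k)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.mirna_clustering
#' @param fit A `mirna_clustering`.
#' @export
plot_eigenvalues <- function(fit, n_values = 50) {
  autoplot.mirna_clustering(fit, n_values = n_values)
}
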