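# Module 2: gene-subspace discovery by perturbation clustering.
#
# Genuinely distinct gene groups keep their pairwise connectivity when the
# data are perturbed with small Gaussian noise; a wrong cluster number breaks
# connectivity under perturbation. For each candidate k the genes are
# clustered on the original data and on noise-perturbed copies; the absolute
# difference between the original connectivity matrix and the mean perturbed
# connectivity is summarised by the area under the empirical CDF of its
# entries (AUC of the CDF-DM). Perfectly stable clusters give AUC 1; the k
# with the highest AUC is selected.

#' Binary connectivity matrix of a partition
#'
#' @param labels vector of cluster labels over N items.
#' @return N x N numeric 0/1 matrix; entry (i, j) is 1 iff items i and j share
#'   a label. Symmetric, unit diagonal, invariant to label renaming.
#' @examples
#' connectivity_matrix(c("A", "A", "B"))
#' @export
connectivity_matrix <- function(labels) {
  if (length(labels) == 0L) {
    abort_srimpute("labels must be non-empty", "srimpute_domain_error")
  }
  outer(labels, labels, `==`) * 1
}

#' Add Gaussian perturbation noise to a matrix
#'
#' @param matrix numeric matrix (training genes x cells).
#' @param noise_sd standard deviation of the i.i.d. N(0, noise_sd^2) noise.
#' @param seed integer seed; the same seed reproduces the same perturbation.
#' @return the perturbed matrix; the input is not modified.
#' @export
perturb <- function(matrix, noise_sd, seed = 1L) {
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort_srimpute("noise_sd must be a single non-negative number",
                   "srimpute_domain_error")
  }
  set.seed(seed)
  matrix + stats::rnorm(length(matrix), 0, noise_sd)
}

#' AUC of the empirical CDF of the connectivity difference matrix
#'
#' Forms `D = |original - perturbed|` element-wise and integrates the
#' empirical CDF of D's entries over \[0, 1\] (exact area under the
#' right-continuous step function). Identical matrices give AUC 1; maximally
#' discordant matrices give 0. Monotone: element-wise larger differences never
#' increase the AUC.
#'
#' @param original_conn binary connectivity matrix of the unperturbed
#'   clustering.
#' @param perturbed_conn element-wise mean of perturbed connectivity matrices,
#'   values in \[0, 1\].
#' @return the AUC, a number in \[0, 1\].
#' @export
auc_cdf_dm <- function(original_conn, perturbed_conn) {
  if (!identical(dim(original_conn), dim(perturbed_conn))) {
    abort_srimpute("connectivity matrices must have the same shape",
                   "srimpute_domain_error")
  }
  d <- abs(as.numeric(original_conn) - as.numeric(perturbed_conn))
  f <- stats::ecdf(d)
  knots <- sort(unique(c(0, d, 1)))
  # step CDF is constant on [t_i, t_{i+1}); the integral is exact
  sum(f(knots[-length(knots)]) * diff(knots))
}

#' Discover gene subspaces in the training data by perturbation clustering
#'
#' For each k in `k_range`, the training genes (rows; cells as features,
#' optionally PCA-reduced) are clustered with k-means, and each of `n_perturb`
#' Gaussian-noise perturbed copies is clustered with the same k. The AUC of
#' the CDF of the |original - mean perturbed| connectivity difference scores
#' the stability of that k; the k with the highest AUC wins (ties go to the
#' smallest k). Final labels are the original-data k-means partition at the
#' selected k.
#'
#' Two scalability valves exist for large inputs: `pca_components` projects
#' the cell dimension onto leading principal components before clustering, and
#' `max_cluster_genes` subsamples the genes used for clustering/AUC, with the
#' remaining genes assigned to their nearest centroid afterwards. Both default
#' to `"auto"`: PCA (50 components) switches on above 500 cells, subsampling
#' (2000 genes) above 2000 training genes.
#'
#' @param training numeric matrix of training genes x cells.
#' @param k_range integer vector of candidate cluster counts (default 2:10);
#'   shrunk with a warning when there are too few genes.
#' @param n_perturb number of perturbed copies per k (default 20).
#' @param noise_sd perturbation noise sd; `NULL` (auto) uses the median of the
#'   per-gene standard deviations of the training matrix.
#' @param seed master seed; all randomness (noise, k-means starts,
#'   subsampling) is derived from it.
#' @param max_cluster_genes `"auto"`, `NULL` (off) or an integer cap on genes
#'   used during clustering.
#' @param pca_components `"auto"`, `NULL` (off) or the number of principal
#'   components for the cell dimension.
#' @param restarts k-means restarts per clustering (best inertia kept).
#' @return an object of class `SubspaceModel`: `k_star`, `labels` (named
#'   integer vector over all training genes), `centroids` (k_star x dims, in
#'   clustering space), `auc_by_k`, `projection` (`NULL` or list with `center`
#'   and `rotation`), `noise_sd`, `n_perturb`, `seed`.
#' @export
discover_subspaces <- function(training, k_range = 2:10, n_perturb = 20,
                               noise_sd = NULL, seed = 1L,
                               max_cluster_genes = "auto",
                               pca_components = "auto", restarts = 10) {
  stopifnot(is.matrix(training), is.numeric(training))
  g <- nrow(training)
  if (ncol(training) < 2L) {
    abort_srimpute("need at least 2 cells to discover subspaces",
                   "srimpute_domain_error")
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range > g - 1L)) {
    warning(sprintf("shrinking k_range: only %d training genes", g))
    k_range <- k_range[k_range <= g - 1L]
  }
  k_range <- k_range[k_range >= 1L]
  if (length(k_range) == 0L) {
    abort_srimpute("k_range is empty after shrinking to the gene count",
                   "srimpute_domain_error")
  }

  if (identical(pca_components, "auto")) {
    pca_components <- if (ncol(training) > 500L) 50L else NULL
  }
  if (identical(max_cluster_genes, "auto")) {
    max_cluster_genes <- if (g > 2000L) 2000L else NULL
  }
  if (is.null(noise_sd)) {
    noise_sd <- stats::median(apply(training, 1L, stats::sd))
    if (!is.finite(noise_sd) || noise_sd == 0) noise_sd <- 1
  }

  # Optional PCA projection of the cell dimension (genes stay the rows).
  projection <- NULL
  if (!is.null(pca_components)) {
    pca_components <- min(as.integer(pca_components), ncol(training), g)
    ctr <- colMeans(training)
    xc <- sweep(training, 2L, ctr)
    sv <- La.svd(xc, nu = 0L, nv = pca_components)
    rotation <- t(sv$vt[seq_len(pca_components), , drop = FALSE])
    projection <- list(center = ctr, rotation = rotation)
  }
  project <- function(m) {
    if (is.null(projection)) m
    else sweep(m, 2L, projection$center) %*% projection$rotation
  }

  xp <- project(training)

  # Subsample the genes used for clustering and AUC; the rest are assigned to
  # the nearest centroid at the end.
  sub_idx <- seq_len(g)
  if (!is.null(max_cluster_genes) && g > max_cluster_genes) {
    set.seed(derive_seed(seed, "subsample"))
    sub_idx <- sort(sample.int(g, max_cluster_genes))
  }
  xs <- xp[sub_idx, , drop = FALSE]

  run_kmeans <- function(dat, k, sd_seed) {
    set.seed(sd_seed)
    stats::kmeans(dat, centers = k, nstart = restarts, iter.max = 50L)
  }

  # Perturbed copies are generated once (in the original space), projected
  # with the same loadings, and reused across all k.
  perturbed <- vector("list", n_perturb)
  for (b in seq_len(n_perturb)) {
    pm <- perturb(training, noise_sd, derive_seed(seed, "perturb", b))
    perturbed[[b]] <- project(pm)[sub_idx, , drop = FALSE]
  }

  auc_by_k <- stats::setNames(numeric(length(k_range)), k_range)
  orig_fit <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- run_kmeans(xs, k, derive_seed(seed, "kmeans_orig", k))
    orig_fit[[i]] <- fit
    conn0 <- connectivity_matrix(fit$cluster)
    acc <- base::matrix(0, nrow(conn0), ncol(conn0))
    for (b in seq_len(n_perturb)) {
      fitp <- run_kmeans(perturbed[[b]], k, derive_seed(seed, "kmeans_pert", k * 1000L + b))
      acc <- acc + connectivity_matrix(fitp$cluster)
    }
    auc_by_k[i] <- auc_cdf_dm(conn0, acc / n_perturb)
  }

  best <- which(auc_by_k == max(auc_by_k))[1L] # ties -> smallest k
  k_star <- k_range[best]
  fit <- orig_fit[[best]]

  labels <- integer(g)
  labels[sub_idx] <- fit$cluster
  if (length(sub_idx) < g) {
    rest <- setdiff(seq_len(g), sub_idx)
    d2 <- cross_dist2(xp[rest, , drop = FALSE], fit$centers)
    labels[rest] <- max.col(-d2, ties.method = "first")
  }
  names(labels) <- rownames(training)

  centroids <- t(vapply(seq_len(k_star), function(k) {
    colMeans(xp[labels == k, , drop = FALSE])
  }, numeric(ncol(xp))))

  structure(list(
    k_star = k_star,
    labels = labels,
    centroids = centroids,
    auc_by_k = auc_by_k,
    projection = projection,
    noise_sd = noise_sd,
    n_perturb = n_perturb,
    seed = seed
  ), class = "SubspaceModel")
}

# Squared Euclidean distances between rows of a and rows of b.
#' @keywords internal
cross_dist2 <- function(a, b) {
  an <- rowSums(a^2)
  bn <- rowSums(b^2)
  d2 <- outer(an, bn, `+`) - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' @export
print.SubspaceModel <- function(x, ...) {
  cat(sprintf("SubspaceModel: k* = %d over %d genes (noise sd %.4g, %d perturbations)\n",
              x$k_star, length(x$labels), x$noise_sd, x$n_perturb))
  cat("AUC by k:", paste(sprintf("%s=%.4f", names(x$auc_by_k), x$auc_by_k),
                         collapse = " "), "\n")
  invisible(x)
}

#' Export the per-k AUC trace as TSV
#' @param model a `SubspaceModel`.
#' @param path output TSV path.
#' @export
write_auc_tsv <- function(model, path) {
  data.table::fwrite(
    data.frame(k = as.integer(names(model$auc_by_k)), auc = model$auc_by_k),
    path, sep = "\t")
  invisible(path)
}
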