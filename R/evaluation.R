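# Evaluation metrics: clustering agreement (ARI, Jaccard, purity), imputation
# error (MAE, Pearson r, per-gene median MAE), landscape similarity (distance
# correlation) and per-gene intra-dispersion.

# Pair-counting contingency summaries shared by ARI and Jaccard.
#' @keywords internal
pair_counts <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    abort_srimpute("label vectors must have equal length", "srimpute_domain_error")
  }
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  list(n_pairs = choose(n, 2), both = sum_ij, a_only = sum_a - sum_ij,
       b_only = sum_b - sum_ij, sum_a = sum_a, sum_b = sum_b)
}

#' Adjusted Rand Index
#'
#' Corrected-for-chance agreement between two partitions via the standard
#' pair-counting contingency formula: 1 for identical partitions (up to label
#' renaming), expectation 0 against random partitionings.
#'
#' @param labels_a,labels_b partitions of the same items.
#' @return the ARI, in \[-1, 1\].
#' @examples
#' ari(c(1, 1, 2, 2), c(2, 2, 1, 1)) # 1
#' @export
ari <- function(labels_a, labels_b) {
  pc <- pair_counts(labels_a, labels_b)
  expected <- pc$sum_a * pc$sum_b / pc$n_pairs
  max_index <- (pc$sum_a + pc$sum_b) / 2
  if (max_index == expected) return(1) # both partitions degenerate
  (pc$both - expected) / (max_index - expected)
}

#' Pair-based Jaccard index of two partitions
#'
#' `a / (a + b + c)` where `a` counts pairs co-clustered in both partitions
#' and `b`, `c` pairs co-clustered in exactly one. The degenerate `0/0` case
#' (no co-clustered pair anywhere) returns 0 by convention.
#'
#' @inheritParams ari
#' @return the Jaccard index, in \[0, 1\].
#' @export
jaccard_index <- function(labels_a, labels_b) {
  pc <- pair_counts(labels_a, labels_b)
  denom <- pc$both + pc$a_only + pc$b_only
  if (denom == 0) return(0)
  pc$both / denom
}

#' Purity of a predicted clustering against truth classes
#'
#' `(1/N) * sum` over predicted clusters of the largest overlap with any
#' truth class. Note the known degenerate optimum: an all-singleton
#' prediction scores 1.
#'
#' @param predicted predicted cluster labels.
#' @param truth ground-truth class labels.
#' @return purity, in (0, 1\].
#' @export
purity <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort_srimpute("label vectors must have equal length", "srimpute_domain_error")
  }
  tab <- table(predicted, truth)
  sum(apply(tab, 1L, max)) / length(predicted)
}

#' Distance correlation between two embeddings of the same cells
#'
#' Energy-statistics distance correlation: pairwise Euclidean distance
#' matrices of `X` and `Y` are double-centered to `A` and `B`;
#' `dCov^2 = mean(A*B)`, `dVar^2(X) = mean(A*A)`, and
#' `dCor = dCov / sqrt(dVar(X) dVar(Y))`. It equals 1 for identical
#' landscapes, is invariant to rotation and translation of either embedding,
#' and captures nonlinear association. Returns 0 when either embedding is
#' degenerate (zero distance variance).
#'
#' @param X,Y numeric matrices with one row per cell (same row count).
#' @return dCor, in \[0, 1\].
#' @export
distance_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) {
    abort_srimpute("X and Y must have the same number of rows",
                   "srimpute_domain_error")
  }
  if (nrow(X) < 2L) {
    abort_srimpute("need at least 2 rows", "srimpute_domain_error")
  }
  dc <- function(M) {
    d <- as.matrix(stats::dist(M))
    sweep(sweep(d, 1L, rowMeans(d)), 2L, colMeans(d)) + mean(d)
  }
  A <- dc(X); B <- dc(Y)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A)
  dvary <- mean(B * B)
  if (dvarx <= 0 || dvary <= 0) return(0)
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvarx) * sqrt(dvary))
}

#' Imputation error over masked entries
#'
#' Compares imputed values with the ground truth at the masked entries: mean
#' absolute error and Pearson correlation over all masked entries, plus the
#' per-gene MAE over the dropout genes (genes with at least one masked entry)
#' and its median — reported because gene-wise medians are robust to a few
#' badly recovered genes.
#'
#' @param imputed,complete matrices of the same shape.
#' @param mask logical matrix, `TRUE` at masked (dropout) entries.
#' @return a list with `mae`, `pearson_r`, `per_gene_mae` (named vector over
#'   dropout genes) and `median_gene_mae`.
#' @export
imputation_error <- function(imputed, complete, mask) {
  if (!all(dim(imputed) == dim(complete)) || !all(dim(imputed) == dim(mask))) {
    abort_srimpute("imputed, complete and mask must have the same shape",
                   "srimpute_domain_error")
  }
  if (!any(mask)) {
    abort_srimpute("mask is empty: nothing to evaluate", "srimpute_domain_error")
  }
  err <- imputed[mask] - complete[mask]
  mae <- mean(abs(err))
  r <- if (stats::sd(imputed[mask]) == 0 || stats::sd(complete[mask]) == 0) {
    NA_real_
  } else {
    stats::cor(imputed[mask], complete[mask])
  }
  drop_genes <- which(rowSums(mask) > 0)
  per_gene <- vapply(drop_genes, function(gi) {
    m <- mask[gi, ]
    mean(abs(imputed[gi, m] - complete[gi, m]))
  }, numeric(1))
  names(per_gene) <- (rownames(complete) %||% as.character(seq_len(nrow(complete))))[drop_genes]
  list(mae = mae, pearson_r = r, per_gene_mae = per_gene,
       median_gene_mae = stats::median(per_gene))
}

#' Per-gene normalized intra-dispersion
#'
#' For each gene, the pooled within-cell-type standard deviation divided by
#' the gene's overall standard deviation. A gene that is constant within each
#' type but differs across types scores 0; with a single cell type the ratio
#' is 1. Genes with zero overall sd are reported as 0; labels with fewer than
#' 2 cells are excluded with a warning.
#'
#' @param matrix expression matrix (genes x cells).
#' @param cell_labels cell-type label per column.
#' @return named numeric vector of ratios, one per gene.
#' @export
intra_dispersion <- function(matrix, cell_labels) {
  stopifnot(ncol(matrix) == length(cell_labels))
  counts <- table(cell_labels)
  small <- names(counts)[counts < 2]
  if (length(small) > 0L) {
    warning(sprintf("excluding label(s) with < 2 cells: %s",
                    paste(small, collapse = ", ")))
    keep <- !(as.character(cell_labels) %in% small)
    matrix <- matrix[, keep, drop = FALSE]
    cell_labels <- cell_labels[keep]
  }
  groups <- split(seq_len(ncol(matrix)), cell_labels)
  n <- ncol(matrix)
  # pooled within-type variance: sum of within-type SS over (n - #types)
  ss_within <- Reduce(`+`, lapply(groups, function(cols) {
    sub <- matrix[, cols, drop = FALSE]
    rowSums((sub - rowMeans(sub))^2)
  }))
  sd_within <- sqrt(ss_within / (n - length(groups)))
  sd_total <- apply(matrix, 1L, stats::sd)
  ratio <- ifelse(sd_total > 0, sd_within / sd_total, 0)
  names(ratio) <- rownames(matrix)
  ratio
}

#' Cluster cells with k-means
#'
#' Cells are the points (genes are features); the best of `restarts` seeded
#' initializations by total within-cluster sum of squares is kept.
#'
#' @param matrix expression matrix (genes x cells).
#' @param k number of clusters.
#' @param seed integer seed.
#' @param restarts number of k-means restarts (default 20).
#' @return integer vector of cell labels, named by cell id.
#' @export
cluster_cells <- function(matrix, k, seed = 1L, restarts = 20) {
  if (k < 1) abort_srimpute("k must be >= 1", "srimpute_domain_error")
  if (k > ncol(matrix)) {
    abort_srimpute("k exceeds the number of cells", "srimpute_domain_error")
  }
  if (k == 1L) {
    return(stats::setNames(rep(1L, ncol(matrix)), colnames(matrix)))
  }
  set.seed(seed)
  fit <- stats::kmeans(t(matrix), centers = k, nstart = restarts, iter.max = 50L)
  stats::setNames(fit$cluster, colnames(matrix))
}
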