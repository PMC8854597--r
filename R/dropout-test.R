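# Module 1: hypergeometric testing of zero entries.
#
# For a zero entry shared by a gene and a cell, let n be the number of
# measured values in the gene (= number of cells), m the number measured in
# the cell (= number of genes), x the number of zeros in the gene and r the
# total number of zeros in the gene-cell pair (the shared entry counted
# once). Under the null that zeros arise at a common rate in the gene and
# the cell, the zero count of the gene conditional on the pair total is
# hypergeometric. Because the tested entry belongs to both the gene and the
# cell, the overlap is removed: population n + m - 1, success states n - 1,
# draws r - 1, observed successes x - 1.

#' Overlap-corrected hypergeometric probability mass
#'
#' Probability of observing exactly `x` zeros in a gene with `n` measured
#' values, given `r` total zeros in the gene-cell pair where the cell has `m`
#' measured values and the pair shares one (zero-valued) entry:
#' \deqn{P = \frac{\binom{n-1}{x-1}\binom{m}{r-x}}{\binom{n+m-1}{r-1}}.}
#' Computed in log space (via `lchoose`) so that matrices with up to ~1e6
#' cells + genes do not overflow.
#'
#' @param n measured values in the gene (number of cells).
#' @param m measured values in the cell (number of genes).
#' @param x zeros observed in the gene, `1 <= x <= min(n, r)`.
#' @param r zeros in the gene-cell pair, `x <= r <= n + m - 1`, `r - x <= m`.
#' @return the probability mass, vectorised over its arguments.
#' @examples
#' hypergeom_pmf(4, 3, 2, 3) # 9/15
#' @export
hypergeom_pmf <- function(n, m, x, r) {
  k <- max(length(n), length(m), length(x), length(r))
  n <- rep_len(as.numeric(n), k); m <- rep_len(as.numeric(m), k)
  x <- rep_len(as.numeric(x), k); r <- rep_len(as.numeric(r), k)
  bad <- x < 1 | x > pmin(n, r) | r > n + m - 1 | r - x > m |
    n < 1 | m < 0 | n != round(n) | m != round(m) | x != round(x) | r != round(r)
  if (any(bad)) {
    abort_srimpute("hypergeom_pmf arguments outside the valid domain",
                   "srimpute_domain_error")
  }
  exp(lchoose(n - 1, x - 1) + lchoose(m, r - x) - lchoose(n + m - 1, r - 1))
}

#' Test every zero entry of an expression matrix for dropout
#'
#' For each zero entry, both one-sided tail probabilities of the
#' overlap-corrected hypergeometric are computed, inclusive of the observed
#' count on both sides: `p_over` is the probability of at least as many zeros
#' in the gene (over-representation, i.e. dropout suspicion) and `p_under`
#' of at most as many (under-representation, i.e. the zero looks like a
#' trusted biological zero).
#'
#' @param matrix expression matrix (genes x cells); only exact zeros are
#'   tested.
#' @return a `data.frame` with one row per zero entry: integer indices
#'   `gene`, `cell`, the counts `x` (zeros in the gene) and `r` (zeros in the
#'   pair), and `p_over` / `p_under`. The matrix dimensions are attached as
#'   attributes `n` (cells) and `m` (genes). Zero rows when the matrix has no
#'   zeros.
#' @export
zero_entry_pvalues <- function(matrix) {
  stopifnot(is.matrix(matrix), is.numeric(matrix))
  n <- ncol(matrix) # measured values per gene
  m <- nrow(matrix) # measured values per cell
  zero <- matrix == 0
  idx <- which(zero)
  res <- if (length(idx) == 0L) {
    data.frame(gene = integer(0), cell = integer(0), x = numeric(0),
               r = numeric(0), p_over = numeric(0), p_under = numeric(0))
  } else {
    zg <- as.integer(rowSums(zero))   # x per gene
    zc <- as.integer(colSums(zero))   # zeros per cell
    rm(zero)
    gi <- as.integer(((idx - 1L) %% m) + 1L)
    ci <- as.integer(((idx - 1L) %/% m) + 1L)
    rm(idx)
    x <- zg[gi]
    r <- x + zc[ci] - 1L
    # The tails depend on the entry only through (x, r): evaluate each
    # distinct pair once and map back. Hypergeometric: population n+m-1,
    # successes n-1, draws r-1, observed x-1; tails inclusive of x-1.
    key <- as.numeric(x) * (n + m) + as.numeric(r)
    uq <- unique(key)
    pos <- match(key, uq)
    rm(key)
    ux <- uq %/% (n + m)
    ur <- uq %% (n + m)
    up_under <- pmin(stats::phyper(ux - 1, n - 1, m, ur - 1), 1)
    up_over <- pmin(stats::phyper(ux - 2, n - 1, m, ur - 1,
                                  lower.tail = FALSE), 1)
    out <- data.frame(gene = gi, cell = ci, x = as.numeric(x),
                      r = as.numeric(r), p_over = up_over[pos],
                      p_under = up_under[pos])
    rm(gi, ci, x, r, pos)
    out
  }
  attr(res, "n") <- n
  attr(res, "m") <- m
  res
}

#' Label zero entries as imputable, trustworthy or neutral
#'
#' An entry whose over-representation p-value falls below `alpha` is labelled
#' `imputable` (judged dropout-induced); one whose under-representation
#' p-value falls below `alpha` is `trustworthy`; all others are `neutral` and
#' are left alone — neither imputed nor used to impute. No multiple-testing
#' correction is applied: the threshold is per entry.
#'
#' @param tests data.frame from [zero_entry_pvalues()].
#' @param alpha per-entry significance threshold in (0, 1); default 0.01.
#' @return `tests` with a `label` column added.
#' @export
classify_entries <- function(tests, alpha = 0.01) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    abort_srimpute("alpha must be a single number in (0, 1)",
                   "srimpute_domain_error")
  }
  lab <- rep("neutral", nrow(tests))
  over <- tests$p_over < alpha
  under <- tests$p_under < alpha
  if (any(over & under)) {
    # Impossible for alpha <= 0.5: the inclusive tails overlap at x-1, so
    # p_over + p_under = 1 + pmf(x-1) >= 1.
    abort_srimpute("entry significant in both tails; inconsistent p-values",
                   "srimpute_internal_error")
  }
  lab[over] <- "imputable"
  lab[under] <- "trustworthy"
  tests$label <- factor(lab, levels = c("imputable", "trustworthy", "neutral"))
  tests
}

#' Partition genes into training, imputable and pass-through sets
#'
#' Non-zero entries count as trustworthy. A gene belongs to the training set
#' `T` when every one of its zero entries is labelled trustworthy (genes with
#' no zeros qualify vacuously); to the imputable set `I` when at least one of
#' its zeros is labelled imputable; all remaining genes are pass-through:
#' copied to the output unchanged and never used for training.
#'
#' @param matrix the tested expression matrix.
#' @param tests labelled tests from [classify_entries()]; must cover every
#'   zero entry of `matrix`.
#' @return a list of class `GenePartition` with character vectors
#'   `training_genes`, `imputable_genes`, `passthrough_genes`, the logical
#'   `imputable_entry_mask` (genes x cells, `TRUE` exactly at
#'   imputable-labelled entries), and integer index vectors `training_idx`,
#'   `imputable_idx`.
#' @export
partition_genes <- function(matrix, tests) {
  stopifnot(is.matrix(matrix))
  if (is.null(tests$label)) {
    abort_srimpute("tests must be labelled; run classify_entries() first",
                   "srimpute_validation_error")
  }
  n_zero <- sum(matrix == 0)
  if (nrow(tests) != n_zero) {
    abort_srimpute(sprintf(
      "tests cover %d entries but the matrix has %d zeros", nrow(tests), n_zero),
      "srimpute_consistency_error")
  }
  g <- nrow(matrix)
  ids <- rownames(matrix) %||% as.character(seq_len(g))

  has_imp <- logical(g)
  has_nontrust <- logical(g) # any zero entry not labelled trustworthy
  if (nrow(tests) > 0L) {
    imp <- tests$label == "imputable"
    has_imp[unique(tests$gene[imp])] <- TRUE
    nt <- tests$label != "trustworthy"
    has_nontrust[unique(tests$gene[nt])] <- TRUE
  }
  training <- !has_nontrust          # all zeros trustworthy (or no zeros)
  imputable <- has_imp
  passthrough <- !training & !imputable

  mask <- base::matrix(FALSE, g, ncol(matrix), dimnames = dimnames(matrix))
  if (any(has_imp)) {
    rows <- tests$gene[imp]
    cols <- tests$cell[imp]
    mask[cbind(rows, cols)] <- TRUE
  }

  structure(list(
    training_genes = ids[training],
    imputable_genes = ids[imputable],
    passthrough_genes = ids[passthrough],
    imputable_entry_mask = mask,
    training_idx = which(training),
    imputable_idx = which(imputable)
  ), class = "GenePartition")
}

#' @export
print.GenePartition <- function(x, ...) {
  cat(sprintf(
    "GenePartition: %d training, %d imputable (%d flagged entries), %d pass-through\n",
    length(x$training_genes), length(x$imputable_genes),
    sum(x$imputable_entry_mask), length(x$passthrough_genes)))
  invisible(x)
}

#' Export zero-entry tests with gene/cell identifiers as TSV
#'
#' @param tests labelled test table from [classify_entries()].
#' @param matrix the matrix the tests were computed on (for ids).
#' @param path output TSV path.
#' @export
write_tests_tsv <- function(tests, matrix, path) {
  df <- data.frame(
    gene_id = (rownames(matrix) %||% as.character(seq_len(nrow(matrix))))[tests$gene],
    cell_id = (colnames(matrix) %||% as.character(seq_len(ncol(matrix))))[tests$cell],
    n = attr(tests, "n") %||% ncol(matrix),
    m = attr(tests, "m") %||% nrow(matrix),
    x = tests$x, r = tests$r,
    p_over = tests$p_over, p_under = tests$p_under,
    label = as.character(tests$label)
  )
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
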