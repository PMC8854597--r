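# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive (direct enumeration / double loops) and share no code
# with the package implementation.

# Exact tail probabilities of the overlap-corrected hypergeometric by direct
# enumeration over the support: arrangements of r-1 zeros among n+m-1
# positions of which n-1 belong to the gene, grouped by the gene's zero
# count k. Counts use exact binomial coefficients.
oracle_hyper_tails <- function(n, m, x, r) {
  ks <- max(0, (r - 1) - m):min(n - 1, r - 1) # support of the gene zero count
  counts <- choose(n - 1, ks) * choose(m, (r - 1) - ks)
  probs <- counts / choose(n + m - 1, r - 1)
  list(
    p_under = sum(probs[ks <= x - 1]),
    p_over = sum(probs[ks >= x - 1]),
    pmf = sum(probs[ks == x - 1])
  )
}

# Pair-enumeration ARI / Jaccard over all item pairs (O(N^2)).
oracle_pair_metrics <- function(a, b) {
  n <- length(a)
  both <- one_a <- one_b <- neither <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      if (sa && sb) both <- both + 1
      else if (sa) one_a <- one_a + 1
      else if (sb) one_b <- one_b + 1
      else neither <- neither + 1
    }
  }
  total <- both + one_a + one_b + neither
  sum_a <- both + one_a
  sum_b <- both + one_b
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  ari <- if (max_index == expected) 1 else (both - expected) / (max_index - expected)
  jac <- if (both + one_a + one_b == 0) 0 else both / (both + one_a + one_b)
  list(ari = ari, jaccard = jac)
}

# Naive distance correlation: explicit double-centering with scalar loops.
oracle_dcor <- function(X, Y) {
  n <- nrow(X)
  dmat <- function(M) {
    d <- matrix(0, n, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) d[i, j] <- sqrt(sum((M[i, ] - M[j, ])^2))
    }
    d
  }
  center <- function(d) {
    out <- matrix(0, n, n)
    rm_ <- rowMeans(d); cm_ <- colMeans(d); gm <- mean(d)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) out[i, j] <- d[i, j] - rm_[i] - cm_[j] + gm
    }
    out
  }
  A <- center(dmat(as.matrix(X)))
  B <- center(dmat(as.matrix(Y)))
  dcov2 <- mean(A * B)
  dvx <- mean(A * A); dvy <- mean(B * B)
  if (dvx <= 0 || dvy <= 0) return(0)
  sqrt(max(dcov2, 0)) / sqrt(sqrt(dvx) * sqrt(dvy))
}

# Strip package attributes so matrices compare on dim/dimnames/values only.
unclass_mat <- function(m) {
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}

# Small fixture: matrix with a planted structure for IO and pipeline tests.
make_toy_matrix <- function(genes = 10, cells = 6, seed = 42) {
  set.seed(seed)
  m <- matrix(round(abs(rnorm(genes * cells, 5, 3)), 3), genes, cells)
  expression_matrix(m, sprintf("g%d", seq_len(genes)),
                    sprintf("c%d", seq_len(cells)))
}

# Two well-separated gene blocks (means 0 and 5, sd 0.1) for subspace tests.
make_two_blocks <- function(per_block = 30, cells = 40, seed = 7) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(per_block * cells, 0, 0.1), per_block, cells),
    matrix(rnorm(per_block * cells, 5, 0.1), per_block, cells)
  )
  rownames(m) <- sprintf("g%d", seq_len(2 * per_block))
  colnames(m) <- sprintf("c%d", seq_len(cells))
  list(matrix = m, labels = rep(1:2, each = per_block))
}

# Fig.6-style data: three gene classes N(0,1) / N(1,1) / N(-1,1).
make_three_classes <- function(per_class = 150, cells = 100, seed = 1) {
  set.seed(seed)
  m <- rbind(
    matrix(rnorm(per_class * cells, 0, 1), per_class, cells),
    matrix(rnorm(per_class * cells, 1, 1), per_class, cells),
    matrix(rnorm(per_class * cells, -1, 1), per_class, cells)
  )
  rownames(m) <- sprintf("g%d", seq_len(3 * per_class))
  colnames(m) <- sprintf("c%d", seq_len(cells))
  list(matrix = m, labels = rep(1:3, each = per_class))
}
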