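test_that("pmf matches hand-evaluated binomial-coefficient cases", {
  # C(3,1)*C(3,1)/C(6,2) = 9/15
  expect_equal(hypergeom_pmf(4, 3, 2, 3), 0.6, tolerance = 1e-14)
  # degenerate support: a single zero in the pair
  expect_equal(hypergeom_pmf(5, 7, 1, 1), 1)
  # gene holds all zeros in the pair (r = x): C(n-1,x-1)*C(m,0)/C(n+m-1,x-1)
  expect_equal(hypergeom_pmf(6, 4, 3, 3),
               choose(5, 2) / choose(9, 2), tolerance = 1e-14)
  expect_error(hypergeom_pmf(4, 3, 0, 2), class = "srimpute_domain_error")
  expect_error(hypergeom_pmf(4, 3, 2, 9), class = "srimpute_domain_error")
})

test_that("pmf stays finite and accurate at large scale (log-space evaluation)", {
  # naive products of factorials would overflow here
  p <- hypergeom_pmf(5e5, 5e5, 3e5, 6e5)
  expect_true(is.finite(p) && p >= 0 && p <= 1)
  expect_equal(p, stats::dhyper(3e5 - 1, 5e5 - 1, 5e5, 6e5 - 1),
               tolerance = 1e-8)
})

test_that("tail p-values match brute-force enumeration over all n, m <= 30", {
  # For every n, m <= 30 and every admissible (x, r): enumerate the support
  # of the gene zero count with exact binomial coefficients, accumulate both
  # tails, and compare against the matrix-level implementation's tails.
  max_err <- 0
  n_checked <- 0L
  for (n in 1:30) for (m in 1:30) for (r in 1:(n + m - 1)) {
    ks <- max(0, (r - 1) - m):min(n - 1, r - 1)
    probs <- choose(n - 1, ks) * choose(m, (r - 1) - ks) /
      choose(n + m - 1, r - 1)
    oracle_under <- cumsum(probs)
    oracle_over <- rev(cumsum(rev(probs)))
    # admissible gene zero counts for this r: the tested entry is zero, and
    # x <= min(n, r), r - x <= m
    xs <- (ks + 1)[ks + 1 >= 1 & ks + 1 <= n & r - (ks + 1) <= m & ks + 1 <= r]
    sel <- match(xs - 1, ks)
    p_under <- stats::phyper(xs - 1, n - 1, m, r - 1)
    p_over <- stats::phyper(xs - 2, n - 1, m, r - 1, lower.tail = FALSE)
    max_err <- max(max_err,
                   abs(p_under - oracle_under[sel]),
                   abs(p_over - oracle_over[sel]))
    n_checked <- n_checked + length(xs)
  }
  expect_lt(max_err, 1e-12)
  expect_gt(n_checked, 2e5) # the grid genuinely covered all combinations

  # cross-check the package's own pmf against the tail overlap on a sample
  set.seed(11)
  n <- sample(2:30, 300, TRUE); m <- sample(1:30, 300, TRUE)
  x <- pmax(1, round(runif(300) * n))
  r <- pmin(x + round(runif(300) * m), n + m - 1)
  p_u <- stats::phyper(x - 1, n - 1, m, r - 1)
  p_o <- stats::phyper(x - 2, n - 1, m, r - 1, lower.tail = FALSE)
  expect_equal(p_o + p_u - 1, hypergeom_pmf(n, m, x, r), tolerance = 1e-10)
})

test_that("zero_entry_pvalues tests exactly the zero entries with correct counts", {
  m <- expression_matrix(rbind(g1 = c(0, 2, 3), g2 = c(1, 0, 0), g3 = c(4, 5, 0)))
  tests <- zero_entry_pvalues(m)
  expect_equal(nrow(tests), 4)
  # entry (g1,c1): x = 1, zeros in c1 = 1 -> r = 1 -> both tails 1
  t11 <- tests[tests$gene == 1 & tests$cell == 1, ]
  expect_equal(t11$x, 1); expect_equal(t11$r, 1)
  expect_equal(t11$p_over, 1); expect_equal(t11$p_under, 1)
  expect_equal(attr(tests, "n"), 3)
  expect_equal(attr(tests, "m"), 3)
})

test_that("all-zero matrix puts every entry at the top of the support", {
  # x = n for every gene, r = n + m - 1 for every pair: x - 1 is the maximum
  # of the hypergeometric support, so p_under = 1 and p_over equals the pmf
  # at the maximum, m / (n + m - 1) — verified against the enumeration oracle.
  m <- expression_matrix(matrix(0, 4, 5))
  tests <- zero_entry_pvalues(m)
  expect_equal(nrow(tests), 20)
  expect_true(all(tests$x == 5))
  expect_true(all(tests$r == 5 + 4 - 1))
  expect_equal(tests$p_under, rep(1, 20))
  o <- oracle_hyper_tails(5, 4, 5, 8)
  expect_equal(tests$p_over, rep(o$p_over, 20))
  expect_equal(o$p_over, 4 / (5 + 4 - 1))
})

test_that("a matrix with no zeros yields an empty test table", {
  m <- expression_matrix(matrix(1:12 + 0.5, 3, 4))
  expect_equal(nrow(zero_entry_pvalues(m)), 0)
})

test_that("tail overlap identity and permutation invariance hold", {
  set.seed(3)
  m <- matrix(rpois(30 * 20, 1.2), 30, 20) * 1.0
  rownames(m) <- sprintf("g%d", 1:30); colnames(m) <- sprintf("c%d", 1:20)
  tests <- zero_entry_pvalues(m)
  pmf <- hypergeom_pmf(ncol(m), nrow(m), tests$x, tests$r)
  expect_equal(tests$p_over + tests$p_under, 1 + pmf, tolerance = 1e-10)

  perm <- sample(ncol(m))
  tp <- zero_entry_pvalues(m[, perm])
  key <- function(tt, cells) paste(tt$gene, cells[tt$cell])
  ord <- order(key(tests, colnames(m)))
  ordp <- order(key(tp, colnames(m)[perm]))
  expect_equal(tests$p_over[ord], tp$p_over[ordp])
  expect_equal(tests$p_under[ord], tp$p_under[ordp])
})

test_that("entry labels follow the alpha = 0.01 rule", {
  tests <- data.frame(gene = 1:3, cell = 1:3, x = 1, r = 1,
                      p_over = c(0.005, 0.999, 0.5),
                      p_under = c(0.999, 0.005, 0.6))
  out <- classify_entries(tests, alpha = 0.01)
  expect_equal(as.character(out$label),
               c("imputable", "trustworthy", "neutral"))
  expect_error(classify_entries(tests, alpha = 0), class = "srimpute_domain_error")
  expect_error(classify_entries(tests, alpha = 1.5), class = "srimpute_domain_error")
})

test_that("gene partition follows the all-trustworthy / any-imputable rule", {
  m <- expression_matrix(rbind(
    no_zero = c(1, 2, 3, 4),
    imp = c(0, 5, 6, 7),
    neut = c(0, 8, 9, 10),
    trust = c(0, 1, 2, 3)
  ))
  tests <- zero_entry_pvalues(m)
  tests$label <- factor(c("imputable", "neutral", "trustworthy"),
                        levels = c("imputable", "trustworthy", "neutral"))[
                          match(tests$gene, c(2, 3, 4))]
  p <- partition_genes(m, tests)
  expect_identical(p$training_genes, c("no_zero", "trust"))
  expect_identical(p$imputable_genes, "imp")
  expect_identical(p$passthrough_genes, "neut")
  expect_equal(which(p$imputable_entry_mask), which(m == 0 & row(m) == 2))
  # sets are disjoint and cover all genes
  expect_setequal(c(p$training_genes, p$imputable_genes, p$passthrough_genes),
                  rownames(m))
})

test_that("partition demands a test for every zero entry", {
  m <- expression_matrix(rbind(a = c(0, 1), b = c(2, 0)))
  tests <- classify_entries(zero_entry_pvalues(m))
  expect_error(partition_genes(m, tests[1, ]),
               class = "srimpute_consistency_error")
})

test_that("few zeros are flagged when zeros occur completely at random", {
  set.seed(5)
  m <- matrix(1 + abs(rnorm(200 * 200)), 200, 200)
  m[matrix(runif(200 * 200) < 0.2, 200, 200)] <- 0
  tests <- classify_entries(zero_entry_pvalues(expression_matrix(m)), 0.01)
  frac_imputable <- mean(tests$label == "imputable")
  expect_lt(frac_imputable, 0.02)
})

test_that("test table exports as TSV with ids and labels", {
  m <- make_toy_matrix(6, 4)
  m[1, 1] <- 0; m[2, 3] <- 0
  tests <- classify_entries(zero_entry_pvalues(m))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tests_tsv(tests, m, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 2)
  expect_setequal(back$gene_id, c("g1", "g2"))
  expect_true(all(c("n", "m", "x", "r", "p_over", "p_under", "label")
                  %in% names(back)))
})
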