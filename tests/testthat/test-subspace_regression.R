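# Minimal hand-built SubspaceModel for assignment tests.
make_model <- function(centroids, projection = NULL) {
  structure(list(k_star = nrow(centroids), labels = NULL,
                 centroids = centroids, auc_by_k = NULL,
                 projection = projection, noise_sd = 1, n_perturb = 1,
                 seed = 1L), class = "SubspaceModel")
}

test_that("genes are assigned to the closest centroid with low-index ties", {
  model <- make_model(rbind(c(0, 0), c(10, 0)))
  hit <- assign_subspace(c(10, 0), model)
  expect_equal(hit$subspace, 2)
  expect_equal(hit$distance, 0)

  near <- assign_subspace(c(1, 0), model)
  expect_equal(near$subspace, 1)
  expect_equal(near$distance, 1)

  tie <- assign_subspace(c(5, 0), model)
  expect_equal(tie$subspace, 1) # equidistant -> lowest index
  expect_identical(assign_subspace(c(5, 0), model), tie) # deterministic

  expect_error(assign_subspace(c(1, 2), make_model(NULL)),
               class = "srimpute_validation_error")
})

test_that("assignment applies the model projection before measuring distance", {
  # projection collapses 4 cells onto their first two coordinates
  proj <- list(center = rep(0, 4), rotation = rbind(diag(2), matrix(0, 2, 2)))
  model <- make_model(rbind(c(0, 0), c(5, 5)), projection = proj)
  hit <- assign_subspace(c(5, 5, 99, -99), model)
  expect_equal(hit$subspace, 2)
  expect_equal(hit$distance, 0)
})

test_that("predictor selection ranks by signed correlation with stable ties", {
  y <- c(1, 2, 3)
  cand <- rbind(a = c(2, 4, 6),    # r = +1
                b = c(3, 2, 1),    # r = -1
                c = c(1, 1, 1),    # zero variance -> excluded
                d = c(1.1, 2, 2.9)) # r ~ +1 but below a
  sel <- select_predictors(y, cand, n_predictors = 10)
  expect_equal(rownames(cand)[sel[1]], "a")
  expect_equal(rownames(cand)[sel[length(sel)]], "b")
  expect_false(3 %in% sel)
  expect_equal(length(sel), 3) # clamps to the usable candidates

  # identical gene ranks first with r = 1
  sel2 <- select_predictors(y, rbind(x = c(5, 5, 5.1), self = y), 1)
  expect_equal(sel2, 2L)

  # all-zero-variance candidates: nothing usable
  expect_equal(length(select_predictors(y, rbind(c(1, 1, 1)), 5)), 0)

  # deterministic tie-break by candidate order on exact ties
  sel3 <- select_predictors(y, rbind(t1 = y, t2 = y, t3 = y), 2)
  expect_equal(sel3, c(1L, 2L))
})

test_that("exact affine relationships are recovered exactly", {
  set.seed(8)
  t1 <- runif(20, 1, 5)
  y <- 2 * t1[1:12] + 1
  fit <- fit_and_impute(y, cbind(t1[1:12]), cbind(t1[13:20]))
  expect_equal(fit$predicted, 2 * t1[13:20] + 1, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
})

test_that("constant outcome reduces to the intercept-only solution", {
  x <- matrix(runif(24), 12, 2)
  fit <- fit_and_impute(rep(3.5, 12), x, matrix(runif(6), 3, 2))
  expect_equal(fit$predicted, rep(3.5, 3), tolerance = 1e-10)
})

test_that("negative predictions clamp to zero", {
  # y = -x forces negative predictions at large positive x
  x_obs <- cbind(c(1, 2, 3, 4, 5))
  fit <- fit_and_impute(-c(1, 2, 3, 4, 5) + 5, x_obs, cbind(c(10, 0)))
  expect_equal(fit$predicted[1], 0) # raw prediction -5, clamped
  expect_equal(fit$predicted[2], 5, tolerance = 1e-10)
})

test_that("predictor count is truncated when observations are scarce", {
  y <- c(1, 2, 4)
  x_obs <- matrix(runif(30), 3, 10)
  x_new <- matrix(runif(10), 1, 10)
  fit <- fit_and_impute(y, x_obs, x_new) # 3 obs -> at most 1 predictor
  expect_equal(length(fit$coefficients), 2)
  expect_true(is.finite(fit$predicted))
})

test_that("rank-deficient designs are resolved without NA predictions", {
  x1 <- c(1, 2, 3, 4, 5, 6)
  x_obs <- cbind(x1, 2 * x1) # collinear
  fit <- fit_and_impute(3 * x1, x_obs, cbind(c(7, 8), c(14, 16)))
  expect_false(any(is.na(fit$predicted)))
  expect_equal(fit$predicted, c(21, 24), tolerance = 1e-8)
})

# End-to-end impute() on a constructed matrix where the imputable gene is an
# exact affine function of training genes.
make_impute_fixture <- function() {
  set.seed(31)
  cells <- 24
  base_a <- matrix(rnorm(8 * cells, 10, 1), 8, cells)   # subspace A
  base_b <- matrix(rnorm(8 * cells, 50, 1), 8, cells)   # subspace B
  g <- 3 * base_a[1, ] + 2                              # affine in subspace A
  masked_cells <- 1:4
  g_obs <- g
  g_obs[masked_cells] <- 0
  m <- rbind(base_a, base_b, g_obs)
  rownames(m) <- c(sprintf("a%d", 1:8), sprintf("b%d", 1:8), "target")
  colnames(m) <- sprintf("c%d", seq_len(cells))

  tests <- zero_entry_pvalues(m)
  tests$label <- factor(rep("imputable", nrow(tests)),
                        levels = c("imputable", "trustworthy", "neutral"))
  partition <- partition_genes(m, tests)
  model <- discover_subspaces(m[partition$training_idx, ], k_range = 2,
                              n_perturb = 3, seed = 2)
  list(m = m, partition = partition, model = model, truth = g,
       masked_cells = masked_cells)
}

test_that("imputation recovers exact affine structure and touches only flagged entries", {
  fx <- make_impute_fixture()
  res <- impute(fx$m, fx$partition, fx$model)
  expect_equal(unname(res$matrix["target", fx$masked_cells]),
               fx$truth[fx$masked_cells], tolerance = 1e-6)
  # non-interference: everything outside the changed mask is bit-identical
  expect_identical(res$matrix[!res$changed_mask], fx$m[!res$changed_mask])
  expect_true(all(res$changed_mask[fx$partition$imputable_entry_mask] ==
                    res$changed_mask[fx$partition$imputable_entry_mask]))
  expect_true(all(!res$changed_mask | fx$partition$imputable_entry_mask))
  # diagnostics describe the one imputable gene
  expect_equal(nrow(res$diagnostics), 1)
  expect_equal(res$diagnostics$gene_id, "target")
  expect_equal(res$diagnostics$r_squared, 1, tolerance = 1e-8)
})

test_that("genes with tiny observed support fall back to the subspace profile", {
  fx <- make_impute_fixture()
  m <- fx$m
  m["target", ] <- 0
  m["target", 1:2] <- fx$truth[1:2] # only 2 observations, below min_obs
  tests <- zero_entry_pvalues(m)
  tests$label <- factor(rep("imputable", nrow(tests)),
                        levels = c("imputable", "trustworthy", "neutral"))
  partition <- partition_genes(m, tests)
  model <- discover_subspaces(m[partition$training_idx, ], k_range = 2,
                              n_perturb = 3, seed = 2)
  res <- impute(m, partition, model)
  expect_true(res$diagnostics$fallback)
  s <- res$diagnostics$subspace
  prof <- colMeans(m[partition$training_idx, ][model$labels == s, ])
  tgt <- which(partition$imputable_entry_mask["target", ])
  expect_equal(unname(res$matrix["target", tgt]), unname(pmax(prof[tgt], 0)),
               tolerance = 1e-12)
})

test_that("empty training set aborts; empty imputable set is a no-op", {
  fx <- make_impute_fixture()
  empty_train <- fx$partition
  empty_train$training_idx <- integer(0)
  empty_train$training_genes <- character(0)
  expect_error(impute(fx$m, empty_train, fx$model),
               class = "srimpute_empty_result_error")

  no_imp <- fx$partition
  no_imp$imputable_idx <- integer(0)
  no_imp$imputable_genes <- character(0)
  no_imp$imputable_entry_mask[] <- FALSE
  res <- impute(fx$m, no_imp, fx$model)
  expect_identical(res$matrix, fx$m)
  expect_false(any(res$changed_mask))
})
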