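# Module 3: subspace regression.
#
# Each imputable gene is assigned to its closest gene subspace (Euclidean
# distance to the centroids, in the clustering space). Within that subspace
# the training genes most correlated with the gene's observed (non-zero) part
# are selected as predictors; an ordinary least-squares fit of the observed
# part on the aligned predictor parts then predicts the gene's
# dropout-flagged entries from the predictors' values at those cells.

#' Assign a gene to its closest subspace
#'
#' The gene's full expression vector (zeros included) is projected with the
#' model's projection when one is present, so that distances are measured in
#' the same space in which the centroids were formed. Ties go to the lowest
#' subspace index.
#'
#' @param gene_vector numeric vector over the cells of the training matrix.
#' @param model a `SubspaceModel` from [discover_subspaces()].
#' @return a list with `subspace` (integer id) and `distance` (Euclidean).
#' @export
assign_subspace <- function(gene_vector, model) {
  if (is.null(model$centroids)) {
    abort_srimpute("model has no centroids", "srimpute_validation_error")
  }
  v <- gene_vector
  if (!is.null(model$projection)) {
    v <- as.numeric((v - model$projection$center) %*% model$projection$rotation)
  }
  d2 <- rowSums(sweep(model$centroids, 2L, v)^2)
  s <- which.min(d2) # which.min returns the first (lowest-index) minimum
  list(subspace = as.integer(s), distance = sqrt(d2[s]))
}

#' Select the training genes most correlated with the observed outcome
#'
#' Pearson correlation is computed between `y` (the gene's observed values)
#' and each candidate training gene restricted to the same cells. The
#' `n_predictors` genes with the highest (signed) correlation are returned,
#' ties broken by candidate order. Zero-variance candidates are excluded; if
#' fewer than `n_predictors` usable candidates remain, all are used.
#'
#' @param y numeric vector of observed (non-zero) values of the gene.
#' @param candidates numeric matrix of candidate genes x the same cells as
#'   `y`.
#' @param n_predictors maximum number of predictors (default 10).
#' @return integer vector of selected candidate row indices, best first;
#'   length 0 when no candidate has variance on `y`'s cells.
#' @export
select_predictors <- function(y, candidates, n_predictors = 10) {
  stopifnot(is.matrix(candidates), length(y) == ncol(candidates))
  r <- suppressWarnings(as.numeric(stats::cor(y, t(candidates))))
  usable <- which(is.finite(r))
  if (length(usable) == 0L) return(integer(0))
  ord <- usable[order(-r[usable], usable)]
  utils::head(ord, n_predictors)
}

#' Fit an OLS model on the observed part and predict the flagged entries
#'
#' Ordinary least squares with intercept of `y` on the predictor columns.
#' When `y` has too few observations for the requested predictor count, the
#' predictor set is truncated so that `length(y) > p + 1`. Rank-deficient
#' designs are resolved by R's pivoted QR with aliased coefficients set to
#' zero. Negative predictions are clamped to zero.
#'
#' @param y observed outcome values.
#' @param x_obs matrix (length(y) x p) of predictor values at the observed
#'   cells.
#' @param x_new matrix (n_new x p) of predictor values at the cells to
#'   predict.
#' @return a list with `coefficients` (intercept first), `predicted`
#'   (clamped at 0) and `r_squared` of the fit on `y`.
#' @export
fit_and_impute <- function(y, x_obs, x_new) {
  stopifnot(is.matrix(x_obs), is.matrix(x_new), nrow(x_obs) == length(y),
            ncol(x_obs) == ncol(x_new))
  p_max <- max(0L, length(y) - 2L)
  if (ncol(x_obs) > p_max) {
    x_obs <- x_obs[, seq_len(p_max), drop = FALSE]
    x_new <- x_new[, seq_len(p_max), drop = FALSE]
  }
  X <- cbind(1, x_obs)
  fit <- stats::lm.fit(X, y)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- as.numeric(cbind(1, x_new) %*% beta)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(coefficients = beta, predicted = pmax(pred, 0), r_squared = r2)
}

#' Impute the dropout-flagged entries of an expression matrix
#'
#' Every gene in the imputable set is assigned to its nearest subspace; the
#' ten (by default) training genes of that subspace most correlated with the
#' gene's observed part serve as OLS predictors for the gene's flagged
#' entries. Training and pass-through genes — and every non-flagged entry of
#' imputable genes — are copied verbatim, so the output differs from the
#' input only inside the imputable-entry mask. Genes with fewer than
#' `min_obs` observed values fall back to the subspace mean profile (the
#' cell-wise mean of the subspace's training genes) at their flagged cells.
#'
#' @param matrix the (preprocessed) expression matrix, genes x cells.
#' @param partition a `GenePartition` from [partition_genes()].
#' @param model a `SubspaceModel` from [discover_subspaces()] fitted on the
#'   training genes of `partition`.
#' @param n_predictors number of predictor genes per imputable gene.
#' @param min_obs minimum observed values for a regression fit (default 4);
#'   below it the centroid fallback is used.
#' @return a list of class `ImputationResult`: `matrix` (imputed, same
#'   shape/ids/order as the input), `changed_mask` (logical matrix marking
#'   entries that received a prediction), and `diagnostics` (one row per
#'   imputable gene: subspace, centroid distance, number of observations,
#'   predictor ids, R^2, fallback flag).
#' @export
impute <- function(matrix, partition, model, n_predictors = 10, min_obs = 4) {
  stopifnot(is.matrix(matrix), inherits(partition, "GenePartition"),
            inherits(model, "SubspaceModel"))
  if (length(partition$training_idx) == 0L) {
    abort_srimpute("empty training set: nothing to learn from",
                   "srimpute_empty_result_error")
  }
  out <- matrix
  changed <- base::matrix(FALSE, nrow(matrix), ncol(matrix),
                          dimnames = dimnames(matrix))
  imp_idx <- partition$imputable_idx
  diag_rows <- vector("list", length(imp_idx))
  if (length(imp_idx) == 0L) {
    return(structure(list(matrix = out, changed_mask = changed,
                          diagnostics = data.frame()),
                     class = "ImputationResult"))
  }

  train <- matrix[partition$training_idx, , drop = FALSE]
  sub_rows <- split(seq_len(nrow(train)), model$labels)
  # Per-subspace mean profile in cell space, for the tiny-support fallback.
  sub_means <- lapply(sub_rows, function(rws) colMeans(train[rws, , drop = FALSE]))

  gene_ids <- rownames(matrix) %||% as.character(seq_len(nrow(matrix)))

  for (j in seq_along(imp_idx)) {
    gi <- imp_idx[j]
    g <- matrix[gi, ]
    asg <- assign_subspace(g, model)
    s <- asg$subspace
    cand_rows <- sub_rows[[as.character(s)]]
    target <- which(partition$imputable_entry_mask[gi, ])
    obs <- which(g != 0)
    rec <- list(gene_id = gene_ids[gi], subspace = s,
                centroid_distance = asg$distance, n_obs = length(obs),
                n_target = length(target), predictors = NA_character_,
                r_squared = NA_real_, fallback = FALSE, skipped = FALSE)

    if (length(obs) < min_obs || length(cand_rows) == 0L) {
      mu <- sub_means[[as.character(s)]]
      out[gi, target] <- pmax(mu[target], 0)
      changed[gi, target] <- TRUE
      rec$fallback <- TRUE
    } else {
      y <- g[obs]
      cand <- train[cand_rows, obs, drop = FALSE]
      sel <- select_predictors(y, cand, n_predictors)
      if (length(sel) == 0L) {
        warning(sprintf("gene %s: no usable predictor; entries left at 0",
                        gene_ids[gi]))
        rec$skipped <- TRUE
      } else {
        pred_rows <- cand_rows[sel]
        fit <- fit_and_impute(y, t(train[pred_rows, obs, drop = FALSE]),
                              t(train[pred_rows, target, drop = FALSE]))
        out[gi, target] <- fit$predicted
        changed[gi, target] <- TRUE
        rec$predictors <- paste(rownames(train)[pred_rows], collapse = ";")
        rec$r_squared <- fit$r_squared
      }
    }
    diag_rows[[j]] <- rec
  }

  diagnostics <- do.call(rbind, lapply(diag_rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))

  structure(list(matrix = out, changed_mask = changed,
                 diagnostics = diagnostics),
            class = "ImputationResult")
}

#' @export
print.ImputationResult <- function(x, ...) {
  cat(sprintf("ImputationResult: %d entries imputed across %d genes\n",
              sum(x$changed_mask),
              if (nrow(x$diagnostics)) nrow(x$diagnostics) else 0L))
  invisible(x)
}
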