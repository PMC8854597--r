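# Pipeline orchestration: preprocess -> zero-entry testing -> subspace
# discovery -> subspace regression, plus a benchmark driver over the
# simulation scenarios.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default. A single master
#' seed fans out to derived per-stage seeds so stages are individually
#' reproducible.
#'
#' @param alpha per-entry significance threshold of the dropout test.
#' @param k_range candidate subspace counts.
#' @param n_perturb perturbed copies per k.
#' @param noise_sd perturbation noise sd (`NULL` = median per-gene sd).
#' @param n_predictors training genes used per imputable gene.
#' @param min_cells,min_nonzero_fraction,range_threshold see [preprocess()].
#' @param pca_components,max_cluster_genes scalability valves, see
#'   [discover_subspaces()].
#' @param restarts k-means restarts.
#' @param seed master seed.
#' @return a list of class `PipelineConfig`.
#' @export
pipeline_config <- function(alpha = 0.01, k_range = 2:10, n_perturb = 20,
                            noise_sd = NULL, n_predictors = 10, min_cells = 2,
                            min_nonzero_fraction = 0.01, range_threshold = 100,
                            pca_components = "auto", max_cluster_genes = "auto",
                            restarts = 10, seed = 1L) {
  structure(list(
    alpha = alpha, k_range = k_range, n_perturb = n_perturb,
    noise_sd = noise_sd, n_predictors = n_predictors, min_cells = min_cells,
    min_nonzero_fraction = min_nonzero_fraction,
    range_threshold = range_threshold, pca_components = pca_components,
    max_cluster_genes = max_cluster_genes, restarts = restarts,
    seed = as.integer(seed)
  ), class = "PipelineConfig")
}

#' Run the full imputation pipeline on an expression matrix
#'
#' Applies [preprocess()], tests every zero entry with
#' [zero_entry_pvalues()] / [classify_entries()], partitions the genes with
#' [partition_genes()], discovers gene subspaces in the training set with
#' [discover_subspaces()] and imputes the flagged entries with [impute()].
#' When the matrix has no imputable entries the (preprocessed) input is
#' returned unchanged with an empty change mask.
#'
#' @param matrix expression matrix (genes x cells), or a file path readable by
#'   [read_expression()].
#' @param config a [pipeline_config()].
#' @param verbose print one log line per stage.
#' @param keep_tests retain the full per-entry test table in the result
#'   (default). Set `FALSE` on very large matrices to save memory; the
#'   `tests` field is then `NULL`.
#' @return a list of class `PipelineResult`: `matrix` (imputed), `changed_mask`,
#'   `partition`, `model` (`NULL` when imputation was skipped), `tests`,
#'   `preprocess_report`, `diagnostics`, `config` and `counts` (named vector:
#'   training / imputable / passthrough gene counts after filtering).
#' @export
sr_impute <- function(matrix, config = pipeline_config(), verbose = FALSE,
                      keep_tests = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is.character(matrix)) matrix <- read_expression(matrix)

  t0 <- proc.time()[["elapsed"]]
  pp <- preprocess(matrix, config$min_cells, config$min_nonzero_fraction,
                   config$range_threshold)
  m <- pp$matrix
  log_stage("preprocess", sprintf("%d x %d -> %d x %d (%.1fs)",
                                  nrow(matrix), ncol(matrix), nrow(m), ncol(m),
                                  proc.time()[["elapsed"]] - t0),
            verbose = verbose)

  t0 <- proc.time()[["elapsed"]]
  tests <- classify_entries(zero_entry_pvalues(m), config$alpha)
  n_tests <- nrow(tests)
  if (!keep_tests) tests <- tests[c("gene", "cell", "label")]
  partition <- partition_genes(m, tests)
  if (!keep_tests) tests <- NULL
  gc(FALSE)
  counts <- c(training = length(partition$training_genes),
              imputable = length(partition$imputable_genes),
              passthrough = length(partition$passthrough_genes))
  log_stage("dropout_test", sprintf(
    "%d zeros tested; %d training / %d imputable / %d passthrough genes (%.1fs)",
    n_tests, counts[1], counts[2], counts[3],
    proc.time()[["elapsed"]] - t0), verbose = verbose)

  if (length(partition$imputable_genes) == 0L) {
    log_stage("impute", "no imputable entries; output equals input",
              verbose = verbose)
    return(structure(list(
      matrix = m,
      changed_mask = base::matrix(FALSE, nrow(m), ncol(m), dimnames = dimnames(m)),
      partition = partition, model = NULL, tests = tests,
      preprocess_report = pp$report, diagnostics = data.frame(),
      config = config, counts = counts
    ), class = "PipelineResult"))
  }
  if (length(partition$training_genes) == 0L) {
    abort_srimpute("empty training set: nothing to learn from",
                   "srimpute_empty_result_error")
  }

  t0 <- proc.time()[["elapsed"]]
  training <- m[partition$training_idx, , drop = FALSE]
  model <- discover_subspaces(
    training, k_range = config$k_range, n_perturb = config$n_perturb,
    noise_sd = config$noise_sd, seed = derive_seed(config$seed, "subspaces"),
    max_cluster_genes = config$max_cluster_genes,
    pca_components = config$pca_components, restarts = config$restarts)
  log_stage("subspaces", sprintf("k* = %d over %d training genes (%.1fs)",
                                 model$k_star, nrow(training),
                                 proc.time()[["elapsed"]] - t0),
            verbose = verbose)

  t0 <- proc.time()[["elapsed"]]
  res <- impute(m, partition, model, n_predictors = config$n_predictors)
  log_stage("impute", sprintf("%d entries imputed in %d genes (%.1fs)",
                              sum(res$changed_mask), counts[2],
                              proc.time()[["elapsed"]] - t0), verbose = verbose)

  structure(list(
    matrix = res$matrix, changed_mask = res$changed_mask,
    partition = partition, model = model, tests = tests,
    preprocess_report = pp$report, diagnostics = res$diagnostics,
    config = config, counts = counts
  ), class = "PipelineResult")
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf("PipelineResult: %d x %d matrix, %d entries imputed\n",
              nrow(x$matrix), ncol(x$matrix), sum(x$changed_mask)))
  print(x$counts)
  invisible(x)
}

#' Run the pipeline on a file and write all artifacts to a directory
#'
#' Writes `imputed.csv`, `changed_mask.mtx` (+ id sidecars),
#' `dropout_tests.tsv`, `subspace_auc.tsv`, `diagnostics.tsv` and
#' `manifest.json` (config, seed, gene-class counts, package version). The
#' manifest carries no timestamps, so identical input + config + seed produce
#' byte-identical output files.
#'
#' @param input input matrix file path (or an in-memory matrix).
#' @param output_dir directory for the artifacts (created if missing).
#' @param config a [pipeline_config()].
#' @param format input format passed to [read_expression()].
#' @param expm1 undo the log2 rescale (`2^x - 1`) on the written matrix.
#' @param allow_negative accept negative input values (e.g. simulated data on
#'   a log-like scale).
#' @param verbose print stage logs.
#' @return the `PipelineResult`, invisibly.
#' @export
run_pipeline <- function(input, output_dir, config = pipeline_config(),
                         format = c("csv", "tsv", "mtx"), expm1 = FALSE,
                         allow_negative = FALSE, verbose = TRUE) {
  m <- if (is.character(input)) {
    read_expression(input, match.arg(format), allow_negative = allow_negative)
  } else input
  res <- sr_impute(m, config, verbose = verbose)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)

  out_m <- res$matrix
  if (expm1 && isTRUE(attr(out_m, "log_scaled"))) out_m <- 2^out_m - 1
  write_expression(out_m, file.path(output_dir, "imputed.csv"), "csv")
  sp <- methods::as(Matrix::Matrix(res$changed_mask * 1, sparse = TRUE),
                    "generalMatrix")
  Matrix::writeMM(sp, file.path(output_dir, "changed_mask.mtx"))
  writeLines(rownames(res$matrix), file.path(output_dir, "genes.txt"))
  writeLines(colnames(res$matrix), file.path(output_dir, "barcodes.txt"))
  write_tests_tsv(res$tests, res$matrix, file.path(output_dir, "dropout_tests.tsv"))
  if (!is.null(res$model)) {
    write_auc_tsv(res$model, file.path(output_dir, "subspace_auc.tsv"))
  }
  if (nrow(res$diagnostics) > 0L) {
    data.table::fwrite(res$diagnostics, file.path(output_dir, "diagnostics.tsv"),
                       sep = "\t")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("srimpute")),
    config = unclass(res$config),
    counts = as.list(res$counts),
    n_genes = nrow(res$matrix), n_cells = ncol(res$matrix),
    n_imputed_entries = sum(res$changed_mask),
    preprocess = res$preprocess_report,
    k_star = if (is.null(res$model)) NA else res$model$k_star
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' Simulate, impute and evaluate one or more benchmark datasets
#'
#' Scenario 1 masks 30% of the entries in a random 40% of the genes of a
#' block-normal dataset. Scenario 2 masks every entry at a global dropout
#' `rate`, either uniformly or with per-gene rates drawn from
#' `N(rate, 0.1)`. Scenario 3 repeats scenario 2 on data whose same-type
#' cells are strongly correlated. Each seed yields one dataset; the masked
#' data are imputed and compared with the complete data.
#'
#' @param scenario 1, 2 or 3.
#' @param n_cells,n_genes dataset size.
#' @param rate dropout rate for scenarios 2-3.
#' @param dist dropout-rate distribution for scenarios 2-3 (`"uniform"` or
#'   `"normal"`).
#' @param seeds integer vector, one dataset per seed.
#' @param config a [pipeline_config()] (the per-dataset seed overrides
#'   `config$seed`).
#' @param within_type_correlation noise correlation for scenario 3.
#' @param output_dir optional directory for per-seed and aggregate reports.
#' @param k_cells number of cell clusters for the ARI evaluation (default: the
#'   number of simulated cell types).
#' @param compute_ari run the k-means ARI evaluation (default `TRUE`); skip it
#'   when only error metrics are needed — on large matrices the clustering
#'   dominates the evaluation cost.
#' @param verbose print stage logs.
#' @return a data.frame with one row per seed: MAE / Pearson r / median
#'   gene-wise MAE of the imputed and of the masked data, and the k-means ARI
#'   against the true cell types on masked and imputed data.
#' @export
run_benchmark <- function(scenario = 1, n_cells = 100, n_genes = 300,
                          rate = 0.6, dist = c("uniform", "normal"),
                          seeds = 1L, config = pipeline_config(),
                          within_type_correlation = 0.9, output_dir = NULL,
                          k_cells = NULL, compute_ari = TRUE, verbose = FALSE) {
  dist <- match.arg(dist)
  stopifnot(scenario %in% 1:3)
  rows <- lapply(seeds, function(s) {
    wtc <- if (scenario == 3) within_type_correlation else 0
    cfg_sim <- simulation_config(n_cells = n_cells, n_genes = n_genes,
                                 within_type_correlation = wtc, seed = s)
    ds <- simulate_block_normal(cfg_sim)
    ds <- if (scenario == 1) {
      mask_uniform_gene_subset(ds)
    } else {
      mask_rate(ds, rate = rate, dist = dist)
    }
    cfg <- config
    cfg$seed <- as.integer(s)
    res <- sr_impute(ds$masked, cfg, verbose = verbose, keep_tests = FALSE)

    # Preprocessing may drop genes; evaluate on the surviving gene set.
    imputed <- res$matrix
    n_imputed <- sum(res$changed_mask)
    rm(res); gc(FALSE)
    keep <- rownames(imputed)
    complete <- ds$complete[keep, , drop = FALSE]
    masked <- ds$masked[keep, , drop = FALSE]
    mask <- ds$mask[keep, , drop = FALSE]
    cell_labels <- ds$cell_labels
    rm(ds); gc(FALSE)

    err_imp <- imputation_error(imputed, complete, mask)
    err_msk <- imputation_error(masked, complete, mask)
    ari_msk <- ari_imp <- NA_real_
    if (compute_ari) {
      k <- k_cells %||% length(cfg_sim$cell_shifts)
      ari_msk <- ari(cluster_cells(masked, k, seed = derive_seed(s, "km_masked")),
                     cell_labels)
      ari_imp <- ari(cluster_cells(imputed, k, seed = derive_seed(s, "km_imputed")),
                     cell_labels)
    }

    data.frame(
      seed = s, scenario = scenario, n_cells = n_cells, n_genes = n_genes,
      rate = if (scenario == 1) NA_real_ else rate,
      dist = if (scenario == 1) "subset" else dist,
      n_genes_kept = length(keep),
      n_imputed = n_imputed,
      mae_imputed = err_imp$mae, mae_masked = err_msk$mae,
      r_imputed = err_imp$pearson_r, r_masked = err_msk$pearson_r,
      median_gene_mae_imputed = err_imp$median_gene_mae,
      median_gene_mae_masked = err_msk$median_gene_mae,
      ari_imputed = ari_imp, ari_masked = ari_msk
    )
  })
  report <- do.call(rbind, rows)
  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(report, file.path(output_dir, "benchmark_per_seed.tsv"),
                       sep = "\t")
    agg <- as.data.frame(lapply(report[vapply(report, is.numeric, logical(1))],
                                mean, na.rm = TRUE))
    data.table::fwrite(agg, file.path(output_dir, "benchmark_aggregate.tsv"),
                       sep = "\t")
  }
  report
}
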