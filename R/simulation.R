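# Synthetic data: block-normal expression with known cell types and gene
# groups, plus dropout masking procedures. The generator emulates the
# benchmark conditions used to study the imputation pipeline: a base
# N(mu, sigma) expression level, additive cell-type shifts (-1, 0, 1, 1.5)
# creating four cell types and additive gene-group shifts (-1, 0, 1) creating
# three gene groups. Values live on an abstract log-like scale and may be
# negative; zeros are created by masking only.

#' Simulation configuration
#'
#' @param n_cells number of cells (columns).
#' @param n_genes number of genes (rows).
#' @param base_mean base expression mean (default 1).
#' @param base_sd base expression sd (default 0.15).
#' @param cell_shifts additive shift per cell type (default `c(-1, 0, 1, 1.5)`,
#'   i.e. four cell types of as-equal-as-possible size).
#' @param gene_shifts additive shift per gene group (default `c(-1, 0, 1)`).
#' @param within_type_correlation correlation of the noise between cells of
#'   the same type, in \[0, 1); 0 gives independent noise, positive values
#'   emulate datasets whose same-type cells are strongly correlated.
#' @param seed integer seed.
#' @return a list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_cells, n_genes, base_mean = 1, base_sd = 0.15,
                              cell_shifts = c(-1, 0, 1, 1.5),
                              gene_shifts = c(-1, 0, 1),
                              within_type_correlation = 0, seed = 1L) {
  if (base_sd <= 0) abort_srimpute("base_sd must be > 0", "srimpute_domain_error")
  if (within_type_correlation < 0 || within_type_correlation >= 1) {
    abort_srimpute("within_type_correlation must be in [0, 1)",
                   "srimpute_domain_error")
  }
  if (n_cells < length(cell_shifts)) {
    abort_srimpute("fewer cells than cell types", "srimpute_domain_error")
  }
  structure(list(
    n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
    base_mean = base_mean, base_sd = base_sd,
    cell_shifts = cell_shifts, gene_shifts = gene_shifts,
    within_type_correlation = within_type_correlation, seed = as.integer(seed)
  ), class = "SimulationConfig")
}

# Split n items into k contiguous groups of as-equal-as-possible size.
#' @keywords internal
even_groups <- function(n, k) {
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0L) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  rep(seq_len(k), times = sizes)
}

#' Simulate block-normal expression with known structure
#'
#' Entry (g, c) is `base_mean + gene_shift[group(g)] + cell_shift[type(c)] +
#' eps` with `eps ~ N(0, base_sd^2)`. With `within_type_correlation = w > 0`,
#' the noise is `sqrt(w) * u[g, type(c)] + sqrt(1 - w) * e[g, c]` where `u`
#' is a shared per-(gene, cell-type) effect, giving same-type cells a noise
#' correlation of `w`.
#'
#' @param config a [simulation_config()].
#' @return a list of class `SimulatedDataset`: `complete` (expression matrix),
#'   `masked` (== complete until a masking step is applied), `mask` (logical
#'   matrix, all `FALSE`), `cell_labels` (integer type per cell),
#'   `gene_groups` (integer group per gene), `config`.
#' @export
simulate_block_normal <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(derive_seed(config$seed, "simulate"))
  g <- config$n_genes; n <- config$n_cells
  cell_labels <- even_groups(n, length(config$cell_shifts))
  gene_groups <- even_groups(g, length(config$gene_shifts))

  mu <- config$base_mean +
    outer(config$gene_shifts[gene_groups], config$cell_shifts[cell_labels], `+`)
  w <- config$within_type_correlation
  eps <- base::matrix(stats::rnorm(g * n, 0, config$base_sd), g, n)
  if (w > 0) {
    u <- base::matrix(stats::rnorm(g * length(config$cell_shifts), 0, config$base_sd),
                      g, length(config$cell_shifts))
    eps <- sqrt(w) * u[, cell_labels, drop = FALSE] + sqrt(1 - w) * eps
  }
  vals <- mu + eps
  complete <- expression_matrix(vals,
                                gene_ids = sprintf("gene%d", seq_len(g)),
                                cell_ids = sprintf("cell%d", seq_len(n)))
  structure(list(
    complete = complete,
    masked = complete,
    mask = base::matrix(FALSE, g, n, dimnames = dimnames(complete)),
    cell_labels = cell_labels,
    gene_groups = gene_groups,
    config = config
  ), class = "SimulatedDataset")
}

#' Mask a fixed fraction of entries in a random subset of genes
#'
#' Selects exactly `round(gene_frac * n_genes)` dropout genes and, within each,
#' zeroes exactly `round(entry_frac * n_cells)` entries chosen uniformly
#' without replacement.
#'
#' @param ds a `SimulatedDataset`.
#' @param gene_frac fraction of genes affected by dropout (default 0.4).
#' @param entry_frac fraction of each affected gene's entries masked
#'   (default 0.3).
#' @param seed integer seed (default: derived from the dataset config seed).
#' @return the dataset with `masked` and `mask` updated.
#' @export
mask_uniform_gene_subset <- function(ds, gene_frac = 0.4, entry_frac = 0.3,
                                     seed = NULL) {
  stopifnot(inherits(ds, "SimulatedDataset"))
  if (gene_frac < 0 || gene_frac > 1 || entry_frac < 0 || entry_frac > 1) {
    abort_srimpute("fractions must be in [0, 1]", "srimpute_domain_error")
  }
  seed <- seed %||% derive_seed(ds$config$seed, "mask_subset")
  set.seed(seed)
  g <- nrow(ds$complete); n <- ncol(ds$complete)
  n_drop_genes <- round(gene_frac * g)
  n_drop_entries <- round(entry_frac * n)
  mask <- base::matrix(FALSE, g, n, dimnames = dimnames(ds$complete))
  if (n_drop_genes > 0L && n_drop_entries > 0L) {
    drop_genes <- sample.int(g, n_drop_genes)
    for (gi in drop_genes) {
      mask[gi, sample.int(n, n_drop_entries)] <- TRUE
    }
  }
  masked <- ds$complete
  masked[mask] <- 0
  ds$masked <- masked
  ds$mask <- mask
  ds
}

#' Mask entries at a given dropout rate
#'
#' With `dist = "uniform"` every entry is masked independently with
#' probability `rate`. With `dist = "normal"` each gene g first draws its own
#' dropout probability `p_g ~ N(rate, normal_sd)` (clipped to \[0, 1\]) and
#' its entries are then masked independently with probability `p_g`.
#'
#' @param ds a `SimulatedDataset`.
#' @param rate overall dropout rate in (0, 1).
#' @param dist `"uniform"` or `"normal"`.
#' @param normal_sd sd of the per-gene rate distribution (default 0.1).
#' @param seed integer seed (default: derived from the dataset config seed).
#' @return the dataset with `masked` and `mask` updated.
#' @export
mask_rate <- function(ds, rate, dist = c("uniform", "normal"), normal_sd = 0.1,
                      seed = NULL) {
  stopifnot(inherits(ds, "SimulatedDataset"))
  dist <- match.arg(dist)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0 || rate >= 1) {
    abort_srimpute("rate must be a single number in (0, 1)",
                   "srimpute_domain_error")
  }
  seed <- seed %||% derive_seed(ds$config$seed, paste0("mask_rate_", dist))
  set.seed(seed)
  g <- nrow(ds$complete); n <- ncol(ds$complete)
  if (dist == "uniform") {
    mask <- base::matrix(stats::runif(g * n) < rate, g, n)
  } else {
    p_g <- pmin(pmax(stats::rnorm(g, rate, normal_sd), 0), 1)
    mask <- base::matrix(stats::runif(g * n), g, n) < p_g
  }
  dimnames(mask) <- dimnames(ds$complete)
  masked <- ds$complete
  masked[mask] <- 0
  ds$masked <- masked
  ds$mask <- mask
  ds
}

#' Write a simulated dataset to a directory
#'
#' Writes `complete.csv`, `masked.csv`, `mask.mtx` (+ sidecar id files),
#' `cell_labels.tsv`, `gene_groups.tsv` and `config.json`.
#'
#' @param ds a `SimulatedDataset`.
#' @param dir output directory (created if missing).
#' @export
write_simulated_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_expression(ds$complete, file.path(dir, "complete.csv"), "csv")
  write_expression(ds$masked, file.path(dir, "masked.csv"), "csv")
  sp <- methods::as(Matrix::Matrix(ds$mask * 1, sparse = TRUE), "generalMatrix")
  Matrix::writeMM(sp, file.path(dir, "mask.mtx"))
  writeLines(rownames(ds$complete), file.path(dir, "genes.txt"))
  writeLines(colnames(ds$complete), file.path(dir, "barcodes.txt"))
  data.table::fwrite(data.frame(cell_id = colnames(ds$complete),
                                type = ds$cell_labels),
                     file.path(dir, "cell_labels.tsv"), sep = "\t")
  data.table::fwrite(data.frame(gene_id = rownames(ds$complete),
                                group = ds$gene_groups),
                     file.path(dir, "gene_groups.tsv"), sep = "\t")
  cfg <- unclass(ds$config)
  jsonlite::write_json(cfg, file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
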