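# End-to-end validation experiments on synthetic data with known ground
# truth. Each returns the summary statistics that the package's acceptance
# checks (and the analysis drivers) consume. Problem sizes follow the
# package's standard study conditions; the methods vignette motivates them.

#' Type-I calibration and power of the compartment-constrained Ripley test
#'
#' CSR genes are simulated inside one soma compartment and tested with the
#' Monte-Carlo H envelope; the per-radius flag rate is compared with the
#' nominal 10% (5% per side). Power uses Thomas-clustered genes (1 um
#' dispersion, 10 offspring per parent) and counts runs flagged above the
#' envelope at any radius.
#'
#' @param seed integer seed.
#' @param n_genes number of CSR genes for calibration.
#' @param n_power number of Thomas-process runs for power.
#' @param n_null envelope randomizations.
#' @param radii test radii, microns.
#' @param mean_count molecules per gene.
#' @param cfg [run_config()].
#' @return list: `rates` (per-radius flag rate), `ci` (binomial 95% interval
#'   around 0.10 at `n_genes`), `in_ci` (per-radius logical),
#'   `thomas_power`.
#' @export
ripley_calibration <- function(seed = 1L, n_genes = 500L, n_power = 100L,
                               n_null = 200L, radii = 3:7, mean_count = 100,
                               cfg = run_config(seed = seed)) {
  cell <- simulate_cell(shape_params(n_primary_branches = 0, soma_radius = 40,
                                     image_size = 128),
                        seed = derive_seed(seed, "calib_cell"))
  attr(cell, "pixel_size") <- cfg$pixel_size
  flags <- matrix(FALSE, n_genes, length(radii))
  for (g in seq_len(n_genes)) {
    tx <- simulate_transcripts(cell, list(gene_model("G", mean_count, -20)),
                               seed = derive_seed(seed, paste0("csr/", g)))
    rr <- ripley_envelope(tx, cell$soma, cfg, radii, n_null = n_null,
                          seed = derive_seed(seed, paste0("env/", g)))
    flags[g, ] <- rr$flag_upper | rr$flag_lower
  }
  rates <- colMeans(flags)
  half <- 1.96 * sqrt(0.1 * 0.9 / n_genes)
  upper_hits <- 0L
  for (g in seq_len(n_power)) {
    tx <- simulate_transcripts(cell, list(gene_model("G", mean_count, -20,
                                                     cluster_sigma = 1,
                                                     cluster_children = 10)),
                               seed = derive_seed(seed, paste0("thomas/", g)))
    rr <- ripley_envelope(tx, cell$soma, cfg, radii, n_null = n_null,
                          seed = derive_seed(seed, paste0("tenv/", g)))
    upper_hits <- upper_hits + any(rr$flag_upper)
  }
  list(rates = setNames(rates, radii), ci = c(0.1 - half, 0.1 + half),
       in_ci = rates >= 0.1 - half & rates <= 0.1 + half,
       thomas_power = upper_hits / n_power)
}

coloc_experiment_panel <- function(n_coloc_pairs) {
  default_gene_panel(n_soma = 3, n_process = 3, n_neutral = 6,
                     mean_count = 40, n_coloc_pairs = n_coloc_pairs,
                     cluster_sigma = 1, cluster_children = 6)
}

run_dataset_soma_coloc <- function(ds, cfg, n_null, seed) {
  genes <- names(ds$truth$gene_compartment)
  obs <- nulls <- list()
  for (i in seq_along(ds$cells)) {
    cell <- ds$cells[[i]]
    tx <- ds$transcripts[ds$transcripts$cell_id == cell$cell_id &
                         ds$transcripts$true_compartment == "soma", ]
    obs[[i]] <- coloc_counts(tx, 1, genes, cfg)
    nulls[[i]] <- coloc_null(tx, cell$soma, 1, genes, cfg, n_null = n_null,
                             seed = derive_seed(seed, paste0("null/", i)))
  }
  coloc_significance(obs, nulls, genes, seed = seed)
}

#' Recovery and null calibration of the co-localization network
#'
#' Simulates datasets with one planted shared-parent gene pair and scores
#' recovery (planted pair adjusted p below alpha), plus CSR datasets
#' (no planted pairs) scored for producing an empty significant network.
#'
#' @param seed integer seed.
#' @param n_datasets datasets per condition.
#' @param n_cells cells per dataset.
#' @param n_null randomizations per cell.
#' @param cfg [run_config()].
#' @return list: `recovery_rate`, `csr_empty_rate`, per-dataset logicals.
#' @export
coloc_recovery_experiment <- function(seed = 1L, n_datasets = 20L,
                                      n_cells = 50L, n_null = 200L,
                                      cfg = run_config(seed = seed)) {
  rec <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    ds <- simulate_dataset(cfg, n_cells, coloc_experiment_panel(1),
                           ramified_fraction = 1,
                           seed = derive_seed(seed, paste0("ds/", d)))
    net <- run_dataset_soma_coloc(ds, cfg, n_null,
                                  derive_seed(seed, paste0("net/", d)))
    pp <- ds$truth$planted_pairs
    row <- net$pairs[net$pairs$gene_a == pp$gene_a[1] &
                     net$pairs$gene_b == pp$gene_b[1], ]
    rec[d] <- nrow(row) == 1 && row$padj < cfg$alpha
  }
  empty <- logical(n_datasets)
  for (d in seq_len(n_datasets)) {
    ds <- simulate_dataset(cfg, n_cells, coloc_experiment_panel(0),
                           ramified_fraction = 1,
                           seed = derive_seed(seed, paste0("csr/", d)))
    net <- run_dataset_soma_coloc(ds, cfg, n_null,
                                  derive_seed(seed, paste0("csrnet/", d)))
    empty[d] <- nrow(net$edges) == 0
  }
  list(recovery_rate = mean(rec), csr_empty_rate = mean(empty),
       recovered = rec, csr_empty = empty)
}

#' Sensitivity and FDR of compartment-enrichment calls on planted truth
#'
#' Simulates ramified cells with genes planted at |log-odds| 2 for soma or
#' process placement, runs the enrichment procedure and scores recovery
#' against the truth manifest.
#'
#' @param seed integer seed.
#' @param n_cells number of ramified cells.
#' @param logodds planted |process_logodds| for enriched genes.
#' @param cfg [run_config()].
#' @return list: `sensitivity`, `fdr`, `n_enriched_true`, `n_called`.
#' @export
enrichment_recovery_experiment <- function(seed = 1L, n_cells = 200L,
                                           logodds = 2,
                                           cfg = run_config(seed = seed)) {
  panel <- default_gene_panel(n_soma = 5, n_process = 5, n_neutral = 10,
                              logodds = logodds, n_coloc_pairs = 0)
  ds <- simulate_dataset(cfg, n_cells, panel, ramified_fraction = 1,
                         seed = derive_seed(seed, "enrich_ds"))
  enr <- compartment_enrichment(ds$counts$soma, ds$counts$process,
                                rownames(ds$counts$soma))
  truth <- ds$truth$gene_compartment
  true_proc <- names(truth)[truth == "process"]
  true_soma <- names(truth)[truth == "soma"]
  called <- c(enr$process_enriched, enr$soma_enriched)
  hits <- sum(enr$process_enriched %in% true_proc) +
    sum(enr$soma_enriched %in% true_soma)
  list(sensitivity = hits / (length(true_proc) + length(true_soma)),
       fdr = if (length(called)) 1 - hits / length(called) else 0,
       n_enriched_true = length(true_proc) + length(true_soma),
       n_called = length(called))
}

#' Ramification-classifier performance on planted expression differences
#'
#' Cells of two shape classes receive a four-fold raw count shift in ten
#' process-linked genes; the random-forest report carries held-out AUROC.
#' The permutation control repeats the fit on label-shuffled data.
#'
#' @param seed integer seed.
#' @param n_per_class cells per class.
#' @param n_genes panel size (first 10 genes carry the shift).
#' @param n_perm permutation refits (their median AUROC is reported).
#' @return list: `auroc`, `auroc_perm` (median), `report`.
#' @export
classifier_experiment <- function(seed = 1L, n_per_class = 200L,
                                  n_genes = 30L, n_perm = 5L) {
  set.seed(derive_seed(seed, "clf_data"))
  n <- 2L * n_per_class
  lab <- rep(c("ramified", "amoeboid"), each = n_per_class)
  mu <- matrix(20, n, n_genes)
  mu[lab == "ramified", 1:10] <- 80
  counts <- matrix(rpois(n * n_genes, mu), n, n_genes,
                   dimnames = list(paste0("c", seq_len(n)),
                                   paste0("g", seq_len(n_genes))))
  ln <- lognormalize(counts)
  labels <- setNames(lab, rownames(ln))
  rep1 <- train_classifier(ln[, 1:10], labels,
                           seed = derive_seed(seed, "clf_fit"))
  perms <- vapply(seq_len(n_perm), function(s) {
    set.seed(derive_seed(seed, paste0("perm/", s)))
    pl <- setNames(sample(lab), rownames(ln))
    train_classifier(ln[, 1:10], pl,
                     seed = derive_seed(seed, paste0("permfit/", s)))$auroc
  }, 0)
  list(auroc = rep1$auroc, auroc_perm = median(perms), report = rep1)
}

#' Kolmogorov distance of uniform-disk transcript distances from x^2
#'
#' Molecules placed uniformly in a disk-shaped cell have normalized
#' centroid distances with CDF x^2; returns the empirical Kolmogorov
#' distance at the stated sample size.
#'
#' @param seed integer seed.
#' @param n_molecules sample size.
#' @param cfg [run_config()].
#' @return list: `ks`, `n`.
#' @export
distance_cdf_experiment <- function(seed = 1L, n_molecules = 5000L,
                                    cfg = run_config(seed = seed)) {
  cell <- simulate_cell(shape_params(n_primary_branches = 0, soma_radius = 40,
                                     image_size = 128),
                        seed = derive_seed(seed, "cdf_cell"))
  attr(cell, "pixel_size") <- cfg$pixel_size
  tx <- simulate_transcripts(cell, list(gene_model("U", n_molecules, -20)),
                             seed = derive_seed(seed, "cdf_tx"))
  dc <- transcript_distance_cdf(cell, tx)
  x <- sort(dc$dist)
  n <- length(x)
  ks <- max(pmax(abs(seq_len(n) / n - x^2), abs((seq_len(n) - 1) / n - x^2)))
  list(ks = ks, n = n)
}
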