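# In-code fixtures: small cells and masks built programmatically.

px_i <- micromorph:::px_index
max_projection <- micromorph:::max_project

make_cell <- function(total2d, soma2d, nz = 1L, cell_id = "cell",
                      centroid = NULL, pixel_size = 0.5) {
  proc2d <- total2d & !soma2d
  dm <- dim(total2d)
  arr <- function(m) array(rep(m, nz), dim = c(dm, nz))
  if (is.null(centroid)) {
    w <- which(soma2d | total2d, arr.ind = TRUE)
    centroid <- c(x = mean(w[, 1]) - 0.5, y = mean(w[, 2]) - 0.5)
  }
  cell <- structure(list(cell_id = cell_id, total = arr(total2d),
                         soma = arr(soma2d), process = arr(proc2d),
                         soma_centroid = centroid,
                         skeleton = matrix(FALSE, dm[1], dm[2]),
                         provenance = NULL),
                    class = "cell_compartments")
  attr(cell, "pixel_size") <- pixel_size
  cell
}

disk2d <- function(size, cx, cy, r) {
  x <- matrix(seq_len(size) - 0.5, size, size)
  y <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

disk_cell <- function(r = 30, size = 128, nz = 1L, ...) {
  d <- disk2d(size, size / 2, size / 2, r)
  make_cell(d, d, nz = nz, centroid = c(x = size / 2, y = size / 2), ...)
}

# tiny coloc testbed: the default small panel used by the co-localization
# recovery checks
coloc_panel <- function(n_coloc_pairs = 1) {
  default_gene_panel(n_soma = 3, n_process = 3, n_neutral = 6,
                     mean_count = 40, n_coloc_pairs = n_coloc_pairs,
                     cluster_sigma = 1, cluster_children = 6)
}

run_soma_coloc <- function(ds, cfg, n_null = 200, seed = 1) {
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
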