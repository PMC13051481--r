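# Compartment-constrained spatial statistics: 3D Ripley K/H clustering test
# with Monte-Carlo envelopes, and the gene-gene co-localization procedure
# (radius selection, pair counting, randomization null, z-test + BH,
# network construction and mixture clustering).

transcripts_to_um <- function(tx, cfg) {
  cbind(tx$x * cfg$pixel_size, tx$y * cfg$pixel_size,
        (tx$z - 1) * cfg$z_spacing)
}

voxel_volume <- function(cfg) cfg$pixel_size^2 * cfg$z_spacing

#' 3D Ripley K estimator on a bounded compartment
#'
#' `K(r) = V / (n (n-1)) * sum_{i != j} 1[d_ij <= r]`, with V the domain
#' volume (on-voxel count times voxel volume). No edge correction is
#' applied: the Monte-Carlo null lives in the same domain, so boundary bias
#' cancels in the envelope comparison.
#'
#' @param pts n x 3 matrix of micron coordinates (>= 2 points).
#' @param volume domain volume in cubic microns.
#' @param radii ascending radii, microns.
#' @return numeric `K(r)` per radius.
#' @export
ripley_k3d <- function(pts, volume, radii) {
  stopifnot(nrow(pts) >= 2, !is.unsorted(radii))
  n <- nrow(pts)
  counts <- cpp_k_counts(pts, radii)
  volume / (n * (n - 1)) * counts
}

#' Besag-style H transform of a 3D K function
#' @param k `K(r)` values.
#' @param radii matching radii.
#' @return `H(r) = (3 K / (4 pi))^(1/3) - r`, centered at 0 under CSR.
#' @export
ripley_h <- function(k, radii) (3 * k / (4 * pi))^(1 / 3) - radii

compartment_h <- function(pts_px, mask3d, cfg, radii, per_process = FALSE) {
  if (!per_process) {
    v <- sum(mask3d) * voxel_volume(cfg)
    pts <- cbind(pts_px$x * cfg$pixel_size, pts_px$y * cfg$pixel_size,
                 (pts_px$z - 1) * cfg$z_spacing)
    return(ripley_h(ripley_k3d(pts, v, radii), radii))
  }
  lab2d <- label_components(max_project(mask3d))
  ix <- px_index(pts_px$x, dim(mask3d)[1])
  iy <- px_index(pts_px$y, dim(mask3d)[2])
  pl <- lab2d[cbind(ix, iy)]
  hs <- NULL
  for (p in seq_len(max(lab2d))) {
    sel <- pl == p
    if (sum(sel) < 2) next
    vox2d <- lab2d == p
    nvox <- sum(mask3d & array(rep(vox2d, dim(mask3d)[3]), dim = dim(mask3d)))
    v <- nvox * voxel_volume(cfg)
    pts <- cbind(pts_px$x[sel] * cfg$pixel_size, pts_px$y[sel] * cfg$pixel_size,
                 (pts_px$z[sel] - 1) * cfg$z_spacing)
    hs <- rbind(hs, ripley_h(ripley_k3d(pts, v, radii), radii))
  }
  if (is.null(hs)) return(rep(NA_real_, length(radii)))
  colMeans(hs)
}

#' Monte-Carlo Ripley H envelope within a compartment
#'
#' The observed H curve is compared with pointwise 5%/95% quantiles of
#' `n_null` curves computed from the same number of points redrawn
#' uniformly over the compartment's voxels. Clustering is flagged at radii
#' where the observed curve leaves the envelope. For the process
#' compartment, the statistic is computed per individual process
#' (connected component) and averaged.
#'
#' @param pts_px data.frame `x, y` (px), `z` (plane index) of one gene's
#'   molecules inside the compartment (>= 2 rows).
#' @param mask3d logical `(x, y, z)` compartment mask (>= 10 voxels).
#' @param cfg [run_config()].
#' @param radii radii in microns.
#' @param n_null number of randomizations (>= 100 recommended).
#' @param seed integer seed.
#' @param per_process average the statistic over individual processes.
#' @return `ripley_result` list: `radii`, `k`, `h`, `lower`, `upper`,
#'   `flag_upper`, `flag_lower`, `flagged` (any radius outside).
#' @export
ripley_envelope <- function(pts_px, mask3d, cfg, radii, n_null = 200L,
                            seed = 1L, per_process = FALSE) {
  stopifnot(nrow(pts_px) >= 2)
  if (sum(mask3d) < 10) stop("compartment has fewer than 10 voxels")
  n <- nrow(pts_px)
  v <- sum(mask3d) * voxel_volume(cfg)
  obs_k <- if (!per_process)
    ripley_k3d(transcripts_to_um(pts_px, cfg), v, radii) else NULL
  obs_h <- compartment_h(pts_px, mask3d, cfg, radii, per_process)
  set.seed(derive_seed(seed, "ripley_envelope"))
  null_h <- matrix(NA_real_, n_null, length(radii))
  for (b in seq_len(n_null)) {
    null_pts <- sample_in_mask3d(mask3d, n)
    null_h[b, ] <- compartment_h(null_pts, mask3d, cfg, radii, per_process)
  }
  lower <- apply(null_h, 2, quantile, probs = 0.05, na.rm = TRUE)
  upper <- apply(null_h, 2, quantile, probs = 0.95, na.rm = TRUE)
  fu <- is.finite(obs_h) & obs_h > upper
  fl <- is.finite(obs_h) & obs_h < lower
  structure(list(radii = radii, k = obs_k, h = obs_h, lower = lower,
                 upper = upper, flag_upper = fu, flag_lower = fl,
                 flagged = any(fu | fl)),
            class = "ripley_result")
}

#' Co-localization radius from pooled soma pairwise distances
#'
#' Linear-interpolation percentile (default the 5th) of all pooled pairwise
#' transcript distances within somata.
#'
#' @param distances pooled pairwise distances, microns (>= 20 values).
#' @param percentile percentile in percent.
#' @return radius in microns.
#' @export
coloc_radius <- function(distances, percentile = 5) {
  if (!length(distances)) stop("no distances supplied")
  stopifnot(length(distances) >= 20)
  unname(quantile(distances, probs = percentile / 100, type = 7))
}

#' Pairwise soma distances for one cell (helper for [coloc_radius()])
#' @param tx assigned transcript rows of one compartment.
#' @param cfg [run_config()].
#' @return numeric vector of 3D distances, microns.
#' @export
compartment_pair_distances <- function(tx, cfg) {
  if (nrow(tx) < 2) return(numeric(0))
  cpp_pdist3(transcripts_to_um(tx, cfg))
}

#' Close-pair counts per unordered gene pair
#'
#' Counts molecule pairs of two distinct genes within `r_coloc` of each
#' other (3D); same-gene pairs are excluded.
#'
#' @param tx transcript rows of one cell compartment.
#' @param r_coloc radius, microns.
#' @param genes gene panel fixing the pair universe.
#' @param cfg [run_config()].
#' @return symmetric-upper integer matrix (genes x genes), diagonal zeroed.
#' @export
coloc_counts <- function(tx, r_coloc, genes, cfg) {
  gidx <- as.integer(factor(tx$gene, levels = genes))
  keep <- !is.na(gidx)
  m <- if (sum(keep) >= 2)
    cpp_pair_counts(transcripts_to_um(tx[keep, , drop = FALSE], cfg),
                    gidx[keep], length(genes), r_coloc)
  else matrix(0L, length(genes), length(genes))
  diag(m) <- 0L
  dimnames(m) <- list(genes, genes)
  m
}

#' Randomization null for co-localization counts
#'
#' Each randomization redraws every molecule uniformly within its own
#' compartment's voxels (per-gene counts preserved) and recomputes the
#' close-pair counts.
#'
#' @param tx transcript rows of one cell compartment.
#' @param mask3d that compartment's voxel mask.
#' @param r_coloc radius, microns.
#' @param genes gene panel.
#' @param cfg [run_config()].
#' @param n_null randomizations (a warning below 100).
#' @param seed integer seed.
#' @return 3D array `(n_null, genes, genes)` of null counts.
#' @export
coloc_null <- function(tx, mask3d, r_coloc, genes, cfg, n_null = 1000L,
                       seed = 1L) {
  if (n_null < 100L) warning("n_null below 100; null quantiles will be noisy")
  gidx <- as.integer(factor(tx$gene, levels = genes))
  gidx <- gidx[!is.na(gidx)]
  n <- length(gidx)
  out <- array(0L, dim = c(n_null, length(genes), length(genes)),
               dimnames = list(NULL, genes, genes))
  if (n < 2) return(out)
  set.seed(derive_seed(seed, "coloc_null"))
  for (b in seq_len(n_null)) {
    pts <- sample_in_mask3d(mask3d, n)
    m <- cpp_pair_counts(as.matrix(phys_dist_matrix_cols(pts$x, pts$y, pts$z, cfg)),
                         gidx, length(genes), r_coloc)
    diag(m) <- 0L
    out[b, , ] <- m
  }
  out
}

pair_index <- function(genes) {
  g <- expand.grid(a = seq_along(genes), b = seq_along(genes))
  g <- g[g$a < g$b, ]
  data.frame(gene_a = genes[g$a], gene_b = genes[g$b], ia = g$a, ib = g$b,
             stringsAsFactors = FALSE)
}

#' Cross-cell co-localization significance and network
#'
#' Per cell, a z-score per gene pair against that cell's randomization null
#' (pairs with zero null sd are skipped in that cell). Across cells, counts
#' and z-scores are averaged per pair, a one-sided upper p is recomputed
#' from the averaged z and BH-adjusted across pairs. An edge is kept iff
#' the average observed count reaches the 90th percentile of non-zero
#' average null contacts, the pair is observed in at least `min_obs` cells
#' and the adjusted p is below `alpha`; connected components of two or
#' fewer genes are dropped; remaining components are clustered with a
#' Gaussian mixture (component count by BIC over k = 1..min(5, nodes)) on a
#' spectral embedding of the z-weighted adjacency.
#'
#' @param obs list (one per cell) of observed count matrices from
#'   [coloc_counts()].
#' @param nulls list (one per cell) of null arrays from [coloc_null()].
#' @param genes gene panel.
#' @param alpha adjusted-p threshold.
#' @param min_obs minimum number of cells with at least one observed
#'   contact.
#' @param count_quantile quantile of non-zero average null contacts used as
#'   the count threshold.
#' @param combine `"average"` (mean z, the default) or `"stouffer"`.
#' @param seed seed for the mixture clustering.
#' @return `coloc_network` list: `pairs` (per-pair table), `edges`
#'   (significant pairs), `components` (node membership), `clusters`
#'   (per-node mixture labels), `count_threshold`.
#' @export
coloc_significance <- function(obs, nulls, genes, alpha = 0.05, min_obs = 4L,
                               count_quantile = 0.9,
                               combine = c("average", "stouffer"),
                               seed = 1L) {
  combine <- match.arg(combine)
  stopifnot(length(obs) == length(nulls))
  pi_tab <- pair_index(genes)
  np <- nrow(pi_tab)
  ncell <- length(obs)
  zmat <- cmat <- matrix(NA_real_, ncell, np)
  nullmean <- matrix(NA_real_, ncell, np)
  for (ci in seq_len(ncell)) {
    o <- obs[[ci]]; nl <- nulls[[ci]]
    for (k in seq_len(np)) {
      oc <- o[pi_tab$ia[k], pi_tab$ib[k]]
      nv <- nl[, pi_tab$ia[k], pi_tab$ib[k]]
      mu <- mean(nv); s <- sd(nv)
      cmat[ci, k] <- oc
      nullmean[ci, k] <- mu
      if (s > 0) zmat[ci, k] <- (oc - mu) / s
    }
  }
  avg_count <- colMeans(cmat, na.rm = TRUE)
  n_obs <- colSums(cmat >= 1, na.rm = TRUE)
  avg_z <- if (combine == "average") colMeans(zmat, na.rm = TRUE) else {
    nz <- colSums(!is.na(zmat))
    colSums(zmat, na.rm = TRUE) / sqrt(pmax(nz, 1))
  }
  p <- pnorm(avg_z, lower.tail = FALSE)
  p[is.na(p)] <- 1
  padj <- p.adjust(p, method = "BH")
  avg_null <- colMeans(nullmean, na.rm = TRUE)
  nz_null <- avg_null[avg_null > 0]
  cthr <- if (length(nz_null)) unname(quantile(nz_null, count_quantile, type = 7))
          else 0
  sig <- is.finite(avg_z) & avg_count >= cthr & n_obs >= min_obs & padj < alpha
  pairs <- data.frame(pi_tab[, c("gene_a", "gene_b")], avg_count = avg_count,
                      avg_z = avg_z, p = p, padj = padj, n_obs = n_obs,
                      significant = sig, stringsAsFactors = FALSE)
  edges <- pairs[sig, , drop = FALSE]
  comp <- clusters <- NULL
  if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                       directed = FALSE)
    igraph::E(g)$weight <- edges$avg_z
    memb <- igraph::components(g)$membership
    keep_comp <- names(which(table(memb) > 2))
    memb <- memb[as.character(memb) %in% keep_comp]
    if (length(memb)) {
      comp <- memb
      edges <- edges[edges$gene_a %in% names(memb) &
                     edges$gene_b %in% names(memb), , drop = FALSE]
      clusters <- cluster_network_components(edges, memb, seed)
    } else {
      edges <- edges[0, , drop = FALSE]
    }
  }
  structure(list(pairs = pairs, edges = edges, components = comp,
                 clusters = clusters, count_threshold = cthr),
            class = "coloc_network")
}

# Gaussian-mixture clustering of each connected component on a 2D spectral
# embedding of the z-weighted adjacency; component count by BIC.
cluster_network_components <- function(edges, membership, seed) {
  labels <- setNames(integer(0), character(0))
  for (cmp in unique(membership)) {
    nodes <- names(membership)[membership == cmp]
    n <- length(nodes)
    A <- matrix(0, n, n, dimnames = list(nodes, nodes))
    sub <- edges[edges$gene_a %in% nodes & edges$gene_b %in% nodes, ]
    for (i in seq_len(nrow(sub))) {
      A[sub$gene_a[i], sub$gene_b[i]] <- sub$avg_z[i]
      A[sub$gene_b[i], sub$gene_a[i]] <- sub$avg_z[i]
    }
    ev <- eigen(A, symmetric = TRUE)
    emb <- ev$vectors[, seq_len(min(2L, n)), drop = FALSE]
    set.seed(derive_seed(seed, paste0("gmm/", cmp)))
    fit <- tryCatch(
      mclust::Mclust(emb, G = seq_len(min(5L, n)), verbose = FALSE),
      error = function(e) NULL)
    cl <- if (is.null(fit)) rep(1L, n) else fit$classification
    labels <- c(labels, setNames(paste0(cmp, ".", cl), nodes))
  }
  labels
}
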