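# Morphology-expression correlation framework: Spearman correlation matrix
# on a training split, top-k gene-set selection, held-out hierarchical
# clustering, region stratification, transcript-distance CDFs, and the
# ramified-vs-amoeboid random-forest classifier.

RAMIFICATION_FEATURES <- c(
  "cell_area", "convex_perimeter", "convex_area", "cell_perimeter",
  "n_branches", "skeleton_length", "roughness", "n_terminal_points",
  "n_branching_points", "soma_ratio", "path_distance", "fractal_dimension",
  "euclidean_distance", "tortuosity", "ramification_index",
  "dendritic_maximum")

#' Names of the ramification-linked morphological features
#' @return character vector.
#' @export
ramification_features <- function() RAMIFICATION_FEATURES

#' Spearman correlation between genes and morphological features
#'
#' Cells are split (seeded) into a training fraction used to compute the
#' correlations and a held-out remainder reserved for clustering; held-out
#' cells never contribute to the correlation matrix. Ties get average
#' ranks; pairs with a constant margin on the training set are set to 0 and
#' flagged.
#'
#' @param features data.frame with `cell_id` and numeric feature columns.
#' @param lognorm cells x genes lognorm matrix (rownames = cell ids).
#' @param train_frac fraction of cells used for training.
#' @param seed integer seed for the split.
#' @return `correlation_matrix` list: `rho` (genes x features), `train_ids`,
#'   `test_ids`, `flagged` (constant pairs), `seed`.
#' @export
correlate <- function(features, lognorm, train_frac = 0.75, seed = 1L) {
  ids <- intersect(features$cell_id, rownames(lognorm))
  stopifnot(length(ids) >= 27)   # >= 20 training cells at the default split
  set.seed(derive_seed(seed, "correlate_split"))
  ntr <- round(train_frac * length(ids))
  train_ids <- sort(sample(ids, ntr))
  test_ids <- setdiff(ids, train_ids)
  fmat <- as.matrix(features[match(train_ids, features$cell_id),
                             setdiff(names(features), "cell_id"), drop = FALSE])
  fmat <- fmat[, apply(fmat, 2, function(v) all(is.finite(v))), drop = FALSE]
  emat <- lognorm[train_ids, , drop = FALSE]
  rho <- suppressWarnings(cor(emat, fmat, method = "spearman"))
  flagged <- which(is.na(rho), arr.ind = TRUE)
  rho[is.na(rho)] <- 0
  structure(list(rho = rho, train_ids = train_ids, test_ids = test_ids,
                 flagged = flagged, seed = seed),
            class = "correlation_matrix")
}

#' Top-k correlated genes per feature, unioned
#'
#' Per feature, the k genes with the largest absolute Spearman correlation
#' (first k after a stable sort; signed ranking available via `signed`).
#'
#' @param corr `correlation_matrix`.
#' @param k genes per feature.
#' @param signed rank by signed rho instead of |rho|.
#' @return character vector of genes, with a `provenance` attribute mapping
#'   each feature to its top-k list.
#' @export
top_gene_sets <- function(corr, k = 5, signed = FALSE) {
  rho <- corr$rho
  stopifnot(nrow(rho) >= k)
  prov <- lapply(colnames(rho), function(f) {
    v <- if (signed) rho[, f] else abs(rho[, f])
    rownames(rho)[order(-v)][seq_len(k)]
  })
  names(prov) <- colnames(rho)
  out <- unique(unlist(prov))
  attr(out, "provenance") <- prov
  out
}

#' Hierarchical two-group clustering of held-out cells on a gene set
#'
#' Average-linkage hierarchical clustering (Euclidean distance on lognorm
#' expression of the gene set), cut into two groups; agreement with the
#' amoeboid-vs-ramified partition (C1/C2 against the rest) is scored by the
#' adjusted Rand index.
#'
#' @param lognorm cells x genes lognorm matrix.
#' @param test_ids held-out cell ids (disjoint from training).
#' @param gene_set genes to cluster on.
#' @param morph_labels named factor/character of morphology classes
#'   (C1..Ck) per cell id.
#' @param amoeboid_classes classes pooled as the amoeboid side.
#' @return list: `groups` (named 1/2 per cell), `ari`, `flagged`.
#' @export
cluster_heldout <- function(lognorm, test_ids, gene_set, morph_labels,
                            amoeboid_classes = c("C1", "C2")) {
  X <- lognorm[test_ids, intersect(gene_set, colnames(lognorm)), drop = FALSE]
  if (nrow(unique(X)) < 2)
    return(list(groups = setNames(rep(1L, nrow(X)), test_ids), ari = NA_real_,
                flagged = TRUE))
  hc <- hclust(dist(X), method = "average")
  grp <- cutree(hc, k = 2)
  truth <- ifelse(as.character(morph_labels[test_ids]) %in% amoeboid_classes,
                  "amoeboid", "ramified")
  list(groups = grp, ari = adjusted_rand_index(grp, truth), flagged = FALSE)
}

#' Adjusted Rand index between two labelings
#' @param a,b label vectors of equal length.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(0)
  (sum_ij - expected) / (maxi - expected)
}

#' Region-stratified top ramification-correlated genes
#'
#' Per region, the mean Spearman correlation of each gene across the
#' ramification feature list; the top 5 genes per region and, across
#' regions, the number of regions in which each gene appears.
#'
#' @param features feature table (`cell_id` + feature columns).
#' @param lognorm cells x genes lognorm matrix.
#' @param regions named character of region labels per cell id.
#' @param feature_list ramification features to average over.
#' @param k genes kept per region.
#' @param min_cells regions with fewer cells are skipped with a warning.
#' @param seed split seed passed to [correlate()] per region.
#' @return list: `per_region` (named list of top-k gene vectors),
#'   `occurrence` (named integer counts, descending).
#' @export
region_stratified_top_genes <- function(features, lognorm, regions,
                                        feature_list = ramification_features(),
                                        k = 5, min_cells = 20, seed = 1L) {
  stopifnot(length(unique(regions)) >= 1)
  per_region <- list()
  for (r in unique(regions)) {
    ids <- names(regions)[regions == r]
    ids <- intersect(ids, intersect(features$cell_id, rownames(lognorm)))
    if (length(ids) < min_cells) {
      warning("region ", r, " has fewer than ", min_cells, " cells; skipped")
      next
    }
    fsub <- features[features$cell_id %in% ids, , drop = FALSE]
    keepf <- intersect(feature_list, names(fsub))
    fmat <- as.matrix(fsub[, keepf, drop = FALSE])
    emat <- lognorm[fsub$cell_id, , drop = FALSE]
    rho <- suppressWarnings(cor(emat, fmat, method = "spearman"))
    rho[is.na(rho)] <- 0
    avg <- rowMeans(rho)
    per_region[[r]] <- names(sort(avg, decreasing = TRUE))[seq_len(min(k, length(avg)))]
  }
  occ <- sort(table(unlist(per_region)), decreasing = TRUE)
  list(per_region = per_region,
       occurrence = setNames(as.integer(occ), names(occ)))
}

#' Normalized transcript-to-soma-centroid distance samples and CDF
#'
#' Per molecule, the in-plane Euclidean distance to the soma centroid is
#' divided by the maximum centroid-to-mask-pixel distance of that cell, so
#' 0 is the soma center and 1 the outermost edge.
#'
#' @param cell `cell_compartments`.
#' @param transcripts assigned `transcript_table` rows for this cell.
#' @return data.frame `gene, dist` plus attribute `cdf`: a named list of
#'   per-gene empirical CDF functions.
#' @export
transcript_distance_cdf <- function(cell, transcripts) {
  mp <- max_project(cell$total)
  w <- which(mp, arr.ind = TRUE)
  ctr <- cell$soma_centroid
  dmax <- max(sqrt((w[, 1] - 0.5 - ctr[1])^2 + (w[, 2] - 0.5 - ctr[2])^2))
  d <- sqrt((transcripts$x - ctr[1])^2 + (transcripts$y - ctr[2])^2) / dmax
  out <- data.frame(gene = transcripts$gene, dist = d,
                    stringsAsFactors = FALSE)
  cdfs <- lapply(split(out$dist, out$gene), ecdf)
  attr(out, "cdf") <- cdfs
  out
}

#' Random-forest classifier for ramified vs amoeboid cells
#'
#' Seeded 80/20 split; a small fixed hyperparameter grid (500-tree forests
#' with `num.trees` in {100, 300} and depth unlimited or 10) is tuned by
#' cross-validated accuracy on the training split only; the report carries
#' held-out AUROC and mean-decrease-in-impurity importances normalized to
#' sum to 1.
#'
#' @param lognorm cells x genes lognorm matrix restricted to the feature
#'   genes (e.g. process-enriched set).
#' @param labels named character of `"ramified"`/`"amoeboid"` per cell id
#'   (cells of other classes must be excluded by the caller).
#' @param split training fraction.
#' @param seed integer seed.
#' @param n_folds cross-validation folds for tuning.
#' @return `classifier_report` list: `auroc`, `importance` (named, sums to
#'   1), `params`, `seed`, `train_ids`, `test_ids`.
#' @export
train_classifier <- function(lognorm, labels, split = 0.8, seed = 1L,
                             n_folds = 5L) {
  ids <- intersect(rownames(lognorm), names(labels))
  y <- factor(labels[ids], levels = c("amoeboid", "ramified"))
  if (nlevels(droplevels(y)) < 2) stop("need both classes to train")
  stopifnot(min(table(y)) >= 20)
  set.seed(derive_seed(seed, "classifier_split"))
  ntr <- round(split * length(ids))
  tr <- sort(sample(seq_along(ids), ntr))
  te <- setdiff(seq_along(ids), tr)
  Xtr <- lognorm[ids[tr], , drop = FALSE]; ytr <- y[tr]
  Xte <- lognorm[ids[te], , drop = FALSE]; yte <- y[te]
  grid <- expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 10L))
  set.seed(derive_seed(seed, "classifier_cv"))
  folds <- sample(rep_len(seq_len(n_folds), nrow(Xtr)))
  acc <- numeric(nrow(grid))
  for (gi in seq_len(nrow(grid))) {
    correct <- 0L
    for (f in seq_len(n_folds)) {
      fit <- ranger::ranger(x = Xtr[folds != f, , drop = FALSE],
                            y = ytr[folds != f],
                            num.trees = grid$num_trees[gi],
                            max.depth = grid$max_depth[gi],
                            seed = derive_seed(seed, paste0("cv/", gi, "/", f)),
                            num.threads = 1L)
      pr <- predict(fit, data = Xtr[folds == f, , drop = FALSE],
                    num.threads = 1L)$predictions
      correct <- correct + sum(pr == ytr[folds == f])
    }
    acc[gi] <- correct / nrow(Xtr)
  }
  best <- grid[which.max(acc), ]
  fit <- ranger::ranger(x = Xtr, y = ytr, num.trees = best$num_trees,
                        max.depth = best$max_depth, probability = TRUE,
                        importance = "impurity",
                        seed = derive_seed(seed, "classifier_final"),
                        num.threads = 1L)
  prob <- predict(fit, data = Xte, num.threads = 1L)$predictions[, "ramified"]
  auroc <- as.numeric(pROC::auc(pROC::roc(response = yte, predictor = prob,
                                          levels = c("amoeboid", "ramified"),
                                          direction = "<", quiet = TRUE)))
  imp <- fit$variable.importance
  imp <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(imp), length(imp))
  structure(list(auroc = auroc, importance = imp,
                 params = as.list(best), cv_accuracy = max(acc), seed = seed,
                 train_ids = ids[tr], test_ids = ids[te]),
            class = "classifier_report")
}

#' Mean Spearman correlation per gene set per feature
#'
#' @param corr `correlation_matrix`.
#' @param gene_sets named list of gene vectors (e.g. soma- and
#'   process-enriched sets).
#' @return list per set: `per_feature` (named means) and `overall` (grand
#'   mean); genes absent from the matrix are skipped with a warning.
#' @export
avg_compartment_correlation <- function(corr, gene_sets) {
  stopifnot(all(lengths(gene_sets) > 0))
  out <- lapply(gene_sets, function(gs) {
    missing <- setdiff(gs, rownames(corr$rho))
    if (length(missing))
      warning("genes absent from correlation matrix: ",
              paste(missing, collapse = ", "))
    gs <- intersect(gs, rownames(corr$rho))
    sub <- corr$rho[gs, , drop = FALSE]
    list(per_feature = colMeans(sub), overall = mean(sub))
  })
  out
}
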