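# Count-matrix QC, log-normalization, Mann-Whitney differential expression
# with Benjamini-Hochberg correction, compartment-enrichment calls, tau
# specificity classification and binned-control gene-set scoring.

#' Quality-control filter on a count matrix
#'
#' Removes cells with fewer than `min_transcripts` total molecules or fewer
#' than `min_genes` distinct detected genes (both thresholds inclusive on
#' the keep side). The gene set is unchanged.
#'
#' @param m cells x genes count matrix.
#' @param min_transcripts minimum total transcripts per cell.
#' @param min_genes minimum unique genes per cell.
#' @return filtered matrix (possibly zero rows).
#' @export
qc_filter <- function(m, min_transcripts = 20, min_genes = 5) {
  keep <- rowSums(m) >= min_transcripts & rowSums(m > 0) >= min_genes
  out <- m[keep, , drop = FALSE]
  attr(out, "layer") <- attr(m, "layer")
  out
}

#' Log-normalize a count matrix
#'
#' Each count is divided by the cell total, scaled to 10,000 and
#' log1p-transformed (natural log): `ln(1 + 1e4 * count / total)`.
#'
#' @param m cells x genes count matrix; every cell must have at least one
#'   transcript.
#' @return matrix of the same shape, layer `"lognorm"`.
#' @export
lognormalize <- function(m) {
  tot <- rowSums(m)
  if (any(tot == 0)) stop("cell with zero transcripts; run qc_filter first")
  out <- log1p(sweep(unclass(m), 1, tot, "/") * 1e4)
  attr(out, "layer") <- "lognorm"
  out
}

#' Mann-Whitney differential expression between two cell groups
#'
#' Two-sided Mann-Whitney-Wilcoxon test per gene (normal approximation with
#' tie correction), BH adjustment across genes, and log2 fold change of
#' depth-normalized mean expression (`expm1` of the lognorm values) with a
#' 1e-9 pseudocount. DEG flags follow the strict rule |log2FC| > 1 and
#' padj < 0.05.
#'
#' @param lognorm lognorm-layer matrix (cells x genes).
#' @param groupA,groupB row names (cell ids) of the two groups (>= 3 cells
#'   each).
#' @param alpha adjusted-p threshold for the DEG flag.
#' @param lfc_threshold log2 fold-change threshold for the DEG flag.
#' @return data.frame: gene, log2fc (A vs B), statistic, p, padj, deg
#'   (`"up"`, `"down"` or `"ns"`).
#' @export
mww_de <- function(lognorm, groupA, groupB, alpha = 0.05, lfc_threshold = 1) {
  stopifnot(length(groupA) >= 3, length(groupB) >= 3)
  A <- lognorm[groupA, , drop = FALSE]
  B <- lognorm[groupB, , drop = FALSE]
  eps <- 1e-9
  genes <- colnames(lognorm)
  stat <- p <- lfc <- numeric(length(genes))
  for (j in seq_along(genes)) {
    a <- A[, j]; b <- B[, j]
    if (all(a == 0) && all(b == 0)) {
      stat[j] <- length(a) * length(b) / 2; p[j] <- 1; lfc[j] <- 0
      next
    }
    wt <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    stat[j] <- unname(wt$statistic)
    p[j] <- wt$p.value
    lfc[j] <- log2((mean(expm1(a)) + eps) / (mean(expm1(b)) + eps))
  }
  p[!is.finite(p)] <- 1
  padj <- p.adjust(p, method = "BH")
  deg <- ifelse(padj < alpha & lfc > lfc_threshold, "up",
                ifelse(padj < alpha & lfc < -lfc_threshold, "down", "ns"))
  data.frame(gene = genes, log2fc = lfc, statistic = stat, p = p,
             padj = padj, deg = deg, stringsAsFactors = FALSE)
}

#' Compartment-enrichment calls from paired soma/process counts
#'
#' Restricted to the most ramified morphology classes (C4/C5),
#' the soma and process count layers are log-normalized independently and
#' compared with [mww_de()] (process vs soma, pairing each cell's two
#' compartment profiles as the two groups). Up-DEGs are process-enriched,
#' down-DEGs soma-enriched.
#'
#' @param soma,process cells x genes count matrices with matching rows.
#' @param ramified_ids cell ids to use (must be non-empty).
#' @param min_total cells (compartment profiles) with fewer total counts are
#'   dropped before normalization.
#' @return `enriched_gene_sets` list: `process_enriched`, `soma_enriched`
#'   (disjoint character vectors), `de` (full table), `cells_used`.
#' @export
compartment_enrichment <- function(soma, process, ramified_ids,
                                   min_total = 1) {
  ramified_ids <- intersect(ramified_ids, intersect(rownames(soma),
                                                    rownames(process)))
  if (!length(ramified_ids)) stop("no ramified cells to compare")
  s <- soma[ramified_ids, , drop = FALSE]
  p <- process[ramified_ids, , drop = FALSE]
  s <- s[rowSums(s) >= min_total, , drop = FALSE]
  p <- p[rowSums(p) >= min_total, , drop = FALSE]
  sl <- lognormalize(s); pl <- lognormalize(p)
  rownames(sl) <- paste0("soma|", rownames(sl))
  rownames(pl) <- paste0("proc|", rownames(pl))
  both <- rbind(pl, sl)
  de <- mww_de(both, rownames(pl), rownames(sl))
  structure(list(process_enriched = de$gene[de$deg == "up"],
                 soma_enriched = de$gene[de$deg == "down"],
                 de = de, cells_used = ramified_ids),
            class = "enriched_gene_sets")
}

#' Tau specificity of a gene across cell types
#'
#' `tau = sum(1 - x_i / max(x)) / (N - 1)` over mean expression per type:
#' 0 for perfectly uniform expression, 1 for expression in a single type.
#' Classification: specific to the target type iff subclass tau >= 0.85
#' with the target as argmax; ubiquitous iff tau < 0.80 at both class and
#' subclass level; otherwise `"other"`.
#'
#' @param class_means,subclass_means genes x types matrices of mean lognorm
#'   expression at the two annotation levels (>= 2 types each).
#' @param target target type name (matched against subclass columns).
#' @param specific_threshold,ubiquitous_threshold tau cutoffs.
#' @return data.frame: gene, tau_class, tau_subclass, argmax, category.
#' @export
tau_specificity <- function(class_means, subclass_means, target = "microglia",
                            specific_threshold = 0.85,
                            ubiquitous_threshold = 0.80) {
  stopifnot(ncol(class_means) >= 2, ncol(subclass_means) >= 2,
            nrow(class_means) == nrow(subclass_means))
  tau_of <- function(x) {
    mx <- max(x)
    if (mx <= 0) return(NA_real_)
    sum(1 - x / mx) / (length(x) - 1)
  }
  genes <- rownames(class_means) %||% as.character(seq_len(nrow(class_means)))
  tc <- apply(class_means, 1, tau_of)
  ts <- apply(subclass_means, 1, tau_of)
  am <- colnames(subclass_means)[apply(subclass_means, 1, which.max)]
  category <- ifelse(is.na(tc) | is.na(ts), "other",
              ifelse(ts >= specific_threshold & am == target, "specific-to-target",
              ifelse(tc < ubiquitous_threshold & ts < ubiquitous_threshold,
                     "ubiquitous", "other")))
  data.frame(gene = genes, tau_class = tc, tau_subclass = ts, argmax = am,
             category = category, row.names = NULL, stringsAsFactors = FALSE)
}

#' Tau statistic for a single expression profile
#' @param x non-negative mean expression per type.
#' @return tau in `[0, 1]` (NA for an all-zero profile).
#' @export
tau_statistic <- function(x) {
  mx <- max(x)
  if (mx <= 0) return(NA_real_)
  sum(1 - x / mx) / (length(x) - 1)
}

#' Score cells for a gene set against expression-matched controls
#'
#' Per cell: mean lognorm expression of the set minus the mean of a control
#' set drawn (seeded) from expression-matched bins — genes are binned by
#' panel-wide mean expression into `n_bins` bins and 50 controls are sampled
#' (with replacement) from each set gene's bin.
#'
#' @param lognorm cells x genes lognorm matrix.
#' @param gene_set character vector (subset of the panel, non-empty).
#' @param n_bins number of expression bins.
#' @param n_ctrl controls sampled per set gene.
#' @param seed integer seed.
#' @return named numeric vector of per-cell scores.
#' @export
score_gene_set <- function(lognorm, gene_set, n_bins = 25, n_ctrl = 50,
                           seed = 1L) {
  stopifnot(length(gene_set) >= 1, all(gene_set %in% colnames(lognorm)))
  set.seed(derive_seed(seed, "score_gene_set"))
  gmean <- colMeans(lognorm)
  bins <- cut(rank(gmean, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  names(bins) <- colnames(lognorm)
  ctrl <- character(0)
  for (g in gene_set) {
    width <- 0L
    repeat {   # widen the bin window until it holds non-set control genes
      pool <- names(bins)[abs(bins - bins[g]) <= width]
      pool <- setdiff(pool, gene_set)
      if (length(pool) || width >= n_bins) break
      width <- width + 1L
    }
    if (!length(pool)) pool <- names(bins)[bins == bins[g]]  # set = panel
    ctrl <- c(ctrl, sample(pool, n_ctrl, replace = TRUE))
  }
  rowMeans(lognorm[, gene_set, drop = FALSE]) -
    rowMeans(lognorm[, ctrl, drop = FALSE])
}
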