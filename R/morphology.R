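# Morphometric suite: the canonical 26-feature vector, skeleton / Sholl /
# fractal / lacunarity analysis, the deterministic 512-d morphology
# embedding, elbow-selected k-means classes ordered by ramification, and the
# projection-depth consistency check.

FEATURE_NAMES <- c(
  "cell_area", "cell_perimeter", "convex_area", "convex_perimeter",
  "solidity", "convexity", "roughness", "circularity", "span_ratio",
  "convex_circularity", "eccentricity", "euler_number", "extent",
  "soma_area", "soma_perimeter", "soma_circularity", "soma_ratio",
  "feret_diameter", "skeleton_length", "mean_branch_length", "n_branches",
  "n_branching_points", "n_terminal_points", "fractal_dimension",
  "lacunarity", "tortuosity")

#' Names of the canonical 26 morphological features
#' @return character vector of length 26.
#' @export
feature_names <- function() FEATURE_NAMES

largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) <= 1L) return(mask)
  keep <- which.max(tabulate(lab[lab > 0L]))
  lab == keep
}

# outer-contour perimeter: 8-connected chain length with a uniform 0.98
# digitization correction (the raw chain overestimates smooth boundaries)
contour_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(largest_component(mask) * 1))[[1]]
  if (nrow(oc) < 2) return(0)
  ring <- rbind(oc, oc[1, , drop = FALSE])
  d2 <- rowSums((ring[-1, , drop = FALSE] - ring[-nrow(ring), , drop = FALSE])^2)
  0.98 * sum(sqrt(d2))
}

hull_metrics <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 3)
    return(list(area = nrow(w), perimeter = 2 * nrow(w), pts = w,
                span_ratio = 1))
  h <- grDevices::chull(w)
  hp <- w[h, , drop = FALSE]
  ring <- rbind(hp, hp[1, , drop = FALSE])
  per <- sum(sqrt(rowSums((ring[-1, , drop = FALSE] -
                           ring[-nrow(ring), , drop = FALSE])^2)))
  area <- polygon_area(ring)
  cv <- cov(hp)
  ev <- eigen(cv, symmetric = TRUE)$values
  span <- if (ev[2] > 1e-9) sqrt(ev[1] / ev[2]) else Inf
  list(area = area, perimeter = per, pts = hp, span_ratio = span)
}

euler_number <- function(mask) {
  lab <- label_components(mask)
  ncomp <- max(lab)
  filled <- EBImage::fillHull(EBImage::Image(mask * 1))
  holes <- matrix(as.numeric(EBImage::imageData(filled)) > 0.5,
                  nrow(mask), ncol(mask)) & !mask
  nholes <- max(label_components(holes))
  ncomp - nholes
}

eccentricity <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 2) return(0)
  ev <- eigen(cov(w), symmetric = TRUE)$values
  ev[ev < 0] <- 0
  if (ev[1] <= 1e-12) return(0)
  sqrt(max(0, 1 - ev[2] / ev[1]))
}

#' Topological skeleton and branch measurements
#'
#' Zhang-Suen thinning followed by branch decomposition: terminal points are
#' skeleton pixels with one 8-neighbour, branching points those with three
#' or more; branches are the maximal skeleton paths left after removing
#' branching points. Branch tortuosity is path length divided by endpoint
#' chord length, averaged over branches.
#'
#' @param mask logical matrix (2D, x-by-y).
#' @return list: `skeleton` (logical matrix), `n_branches`,
#'   `n_branching_points`, `n_terminal_points`, `skeleton_length`,
#'   `mean_branch_length`, `tortuosity`, `euclidean_distance`,
#'   `path_distance` (the last two are per-branch means).
#' @export
skeletonize_and_measure <- function(mask) {
  empty <- list(skeleton = mask & FALSE, n_branches = 0L,
                n_branching_points = 0L, n_terminal_points = 0L,
                skeleton_length = 0, mean_branch_length = 0, tortuosity = 0,
                euclidean_distance = 0, path_distance = 0)
  if (sum(mask) < 3) return(empty)
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  skp <- cpp_zhang_suen(pad)
  skel <- skp[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)]
  if (sum(skel) < 1) return(empty)
  nbr <- skeleton_degree(skel)
  terminals <- skel & nbr == 1L
  branchpts <- skel & nbr >= 3L
  segs <- skel & !branchpts
  lab <- label_components(segs)
  nseg <- max(lab)
  lens <- chords <- numeric(0)
  for (s in seq_len(nseg)) {
    pix <- which(lab == s, arr.ind = TRUE)
    m <- trace_path(pix)
    if (is.null(m)) next
    lens <- c(lens, m$path)
    chords <- c(chords, m$chord)
  }
  tort <- if (length(lens)) {
    ok <- chords > 0
    if (any(ok)) mean(lens[ok] / chords[ok]) else 0
  } else 0
  list(skeleton = skel,
       n_branches = as.integer(nseg),
       n_branching_points = as.integer(sum(branchpts)),
       n_terminal_points = as.integer(sum(terminals)),
       skeleton_length = skeleton_length(skel),
       mean_branch_length = if (length(lens)) mean(lens) else 0,
       tortuosity = tort,
       euclidean_distance = if (length(chords)) mean(chords) else 0,
       path_distance = if (length(lens)) mean(lens) else 0)
}

shift_mask <- function(mask, dx, dy) {
  nx <- nrow(mask); ny <- ncol(mask)
  p <- matrix(FALSE, nx + 2L, ny + 2L)
  p[2:(nx + 1L), 2:(ny + 1L)] <- mask
  p[(2:(nx + 1L)) + dx, (2:(ny + 1L)) + dy]
}

# skeleton-graph degree with redundant-diagonal cleanup: a diagonal
# adjacency does not count when the two pixels already share an orthogonal
# on-pixel (staircase corners are paths, not junctions)
skeleton_degree <- function(skel) {
  deg <- matrix(0L, nrow(skel), ncol(skel))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    deg <- deg + (shift_mask(skel, d[1], d[2]) & skel)
  for (d in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    diagn <- shift_mask(skel, d[1], d[2]) & skel
    bridge <- (shift_mask(skel, d[1], 0) | shift_mask(skel, 0, d[2])) & skel
    deg <- deg + (diagn & !bridge)
  }
  deg
}

# order the pixels of a thin path segment endpoint-to-endpoint; returns NULL
# for single pixels without extent
trace_path <- function(pix) {
  n <- nrow(pix)
  if (n == 1L) return(list(path = 0, chord = 0))
  d <- as.matrix(dist(pix))
  adj <- d > 0 & d < 1.6
  deg <- rowSums(adj)
  start <- which(deg == 1L)[1]
  if (is.na(start)) start <- 1L   # tiny loop; arbitrary start
  visited <- logical(n); cur <- start; visited[cur] <- TRUE
  path <- 0; last <- cur
  for (k in seq_len(n - 1L)) {
    nxt <- which(adj[cur, ] & !visited)
    if (!length(nxt)) break
    nxt <- nxt[which.min(d[cur, nxt])]
    path <- path + d[cur, nxt]
    visited[nxt] <- TRUE
    cur <- nxt
  }
  list(path = path, chord = sqrt(sum((pix[cur, ] - pix[start, ])^2)))
}

skeleton_length <- function(skel) {
  len <- 0
  for (sh in list(c(1, 0), c(0, 1)))
    len <- len + sum(shift_mask(skel, sh[1], sh[2]) & skel)
  for (sh in list(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))) {
    diagn <- shift_mask(skel, sh[1], sh[2]) & skel
    bridge <- (shift_mask(skel, sh[1], 0) | shift_mask(skel, 0, sh[2])) & skel
    len <- len + sqrt(2) * sum(diagn & !bridge) / 2
  }
  len
}

#' Box-counting fractal dimension
#'
#' Counts occupied boxes at dyadic sizes `2, 4, 8, ..., side/4` on a grid
#' anchored at the mask bounding-box corner, and returns the least-squares
#' slope of `log N(s)` against `log(1/s)`.
#'
#' @param mask logical matrix.
#' @return scalar dimension estimate (0 for degenerate masks).
#' @export
fractal_dimension <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) < 2) return(0)
  sub <- mask[min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2]), drop = FALSE]
  side <- max(dim(sub))
  sizes <- 2^(1:floor(log2(side / 4)))
  sizes <- sizes[sizes >= 2]
  if (length(sizes) < 2) return(0)
  counts <- vapply(sizes, function(s) {
    bx <- (which(sub, arr.ind = TRUE) - 1L) %/% s
    nrow(unique(bx))
  }, 0L)
  fit <- stats::lm.fit(cbind(1, log(1 / sizes)), log(counts))
  unname(fit$coefficients[2])
}

#' Gliding-box lacunarity
#'
#' Box size is `ceiling(side / 8)` of the bounding box; the statistic is
#' `var(mass) / mean(mass)^2 + 1` over all gliding positions (population
#' variance), so a fully filled mask gives exactly 1.
#'
#' @param mask logical matrix.
#' @return scalar >= 1 (NA for an empty mask).
#' @export
lacunarity <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(NA_real_)
  sub <- mask[min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2]), drop = FALSE]
  b <- max(1L, ceiling(max(dim(sub)) / 8))
  nx <- nrow(sub); ny <- ncol(sub)
  if (b >= nx || b >= ny) b <- max(1L, min(nx, ny) - 1L)
  S <- sat(sub * 1)
  x0 <- seq_len(nx - b + 1L); y0 <- seq_len(ny - b + 1L)
  g <- expand.grid(x0 = x0, y0 = y0)
  mass <- sat_box(S, g$x0, g$x0 + b - 1L, g$y0, g$y0 + b - 1L)
  mu <- mean(mass)
  if (mu == 0) return(NA_real_)
  v <- mean(mass^2) - mu^2
  v / mu^2 + 1
}

#' Sholl analysis of a skeleton
#'
#' Counts intersections between the skeleton and circles of increasing
#' radius around the soma centroid; an intersection is a connected component
#' of the skeleton restricted to a 1-px-wide annulus. Summaries follow the
#' radius-ratio convention: the ramification index is the radius of maximal
#' intersections divided by the first non-zero radius.
#'
#' @param skeleton logical matrix.
#' @param soma_centroid `(x, y)` in px.
#' @param radius_step circle spacing, px.
#' @return `sholl_result` list: `radii`, `intersections`,
#'   `ramification_index`, `critical_radius`, `dendritic_maximum`.
#' @export
sholl <- function(skeleton, soma_centroid, radius_step = 2) {
  stopifnot(any(skeleton))
  w <- which(skeleton, arr.ind = TRUE)
  dists <- sqrt((w[, 1] - 0.5 - soma_centroid[1])^2 +
                (w[, 2] - 0.5 - soma_centroid[2])^2)
  rmax <- max(dists)
  radii <- seq(radius_step, max(radius_step, ceiling(rmax)), by = radius_step)
  inter <- integer(length(radii))
  dmat <- matrix(0, nrow(skeleton), ncol(skeleton))
  dmat[w] <- dists
  hw <- sqrt(2) / 2   # annulus half-width: an 8-connected path cannot skip it
  for (k in seq_along(radii)) {
    ann <- skeleton & abs(dmat - radii[k]) <= hw
    inter[k] <- max(label_components(ann))
  }
  nz <- which(inter > 0)
  if (!length(nz)) {
    return(structure(list(radii = radii, intersections = inter,
                          ramification_index = NA_real_,
                          critical_radius = NA_real_,
                          dendritic_maximum = NA_real_, flagged = TRUE),
                     class = "sholl_result"))
  }
  crit <- radii[which.max(inter)]
  first <- radii[nz[1]]
  structure(list(radii = radii, intersections = inter,
                 ramification_index = crit / first,
                 critical_radius = crit,
                 dendritic_maximum = radii[max(nz)], flagged = FALSE),
            class = "sholl_result")
}

#' Compute the canonical 26-feature morphometric vector for one cell
#'
#' Works on the maximum projection of the per-plane masks. Ratio features
#' follow their standard definitions (solidity = area / convex area,
#' circularity = 4 pi area / perimeter^2, roughness = perimeter / convex
#' perimeter, convexity = its inverse, soma ratio = soma area / cell area);
#' skeleton features come from [skeletonize_and_measure()], complexity
#' measures from [fractal_dimension()] and [lacunarity()].
#'
#' @param cell `cell_compartments`.
#' @param intensity optional 2D intensity image (x-by-y) for the
#'   supplementary mean-intensity feature.
#' @param radius_step Sholl circle spacing for the supplementary Sholl
#'   scalars.
#' @return named numeric vector of length 26 (attribute `supplementary`
#'   holds Sholl scalars, per-branch distances and mean intensity;
#'   attribute `flags` notes degenerate inputs).
#' @export
compute_features <- function(cell, intensity = NULL, radius_step = 2) {
  total <- max_project(cell$total)
  soma <- max_project(cell$soma)
  stopifnot(any(total))
  area <- sum(total)
  per <- contour_perimeter(total)
  h <- hull_metrics(total)
  flags <- character(0)
  sk <- skeletonize_and_measure(total)
  soma_feats <- if (any(soma)) {
    sa <- sum(soma); sp <- contour_perimeter(soma)
    c(soma_area = sa, soma_perimeter = sp,
      soma_circularity = if (sp > 0) 4 * pi * sa / sp^2 else 0,
      soma_ratio = sa / area)
  } else {
    flags <- c(flags, "empty soma mask")
    c(soma_area = 0, soma_perimeter = 0, soma_circularity = 0, soma_ratio = 0)
  }
  feret <- if (nrow(h$pts) >= 2) sqrt(max(cpp_pdist3(cbind(h$pts, 0))^2)) else 0
  w <- which(total, arr.ind = TRUE)
  bbox_area <- prod(apply(w, 2, function(v) diff(range(v)) + 1L))
  out <- c(
    cell_area = area,
    cell_perimeter = per,
    convex_area = h$area,
    convex_perimeter = h$perimeter,
    solidity = min(1, area / max(h$area, 1e-9)),
    convexity = if (per > 0) h$perimeter / per else 0,
    roughness = if (h$perimeter > 0) per / h$perimeter else 0,
    circularity = if (per > 0) 4 * pi * area / per^2 else 0,
    span_ratio = h$span_ratio,
    convex_circularity = if (h$perimeter > 0) 4 * pi * h$area / h$perimeter^2 else 0,
    eccentricity = eccentricity(total),
    euler_number = euler_number(total),
    extent = area / bbox_area,
    soma_feats,
    feret_diameter = feret,
    skeleton_length = sk$skeleton_length,
    mean_branch_length = sk$mean_branch_length,
    n_branches = sk$n_branches,
    n_branching_points = sk$n_branching_points,
    n_terminal_points = sk$n_terminal_points,
    fractal_dimension = fractal_dimension(total),
    lacunarity = {
      l <- lacunarity(total)
      if (is.na(l)) { flags <- c(flags, "lacunarity undefined"); 0 } else l
    },
    tortuosity = sk$tortuosity)
  out <- out[FEATURE_NAMES]
  sh <- if (any(sk$skeleton))
    sholl(sk$skeleton, cell$soma_centroid, radius_step) else NULL
  supp <- c(ramification_index = if (!is.null(sh)) sh$ramification_index else NA_real_,
            critical_radius = if (!is.null(sh)) sh$critical_radius else NA_real_,
            dendritic_maximum = if (!is.null(sh)) sh$dendritic_maximum else NA_real_,
            euclidean_distance = sk$euclidean_distance,
            path_distance = sk$path_distance,
            mean_intensity = if (!is.null(intensity)) mean(intensity[total]) else NA_real_)
  attr(out, "supplementary") <- supp
  attr(out, "flags") <- flags
  out
}

#' Feature table for a list of cells
#' @param cells list of `cell_compartments`.
#' @param ... passed to [compute_features()].
#' @return data.frame: `cell_id` plus the 26 canonical and the supplementary
#'   columns.
#' @export
feature_table <- function(cells, ...) {
  rows <- lapply(cells, function(cl) {
    f <- compute_features(cl, ...)
    c(f, attr(f, "supplementary"))
  })
  df <- as.data.frame(do.call(rbind, rows))
  df <- cbind(cell_id = vapply(cells, `[[`, "", "cell_id"), df)
  rownames(df) <- NULL
  df
}

# ---- embedding -------------------------------------------------------------

resize_gray <- function(img, w, h) {
  out <- EBImage::resize(EBImage::Image(img), w = w, h = h)
  matrix(as.numeric(EBImage::imageData(out)), w, h)
}

#' Prepare a cell crop for embedding: 112x112 resize, mid-gray pad to 224x224
#' @param crop 2D numeric matrix (x-by-y), values in `[0, 1]`.
#' @return 224x224 matrix.
#' @export
embed_preprocess <- function(crop) {
  stopifnot(length(dim(crop)) == 2, all(dim(crop) >= 1))
  sc <- 112 / max(dim(crop))
  w <- max(1L, round(dim(crop)[1] * sc)); h <- max(1L, round(dim(crop)[2] * sc))
  small <- resize_gray(crop, w, h)
  out <- matrix(0.5, 224, 224)
  x0 <- floor((224 - w) / 2); y0 <- floor((224 - h) / 2)
  out[x0 + seq_len(w), y0 + seq_len(h)] <- small
  out
}

pool_grid <- function(img, g) {
  n <- nrow(img)
  b <- n / g
  idx <- rep(seq_len(g), each = b)
  rs <- rowsum(img, idx)
  t(rowsum(t(rs), idx)) / b^2
}

#' Deterministic multiscale morphology embedding (512 values per image)
#'
#' The backend is a handcrafted multiscale descriptor: the padded 224x224
#' image is mean-pooled to a 16x16 intensity grid and its gradient-magnitude
#' image to another 16x16 grid, concatenated to exactly 512 values. It is
#' fully deterministic and needs no pretrained weights; it fulfils the same
#' length/preprocessing contract as a convolutional-network backend.
#'
#' @param crops list of 2D numeric matrices (one raw max-projection crop per
#'   cell, bounding box of the mask).
#' @return numeric matrix, one 512-long row per cell.
#' @export
embed_cells <- function(crops) {
  stopifnot(length(crops) >= 1)
  emb <- t(vapply(crops, function(crop) {
    if (!length(crop) || !all(dim(crop) >= 1)) stop("empty crop")
    img <- embed_preprocess(crop)
    gx <- img[c(2:224, 224), ] - img[c(1, 1:223), ]
    gy <- img[, c(2:224, 224)] - img[, c(1, 1:223)]
    gm <- sqrt(gx^2 + gy^2)
    v <- c(as.numeric(pool_grid(img, 16L)), as.numeric(pool_grid(gm, 16L)))
    stopifnot(length(v) == 512L, all(is.finite(v)))
    v
  }, numeric(512L)))
  emb
}

#' Crop the raw image to a mask bounding box
#' @param image 2D numeric matrix (x-by-y).
#' @param mask logical matrix, same shape.
#' @return cropped matrix.
#' @export
crop_to_mask <- function(image, mask) {
  w <- which(mask, arr.ind = TRUE)
  stopifnot(nrow(w) > 0)
  image[min(w[, 1]):max(w[, 1]), min(w[, 2]):max(w[, 2]), drop = FALSE]
}

#' Cluster cells in morphology-embedding space
#'
#' PCA to the top 10 components, k-means over k = 1..10 (10 restarts,
#' seed-derived) and a Kneedle elbow pick on the inertia curve; clusters are
#' relabelled C1..Ck in ascending order of mean terminal-point count (C1 =
#' least ramified), with mean cell area as the tie-break.
#'
#' @param embeddings n x 512 matrix from [embed_cells()].
#' @param features feature table with `n_terminal_points` and `cell_area`
#'   columns, same row order as `embeddings`.
#' @param seed integer seed.
#' @param k_max largest k tried.
#' @return `morphology_clusters` list: `labels` (factor C1..Ck), `k`,
#'   `inertia`, `pca` (top-10 rotation), `order_key` (per-cluster mean
#'   terminal points).
#' @export
cluster_morphology <- function(embeddings, features, seed, k_max = 10L) {
  n <- nrow(embeddings)
  if (n < 10L) stop("need at least 10 cells to cluster")
  stopifnot(nrow(features) == n)
  pc <- prcomp(embeddings, center = TRUE, scale. = FALSE)
  ncomp <- min(10L, ncol(pc$x))
  X <- pc$x[, seq_len(ncomp), drop = FALSE]
  ks <- seq_len(min(k_max, n - 1L))
  inertia <- numeric(length(ks))
  fits <- vector("list", length(ks))
  for (i in seq_along(ks)) {
    set.seed(derive_seed(seed, paste0("kmeans/", ks[i])))
    fits[[i]] <- kmeans(X, centers = ks[i], nstart = 10L, iter.max = 100L)
    inertia[i] <- fits[[i]]$tot.withinss
  }
  k <- kneedle(ks, inertia)
  fit <- fits[[which(ks == k)]]
  raw <- fit$cluster
  key <- vapply(seq_len(k), function(cl)
    mean(features$n_terminal_points[raw == cl]), 0)
  tie <- vapply(seq_len(k), function(cl) mean(features$cell_area[raw == cl]), 0)
  ord <- order(key, tie)
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  labels <- factor(paste0("C", relabel[raw]),
                   levels = paste0("C", seq_len(k)))
  structure(list(labels = labels, k = k, inertia = setNames(inertia, ks),
                 pca = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 order_key = key[ord]),
            class = "morphology_clusters")
}

#' Fractal-dimension consistency across maximum-projection depths
#'
#' For each cell, compares the fractal dimension of the full-depth maximum
#' projection with the mean over a sliding family of fixed-thickness
#' windows containing the soma plane (from the window ending at the soma
#' plane to the window starting there), and fits section-limited FD against
#' full-depth FD by least squares.
#'
#' @param cells list of `cell_compartments`.
#' @param thicknesses window thicknesses in microns.
#' @param cfg [run_config()] (supplies `z_spacing`).
#' @param soma_plane soma-center plane index per cell (default: middle
#'   plane).
#' @return list: `table` (cell, thickness, full_fd, section_fd), `slope`,
#'   `intercept`, `correlation`.
#' @export
projection_consistency <- function(cells, thicknesses = c(10, 15, 20), cfg,
                                   soma_plane = NULL) {
  rows <- list()
  for (ci in seq_along(cells)) {
    cell <- cells[[ci]]
    nz <- dim(cell$total)[3]
    sp <- if (is.null(soma_plane)) ceiling(nz / 2) else soma_plane[ci]
    full_fd <- fractal_dimension(max_project(cell$total))
    for (th in thicknesses) {
      wplanes <- max(1L, round(th / cfg$z_spacing))
      if (wplanes > nz) { warning("thickness ", th, " um exceeds stack; skipped"); next }
      starts <- seq(max(1L, sp - wplanes + 1L), min(sp, nz - wplanes + 1L))
      fds <- vapply(starts, function(s)
        fractal_dimension(max_project(cell$total[, , s:(s + wplanes - 1L),
                                                 drop = FALSE])), 0)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cell$cell_id, thickness = th, full_fd = full_fd,
        section_fd = mean(fds))
    }
  }
  tab <- do.call(rbind, rows)
  if (sd(tab$full_fd) == 0 || sd(tab$section_fd) == 0) {
    slope <- if (all(tab$section_fd == tab$full_fd)) 1 else NA_real_
    return(list(table = tab, slope = slope, intercept = 0,
                correlation = if (identical(slope, 1)) 1 else NA_real_))
  }
  fit <- stats::lm.fit(cbind(1, tab$full_fd), tab$section_fd)
  list(table = tab, slope = unname(fit$coefficients[2]),
       intercept = unname(fit$coefficients[1]),
       correlation = cor(tab$full_fd, tab$section_fd))
}
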