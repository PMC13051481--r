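# Internal geometry and raster helpers.
#
# Raster convention used throughout: masks are logical matrices (or 3D arrays
# with the plane as the third dimension) whose FIRST index runs along x
# (rightward from the top-left origin) and SECOND index along y (downward),
# matching EBImage. A continuous coordinate (x, y) with 0 <= x < nx falls in
# pixel (floor(x) + 1, floor(y) + 1).

px_index <- function(coord, n) {
  i <- floor(coord) + 1L
  i[i < 1L] <- 1L
  i[i > n] <- n
  as.integer(i)
}

# logical matrix -> integer matrix of connected component labels (8-connected)
label_components <- function(mask) {
  mask <- mask > 0
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  cpp_label8(mask)
}

# physical 3D distance between transcript rows (x, y in px; z plane index)
phys_dist_matrix_cols <- function(x, y, z, cfg) {
  cbind(x * cfg$pixel_size, y * cfg$pixel_size, (z - 1) * cfg$z_spacing)
}

# summed-area table of a numeric matrix (for gliding-box sums)
sat <- function(m) {
  s <- apply(m, 2L, cumsum)
  t(apply(s, 1L, cumsum))
}

# sum over the box [x0..x1, y0..y1] from a summed-area table
sat_box <- function(S, x0, x1, y0, y1) {
  a <- S[cbind(x1, y1)]
  b <- ifelse(x0 > 1, S[cbind(pmax(x0 - 1, 1), y1)], 0)
  d <- ifelse(y0 > 1, S[cbind(x1, pmax(y0 - 1, 1))], 0)
  e <- ifelse(x0 > 1 & y0 > 1, S[cbind(pmax(x0 - 1, 1), pmax(y0 - 1, 1))], 0)
  a - b - d + e
}

# Kneedle elbow for a convex decreasing curve y(x): the knee is the x
# maximizing the difference between the normalized curve and the chord.
kneedle <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  xn <- (x - min(x)) / (max(x) - min(x))
  yr <- max(y) - min(y)
  if (yr == 0) return(x[1])
  yn <- (y - min(y)) / yr
  diffc <- (1 - xn) - yn        # distance above the decreasing chord
  x[which.max(diffc)]
}

# uniform sample of n points inside the on-voxels of a 3D mask; returns
# continuous (x, y, z-plane) coordinates jittered within each voxel footprint
# (z stays at the plane index: molecules live on decoded planes).
sample_in_mask3d <- function(mask3d, n) {
  idx <- which(mask3d)
  if (!length(idx)) stop("empty mask")
  pick <- idx[sample.int(length(idx), n, replace = TRUE)]
  dm <- dim(mask3d)
  a <- arrayInd(pick, dm)
  data.frame(x = a[, 1] - runif(n), y = a[, 2] - runif(n), z = a[, 3])
}

max_project <- function(stack3d) {
  out <- apply(stack3d, c(1L, 2L), max)
  if (is.logical(stack3d)) out > 0 else out
}

# centroid (x, y) of a logical matrix, in continuous pixel coordinates
mask_centroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(x = mean(w[, 1]) - 0.5, y = mean(w[, 2]) - 0.5)
}
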