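# Image-derived cell delineation: coarse stain segmentation, unique matching
# of image labels to transcriptomic boundaries, soma/process decomposition
# with astrocyte (GFAP) subtraction, transcript-to-compartment assignment,
# and stain-aggregate detection.
#
# Noise suppression in coarse_segment requires a pixel to fail BOTH the
# edge-magnitude and the intensity Otsu cut before it is zeroed: suppressing
# on edge magnitude alone hollows out flat stain interiors and fragments
# one cell into several labels, which the unique-matching rule then drops.

otsu_threshold <- function(img) {
  EBImage::otsu(EBImage::Image(pmin(pmax(img, 0), 1)))
}

sobel_magnitude <- function(img) {
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)
  e1 <- EBImage::filter2(EBImage::Image(img), kx)
  e2 <- EBImage::filter2(EBImage::Image(img), t(kx))
  m <- sqrt(as.numeric(EBImage::imageData(e1))^2 +
            as.numeric(EBImage::imageData(e2))^2)
  matrix(m, nrow(img), ncol(img))
}

# local-mean adaptive threshold: on iff value exceeds the boxcar mean of a
# (window x window) neighbourhood by `offset` (2/255, i.e. 2 intensity units
# on the 8-bit scale)
adaptive_threshold <- function(img, window, offset = 2 / 255) {
  w <- min(window, min(dim(img)) - 2L)
  w <- max(3L, 2L * floor(w / 2) + 1L)       # odd, within the frame
  k <- matrix(1 / (w * w), w, w)
  mu <- EBImage::filter2(EBImage::Image(img), k)
  img > matrix(as.numeric(EBImage::imageData(mu)), nrow(img), ncol(img)) + offset
}

#' Coarse segmentation of an IBA1 maximum projection
#'
#' Pipeline: histogram equalization, 8-bit quantization, rolling-ball style
#' background subtraction (white top-hat), suppression of pixels whose Sobel
#' edge magnitude falls below the Otsu threshold of the edge image (removes
#' flat autofluorescence noise), Gaussian blur, Otsu threshold, connected-
#' component labeling.
#'
#' @param img 2D numeric matrix (x-by-y), values in `[0, 1]`.
#' @param blur_sigma Gaussian blur sd, px.
#' @param bg_radius top-hat structuring-element radius, px.
#' @param min_area components smaller than this many pixels are discarded
#'   as residual speckle noise.
#' @return integer label matrix (0 = background); a constant image yields
#'   zero labels.
#' @export
coarse_segment <- function(img, blur_sigma = 2, bg_radius = 25,
                           min_area = 64L) {
  stopifnot(length(dim(img)) == 2)
  if (max(img) == min(img)) return(matrix(0L, nrow(img), ncol(img)))
  eq <- EBImage::equalize(EBImage::Image(img), range = c(0, 1), levels = 256)
  q <- round(matrix(as.numeric(EBImage::imageData(eq)), nrow(img), ncol(img)) * 255) / 255
  br <- EBImage::makeBrush(2L * bg_radius + 1L, "disc")
  op <- EBImage::opening(EBImage::Image(q), br)
  bg_sub <- pmax(q - matrix(as.numeric(EBImage::imageData(op)),
                            nrow(img), ncol(img)), 0)
  edge <- sobel_magnitude(bg_sub)
  if (max(edge) > 0 && max(bg_sub) > 0) {
    # noise = low gradient AND low intensity; flat bright interiors survive
    thr_e <- otsu_threshold(edge / max(edge)) * max(edge)
    thr_i <- otsu_threshold(bg_sub / max(bg_sub)) * max(bg_sub)
    bg_sub[edge < thr_e & bg_sub < thr_i] <- 0
  }
  bl <- EBImage::gblur(EBImage::Image(bg_sub), sigma = blur_sigma)
  blm <- matrix(as.numeric(EBImage::imageData(bl)), nrow(img), ncol(img))
  if (max(blm) == min(blm)) return(matrix(0L, nrow(img), ncol(img)))
  bin <- blm > otsu_threshold(blm / max(blm)) * max(blm)
  lab <- label_components(bin)
  if (max(lab) > 0L && min_area > 1L) {
    sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
    keep <- which(sizes >= min_area)
    lab <- label_components(matrix(lab %in% keep, nrow(lab), ncol(lab)))
  }
  lab
}

polygon_pixel_mask <- function(ring, nx, ny) {
  xr <- range(ring[, 1]); yr <- range(ring[, 2])
  xs <- max(1L, floor(xr[1])):min(nx, ceiling(xr[2]) + 1L)
  ys <- max(1L, floor(yr[1])):min(ny, ceiling(yr[2]) + 1L)
  if (!length(xs) || !length(ys)) return(matrix(FALSE, nx, ny))
  g <- expand.grid(x = xs, y = ys)
  inside <- mgcv::in.out(ring, cbind(g$x - 0.5, g$y - 0.5))
  m <- matrix(FALSE, nx, ny)
  m[cbind(g$x[inside], g$y[inside])] <- TRUE
  m
}

#' Uniquely match image labels to transcriptomic boundaries
#'
#' A (label, cell) pair is kept iff the boundary polygon overlaps exactly one
#' label and that label overlaps exactly one boundary (mutually unique
#' mapping); when annotations are supplied, the cell must additionally carry
#' the target annotation.
#'
#' @param labels integer label matrix from [coarse_segment()].
#' @param boundaries `boundary_set` in the same pixel frame.
#' @param annotations optional named character (cell_id -> type); defaults
#'   to the boundary set's own annotation.
#' @param target annotation required when annotations are present.
#' @return data.frame `label, cell_id` (possibly empty).
#' @export
match_labels <- function(labels, boundaries, annotations = boundaries$annotation,
                         target = "microglia") {
  nx <- nrow(labels); ny <- ncol(labels)
  ids <- names(boundaries$polygons)
  if (!length(ids) || max(labels) == 0L)
    return(data.frame(label = integer(0), cell_id = character(0)))
  overlap <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    m <- polygon_pixel_mask(boundaries$polygons[[ids[i]]], nx, ny)
    overlap[[i]] <- sort(unique(labels[m & labels > 0L]))
  }
  lab_deg <- tabulate(unlist(overlap), nbins = max(labels))
  keep <- data.frame(label = integer(0), cell_id = character(0),
                     stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    labs <- overlap[[i]]
    if (length(labs) != 1L) next
    if (lab_deg[labs] != 1L) next
    if (!is.null(annotations)) {
      ann <- annotations[ids[i]]
      if (is.na(ann) || ann != target) next
    }
    keep <- rbind(keep, data.frame(label = labs, cell_id = ids[i],
                                   stringsAsFactors = FALSE))
  }
  keep
}

#' Refine a matched cell into soma / process / total compartments
#'
#' Adaptive local-mean thresholding (coarse window) of the IBA1 and DAPI
#' maximum projections defines the soma as the DAPI-and-IBA1 component
#' containing the cell center. Per z-plane, IBA1 and GFAP are re-thresholded
#' at the fine window and GFAP-positive pixels are subtracted from that
#' plane's process mask (astrocyte false-positive removal). The total mask
#' is defined post-subtraction (soma union subtracted process) so that
#' per-plane masks always partition it.
#'
#' @param stack array `(channels, z, y, x)` with channels named `IBA1`,
#'   `DAPI` and optionally `GFAP`.
#' @param center `(x, y)` matched cell coordinate, px.
#' @param cell_id identifier for the result.
#' @param window_coarse,window_fine adaptive-threshold window sizes, px.
#' @param provenance optional list stored on the result.
#' @return a `cell_compartments` object, or `NULL` (with a warning) when no
#'   DAPI/IBA1 overlap exists at the cell center.
#' @export
refine_compartments <- function(stack, center, cell_id = "cell",
                                window_coarse = 200, window_fine = 50,
                                provenance = NULL) {
  iba <- stack_channel_xyz(stack, "IBA1")
  dapi <- stack_channel_xyz(stack, "DAPI")
  gfap <- if ("GFAP" %in% dimnames(stack)[[1]])
    stack_channel_xyz(stack, "GFAP") else NULL
  nx <- dim(iba)[1]; ny <- dim(iba)[2]; nz <- dim(iba)[3]
  iba_mp <- max_project(iba); dapi_mp <- max_project(dapi)
  iba_mask <- adaptive_threshold(iba_mp, window_coarse)
  dapi_mask <- adaptive_threshold(dapi_mp, window_coarse)
  joint <- label_components(iba_mask & dapi_mask)
  cx <- px_index(center[1], nx); cy <- px_index(center[2], ny)
  soma_lab <- joint[cx, cy]
  if (soma_lab == 0L) {
    # tolerate single-pixel holes: majority label within a 5-px neighbourhood
    xs <- max(1L, cx - 5L):min(nx, cx + 5L)
    ys <- max(1L, cy - 5L):min(ny, cy + 5L)
    near <- joint[xs, ys]
    near <- near[near > 0L]
    if (length(near)) soma_lab <- as.integer(names(which.max(table(near))))
  }
  if (soma_lab == 0L) {
    warning("no DAPI/IBA1 overlap at center of ", cell_id, "; cell skipped")
    return(NULL)
  }
  soma2d <- joint == soma_lab
  total <- soma <- process <- array(FALSE, dim = c(nx, ny, nz))
  for (p in seq_len(nz)) {
    iba_fine <- adaptive_threshold(iba[, , p], window_fine)
    proc_p <- iba_fine & !soma2d
    if (!is.null(gfap)) {
      gfap_fine <- adaptive_threshold(gfap[, , p], window_fine)
      proc_p <- proc_p & !gfap_fine
    }
    soma[, , p] <- soma2d
    process[, , p] <- proc_p
    total[, , p] <- soma2d | proc_p
  }
  sk <- skeletonize_and_measure(max_project(total))
  structure(list(cell_id = cell_id, total = total, soma = soma,
                 process = process, soma_centroid = mask_centroid(soma2d),
                 skeleton = sk$skeleton, provenance = provenance),
            class = "cell_compartments")
}

#' Assign transcripts to compartments and aggregate counts
#'
#' Each molecule is labeled `soma` or `process` when it falls inside the
#' respective mask at its z-plane, otherwise `unassigned` (never an error).
#' Counts are aggregated per gene; soma + process = total by construction.
#'
#' @param transcripts `transcript_table` (rows for this cell).
#' @param cell `cell_compartments`.
#' @param genes optional gene panel fixing the count-vector order.
#' @return list: `transcripts` (labeled table) and `counts` (list of named
#'   integer vectors `soma`, `process`, `total`).
#' @export
assign_transcripts <- function(transcripts, cell, genes = NULL) {
  dm <- dim(cell$total)
  n <- nrow(transcripts)
  comp <- rep("unassigned", n)
  if (n) {
    ix <- px_index(transcripts$x, dm[1])
    iy <- px_index(transcripts$y, dm[2])
    iz <- pmin(pmax(as.integer(transcripts$z), 1L), dm[3])
    oob <- transcripts$x >= dm[1] | transcripts$y >= dm[2] |
      transcripts$z > dm[3]
    idx <- cbind(ix, iy, iz)
    in_soma <- cell$soma[idx] & !oob
    in_proc <- cell$process[idx] & !oob
    comp[in_soma] <- "soma"
    comp[in_proc & !in_soma] <- "process"
  }
  out <- transcripts
  out$compartment <- comp
  lv <- genes %||% sort(unique(out$gene))
  gf <- factor(out$gene, levels = lv)
  counts <- list(
    soma = as.integer(table(gf[comp == "soma"])),
    process = as.integer(table(gf[comp == "process"])))
  names(counts$soma) <- names(counts$process) <- lv
  counts$total <- counts$soma + counts$process
  list(transcripts = out, counts = counts)
}

#' Detect stain aggregates (e.g. AXL puncta) within microglial masks
#'
#' Per-plane Otsu segmentation of the target channel keeps components with
#' area strictly greater than `min_area - 1` pixels; kept aggregates are
#' intersected with the per-plane adaptive IBA1 mask restricted to the
#' maximum-projection cell outline. The host cell is scored ramified or
#' amoeboid by thresholding its solidity and fractal dimension at supplied
#' reference medians.
#'
#' @param channel 3D array `(x, y, z)` of the aggregate stain.
#' @param iba1 3D array `(x, y, z)` of the IBA1 stain.
#' @param min_area aggregates must have `area > min_area - 1` px (default
#'   keeps components of more than 50 pixels).
#' @param window_fine adaptive-threshold window for the per-plane IBA1 mask.
#' @param ref_solidity,ref_fd reference medians for the ramified/amoeboid
#'   call (values below the solidity threshold and above the fractal
#'   threshold score as ramified).
#' @return list: `aggregates` (data.frame plane, label, area, in_iba1),
#'   `host_class` (`"ramified"`/`"amoeboid"`/NA), `host_solidity`,
#'   `host_fd`.
#' @export
detect_aggregates <- function(channel, iba1, min_area = 51, window_fine = 50,
                              ref_solidity = NULL, ref_fd = NULL) {
  stopifnot(identical(dim(channel), dim(iba1)))
  nz <- dim(channel)[3]
  iba_mp <- max_project(iba1)
  outline <- adaptive_threshold(iba_mp, 200)
  rows <- list()
  for (p in seq_len(nz)) {
    img <- channel[, , p]
    if (max(img) == min(img)) next
    bin <- img > otsu_threshold(img / max(img)) * max(img)
    lab <- label_components(bin)
    if (max(lab) == 0L) next
    iba_fine <- adaptive_threshold(iba1[, , p], window_fine) & outline
    for (l in seq_len(max(lab))) {
      a <- sum(lab == l)
      if (a <= min_area - 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        plane = p, label = l, area = a,
        in_iba1 = any(lab == l & iba_fine))
    }
  }
  agg <- if (length(rows)) do.call(rbind, rows) else
    data.frame(plane = integer(0), label = integer(0), area = integer(0),
               in_iba1 = logical(0))
  host_sol <- host_fd <- NA_real_
  host_class <- NA_character_
  if (any(outline)) {
    hm <- hull_metrics(outline)
    host_sol <- min(1, sum(outline) / max(hm$area, 1e-9))
    host_fd <- fractal_dimension(outline)
    if (!is.null(ref_solidity) && !is.null(ref_fd))
      host_class <- if (host_fd > ref_fd && host_sol < ref_solidity)
        "ramified" else "amoeboid"
  }
  list(aggregates = agg, host_class = host_class,
       host_solidity = host_sol, host_fd = host_fd)
}
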