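# Synthetic microglia generator. Plants known ground truth -- shape class,
# per-gene compartment enrichment (log-odds), within-compartment Thomas-
# process clustering, shared-parent co-localized gene pairs, astrocyte
# contamination and an age effect -- so every downstream stage can be tested
# against a manifest without any external data.

#' Shape parameters for a synthetic microglial cell
#'
#' @param soma_radius soma disk radius, px (>= 2).
#' @param n_primary_branches number of primary processes grown from the soma
#'   rim (0 = amoeboid disk).
#' @param branch_length_mean mean primary branch length, px.
#' @param branch_tortuosity >= 1; 1 gives straight branches, larger values
#'   add wrapped-Gaussian heading jitter per step.
#' @param branch_width process thickness, px (dilation diameter).
#' @param n_planes number of z-planes in the stack.
#' @param image_size side of the square frame, px.
#' @return `shape_params` list.
#' @export
shape_params <- function(soma_radius = 8, n_primary_branches = 4,
                         branch_length_mean = 30, branch_tortuosity = 1.15,
                         branch_width = 3, n_planes = 6, image_size = 128) {
  stopifnot(soma_radius >= 2, n_primary_branches >= 0, branch_tortuosity >= 1,
            branch_width >= 1, n_planes >= 1,
            image_size >= 2 * (soma_radius + branch_length_mean) * 0.9)
  structure(as.list(environment()), class = "shape_params")
}

#' Per-gene generative model
#'
#' @param gene gene name.
#' @param mean_count expected molecules per cell (Poisson).
#' @param process_logodds log-odds that a molecule is placed in the process
#'   compartment rather than the soma; 0 = neutral, +/-Inf saturate.
#' @param cluster_sigma Thomas-process offspring dispersion, microns
#'   (0 = complete spatial randomness within the compartment).
#' @param cluster_children mean molecules per cluster parent (>= 1 when
#'   `cluster_sigma > 0`).
#' @param coloc_partner optional name of a gene sharing cluster parents
#'   (planted co-localization).
#' @return `gene_model` list.
#' @export
gene_model <- function(gene, mean_count = 30, process_logodds = 0,
                       cluster_sigma = 0, cluster_children = 1,
                       coloc_partner = NULL) {
  stopifnot(nzchar(gene), mean_count >= 0,
            cluster_sigma == 0 || cluster_children >= 1)
  structure(list(gene = gene, mean_count = mean_count,
                 process_logodds = process_logodds,
                 cluster_sigma = cluster_sigma,
                 cluster_children = cluster_children,
                 coloc_partner = coloc_partner), class = "gene_model")
}

#' Age effect applied to a gene panel
#'
#' Emulates the reduction of RNA compartmentalization with age: enrichment
#' log-odds are attenuated and only a fraction of planted co-localized pairs
#' is retained. The default retained fraction of 0.25 mirrors the roughly
#' four-fold drop in significant pairs between young and aged networks.
#'
#' @param enrichment_attenuation multiplier in `[0, 1]` applied to
#'   `|process_logodds|`.
#' @param coloc_pair_fraction fraction of planted partner links retained,
#'   `[0, 1]`; exactly `ceiling(fraction * P)` of `P` pairs survive.
#' @return `age_effect` list.
#' @export
age_effect <- function(enrichment_attenuation = 0.5,
                       coloc_pair_fraction = 0.25) {
  stopifnot(enrichment_attenuation >= 0, enrichment_attenuation <= 1,
            coloc_pair_fraction >= 0, coloc_pair_fraction <= 1)
  structure(list(enrichment_attenuation = enrichment_attenuation,
                 coloc_pair_fraction = coloc_pair_fraction),
            class = "age_effect")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

disk_mask <- function(size, cx, cy, r) {
  x <- matrix(seq_len(size) - 0.5, size, size)
  y <- matrix(seq_len(size) - 0.5, size, size, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

dilate_mask <- function(mask, width) {
  b <- max(1L, 2L * floor(width / 2) + 1L)
  if (b == 1L) return(mask)
  out <- EBImage::dilate(EBImage::Image(mask * 1), EBImage::makeBrush(b, "disc"))
  matrix(as.numeric(EBImage::imageData(out)) > 0.5, nrow(mask), ncol(mask))
}

erode_mask <- function(mask, width = 3L) {
  out <- EBImage::erode(EBImage::Image(mask * 1), EBImage::makeBrush(width, "disc"))
  matrix(as.numeric(EBImage::imageData(out)) > 0.5, nrow(mask), ncol(mask))
}

grow_branch <- function(start, theta0, len, jitter_sd, size) {
  pos <- matrix(NA_real_, len + 1L, 2L)
  pos[1L, ] <- start
  theta <- theta0
  clipped <- FALSE
  for (s in seq_len(len)) {
    theta <- theta + rnorm(1L, 0, jitter_sd)
    nxt <- pos[s, ] + c(cos(theta), sin(theta))
    if (any(nxt < 1) || any(nxt > size - 1)) { clipped <- TRUE; break }
    pos[s + 1L, ] <- nxt
  }
  list(path = pos[!is.na(pos[, 1]), , drop = FALSE], clipped = clipped)
}

#' Simulate one microglial cell across z-planes
#'
#' The total mask is the union of a soma disk and the dilation of a random
#' branching skeleton grown from the soma rim (biased random walk with
#' wrapped-Gaussian heading jitter; one optional level of secondary branching
#' with probability 0.3 at branch midpoints). The same 2D shape is replicated
#' across planes with per-plane boundary erosion noise on the processes; the
#' soma is held fixed so that per-plane masks always partition the total.
#'
#' @param shape [shape_params()].
#' @param seed integer seed; identical seeds give identical cells.
#' @param cell_id identifier stored on the result.
#' @return a `cell_compartments` object: logical `(x, y, z)` arrays `total`,
#'   `soma`, `process`; `soma_centroid` (x, y in px); 2D `skeleton` mask;
#'   `shape_class` attribute.
#' @export
simulate_cell <- function(shape, seed, cell_id = "cell_1") {
  stopifnot(inherits(shape, "shape_params"))
  set.seed(seed)
  size <- shape$image_size
  ctr <- c(size / 2, size / 2)
  soma2d <- disk_mask(size, ctr[1], ctr[2], shape$soma_radius)
  skel <- matrix(FALSE, size, size)
  jitter_sd <- 0.35 * (shape$branch_tortuosity - 1) + 0.02
  clipped_any <- FALSE
  if (shape$n_primary_branches > 0) {
    angles <- runif(shape$n_primary_branches, 0, 2 * pi)
    for (a in angles) {
      start <- ctr + (shape$soma_radius - 0.5) * c(cos(a), sin(a))
      len <- max(4L, round(rnorm(1L, shape$branch_length_mean,
                                 0.2 * shape$branch_length_mean)))
      br <- grow_branch(start, a, len, jitter_sd, size)
      clipped_any <- clipped_any || br$clipped
      ij <- unique(cbind(px_index(br$path[, 1], size), px_index(br$path[, 2], size)))
      skel[ij] <- TRUE
      if (runif(1L) < 0.3 && nrow(br$path) > 6L) {
        mid <- br$path[ceiling(nrow(br$path) / 2), ]
        theta2 <- a + sample(c(-1, 1), 1L) * runif(1L, pi / 6, pi / 3)
        br2 <- grow_branch(mid, theta2, max(3L, len %/% 2L), jitter_sd, size)
        clipped_any <- clipped_any || br2$clipped
        ij2 <- unique(cbind(px_index(br2$path[, 1], size), px_index(br2$path[, 2], size)))
        skel[ij2] <- TRUE
      }
    }
  }
  if (clipped_any) warning("branch clipped at image bounds for ", cell_id)
  proc2d <- dilate_mask(skel, shape$branch_width) & !soma2d
  total2d <- soma2d | proc2d
  nz <- shape$n_planes
  total <- soma <- process <- array(FALSE, dim = c(size, size, nz))
  boundary <- proc2d & !erode_mask(proc2d, 3L)
  bidx <- which(boundary)
  for (p in seq_len(nz)) {
    proc_p <- proc2d
    if (length(bidx)) {
      drop <- bidx[runif(length(bidx)) < 0.2]
      proc_p[drop] <- FALSE
    }
    soma[, , p] <- soma2d
    process[, , p] <- proc_p
    total[, , p] <- soma2d | proc_p
  }
  structure(list(cell_id = cell_id, total = total, soma = soma,
                 process = process,
                 soma_centroid = c(x = ctr[1], y = ctr[2]),
                 skeleton = skel, provenance = NULL,
                 shape_class = if (shape$n_primary_branches >= 3) "ramified"
                               else "amoeboid"),
            class = "cell_compartments")
}

# draw n molecules in one compartment of one cell; Thomas clustering when
# sigma > 0; optional shared parent pool for planted co-localization
place_molecules <- function(mask3d, n, sigma_um, children, pixel_size,
                            parents = NULL) {
  if (n == 0L) return(list(pts = data.frame(x = numeric(0), y = numeric(0),
                                            z = integer(0)), parents = parents))
  if (sigma_um <= 0) {
    return(list(pts = sample_in_mask3d(mask3d, n), parents = parents))
  }
  sigma_px <- sigma_um / pixel_size
  if (is.null(parents)) {
    np <- max(1L, ceiling(n / children))
    parents <- sample_in_mask3d(mask3d, np)
  }
  pick <- sample.int(nrow(parents), n, replace = TRUE)
  dmv <- dim(mask3d)
  pts <- data.frame(x = numeric(n), y = numeric(n), z = integer(n))
  for (k in seq_len(n)) {
    par <- parents[pick[k], ]
    ok <- FALSE
    for (try in seq_len(200L)) {
      cand <- c(par$x + rnorm(1L, 0, sigma_px), par$y + rnorm(1L, 0, sigma_px))
      ix <- px_index(cand[1], dmv[1]); iy <- px_index(cand[2], dmv[2])
      if (cand[1] >= 0 && cand[2] >= 0 && cand[1] < dmv[1] && cand[2] < dmv[2] &&
          mask3d[ix, iy, par$z]) { ok <- TRUE; break }
    }
    if (!ok) cand <- c(par$x, par$y)
    pts$x[k] <- cand[1]; pts$y[k] <- cand[2]; pts$z[k] <- par$z
  }
  list(pts = pts, parents = parents)
}

#' Simulate decoded transcripts for one cell
#'
#' Per gene the molecule count is Poisson(`mean_count`); each molecule picks
#' the process compartment with probability `sigmoid(process_logodds)` and is
#' placed uniformly in that compartment's voxels, or as a Thomas process
#' when `cluster_sigma > 0` (parents uniform in the compartment, offspring
#' isotropic Gaussian in-plane, redrawn until inside the mask). Genes with a
#' `coloc_partner` share the partner's parent points compartment-wise.
#'
#' @param cell `cell_compartments`.
#' @param genes list of [gene_model()].
#' @param seed integer seed.
#' @return `transcript_table` with columns `gene, x, y, z, cell_id` and the
#'   generator's `true_compartment`.
#' @export
simulate_transcripts <- function(cell, genes, seed) {
  set.seed(seed)
  shared_parents <- list()   # key: paste(pair_key, compartment)
  rows <- list()
  gene_names <- vapply(genes, `[[`, "", "gene")
  for (g in genes) {
    n <- rpois(1L, g$mean_count)
    if (n == 0L) next
    p_proc <- sigmoid(g$process_logodds)
    in_proc <- runif(n) < p_proc
    if (any(in_proc) && !any(cell$process))
      stop("gene ", g$gene, " requests process placement but process mask is empty")
    pair_key <- if (!is.null(g$coloc_partner))
      paste(sort(c(g$gene, g$coloc_partner)), collapse = "|") else NULL
    for (comp in c("soma", "process")) {
      idx <- if (comp == "process") which(in_proc) else which(!in_proc)
      if (!length(idx)) next
      key <- if (!is.null(pair_key)) paste(pair_key, comp) else NULL
      par0 <- if (!is.null(key)) shared_parents[[key]] else NULL
      res <- place_molecules(cell[[comp]], length(idx), g$cluster_sigma,
                             g$cluster_children, attr(cell, "pixel_size") %||% 0.5,
                             parents = par0)
      if (!is.null(key) && g$cluster_sigma > 0)
        shared_parents[[key]] <- res$parents
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g$gene, x = res$pts$x, y = res$pts$y, z = res$pts$z,
        cell_id = cell$cell_id, true_compartment = comp,
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), x = numeric(0), y = numeric(0),
               z = integer(0), cell_id = character(0),
               true_compartment = character(0), stringsAsFactors = FALSE)
  as_transcript_table(df)
}

#' A default synthetic gene panel
#'
#' Soma-enriched, process-enriched and neutral genes at a stated log-odds,
#' plus planted co-localized pairs (shared Thomas parents).
#'
#' @param n_soma,n_process,n_neutral panel composition.
#' @param logodds absolute compartment log-odds for enriched genes; a
#'   vector is recycled across the enriched genes of each compartment
#'   (graded enrichment strengths).
#' @param mean_count expected molecules per gene per cell.
#' @param n_coloc_pairs number of planted co-localized gene pairs (taken from
#'   the neutral set, clustered with `cluster_sigma`).
#' @param cluster_sigma Thomas dispersion for planted pairs, microns.
#' @param cluster_children mean offspring per parent for planted pairs.
#' @return list of [gene_model()].
#' @export
default_gene_panel <- function(n_soma = 6, n_process = 6, n_neutral = 12,
                               logodds = 2.5, mean_count = 30,
                               n_coloc_pairs = 2, cluster_sigma = 1,
                               cluster_children = 5) {
  stopifnot(n_neutral >= 2 * n_coloc_pairs)
  lo_s <- rep_len(logodds, max(n_soma, 1L))
  lo_p <- rep_len(logodds, max(n_process, 1L))
  panel <- list()
  for (i in seq_len(n_soma))
    panel <- c(panel, list(gene_model(sprintf("Soma%02d", i), mean_count, -lo_s[i])))
  for (i in seq_len(n_process))
    panel <- c(panel, list(gene_model(sprintf("Proc%02d", i), mean_count, lo_p[i])))
  k <- 0L
  for (i in seq_len(n_neutral)) {
    nm <- sprintf("Neut%02d", i)
    if (k < n_coloc_pairs * 2L) {
      k <- k + 1L
      partner <- if (k %% 2L == 0L) sprintf("Neut%02d", i - 1L)
                 else sprintf("Neut%02d", i + 1L)
      panel <- c(panel, list(gene_model(nm, mean_count, 0, cluster_sigma,
                                        cluster_children, partner)))
    } else {
      panel <- c(panel, list(gene_model(nm, mean_count, 0)))
    }
  }
  panel
}

apply_age_effect <- function(genes, age) {
  if (is.null(age)) return(genes)
  stopifnot(inherits(age, "age_effect"))
  pairs <- planted_pairs(genes)
  keep_n <- ceiling(age$coloc_pair_fraction * nrow(pairs))
  keep <- if (keep_n > 0) pairs[seq_len(keep_n), , drop = FALSE] else pairs[0, ]
  out <- lapply(genes, function(g) {
    g$process_logodds <- g$process_logodds * age$enrichment_attenuation
    if (!is.null(g$coloc_partner)) {
      key <- paste(sort(c(g$gene, g$coloc_partner)), collapse = "|")
      if (!(key %in% paste(keep$gene_a, keep$gene_b, sep = "|")))
        g$coloc_partner <- NULL
    }
    g
  })
  out
}

planted_pairs <- function(genes) {
  keys <- character(0)
  for (g in genes) if (!is.null(g$coloc_partner))
    keys <- c(keys, paste(sort(c(g$gene, g$coloc_partner)), collapse = "|"))
  keys <- unique(keys)
  if (!length(keys)) return(data.frame(gene_a = character(0), gene_b = character(0)))
  sp <- strsplit(keys, "|", fixed = TRUE)
  data.frame(gene_a = vapply(sp, `[`, "", 1L), gene_b = vapply(sp, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

cell_contour <- function(cell) {
  mp <- max_project(cell$total)
  oc <- EBImage::ocontour(EBImage::Image(mp * 1))[[1]]
  ring <- rbind(oc, oc[1, , drop = FALSE])
  colnames(ring) <- NULL
  ring
}

#' Simulate a full dataset with ground truth
#'
#' Generates `n_cells` microglia (a stated fraction ramified, the rest
#' amoeboid), decoded transcripts per cell, total-mask boundary polygons,
#' per-compartment count matrices and a truth manifest. An `age_effect`
#' is applied to the gene models before simulation ("aged" condition).
#'
#' @param cfg [run_config()].
#' @param n_cells number of cells (>= 1).
#' @param gene_models list of [gene_model()]; default [default_gene_panel()].
#' @param age optional [age_effect()] (NULL = young).
#' @param seed integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param ramified_fraction fraction of cells given ramified shapes.
#' @param shape_ramified,shape_amoeboid [shape_params()] per class.
#' @param astro optional astrocyte contamination:
#'   `list(fraction =, genes =, mean_count =)` places a GFAP blob over part
#'   of the processes with its own genes inside it.
#' @param out_dir optional directory; when given, writes transcripts.csv,
#'   boundaries.geojson, counts_{total,soma,process}.mtx, per-cell stack
#'   TIFFs and truth.json.
#' @return list: `cells` (list of `cell_compartments`), `transcripts`
#'   (single `transcript_table` with `cell_id`), `counts` (list of three
#'   matrices), `boundaries` (`boundary_set`), `truth` (manifest list).
#' @export
simulate_dataset <- function(cfg, n_cells, gene_models = default_gene_panel(),
                             age = NULL, seed = cfg$seed,
                             ramified_fraction = 0.5,
                             shape_ramified = shape_params(n_primary_branches = 5,
                                                           branch_length_mean = 30),
                             shape_amoeboid = shape_params(n_primary_branches = 1,
                                                           branch_length_mean = 8),
                             astro = NULL, out_dir = NULL) {
  stopifnot(n_cells >= 1)
  genes <- apply_age_effect(gene_models, age)
  n_ram <- round(ramified_fraction * n_cells)
  classes <- rep(c("ramified", "amoeboid"), c(n_ram, n_cells - n_ram))
  cells <- vector("list", n_cells)
  tx <- vector("list", n_cells)
  gene_names <- vapply(genes, `[[`, "", "gene")
  counts_soma <- counts_proc <- matrix(0L, n_cells, length(gene_names),
                                       dimnames = list(NULL, gene_names))
  ids <- sprintf("cell_%03d", seq_len(n_cells))
  astro_ids <- character(0)
  if (!is.null(astro) && astro$fraction > 0) {
    set.seed(derive_seed(seed, "astro_pick"))
    astro_ids <- ids[runif(n_cells) < astro$fraction]
  }
  for (i in seq_len(n_cells)) {
    sh <- if (classes[i] == "ramified") shape_ramified else shape_amoeboid
    cell <- simulate_cell(sh, derive_seed(seed, paste0("cell/", i)), ids[i])
    attr(cell, "pixel_size") <- cfg$pixel_size
    if (ids[i] %in% astro_ids)
      cell <- add_astro_blob(cell, derive_seed(seed, paste0("astro/", i)))
    cells[[i]] <- cell
    ti <- simulate_transcripts(cell, genes, derive_seed(seed, paste0("tx/", i)))
    if (ids[i] %in% astro_ids && length(astro$genes)) {
      ti <- rbind_transcripts(ti, simulate_astro_transcripts(
        cell, astro, derive_seed(seed, paste0("astrotx/", i))))
    }
    tx[[i]] <- ti
    tab <- table(factor(ti$gene, levels = gene_names),
                 factor(ti$true_compartment, levels = c("soma", "process")))
    counts_soma[i, ] <- tab[, "soma"]
    counts_proc[i, ] <- tab[, "process"]
  }
  rownames(counts_soma) <- rownames(counts_proc) <- ids
  transcripts <- do.call(rbind_transcripts, tx)
  polys <- lapply(cells, cell_contour)
  names(polys) <- ids
  boundaries <- structure(list(polygons = polys,
                               annotation = setNames(rep("microglia", n_cells), ids)),
                          class = "boundary_set")
  truth <- list(
    seed = seed,
    shape_class = setNames(classes, ids),
    gene_compartment = setNames(
      ifelse(vapply(genes, `[[`, 0, "process_logodds") > 0, "process",
             ifelse(vapply(genes, `[[`, 0, "process_logodds") < 0, "soma",
                    "neutral")), gene_names),
    planted_pairs = planted_pairs(genes),
    age = if (is.null(age)) NULL else unclass(age),
    astro_cells = astro_ids,
    n_cells = n_cells, ramified_fraction = ramified_fraction)
  counts_total <- counts_soma + counts_proc
  out <- list(cells = cells, transcripts = transcripts,
              counts = list(total = counts_total, soma = counts_soma,
                            process = counts_proc),
              boundaries = boundaries, truth = truth, config = cfg)
  if (!is.null(out_dir)) write_dataset(out, out_dir)
  out
}

rbind_transcripts <- function(...) {
  parts <- list(...)
  df <- do.call(rbind, lapply(parts, as.data.frame))
  structure(df, rejected = data.frame(line = integer(0), reason = character(0)),
            class = c("transcript_table", "data.frame"))
}

add_astro_blob <- function(cell, seed) {
  set.seed(seed)
  size <- dim(cell$total)[1]
  pidx <- which(max_project(cell$process), arr.ind = TRUE)
  ctr <- if (nrow(pidx)) pidx[sample.int(nrow(pidx), 1L), ] else c(size / 2, size / 2)
  blob <- disk_mask(size, ctr[1], ctr[2], max(6, size / 12))
  attr(cell, "astro_mask") <- blob
  cell
}

simulate_astro_transcripts <- function(cell, astro, seed) {
  set.seed(seed)
  blob <- attr(cell, "astro_mask")
  nz <- dim(cell$total)[3]
  blob3d <- array(rep(blob, nz), dim = c(dim(blob), nz))
  rows <- list()
  for (g in astro$genes) {
    n <- rpois(1L, astro$mean_count)
    if (n == 0L) next
    pts <- sample_in_mask3d(blob3d, n)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = g, x = pts$x, y = pts$y, z = pts$z, cell_id = cell$cell_id,
      true_compartment = "astro", stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(0), x = numeric(0), y = numeric(0),
               z = integer(0), cell_id = character(0),
               true_compartment = character(0))
  as_transcript_table(df)
}

#' Render a synthetic cell as a multi-channel image stack
#'
#' IBA1 follows the total mask (soma slightly brighter), DAPI the soma and
#' GFAP the planted astrocyte blob (if any); a touch of deterministic-seeded
#' Gaussian noise is added per plane.
#'
#' @param cell `cell_compartments` from [simulate_cell()].
#' @param seed noise seed.
#' @return array `(channels = IBA1, DAPI, GFAP; z; y; x)`, values in `[0, 1]`.
#' @export
render_cell_stack <- function(cell, seed = 1L) {
  set.seed(seed)
  dm <- dim(cell$total)
  arr <- array(0, dim = c(3L, dm[3], dm[2], dm[1]),
               dimnames = list(c("IBA1", "DAPI", "GFAP"), NULL, NULL, NULL))
  astro <- attr(cell, "astro_mask")
  for (p in seq_len(dm[3])) {
    iba <- 0.55 * cell$total[, , p] + 0.25 * cell$soma[, , p]
    dapi <- 0.8 * cell$soma[, , p]
    gfap <- if (!is.null(astro)) 0.8 * astro else matrix(0, dm[1], dm[2])
    for (ch in 1:3) {
      img <- switch(ch, iba, dapi, gfap)
      img <- pmin(1, pmax(0, img + matrix(rnorm(dm[1] * dm[2], 0, 0.02),
                                          dm[1], dm[2])))
      arr[ch, p, , ] <- t(img)   # (y, x) page layout
    }
  }
  arr
}

write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_transcript_table(ds$transcripts, file.path(out_dir, "transcripts.csv"))
  write_boundaries(ds$boundaries, file.path(out_dir, "boundaries.geojson"))
  for (layer in names(ds$counts))
    write_expression_matrix(ds$counts[[layer]],
                            file.path(out_dir, sprintf("counts_%s.mtx", layer)))
  stack_dir <- file.path(out_dir, "stacks")
  dir.create(stack_dir, showWarnings = FALSE)
  for (cell in ds$cells)
    write_stack(render_cell_stack(cell, derive_seed(ds$truth$seed,
                                                    paste0("render/", cell$cell_id))),
                file.path(stack_dir, paste0(cell$cell_id, ".tif")))
  jsonlite::write_json(ds$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
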