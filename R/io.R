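# Readers/writers for the external formats the pipeline touches. All
# downstream operations consume the in-memory types built here and never
# touch files themselves.

#' Read a decoded transcript table
#'
#' Transcript tables are CSV (or Parquet) files of decoded molecules with one
#' row per molecule: gene label, x/y position in pixels and z as a 1-based
#' plane index, plus optional `cell_id` and `compartment` columns. Rows with
#' an empty gene, a negative coordinate or a non-finite value are rejected
#' and reported (with line numbers) in the `rejected` attribute.
#'
#' @param path CSV or Parquet file with columns `gene, x, y, z[, cell_id]`.
#' @param columns optional named character vector remapping header names,
#'   e.g. `c(gene = "gene_symbol")`.
#' @return a `data.frame` (class `transcript_table`) with attribute
#'   `rejected`: a data.frame of `line, reason` for discarded rows.
#' @export
read_transcript_table <- function(path, columns = NULL) {
  stopifnot(file.exists(path))
  df <- if (grepl("\\.parquet$", path)) {
    if (!requireNamespace("arrow", quietly = TRUE))
      stop("arrow is required to read Parquet transcript tables")
    as.data.frame(arrow::read_parquet(path))
  } else {
    as.data.frame(data.table::fread(path))
  }
  for (std in names(columns)) {
    names(df)[names(df) == columns[[std]]] <- std
  }
  need <- c("gene", "x", "y", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("transcript table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  as_transcript_table(df)
}

#' Construct a validated transcript table from a data frame
#'
#' @param df data frame with columns `gene, x, y, z` (and optionally
#'   `cell_id`, `compartment`).
#' @return `transcript_table` with invalid rows dropped and recorded in the
#'   `rejected` attribute.
#' @export
as_transcript_table <- function(df) {
  stopifnot(all(c("gene", "x", "y", "z") %in% names(df)))
  df$gene <- as.character(df$gene)
  bad_gene <- is.na(df$gene) | !nzchar(df$gene)
  bad_xy <- !is.finite(df$x) | !is.finite(df$y) | df$x < 0 | df$y < 0
  bad_z <- !is.finite(df$z) | df$z < 1 | df$z != round(df$z)
  bad <- bad_gene | bad_xy | bad_z
  reason <- ifelse(bad_gene, "empty gene",
                   ifelse(bad_xy, "negative or non-finite coordinate",
                          "invalid z plane"))
  rejected <- data.frame(line = which(bad), reason = reason[bad],
                         stringsAsFactors = FALSE)
  out <- df[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out$z <- as.integer(out$z)
  if (is.null(out$compartment))
    out$compartment <- rep(NA_character_, nrow(out))
  if (nrow(rejected))
    message(nrow(rejected), " transcript row(s) rejected")
  structure(out, rejected = rejected,
            class = c("transcript_table", "data.frame"))
}

#' Write a transcript table to CSV (round-trips with [read_transcript_table()])
#' @param tt transcript table.
#' @param path output CSV path.
#' @export
write_transcript_table <- function(tt, path) {
  keep <- intersect(c("gene", "x", "y", "z", "cell_id", "compartment",
                      "true_compartment"), names(tt))
  data.table::fwrite(as.data.frame(tt)[keep], path)
  invisible(path)
}

# ---- boundaries (GeoJSON polygons) ----------------------------------------

ring_is_simple <- function(ring) {
  # ring: closed n x 2 matrix (last row == first). Check no two
  # non-adjacent edges properly intersect.
  n <- nrow(ring) - 1L
  if (n < 3L) return(FALSE)
  seg <- function(i) rbind(ring[i, ], ring[i + 1L, ])
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  inter <- function(p1, p2, q1, q2) {
    d1 <- cross(q1, q2, p1); d2 <- cross(q1, q2, p2)
    d3 <- cross(p1, p2, q1); d4 <- cross(p1, p2, q2)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i + 1L) next
    if (i == 1L && j == n) next        # first and last edge are adjacent
    si <- seg(i); sj <- seg(j)
    if (inter(si[1, ], si[2, ], sj[1, ], sj[2, ])) return(FALSE)
  }
  TRUE
}

#' Read transcriptomically derived cell boundaries from GeoJSON
#'
#' Expects a FeatureCollection of Polygon features, each with a `cell_id`
#' property (and optionally a `cell_type` annotation). Rings must be closed
#' and simple; duplicate cell ids and non-polygon geometries are errors.
#'
#' @param path GeoJSON file.
#' @return a `boundary_set`: list with `polygons` (named list of closed
#'   `n x 2` coordinate matrices, pixel units) and `annotation` (named
#'   character or NULL).
#' @export
read_boundaries <- function(path) {
  stopifnot(file.exists(path))
  gj <- jsonlite::read_json(path)
  if (is.null(gj$type) || gj$type != "FeatureCollection")
    stop("expected a GeoJSON FeatureCollection")
  polys <- list(); ann <- character(0)
  for (f in gj$features) {
    if (is.null(f$geometry$type) || f$geometry$type != "Polygon")
      stop("non-polygon geometry in boundary file: ",
           f$geometry$type %||% "missing")
    cid <- as.character(f$properties$cell_id)
    if (!length(cid) || !nzchar(cid)) stop("feature without cell_id")
    if (cid %in% names(polys)) stop("duplicate cell_id: ", cid)
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    if (!isTRUE(all.equal(ring[1, ], ring[nrow(ring), ])))
      stop("ring not closed for cell_id ", cid)
    if (!ring_is_simple(ring))
      stop("self-intersecting ring for cell_id ", cid)
    polys[[cid]] <- ring
    ann[cid] <- if (!is.null(f$properties$cell_type))
      as.character(f$properties$cell_type) else NA_character_
  }
  structure(list(polygons = polys,
                 annotation = if (all(is.na(ann))) NULL else ann),
            class = "boundary_set")
}

#' Write a boundary set to GeoJSON
#' @param bs `boundary_set`.
#' @param path output path.
#' @export
write_boundaries <- function(bs, path) {
  feats <- lapply(names(bs$polygons), function(cid) {
    ring <- bs$polygons[[cid]]
    props <- list(cell_id = cid)
    if (!is.null(bs$annotation) && !is.na(bs$annotation[cid]))
      props$cell_type <- unname(bs$annotation[cid])
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) as.list(ring[i, ])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Polygon area (shoelace), px^2
#' @param ring closed `n x 2` matrix.
#' @export
polygon_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]; n <- nrow(ring)
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

# ---- image stacks (multi-page TIFF) ---------------------------------------

#' Read a multi-channel image stack
#'
#' Multi-page TIFF with one page per (channel, z) pair. The page layout is
#' declared by the caller: `order = "cz"` means channel varies fastest
#' (c1z1, c2z1, ...), `"zc"` means z varies fastest.
#'
#' @param path TIFF file.
#' @param channels character vector of channel names (e.g. `c("IBA1",
#'   "DAPI", "GFAP")`).
#' @param order `"cz"` or `"zc"` page layout.
#' @return numeric array of shape `(channels, z, y, x)` with channel
#'   dimnames.
#' @export
read_stack <- function(path, channels, order = c("cz", "zc")) {
  order <- match.arg(order)
  stopifnot(file.exists(path), length(channels) >= 1)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- length(channels)
  if (length(pages) %% nc != 0)
    stop("page count ", length(pages), " not divisible by channel count ", nc)
  nz <- length(pages) %/% nc
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  arr <- array(0, dim = c(nc, nz, h, w),
               dimnames = list(channels, NULL, NULL, NULL))
  for (p in seq_along(pages)) {
    if (order == "cz") {
      ci <- (p - 1L) %% nc + 1L; zi <- (p - 1L) %/% nc + 1L
    } else {
      zi <- (p - 1L) %% nz + 1L; ci <- (p - 1L) %/% nz + 1L
    }
    arr[ci, zi, , ] <- pages[[p]]
  }
  arr
}

#' Write a multi-channel stack as multi-page TIFF (inverse of [read_stack()])
#' @param arr array `(channels, z, y, x)`, values in `[0, 1]`.
#' @param path output path.
#' @param order page layout, as in [read_stack()].
#' @export
write_stack <- function(arr, path, order = c("cz", "zc")) {
  order <- match.arg(order)
  stopifnot(length(dim(arr)) == 4)
  nc <- dim(arr)[1]; nz <- dim(arr)[2]
  pages <- vector("list", nc * nz)
  for (ci in seq_len(nc)) for (zi in seq_len(nz)) {
    p <- if (order == "cz") (zi - 1L) * nc + ci else (ci - 1L) * nz + zi
    pages[[p]] <- arr[ci, zi, , ]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

# convert one channel of a (c, z, y, x) stack into the internal (x, y, z)
# array convention
stack_channel_xyz <- function(arr, channel) {
  sub <- arr[channel, , , , drop = FALSE]   # (1, z, y, x)
  nz <- dim(sub)[2]; h <- dim(sub)[3]; w <- dim(sub)[4]
  out <- array(0, dim = c(w, h, nz))
  for (zi in seq_len(nz)) out[, , zi] <- t(sub[1, zi, , ])
  out
}

# ---- expression matrices ---------------------------------------------------

#' Read a cell-by-gene count matrix
#'
#' Accepts MatrixMarket (`.mtx`, with `<stem>.genes.txt` / `<stem>.cells.txt`
#' sidecars) or dense CSV (first column = cell id, header = genes).
#'
#' @param path `.mtx` or `.csv` file.
#' @param layer layer tag: `"total"`, `"soma"`, `"process"` or `"lognorm"`.
#' @return numeric matrix, cells in rows, genes in columns, with attribute
#'   `layer`.
#' @export
read_expression_matrix <- function(path, layer = "total") {
  stopifnot(file.exists(path))
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- readLines(paste0(stem, ".cells.txt"))
    colnames(m) <- readLines(paste0(stem, ".genes.txt"))
  } else {
    df <- read.csv(path, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- as.character(df[[1]])
  }
  if (layer != "lognorm" && any(m != round(m) | m < 0))
    stop("count layer must hold non-negative integers")
  attr(m, "layer") <- layer
  m
}

#' Write a cell-by-gene matrix (MTX with sidecars, or dense CSV)
#' @param m matrix with cells in rows.
#' @param path output path ending in `.mtx` or `.csv`.
#' @export
write_expression_matrix <- function(m, path) {
  if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(Matrix::Matrix(unclass(m), sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(m), paste0(stem, ".cells.txt"))
    writeLines(colnames(m), paste0(stem, ".genes.txt"))
  } else {
    df <- data.frame(cell_id = rownames(m), as.data.frame(unclass(m),
                                                          check.names = FALSE))
    data.table::fwrite(df, path)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
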