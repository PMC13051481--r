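#' Run configuration
#'
#' A single object holding the geometry and statistical settings shared by
#' every stage of the pipeline. All physical distances are computed in one
#' place as `sqrt((dx * pixel_size)^2 + (dy * pixel_size)^2 +
#' (dz * z_spacing)^2)`, where `dx`, `dy` are pixel offsets and `dz` is a
#' z-plane index offset; transcript tables keep `z` as a plane index.
#'
#' @param seed integer seed for the run; every stochastic stage derives its
#'   own stream from this seed plus a stage tag (see [derive_seed()]).
#' @param pixel_size microns per pixel in x/y (> 0).
#' @param z_spacing microns between adjacent z-planes (> 0); image stacks are
#'   acquired over 6-7 planes spaced 1.5 um apart.
#' @param qc_min_transcripts minimum total transcripts per cell kept by QC.
#' @param qc_min_genes minimum unique genes per cell kept by QC.
#' @param coloc_percentile percentile (percent) of pooled soma pairwise
#'   distances used as the co-localization radius.
#' @param n_null number of Monte-Carlo randomizations for envelope and
#'   co-localization nulls.
#' @param alpha significance level for adjusted p-values.
#' @return an object of class `run_config`.
#' @export
run_config <- function(seed = 1L, pixel_size = 0.5, z_spacing = 1.5,
                       qc_min_transcripts = 20L, qc_min_genes = 5L,
                       coloc_percentile = 5, n_null = 1000L, alpha = 0.05) {
  stopifnot(length(seed) == 1, is.finite(seed),
            pixel_size > 0, z_spacing > 0,
            qc_min_transcripts > 0, qc_min_genes > 0,
            coloc_percentile > 0, n_null > 0, alpha > 0)
  structure(list(seed = as.integer(seed), pixel_size = pixel_size,
                 z_spacing = z_spacing,
                 qc_min_transcripts = as.integer(qc_min_transcripts),
                 qc_min_genes = as.integer(qc_min_genes),
                 coloc_percentile = coloc_percentile,
                 n_null = as.integer(n_null), alpha = alpha),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Keys absent from the file fall back to the [run_config()] defaults.
#'
#' @param path JSON file of key-value settings.
#' @return a `run_config`.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, vals)
}

#' Derive a per-stage random seed
#'
#' Mixes the run seed with a stage tag so that independent stages use
#' independent, reproducible streams. The result is always a valid 32-bit
#' integer seed.
#'
#' @param seed integer run seed.
#' @param tag character stage tag (e.g. `"simulate_cell/7"`).
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% 2147483629
  as.integer((as.numeric(seed) + h) %% 2147483629)
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config: seed", x$seed,
      sprintf("| pixel %g um | z %g um | QC >=%d tx, >=%d genes | n_null %d | alpha %g\n",
              x$pixel_size, x$z_spacing, x$qc_min_transcripts,
              x$qc_min_genes, x$n_null, x$alpha))
  invisible(x)
}
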