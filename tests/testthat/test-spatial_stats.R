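cfg <- run_config(seed = 3)

test_that("the 3D Ripley K estimator matches its closed form", {
  pts <- rbind(c(0, 0, 0), c(3, 0, 0))
  V <- 1000
  k <- ripley_k3d(pts, V, radii = c(1, 2, 2.9, 3, 4))
  expect_equal(k, c(0, 0, 0, V, V))
  expect_false(is.unsorted(k))
  expect_error(ripley_k3d(pts[1, , drop = FALSE], V, 1:3), "nrow")
})

test_that("K under CSR in a cube tracks the Poisson expectation", {
  side <- 40; V <- side^3   # radii well below the side keep boundary bias small
  radii <- c(0.6, 1.0)
  acc <- matrix(0, 300, length(radii))
  set.seed(8)
  for (b in 1:300) {
    pts <- matrix(runif(500 * 3, 0, side), 500, 3)
    acc[b, ] <- ripley_k3d(pts, V, radii)
  }
  expected <- 4 / 3 * pi * radii^3
  rel <- abs(colMeans(acc) - expected) / expected
  expect_true(all(rel < 0.05))
})

test_that("Monte-Carlo envelopes are seeded and flag Thomas clustering", {
  cell <- simulate_cell(shape_params(n_primary_branches = 0, soma_radius = 40,
                                     image_size = 128), seed = 3)
  attr(cell, "pixel_size") <- cfg$pixel_size
  radii <- 3:7
  tx <- simulate_transcripts(cell, list(gene_model("G", 80, -20)), seed = 5)
  r1 <- ripley_envelope(tx, cell$soma, cfg, radii, n_null = 100, seed = 6)
  r2 <- ripley_envelope(tx, cell$soma, cfg, radii, n_null = 100, seed = 6)
  expect_identical(r1$lower, r2$lower)
  expect_identical(r1$upper, r2$upper)
  expect_true(all(r1$lower <= r1$upper))

  flagged <- 0L
  for (s in 1:20) {
    txc <- simulate_transcripts(cell, list(gene_model("G", 80, -20,
                                                      cluster_sigma = 1,
                                                      cluster_children = 10)),
                                seed = 100 + s)
    rc <- ripley_envelope(txc, cell$soma, cfg, radii, n_null = 100,
                          seed = 200 + s)
    flagged <- flagged + any(rc$flag_upper)
  }
  expect_gte(flagged, 18L)
  expect_error(ripley_envelope(tx, cell$soma[1:2, 1:2, 1, drop = FALSE] &
                                 FALSE, cfg, radii), "10 voxels")
})

test_that("per-process averaging uses individual process components", {
  cell <- simulate_cell(shape_params(n_primary_branches = 5), seed = 9)
  attr(cell, "pixel_size") <- cfg$pixel_size
  tx <- simulate_transcripts(cell, list(gene_model("G", 120, +20)), seed = 10)
  rp <- ripley_envelope(tx, cell$process, cfg, radii = 2:4, n_null = 50,
                        seed = 11, per_process = TRUE)
  expect_true(all(is.finite(rp$h)))
  expect_length(rp$h, 3)
})

test_that("the co-localization radius is a linear-interpolation percentile", {
  expect_equal(coloc_radius(1:100, 5), 5.95)
  expect_equal(coloc_radius(rep(2.5, 30), 5), 2.5)
  r5 <- coloc_radius(1:100, 5); r10 <- coloc_radius(1:100, 10)
  expect_lt(r5, r10)
  expect_error(coloc_radius(numeric(0)), "no distances")
})

test_that("close-pair counting is exact and excludes same-gene pairs", {
  tx <- as_transcript_table(data.frame(
    gene = c("A", "B", "B", "A"),
    x = c(10, 10.8, 10, 30), y = c(10, 10, 10.8, 30),
    z = c(1L, 1L, 1L, 1L)))
  m <- coloc_counts(tx, r_coloc = 1, genes = c("A", "B"), cfg = cfg)
  # molecule 1 (A) is 0.4 um from both B molecules; the far A pairs with none
  expect_equal(m["A", "B"], 2L)
  expect_equal(m["A", "A"], 0L)
  solo <- as_transcript_table(data.frame(gene = c("A", "A"),
                                         x = c(1, 1.2), y = c(1, 1),
                                         z = c(1L, 1L)))
  m2 <- coloc_counts(solo, 1, c("A", "B"), cfg)
  expect_true(all(m2 == 0L))
})

test_that("the randomization null preserves counts and matches geometry", {
  mask <- array(TRUE, dim = c(16, 16, 2))
  tx <- as_transcript_table(data.frame(
    gene = c("A", "B"), x = c(2, 9), y = c(2, 9), z = c(1L, 2L)))
  nl <- coloc_null(tx, mask, r_coloc = 1.5, genes = c("A", "B"), cfg = cfg,
                   n_null = 5000, seed = 2)
  got <- mean(nl[, "A", "B"])

  # independent oracle: plain uniform sampling of the same box geometry
  set.seed(99)
  B <- 200000
  p1 <- cbind(runif(B, 0, 16) * cfg$pixel_size, runif(B, 0, 16) * cfg$pixel_size,
              (sample(2, B, TRUE) - 1) * cfg$z_spacing)
  p2 <- cbind(runif(B, 0, 16) * cfg$pixel_size, runif(B, 0, 16) * cfg$pixel_size,
              (sample(2, B, TRUE) - 1) * cfg$z_spacing)
  oracle <- mean(sqrt(rowSums((p1 - p2)^2)) <= 1.5)
  expect_lt(abs(got - oracle) / oracle, 0.1)

  expect_warning(n2 <- coloc_null(tx, mask, 1.5, c("A", "B"), cfg,
                                  n_null = 50, seed = 7), "noisy")
  expect_warning(n3 <- coloc_null(tx, mask, 1.5, c("A", "B"), cfg,
                                  n_null = 50, seed = 7), "noisy")
  expect_identical(n2, n3)
})

test_that("significance aggregation builds networks with the stated rules", {
  genes <- c("A", "B", "C", "D", "E", "F", "X", "Y")
  np <- length(genes)
  mk_obs <- function(hot_pairs, base = 0L, hot = 12L) {
    m <- matrix(base, np, np, dimnames = list(genes, genes))
    for (p in hot_pairs) m[p[1], p[2]] <- hot
    m
  }
  triads <- list(c("A", "B"), c("A", "C"), c("B", "C"),
                 c("D", "E"), c("D", "F"), c("E", "F"))
  set.seed(4)
  obs <- lapply(1:6, function(i) mk_obs(triads))
  nulls <- lapply(1:6, function(i) {
    arr <- array(rpois(200 * np * np, 1.0), dim = c(200, np, np),
                 dimnames = list(NULL, genes, genes))
    arr
  })
  net <- coloc_significance(obs, nulls, genes, seed = 5)
  sig <- net$pairs[net$pairs$significant, ]
  expect_setequal(paste(sig$gene_a, sig$gene_b),
                  vapply(triads, paste, "", collapse = " "))
  expect_equal(length(unique(net$components)), 2)
  expect_length(net$clusters, 6)
  # two disjoint triads are clustered separately
  comp_of <- net$components
  expect_true(all(comp_of[c("A", "B", "C")] == comp_of["A"]))
  expect_true(all(comp_of[c("D", "E", "F")] == comp_of["D"]))
  expect_false(comp_of["A"] == comp_of["D"])

  # edge set is invariant to cell ordering
  net2 <- coloc_significance(obs[c(3, 1, 2, 6, 5, 4)],
                             nulls[c(3, 1, 2, 6, 5, 4)], genes, seed = 5)
  expect_equal(net$edges[, c("gene_a", "gene_b")],
               net2$edges[, c("gene_a", "gene_b")])

  # a pair observed in fewer than four cells is never an edge
  obs_rare <- lapply(1:6, function(i)
    mk_obs(if (i <= 3) triads else list(), base = 0L))
  net3 <- coloc_significance(obs_rare, nulls, genes, seed = 5)
  expect_equal(nrow(net3$edges), 0)
})

test_that("planted shared-parent pairs are recovered; CSR stays empty", {
  panel <- coloc_panel(n_coloc_pairs = 1)
  ds <- simulate_dataset(cfg, n_cells = 15, gene_models = panel,
                         ramified_fraction = 1, seed = 23)
  net <- run_soma_coloc(ds, cfg, n_null = 150, seed = 23)
  pp <- ds$truth$planted_pairs
  row <- net$pairs[net$pairs$gene_a == pp$gene_a[1] &
                   net$pairs$gene_b == pp$gene_b[1], ]
  expect_lt(row$padj, 0.05)

  panel0 <- coloc_panel(n_coloc_pairs = 0)
  ds0 <- simulate_dataset(cfg, n_cells = 15, gene_models = panel0,
                          ramified_fraction = 1, seed = 29)
  net0 <- run_soma_coloc(ds0, cfg, n_null = 150, seed = 29)
  expect_equal(nrow(net0$edges), 0)
})
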