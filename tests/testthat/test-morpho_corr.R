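mk_expr <- function(n, G, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * G, 20), n, G,
              dimnames = list(paste0("c", seq_len(n)),
                              paste0("g", seq_len(G))))
  lognormalize(m)
}

test_that("Spearman correlations honor the train/test split and rank ties", {
  ln <- mk_expr(200, 20, seed = 2)
  feats <- data.frame(cell_id = rownames(ln),
                      cell_area = ln[, "g1"] * 3 + 7,   # monotone in g1
                      n_terminal_points = rnorm(200))
  cm <- correlate(feats, ln, seed = 5)
  expect_length(intersect(cm$train_ids, cm$test_ids), 0)
  expect_equal(length(cm$train_ids), 150)
  expect_equal(unname(cm$rho["g1", "cell_area"]), 1)
  expect_true(all(abs(cm$rho) <= 1))

  # Spearman is invariant to monotone transforms of either margin
  feats2 <- feats; feats2$cell_area <- exp(feats$cell_area / 4)
  cm2 <- correlate(feats2, ln, seed = 5)
  expect_equal(cm$rho[, "cell_area"], cm2$rho[, "cell_area"], tolerance = 1e-12)
})

test_that("independent genes stay near zero correlation across seeds", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    x <- rnorm(500); y <- rnorm(500)
    hits <- hits + (abs(cor(x, y, method = "spearman")) < 0.15)
  }
  expect_gte(hits, 95)

  ln <- mk_expr(400, 10, seed = 3)
  feats <- data.frame(cell_id = rownames(ln),
                      cell_area = ln[, "g1"] + rnorm(400, 0, 0.05))
  r1 <- correlate(feats, ln, seed = 1)$rho["g1", "cell_area"]
  r2 <- correlate(feats, ln, seed = 2)$rho["g1", "cell_area"]
  expect_gt(r1, 0.8)
  expect_gt(r2, 0.8)
})

test_that("top-k selection unions per-feature gene lists with provenance", {
  rho <- matrix(0, 10, 2, dimnames = list(paste0("g", 1:10), c("f1", "f2")))
  rho[1:5, 1] <- c(0.9, -0.8, 0.7, 0.6, 0.5)
  rho[, 2] <- rho[, 1]
  cm <- structure(list(rho = rho), class = "correlation_matrix")
  gs <- top_gene_sets(cm, k = 5)
  expect_length(gs, 5)
  expect_setequal(as.character(gs), paste0("g", 1:5))
  prov <- attr(gs, "provenance")
  expect_length(prov, 2)

  one <- structure(list(rho = rho[, 1, drop = FALSE]),
                   class = "correlation_matrix")
  expect_length(top_gene_sets(one, k = 5), 5)
})

test_that("planted feature-correlated genes are recovered by the union", {
  set.seed(11)
  n <- 300; G <- 60; nf <- 6
  feats <- data.frame(cell_id = paste0("c", 1:n))
  counts <- matrix(rpois(n * G, 20), n, G,
                   dimnames = list(feats$cell_id, paste0("g", 1:G)))
  planted <- split(1:30, rep(1:nf, each = 5))
  for (f in seq_len(nf)) {
    drive <- rnorm(n)
    feats[[paste0("f", f)]] <- drive
    for (g in planted[[f]])
      counts[, g] <- rpois(n, 20 * exp(0.8 * drive))
  }
  cm <- correlate(feats, lognormalize(counts), seed = 4)
  gs <- top_gene_sets(cm, k = 5)
  rec <- mean(paste0("g", 1:30) %in% gs)
  expect_gte(rec, 0.8)
})

test_that("held-out clustering separates expression-linked shape classes", {
  set.seed(21)
  n <- 200
  lab <- rep(c("C1", "C5"), each = n / 2)
  mu <- matrix(20, n, 20)
  mu[lab == "C5", 1:6] <- 90
  counts <- matrix(rpois(n * 20, mu), n, 20,
                   dimnames = list(paste0("c", 1:n), paste0("g", 1:20)))
  ln <- lognormalize(counts)
  morph <- setNames(lab, rownames(ln))
  test_ids <- paste0("c", seq(1, n, by = 2))
  ch <- cluster_heldout(ln, test_ids, paste0("g", 1:6), morph)
  expect_gt(ch$ari, 0.8)
  ch_rev <- cluster_heldout(ln, test_ids, rev(paste0("g", 1:6)), morph)
  expect_equal(ch$ari, ch_rev$ari)

  aris <- vapply(1:50, function(s) {
    set.seed(s)
    shuf <- setNames(sample(lab), rownames(ln))
    gs <- sample(colnames(ln), 5)
    cluster_heldout(ln, test_ids, gs, shuf)$ari
  }, 0)
  expect_lt(abs(median(aris)), 0.1)

  flat <- ln; flat[, ] <- 1
  expect_true(cluster_heldout(flat, test_ids, paste0("g", 1:6), morph)$flagged)
})

test_that("region stratification counts cross-region gene occurrences", {
  set.seed(31)
  n <- 120
  ids <- paste0("c", 1:n)
  drive <- rnorm(n)
  counts <- matrix(rpois(n * 30, 20), n, 30,
                   dimnames = list(ids, paste0("g", 1:30)))
  counts[, 1] <- rpois(n, 20 * exp(1.2 * drive))
  ln <- lognormalize(counts)
  feats <- data.frame(cell_id = ids, cell_area = drive + rnorm(n, 0, 0.1),
                      fractal_dimension = drive + rnorm(n, 0, 0.1))
  regions3 <- setNames(rep(c("cortex", "mpm", "cerebellum"), length.out = n), ids)
  rs <- region_stratified_top_genes(feats, ln, regions3,
                                    feature_list = c("cell_area",
                                                     "fractal_dimension"))
  expect_equal(unname(rs$occurrence["g1"]), 3L)
  expect_true(all(rs$occurrence <= 3))

  one <- setNames(rep("cortex", n), ids)
  rs1 <- region_stratified_top_genes(feats, ln, one,
                                     feature_list = c("cell_area"))
  expect_true(all(rs1$occurrence == 1L))
  expect_warning(region_stratified_top_genes(
    feats[1:10, ], ln[1:10, , drop = FALSE], one[1:10],
    feature_list = "cell_area"), "skipped")
})

test_that("normalized transcript distances span [0, 1] with analytic anchors", {
  cell <- disk_cell(r = 30, size = 100)
  edge_px <- c(cell$soma_centroid[1] + 29.4, cell$soma_centroid[2])
  tx <- as_transcript_table(data.frame(
    gene = c("A", "A"), x = c(cell$soma_centroid[1], edge_px[1]),
    y = c(cell$soma_centroid[2], edge_px[2]), z = c(1L, 1L)))
  dc <- transcript_distance_cdf(cell, tx)
  expect_equal(dc$dist[1], 0, tolerance = 1e-9)
  expect_gte(dc$dist[2], 0.97)
  expect_lte(max(dc$dist), 1 + 1e-9)
})

test_that("the ramification classifier is strong on signal, flat on noise", {
  set.seed(41)
  n <- 120; G <- 10
  lab <- rep(c("ramified", "amoeboid"), each = n / 2)
  mu <- matrix(20, n, G); mu[lab == "ramified", 1] <- 200
  counts <- matrix(rpois(n * G, mu), n, G,
                   dimnames = list(paste0("c", 1:n), paste0("g", 1:G)))
  ln <- lognormalize(counts)
  labels <- setNames(lab, rownames(ln))
  rep1 <- train_classifier(ln, labels, seed = 1)
  expect_equal(rep1$auroc, 1.0, tolerance = 0.02)
  expect_equal(sum(rep1$importance), 1, tolerance = 1e-9)
  expect_true(all(rep1$importance >= 0))
  expect_length(intersect(rep1$train_ids, rep1$test_ids), 0)

  nulls <- vapply(1:10, function(s) {
    set.seed(s)
    perm <- setNames(sample(lab), rownames(ln))
    train_classifier(ln, perm, seed = s)$auroc
  }, 0)
  expect_true(median(nulls) >= 0.35 && median(nulls) <= 0.65)
  expect_error(train_classifier(ln, setNames(rep("ramified", n),
                                             rownames(ln))), "both classes")
})

test_that("set-averaged correlations behave like means of member rows", {
  rho <- matrix(c(0.5, -0.5, 0.2), 3, 1,
                dimnames = list(c("a", "b", "c"), "cell_area"))
  cm <- structure(list(rho = rho), class = "correlation_matrix")
  av <- avg_compartment_correlation(cm, list(single = "a", pair = c("a", "b")))
  expect_equal(unname(av$single$per_feature), 0.5)
  expect_equal(av$pair$overall, 0)
  expect_warning(avg_compartment_correlation(cm, list(ghost = c("a", "zz"))),
                 "absent")
})
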