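test_that("the canonical feature vector has 26 well-behaved entries", {
  cell <- simulate_cell(shape_params(), seed = 1)
  f <- compute_features(cell)
  expect_length(f, 26)
  expect_identical(names(f), feature_names())
  expect_false(any(is.na(f)))
  expect_lte(f[["solidity"]], 1)
  expect_lte(f[["extent"]], 1)
  expect_lte(f[["circularity"]], 1.1)
  expect_equal(f[["cell_area"]], sum(max_projection(cell$total) > 0))
  expect_true(f[["soma_ratio"]] >= 0 && f[["soma_ratio"]] <= 1)
})

test_that("analytic shapes recover their morphometric values", {
  cl <- simulate_cell(shape_params(n_primary_branches = 0, soma_radius = 30,
                                   image_size = 128), seed = 7)
  f <- compute_features(cl)
  expect_gte(f[["solidity"]], 0.98)
  expect_true(f[["circularity"]] >= 0.95 && f[["circularity"]] <= 1.0)
  expect_equal(f[["euler_number"]], 1)

  bar <- make_cell(total2d = {
    m <- matrix(FALSE, 64, 64); m[6:55, 20:29] <- TRUE; m
  }, soma2d = matrix(FALSE, 64, 64) | FALSE, cell_id = "bar")
  fb <- suppressWarnings(compute_features(bar))
  expect_lt(abs(fb[["feret_diameter"]] - sqrt(49^2 + 9^2)), 1)
})

test_that("skeleton measurements are exact on bar, Y and L fixtures", {
  bar <- matrix(FALSE, 60, 60); bar[10:50, 30] <- TRUE
  m <- skeletonize_and_measure(bar)
  expect_equal(m$n_terminal_points, 2L)
  expect_equal(m$n_branching_points, 0L)
  expect_equal(m$n_branches, 1L)
  expect_true(m$tortuosity >= 1 && m$tortuosity <= 1.05)

  Y <- matrix(FALSE, 80, 80); Y[40, 10:40] <- TRUE
  for (k in 0:25) { Y[40 + k, 40 + k] <- TRUE; Y[40 - k, 40 + k] <- TRUE }
  m2 <- skeletonize_and_measure(Y)
  expect_equal(m2$n_terminal_points, 3L)
  expect_equal(m2$n_branching_points, 1L)
  expect_equal(m2$n_branches, 3L)

  L <- matrix(FALSE, 60, 60); L[10:30, 10] <- TRUE; L[30, 10:30] <- TRUE
  m3 <- skeletonize_and_measure(L)
  expect_lt(abs(m3$tortuosity - sqrt(2)), 0.08)

  tiny <- matrix(FALSE, 10, 10); tiny[5, 5] <- TRUE
  expect_equal(skeletonize_and_measure(tiny)$skeleton_length, 0)
})

test_that("box-counting dimension matches analytic dimensions", {
  expect_true(abs(fractal_dimension(matrix(TRUE, 256, 256)) - 2) <= 0.1)
  ln <- matrix(FALSE, 256, 256); ln[, 128] <- TRUE
  expect_true(fractal_dimension(ln) >= 0.95 && fractal_dimension(ln) <= 1.05)
  sp <- outer(0:127, 0:127, function(i, j) bitwAnd(i, j) == 0)
  fd <- fractal_dimension(sp)
  expect_true(fd >= 1.5 && fd <= 1.66)
  expect_equal(fractal_dimension(matrix(c(TRUE, rep(FALSE, 99)), 10, 10)), 0)
})

test_that("fractal dimension is stable under translation and rotation", {
  cell <- simulate_cell(shape_params(), seed = 3)
  m <- max_projection(cell$total)
  fd <- fractal_dimension(m)
  shifted <- matrix(FALSE, nrow(m) + 20, ncol(m) + 20)
  shifted[13:(nrow(m) + 12), 8:(ncol(m) + 7)] <- m
  expect_lte(abs(fractal_dimension(shifted) - fd), 0.02)
  expect_lte(abs(fractal_dimension(t(m)[ncol(m):1, ]) - fd), 0.02)
})

test_that("gliding-box lacunarity is 1 for filled masks and larger when sparse", {
  expect_equal(lacunarity(matrix(TRUE, 64, 64)), 1.0)
  cell <- simulate_cell(shape_params(), seed = 5)
  expect_gte(lacunarity(max_projection(cell$total)), 1)
  sparse_wins <- 0L
  for (s in 1:20) {
    set.seed(s)
    lo <- matrix(runif(96 * 96) < 0.05, 96, 96)
    hi <- matrix(runif(96 * 96) < 0.50, 96, 96)
    sparse_wins <- sparse_wins + (lacunarity(lo) > lacunarity(hi))
  }
  expect_gte(sparse_wins, 18L)
  expect_true(is.na(lacunarity(matrix(FALSE, 8, 8))))
})

test_that("Sholl intersections follow constructed ray geometries", {
  ray <- matrix(FALSE, 101, 101); ray[51:95, 51] <- TRUE
  s1 <- sholl(ray, c(50.5, 50.5), 2)
  expect_true(all(s1$intersections[s1$radii <= 40] == 1))
  expect_equal(s1$ramification_index, 1)
  expect_equal(s1$critical_radius, s1$radii[1])

  two <- matrix(FALSE, 101, 101); two[6:95, 51] <- TRUE
  s2 <- sholl(two, c(50.5, 50.5), 2)
  expect_true(all(s2$intersections[s2$radii <= 40] == 2))

  yk <- matrix(FALSE, 121, 121); yk[61:80, 61] <- TRUE
  for (t in seq(0, 42, by = 0.4)) {
    yk[cbind(round(81 + t * 0.707), round(61 + t * 0.707))] <- TRUE
    yk[cbind(round(81 + t * 0.707), round(61 - t * 0.707))] <- TRUE
  }
  s3 <- sholl(yk, c(60.5, 60.5), 2)
  expect_true(all(s3$intersections[s3$radii < 19] == 1))
  expect_true(all(s3$intersections[s3$radii > 22 & s3$radii <= 45] == 2))
  expect_gt(s3$critical_radius, 20)
  expect_lte(s3$critical_radius, s3$dendritic_maximum)
})

test_that("the embedding contract holds: 224x224 padding, 512 finite values", {
  crop <- matrix(runif(40 * 25), 40, 25)
  pad <- embed_preprocess(crop)
  expect_equal(dim(pad), c(224, 224))
  e <- embed_cells(list(crop, crop, matrix(0.5, 30, 30)))
  expect_equal(dim(e), c(3L, 512L))
  expect_true(all(is.finite(e)))
  expect_identical(e[1, ], e[2, ])
  expect_error(embed_cells(list(matrix(numeric(0), 0, 0))), "empty")
})

test_that("elbow-selected clustering recovers separated groups and orders them", {
  set.seed(99)
  n <- 30
  emb <- rbind(matrix(rnorm(n * 512, 0, 1), n, 512),
               matrix(rnorm(n * 512, 10, 1), n, 512))
  feats <- data.frame(n_terminal_points = rep(c(2, 9), each = n),
                      cell_area = rep(c(400, 900), each = n))
  mc <- cluster_morphology(emb, feats, seed = 4)
  expect_equal(mc$k, 2)
  expect_true(all(mc$labels[1:n] == "C1"))
  expect_true(all(mc$labels[(n + 1):(2 * n)] == "C2"))
  expect_true(all(diff(mc$order_key) >= 0))
  mc2 <- cluster_morphology(emb, feats, seed = 4)
  expect_identical(mc$labels, mc2$labels)

  dup <- cluster_morphology(rbind(emb, emb), rbind(feats, feats), seed = 4)
  expect_identical(as.character(dup$labels[seq_len(2 * n)]),
                   as.character(mc$labels))
})

test_that("projection-depth consistency is exact for replicated planes", {
  cfg <- run_config(seed = 1)
  tot <- disk2d(96, 48, 48, 20)
  cells <- lapply(1:3, function(i) {
    cl <- make_cell(tot, disk2d(96, 48, 48, 8), nz = 14,
                    cell_id = paste0("c", i))
    cl
  })
  pc <- projection_consistency(cells, thicknesses = c(10, 15, 20), cfg = cfg)
  expect_equal(pc$table$section_fd, pc$table$full_fd)
  expect_equal(pc$slope, 1)
  expect_equal(pc$correlation, 1)

  # plane-varying masks keep a positive association with full-depth FD
  cells2 <- lapply(1:25, function(i)
    simulate_cell(shape_params(n_planes = 14), seed = 500 + i,
                  cell_id = paste0("v", i)))
  pc2 <- projection_consistency(cells2, thicknesses = c(10, 15, 20), cfg = cfg)
  expect_gt(pc2$correlation, 0)
})
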