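cfg <- run_config(seed = 7)

test_that("coarse segmentation handles degenerate and constructed inputs", {
  z <- matrix(0, 100, 100)
  expect_equal(max(coarse_segment(z)), 0)
  expect_equal(max(coarse_segment(matrix(0.4, 100, 100))), 0)

  img <- matrix(0, 200, 200)
  img[disk2d(200, 50, 100, 15)] <- 0.9
  img[disk2d(200, 150, 100, 15)] <- 0.9
  lab <- coarse_segment(img)
  expect_equal(max(lab), 2)
  expect_identical(lab, coarse_segment(img))
})

test_that("label-boundary matching is mutually unique and annotation-aware", {
  lab <- matrix(0L, 60, 60)
  lab[10:20, 10:20] <- 1L
  lab[30:40, 10:20] <- 2L
  big <- rbind(c(5, 5), c(45, 5), c(45, 25), c(5, 25), c(5, 5))
  one <- rbind(c(8, 8), c(22, 8), c(22, 22), c(8, 22), c(8, 8))
  far <- rbind(c(48, 48), c(58, 48), c(58, 58), c(48, 58), c(48, 48))

  bs <- structure(list(polygons = list(spans = big),
                       annotation = c(spans = "microglia")),
                  class = "boundary_set")
  expect_equal(nrow(match_labels(lab, bs)), 0)   # overlaps two labels

  bs2 <- structure(list(polygons = list(a = one, b = far),
                        annotation = c(a = "microglia", b = "microglia")),
                   class = "boundary_set")
  m <- match_labels(lab, bs2)
  expect_equal(m$cell_id, "a")
  expect_equal(m$label, 1L)

  bs3 <- structure(list(polygons = list(a = one),
                        annotation = c(a = "astrocyte")),
                   class = "boundary_set")
  expect_equal(nrow(match_labels(lab, bs3)), 0)

  empty <- structure(list(polygons = list(), annotation = NULL),
                     class = "boundary_set")
  expect_equal(nrow(match_labels(lab, empty)), 0)
})

test_that("simulated boundaries match their own coarse segmentations", {
  matched <- 0L
  for (s in 1:4) {
    cell <- simulate_cell(shape_params(), seed = s, cell_id = paste0("c", s))
    stack <- render_cell_stack(cell, seed = 100 + s)
    iba <- max_projection(micromorph:::stack_channel_xyz(stack, "IBA1"))
    lab <- coarse_segment(iba)
    ring <- micromorph:::cell_contour(cell)
    bs <- structure(list(polygons = setNames(list(ring), cell$cell_id),
                         annotation = setNames("microglia", cell$cell_id)),
                    class = "boundary_set")
    matched <- matched + nrow(match_labels(lab, bs))
  }
  expect_equal(matched, 4L)
})

test_that("compartment refinement partitions the total mask and subtracts GFAP", {
  cell <- simulate_cell(shape_params(), seed = 9)
  stack <- render_cell_stack(cell, seed = 10)
  rc <- refine_compartments(stack, cell$soma_centroid, "r1",
                            window_coarse = 60, window_fine = 30)
  for (p in seq_len(dim(rc$total)[3])) {
    expect_false(any(rc$soma[, , p] & rc$process[, , p]))
    expect_identical(rc$total[, , p], rc$soma[, , p] | rc$process[, , p])
  }
  sc <- rc$soma_centroid
  expect_true(rc$soma[px_i(sc[1], dim(rc$soma)[1]),
                      px_i(sc[2], dim(rc$soma)[2]), 1])

  # all-zero GFAP leaves the process mask at exactly fine-IBA1 minus soma
  stack0 <- stack; stack0["GFAP", , , ] <- 0
  rc0 <- refine_compartments(stack0, cell$soma_centroid, "r0",
                             window_coarse = 60, window_fine = 30)
  iba <- micromorph:::stack_channel_xyz(stack0, "IBA1")
  soma2d <- rc0$soma[, , 1]
  for (p in seq_len(dim(rc0$process)[3])) {
    manual <- micromorph:::adaptive_threshold(iba[, , p], 30) & !soma2d
    expect_identical(rc0$process[, , p], manual)
  }

  # GFAP tracking the IBA1 signal removes those pixels from the process mask
  stack_full <- stack
  stack_full["GFAP", , , ] <- stack_full["IBA1", , , ]
  rc1 <- refine_compartments(stack_full, cell$soma_centroid, "rf",
                             window_coarse = 60, window_fine = 30)
  expect_lt(sum(rc1$process), 0.05 * sum(rc$process))

  # no nuclear signal at the center: cell is flagged and skipped
  stack2 <- stack; stack2["DAPI", , , ] <- 0
  expect_warning(out <- refine_compartments(stack2, cell$soma_centroid, "rx",
                                            window_coarse = 60,
                                            window_fine = 30), "skipped")
  expect_null(out)
})

test_that("planted astrocyte signal is removed from the refined process mask", {
  ds <- simulate_dataset(cfg, n_cells = 3, ramified_fraction = 1, seed = 30,
                         astro = list(fraction = 1, genes = c("AstroA"),
                                      mean_count = 80))
  removed <- total_astro <- 0
  for (cell in ds$cells) {
    stack <- render_cell_stack(cell,
                               derive_seed(30, paste0("render/", cell$cell_id)))
    rc <- refine_compartments(stack, cell$soma_centroid, cell$cell_id,
                              window_coarse = 60)
    tx <- ds$transcripts[ds$transcripts$cell_id == cell$cell_id &
                         ds$transcripts$gene == "AstroA", ]
    if (!nrow(tx)) next
    idx <- cbind(px_i(tx$x, dim(rc$process)[1]),
                 px_i(tx$y, dim(rc$process)[2]), tx$z)
    removed <- removed + sum(!rc$process[idx])
    total_astro <- total_astro + nrow(tx)
  }
  expect_gte(removed / total_astro, 0.95)
})

test_that("transcript assignment is conservative, idempotent and order-free", {
  cell <- simulate_cell(shape_params(), seed = 3)
  attr(cell, "pixel_size") <- cfg$pixel_size
  tx <- simulate_transcripts(cell, default_gene_panel(), seed = 4)
  genes <- sort(unique(tx$gene))
  asn <- assign_transcripts(tx, cell, genes = genes)
  expect_identical(asn$counts$soma + asn$counts$process, asn$counts$total)

  ctr <- data.frame(gene = "G", x = cell$soma_centroid[1],
                    y = cell$soma_centroid[2], z = 1L)
  expect_equal(assign_transcripts(as_transcript_table(ctr), cell,
                                  "G")$transcripts$compartment, "soma")

  off <- data.frame(gene = "G", x = 1, y = 1, z = 1L)
  a_off <- assign_transcripts(as_transcript_table(off), cell, "G")
  expect_equal(a_off$transcripts$compartment, "unassigned")
  expect_equal(unname(a_off$counts$total), 0L)

  perm <- sample(nrow(tx))
  asn2 <- assign_transcripts(tx[perm, ], cell, genes = genes)
  expect_identical(asn2$counts, asn$counts)
  asn3 <- assign_transcripts(asn$transcripts, cell, genes = genes)
  expect_identical(asn3$counts, asn$counts)

  sat <- simulate_transcripts(cell, list(gene_model("P", 50, +20)), seed = 5)
  asat <- assign_transcripts(sat, cell, "P")
  expect_equal(asat$counts$process, asat$counts$total)
})

test_that("aggregate detection applies the strict pixel-area rule", {
  ch <- array(0, dim = c(120, 120, 2))
  ch[10:16, 10:16, 1] <- 0.9                       # 49 px: rejected
  ch[60:69, 60:65, 1] <- 0.9                       # 60 px: kept
  ch[100:109, 100:105, 2] <- 0.9                   # 60 px outside IBA1
  iba <- array(0, dim = c(120, 120, 2))
  iba[40:80, 40:80, ] <- 0.8
  res <- detect_aggregates(ch, iba, min_area = 51, window_fine = 30)
  expect_equal(nrow(res$aggregates), 2)
  expect_true(all(res$aggregates$area > 50))
  in1 <- res$aggregates[res$aggregates$plane == 1, ]
  expect_true(in1$in_iba1)
  out2 <- res$aggregates[res$aggregates$plane == 2, ]
  expect_false(out2$in_iba1)
  blank <- detect_aggregates(array(0, dim = c(50, 50, 1)),
                             array(0, dim = c(50, 50, 1)))
  expect_equal(nrow(blank$aggregates), 0)
})
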