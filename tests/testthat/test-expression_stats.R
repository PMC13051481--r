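mk_counts <- function(n, G, mu = 20, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n * G, mu), n, G,
              dimnames = list(paste0("c", seq_len(n)),
                              paste0("g", seq_len(G))))
  m
}

test_that("QC thresholds are inclusive exactly at the boundary", {
  m <- rbind(c(19, 0, 0, 0, 0),
             c(4, 4, 4, 4, 4),
             c(16, 1, 1, 1, 1),
             c(30, 0, 0, 0, 0))
  rownames(m) <- paste0("c", 1:4); colnames(m) <- paste0("g", 1:5)
  kept <- qc_filter(m, min_transcripts = 20, min_genes = 5)
  expect_identical(rownames(kept), c("c2", "c3"))
  expect_equal(ncol(kept), 5)
  expect_equal(nrow(qc_filter(m[0, , drop = FALSE])), 0)
})

test_that("log-normalization matches its closed form and conserves depth", {
  m <- matrix(c(10, 0, 0, 5, 5, 10), 2, 3, byrow = TRUE,
              dimnames = list(c("a", "b"), c("g1", "g2", "g3")))
  ln <- lognormalize(m)
  expect_equal(ln["a", "g1"], log(10001), tolerance = 1e-12)
  expect_equal(ln["a", "g2"], 0)
  expect_true(all(abs(rowSums(expm1(ln)) - 1e4) < 1e-6))
  z <- m; z[1, ] <- 0
  expect_error(lognormalize(z), "zero transcripts")
})

test_that("Mann-Whitney DE is null-calibrated, symmetric and recovers shifts", {
  counts <- mk_counts(40, 20, seed = 3)
  ln <- lognormalize(counts)
  same <- mww_de(ln, paste0("c", 1:20), paste0("c", 1:20))
  expect_true(all(same$padj == 1))
  expect_true(all(same$deg == "ns"))

  one <- mww_de(ln[, 1, drop = FALSE], paste0("c", 1:20), paste0("c", 21:40))
  expect_equal(one$padj, one$p)

  ab <- mww_de(ln, paste0("c", 1:20), paste0("c", 21:40))
  ba <- mww_de(ln, paste0("c", 21:40), paste0("c", 1:20))
  expect_equal(ab$log2fc, -ba$log2fc, tolerance = 1e-9)
  expect_equal(ab$p, ba$p, tolerance = 1e-9)
  expect_false(is.unsorted(ab$padj[order(ab$p)]))

  hits <- 0L; declared <- 0L
  for (s in 1:20) {
    set.seed(s)
    n <- 100; G <- 100
    mu <- matrix(20, 2 * n, G)
    mu[1:n, 1:10] <- 80
    cm <- matrix(rpois(2 * n * G, mu), 2 * n, G,
                 dimnames = list(paste0("c", 1:(2 * n)), paste0("g", 1:G)))
    de <- mww_de(lognormalize(cm), paste0("c", 1:n), paste0("c", (n + 1):(2 * n)))
    up <- which(de$deg == "up")
    hits <- hits + sum(up %in% 1:10)
    declared <- declared + length(up)
  }
  expect_gte(hits / (20 * 10), 0.9)                 # planted genes found
  expect_lte((declared - hits) / max(declared, 1), 0.1)  # FDR among flags
})

test_that("two random halves of one population rarely exceed the FDR level", {
  counts <- mk_counts(80, 60, seed = 9)
  ln <- lognormalize(counts)
  bad <- 0L
  for (s in 1:100) {
    set.seed(s)
    half <- sample(rownames(ln), 40)
    de <- mww_de(ln, half, setdiff(rownames(ln), half))
    bad <- bad + (mean(de$padj < 0.05) > 0.05)
  }
  expect_gte(100 - bad, 95)
})

test_that("compartment enrichment recovers planted log-odds and stays disjoint", {
  cfg <- run_config(seed = 19)
  panel <- default_gene_panel(n_soma = 5, n_process = 5, n_neutral = 10,
                              logodds = 2, n_coloc_pairs = 0)
  ds <- simulate_dataset(cfg, n_cells = 60, gene_models = panel,
                         ramified_fraction = 1, seed = 19)
  enr <- compartment_enrichment(ds$counts$soma, ds$counts$process,
                                rownames(ds$counts$soma))
  truth <- ds$truth$gene_compartment
  expect_length(intersect(enr$process_enriched, enr$soma_enriched), 0)
  sens_p <- mean(names(truth)[truth == "process"] %in% enr$process_enriched)
  sens_s <- mean(names(truth)[truth == "soma"] %in% enr$soma_enriched)
  expect_gte(sens_p, 0.8)
  expect_gte(sens_s, 0.8)

  flat <- matrix(10L, 6, 4, dimnames = list(paste0("c", 1:6), paste0("g", 1:4)))
  enr0 <- compartment_enrichment(flat, flat, rownames(flat))
  expect_length(enr0$process_enriched, 0)
  expect_length(enr0$soma_enriched, 0)
  expect_error(compartment_enrichment(flat, flat, character(0)), "no ramified")
})

test_that("tau specificity matches analytic values and categories", {
  expect_equal(tau_statistic(c(2, 2, 2)), 0)
  expect_equal(tau_statistic(c(0, 3, 0)), 1)
  expect_equal(tau_statistic(c(1, 0.5, 0)), 0.75)
  expect_true(is.na(tau_statistic(c(0, 0, 0))))

  cls <- rbind(ubi = c(1, 1, 1), mg = c(0.05, 2, 0.05), odd = c(1, 0.2, 0))
  sub <- rbind(ubi = c(1, 1, 1, 1), mg = c(0.04, 2.2, 0.05, 0.02),
               odd = c(1, 0.2, 0, 0.4))
  colnames(cls) <- c("astro", "microglia", "neuron")
  colnames(sub) <- c("astro", "microglia", "neuron", "oligo")
  tr <- tau_specificity(cls, sub, target = "microglia")
  expect_equal(tr$category, c("ubiquitous", "specific-to-target", "other"))
})

test_that("binned-control gene-set scores are seeded and detect planted sets", {
  counts <- mk_counts(200, 60, seed = 5)
  counts[1:100, 1:5] <- counts[1:100, 1:5] + matrix(rpois(100 * 5, 60), 100, 5)
  ln <- lognormalize(counts)
  s1 <- score_gene_set(ln, paste0("g", 1:5), seed = 2)
  s2 <- score_gene_set(ln, paste0("g", 1:5), seed = 2)
  expect_identical(s1, s2)

  whole <- score_gene_set(ln, colnames(ln), seed = 2)
  expect_lte(max(abs(whole)), 0.05)

  p <- wilcox.test(s1[1:100], s1[101:200], alternative = "greater")$p.value
  expect_lt(p, 0.01)
  expect_error(score_gene_set(ln, character(0)), "length")
})
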