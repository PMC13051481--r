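# micromorph

Joint morphology and subcellular transcript-localization analysis of
microglia for imaging-based spatial transcriptomics (MERFISH-style data),
in R.

Microglia shift between a compact *amoeboid* and a branched *ramified*
morphology, and where a cell places its mRNA — in the soma or out in its
processes — is part of that functional picture. Given per-molecule decoded
transcript tables (gene, x, y, z-plane), immunofluorescence stacks
(microglial, nuclear and astrocyte stains) and transcriptomically derived
cell boundary polygons, micromorph:

* segments each microglial cell and decomposes it into **soma** and
  **process** compartments (with astrocyte-signal subtraction), then
  assigns every molecule to a compartment per z-plane;
* quantifies morphology with a canonical **26-feature** vector —
  solidity `A/A_hull`, circularity `4πA/P²`, skeleton branch/terminal
  counts, Sholl ramification index, box-counting fractal dimension,
  gliding-box lacunarity, tortuosity, … — plus a deterministic 512-d
  image embedding and elbow-selected k-means classes C1 (amoeboid) …
  Ck (ramified);
* tests **compartment enrichment** per gene with Mann-Whitney
  differential expression (`|log2FC| > 1`, BH-adjusted `p < 0.05`) on
  independently log-normalized soma and process counts
  (`ln(1 + 10⁴·count/total)`), and classifies genes by tau specificity
  `τ = Σ(1−x̂ᵢ)/(N−1)`;
* links morphology to expression with train/test-split Spearman
  correlations, top-5-per-feature gene sets, held-out hierarchical
  clustering, and a random-forest ramified-vs-amoeboid classifier
  (held-out AUROC, impurity importances);
* tests **within-compartment spatial clustering** with a 3D Ripley
  K/H function, `H(r) = (3K(r)/4π)^{1/3} − r`, against Monte-Carlo
  envelopes drawn uniformly from the same compartment voxels, and builds
  **gene–gene co-localization networks** from close-pair counts at the
  5th-percentile soma distance radius, a position-randomization null,
  z-tests with BH correction, and BIC-selected Gaussian-mixture
  clustering of network components.

A first-class synthetic generator (`simulate_dataset()`) plants known
ground truth — shape classes, per-gene compartment log-odds, Thomas-
process clustering, shared-parent co-localized gene pairs, astrocyte
contamination, and an age effect that attenuates enrichment and prunes
co-localized pairs — so the whole pipeline is testable end to end without
any external data. It is intended for computational biologists analysing
subcellular spatial transcriptomics of glia, and for method developers
who need a calibrated reference implementation of these statistics.

## Worked example

```r
library(micromorph)

cfg <- run_config(seed = 7)                       # 0.5 um/px, 1.5 um z-steps
ds  <- simulate_dataset(cfg, n_cells = 30, ramified_fraction = 0.5, seed = 7)

# morphometry of one ramified cell
f <- compute_features(ds$cells[[1]])
round(f[c("cell_area", "solidity", "fractal_dimension",
          "n_terminal_points", "soma_ratio")], 3)
#>         cell_area          solidity fractal_dimension n_terminal_points
#>           769.000             0.480             1.515             5.000
#>        soma_ratio
#>             0.270

# compartment enrichment on the ramified half of the cohort
ram <- names(ds$truth$shape_class)[ds$truth$shape_class == "ramified"]
enr <- compartment_enrichment(ds$counts$soma, ds$counts$process, ram)
enr$process_enriched
#> [1] "Proc01" "Proc02" "Proc03" "Proc04" "Proc05" "Proc06"
enr$soma_enriched
#> [1] "Soma01" "Soma02" "Soma03" "Soma04" "Soma05" "Soma06"

# co-localization radius: 5th percentile of pooled soma pairwise distances
d <- unlist(lapply(ds$cells, function(cl) {
  tx <- ds$transcripts[ds$transcripts$cell_id == cl$cell_id &
                       ds$transcripts$true_compartment == "soma", ]
  compartment_pair_distances(tx, cfg)
}))
coloc_radius(d, cfg$coloc_percentile)
#> [1] 1.87        # microns, from 1,877,871 pairwise distances

# Ripley H envelope for a planted Thomas-clustered gene in one soma
cell <- ds$cells[[1]]
tx <- ds$transcripts[ds$transcripts$cell_id == cell$cell_id &
                     ds$transcripts$gene == ds$truth$planted_pairs$gene_a[1] &
                     ds$transcripts$true_compartment == "soma", ]
rr <- ripley_envelope(tx, cell$soma, cfg, radii = 2:6, n_null = 200, seed = 7)
any(rr$flag_upper)
#> [1] TRUE        # clustering detected above the 95% CSR envelope
```

The 12 enriched calls above are exactly the 12 genes planted with
|log-odds| 2.5 (cell bodies keep `Soma*`, processes keep `Proc*`); the
flagged gene was planted as a Thomas cluster process with 1 µm
dispersion. On a cohort, `feature_table()`, `embed_cells()` +
`cluster_morphology()`, `correlate()` + `train_classifier()`, and
`coloc_counts()` + `coloc_null()` + `coloc_significance()` chain the same
way; the numbered scripts under `analysis/` run the full young-vs-aged
workflow and write their tables under `results/`.

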