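# image3c

Antibody-free analysis of imaging flow cytometry data in R.

Imaging flow cytometers record a multi-channel image of every cell in
flow — brightfield (BF), darkfield/side scatter (SSC) and fluorescence
channels such as a nuclear dye. When antibody panels are unavailable (new
research organisms, unknown epitopes), the images themselves carry enough
morphology to define cell types. image3c implements that idea end to end:

1. **Feature extraction** — spillover compensation, background
   subtraction, segmentation, and an open per-event feature panel
   (geometry on cell and nucleus masks, intensity statistics, a
   morphological granularity spectrum), followed by gating to focused,
   nucleated singlets.
2. **Preprocessing** — redundancy trimming at Spearman |ρ| ≥ 0.85,
   replicate QC against a leave-one-out reference, logicle
   (biexponential) transformation of fluorescence features, alignment of
   the 2N/4N DNA-content peaks across samples by monotone landmark
   warping, and scaling of all features to unit SD.
3. **De novo clustering** — kNN-density mode seeking (density
   `k / (n V_d r_k^d)`, ascent to the densest of the k nearest
   neighbours, density-valley mode consolidation), with k chosen by the
   elbow of the cluster-count curve over k = 5…150, plus a seeded
   force-directed layout of the kNN graph with graphML export.
4. **Differential abundance** — negative binomial regression of
   per-cluster counts with log-total offsets and a common Cox-Reid
   dispersion (`log μ = offset + β₀ + β₁·condition`, likelihood-ratio
   test of β₁ = 0, log2 fold changes, Benjamini–Hochberg FDR), plus
   one-way ANOVA for multi-group abundance comparisons and volcano
   exports.
5. **Classification** — a compact DenseNet-style CNN (three dense
   blocks, 32×32×3 input → 4×4×87 feature maps → flatten 1392 → class
   logits) trained with Adam on softmax cross-entropy + L2 against the
   de novo cluster labels, so later experiments can be mapped onto the
   same classes via per-event probability vectors.

A synthetic-data generator (`population_spec()`, `simulate_sample()`,
`demo_populations()`) emulates the structure the pipeline assumes —
distinct populations, 2N/4N bimodality, intensity drift, spillover,
doublets and debris — so everything is testable without instrument data.

## A worked example

Simulate four samples from the four-population demonstration panel,
extract and preprocess features, cluster, and test a count matrix with a
planted abundance shift:

```r
library(image3c)

specs <- lapply(1:4, function(s)
  sample_spec(sprintf("s%02d", s),
              condition = c("ctrl", "treated")[(s %% 2) + 1],
              n_events = 400, populations = demo_populations(),
              doublet_rate = 0.03, debris_rate = 0.03, seed = 100 + s))
sim <- simulate_feature_table(specs)   # render -> segment -> featurise

processed <- gate_events(sim$table) |>
  spearman_trim() |> getElement("table") |>
  logicle_transform_features(c("DNA_intensity", "FL1_intensity")) |>
  normalize_dna_peaks() |>
  scale_features()

clusters <- cluster_events(processed, k_grid = seq(5, 100, 5), seed = 1)
clusters
#> <image3c_clusters> 1506 events, 4 clusters (k = 65)
glance(clusters)
#> # A tibble: 1 × 4
#>   n_events n_clusters k_used n_samples
#>      <int>      <int>  <int>     <int>
#> 1     1506          4     65         4
```

The elbow picked k = 65, where the cluster-count curve flattens at 4 —
the number of simulated populations; against the generator's ground
truth the assignment reaches an adjusted Rand index of 0.948. `tidy()`
returns the per-event assignments with layout coordinates,
`autoplot(clusters)` draws the force-directed layout, and
`autoplot(clusters$elbow)` the cluster-count curve.

Differential abundance on a simulated count matrix (12 clusters, 6 + 6
samples of 10,000 events, a log2 fold change of 1.5 planted in the first
cluster):

```r
counts <- simulate_count_matrix(12, n_per_condition = 6,
                                effect_log2 = c(1.5, rep(0, 11)),
                                dispersion = 0.1, seed = 7)
diff <- nb_test(counts)
glance(diff)
#> # A tibble: 1 × 5
#>   n_clusters dispersion contrast n_significant_05 n_significant_01
#>        <int>      <dbl> <chr>               <int>            <int>
#> 1         12     0.0731 B vs A                  1                1
head(tidy(diff), 3)
#> # A tibble: 3 × 6
#>   cluster  logFC       p_value          fdr mean_abundance flagged
#>   <chr>    <dbl>         <dbl>        <dbl>          <dbl> <lgl>
#> 1 c01      1.41  0.00000000105 0.0000000126         0.148  FALSE
#> 2 c02     -0.179 0.432         0.647                0.0736 FALSE
#> 3 c03     -0.508 0.0257        0.103                0.0746 FALSE
```

The planted cluster is recovered (logFC 1.41 against a true 1.5) as the
single discovery at FDR ≤ 0.01; `autoplot(diff)` draws the volcano plot.

To train the classifier on clustered events and classify a new
experiment:

```r
# `events` are the per-event image stacks (from simulate_sample(), or
# read_event_images() on exported TIFFs), aligned with the cluster table
labels <- as.character(clusters$table$cluster_id)
split  <- split_dataset(labels, c(0.8, 0.1, 0.1), seed = 1)
model  <- build_network(length(unique(labels)), classifier_config(seed = 1))
model  <- train_classifier(model, events[split$train], labels[split$train],
                           events[split$test], labels[split$test],
                           iterations = 2000, batch_size = 64)
evaluate_classifier(model, events[split$validate], labels[split$validate])
probs  <- classify(model, new_events)   # per-event probability vectors
```

## Command line

The pipeline also runs as restartable stages over on-disk artifacts:

```sh
Rscript inst/cli/image3c.R simulate   --config cfg.yaml
Rscript inst/cli/image3c.R features   --config cfg.yaml
Rscript inst/cli/image3c.R preprocess --config cfg.yaml
Rscript inst/cli/image3c.R cluster    --config cfg.yaml
Rscript inst/cli/image3c.R stats      --config cfg.yaml
```

(after install, the script is at `system.file("cli/image3c.R",
package = "image3c")`). Each stage writes its CSV outputs plus a JSON run
manifest (config hash, seed, input hashes, wall time); identical config
and seed reproduce identical artifacts.

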