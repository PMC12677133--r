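# trajrank

Reference-gene coexpression ranking along diffusion-pseudotime
trajectories in single-cell RNA-seq.

## The problem

Olfactory sensory neurons (OSNs) mature through a linear lineage — globose
basal cells (GBC) → immediate neuronal precursors (INP) → immature OSNs
(iOSN) → mature OSNs (mOSN). Accessory proteins such as Rtp1 are induced
along this axis and are needed for odorant receptors to reach the cell
surface; genes *coregulated* with such a reference gene during maturation
are candidates for the same trafficking machinery. `trajrank` finds them:
it orders cells along a continuous maturation axis (diffusion pseudotime),
summarizes every gene as a binned expression trajectory, and ranks genes
by similarity to the reference gene's trajectory, integrating over four
count representations so that no single normalization biases the call.

## The method

1. **QC / normalization** — mitochondrial-fraction and depth filters;
   counts scaled to 10,000 per cell, then log1p.
2. **Pseudotime** — PCA (40 PCs on highly variable genes, OR genes masked
   from the embedding) → kNN graph (k = 10, adaptive Gaussian kernel) →
   diffusion map (density-normalized operator) → diffusion pseudotime from
   a marker-defined GBC root, rescaled to [0, 1].
3. **Trajectories** — 50 equal-width pseudotime bins; per-gene mean per
   bin under four count forms: normalized (`NORM`), log (`LOG`), and their
   per-gene max-scaled variants (`NORM_MAX`, `LOG_MAX`).
4. **Ranking** — per form, RMSE against the reference gene

   `RMSE_g = sqrt( (1/B) * sum_b (x_gb - x_ref,b)^2 )`

   and 1-based ascending ranks; integration by `topk_hits` (number of
   forms with rank ≤ 50), then mean rank. The reference gene is RMSE 0,
   rank 1 in every form by construction.
5. **Annotation** — onset timing via trajectory AUC (larger = earlier
   onset), early/mid/late terciles, cell-type enrichment (Wilcoxon +
   log2FC), hypergeometric gene-set over-representation, pan-neuronal
   exclusion lists, and overlays from regulatory-network edge lists
   (ER-stress TF interaction counts) and external DE tables.

A negative-binomial lineage simulator with planted coregulated genes,
pan-neuronal genes, a one-receptor-per-mature-cell OR mosaic, and damaged
high-mito cells makes every stage testable end to end. See the methods
vignette (`vignettes/trajectory-coexpression-methods.Rmd`) for the model,
parameter meanings, and design decisions.

## Worked example

```r
library(trajrank)

cfg <- sim_preset("tiny", seed = 42)          # 300 cells x 200 genes
sim <- simulate_lineage(cfg)
res <- run_pipeline(sim$counts,
                    setNames(sim$meta$stage, sim$meta$barcode),
                    pipeline_config(root_markers = sprintf("GbcMark%d", 1:5),
                                    n_hvg = 150, n_pcs = 20, bins = 20,
                                    min_counts = 50))
head(res$rank_table[, c("gene", "rmse_log_max", "mean_rank", "topk_hits")], 8)
```

```
      gene rmse_log_max mean_rank topk_hits
1     Rtp1        0.000      1.00         4
2 Coreg001        0.147      2.75         4
3 Coreg002        0.170      3.75         4
4 Gene0050        0.165      6.25         4
5 Gene0060        0.181      7.25         4
6 Gene0061        0.172      7.25         4
7   Pan005        0.182      8.00         4
8 Coreg006        0.178      8.50         4
```

The reference gene `Rtp1` anchors the table at RMSE 0 / rank 1 in all four
forms; genes planted by the simulator to share its expression program
(`Coreg*`) dominate the top of the integrated ranking, each inside the
top-50 of all four count forms (`topk_hits = 4`). The recovered pseudotime
tracks the simulator's true latent time (Spearman 0.986 here), and the
reference's trajectory AUC of 0.677 reflects its mid-maturation onset:

```r
cor(res$meta$pseudotime,
    sim$meta$latent_time[match(res$meta$barcode, sim$meta$barcode)],
    method = "spearman")   # 0.986
res$auc[["Rtp1"]]          # 0.677
```

Real data enters through `read_counts()` (Matrix Market triplet directory
or dense TSV) with cluster labels from a metadata TSV; a thin CLI wraps
the same functions:

```sh
Rscript inst/cli/trajrank.R simulate --seed 1 --preset default --out sim/
Rscript inst/cli/trajrank.R run-all --counts sim/ --meta sim/cell_meta.tsv \
    --root-markers GbcMark1,GbcMark2 --out run/
Rscript inst/cli/trajrank.R export --run run/ --genes Rtp1,Coreg001 --out exp
```

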