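# Fixture builders shared across test files; everything is generated in
# code so tests carry no binary data.

## small dense count fixture with named axes
toy_counts <- function(values, barcodes = NULL, genes = NULL) {
  m <- as.matrix(values)
  if (is.null(barcodes)) barcodes <- sprintf("c%02d", seq_len(nrow(m)))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(ncol(m)))
  CountMatrix(m, barcodes = barcodes, genes = genes)
}

## hand-built TrajectorySet over B bins (bypasses binning, for ranking and
## timing tests where the trajectories themselves are the fixture)
toy_trajectories <- function(norm_mat, log_mat = log1p(norm_mat)) {
  B <- ncol(norm_mat)
  cf <- make_count_forms(norm_mat, log_mat)
  edges <- seq(0, 1, length.out = B + 1)
  structure(list(forms = cf$forms, zero_genes = cf$zero_genes,
                 edges = edges,
                 midpoints = (edges[-1] + edges[-(B + 1)]) / 2,
                 occupancy = rep(10, B), interpolated = rep(FALSE, B)),
            class = "TrajectorySet")
}

## deterministic cluster labels as run_pipeline expects them
sim_clusters <- function(sim) {
  stats::setNames(sim$meta$stage, sim$meta$barcode)
}

gbc_markers <- function(n = 5) sprintf("GbcMark%d", seq_len(n))

## run the full pipeline on a simulated lineage, returning everything the
## recovery checks need
run_sim_pipeline <- function(seed, preset = "default", ...) {
  cfg <- sim_preset(preset, seed = seed, ...)
  sim <- simulate_lineage(cfg)
  pcfg <- if (preset == "tiny") {
    pipeline_config(root_markers = gbc_markers(), n_hvg = 150, n_pcs = 20,
                    bins = 20, min_counts = 50)
  } else {
    pipeline_config(root_markers = gbc_markers())
  }
  res <- suppressMessages(run_pipeline(sim$counts, sim_clusters(sim), pcfg))
  list(sim = sim, res = res, cfg = cfg)
}
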