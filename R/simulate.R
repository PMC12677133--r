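#' Configuration for the synthetic maturation-lineage simulator
#'
#' The simulator emulates the statistical structure the pipeline relies on:
#' a single linear maturation axis (latent time t ~ Uniform(0,1)) split into
#' four stages (GBC / INP / iOSN / mOSN), per-gene mean programs that are
#' smooth functions of t, negative-binomial counts with log-normal
#' library-size variation, a small mitochondrial gene block with a damaged
#' high-mito cell fraction, a planted block of genes coregulated with the
#' reference gene, planted pan-neuronal genes, and mutually exclusive
#' one-per-cell odorant-receptor-like expression in mature cells.
#'
#' @param n_cells,n_genes dataset size (defaults 3000 x 2000; `n_genes`
#'   counts all genes including the planted blocks).
#' @param n_coreg planted reference-coregulated genes (default 25).
#' @param n_panneuronal planted pan-neuronal genes (default 30).
#' @param n_or odorant-receptor-like genes (default 100).
#' @param n_mito mitochondrial genes (default 10).
#' @param n_root_markers progenitor (GBC) marker genes (default 5).
#' @param stage_boundaries latent-time cut points GBC|INP|iOSN|mOSN.
#' @param phi negative-binomial dispersion (var = m + phi m^2, default 0.3).
#' @param lib_meanlog,lib_sdlog log-normal library-size factor parameters.
#' @param frac_damaged fraction of cells given inflated mitochondrial
#'   content (default 0.03).
#' @param reference_t0,reference_slope,reference_amplitude sigmoid-on
#'   parameters of the reference gene's program.
#' @param coreg_t0_jitter,coreg_slope_jitter spread of the planted
#'   coregulated genes around the reference program (SD of onset time;
#'   log-SD of slope and amplitude).
#' @param or_amplitude mean expression of a mature cell's single active
#'   OR-like gene.
#' @param planted_mode `"coregulated"` plants the coregulated block sharing
#'   the reference program; `"shuffled"` is the negative control: the same
#'   gene names are flagged but their programs are redrawn from dynamics
#'   far from the reference (late pulses and sigmoid-off), destroying the
#'   planted coregulation.
#' @param seed RNG seed; all output is reproducible from it.
#' @return `SimConfig` list.
#' @export
sim_config <- function(n_cells = 3000, n_genes = 2000, n_coreg = 25,
                       n_panneuronal = 30, n_or = 100, n_mito = 10,
                       n_root_markers = 5,
                       stage_boundaries = c(0.25, 0.5, 0.75),
                       phi = 0.3, lib_meanlog = 0, lib_sdlog = 0.3,
                       frac_damaged = 0.03,
                       reference_t0 = 0.35, reference_slope = 12,
                       reference_amplitude = 4,
                       coreg_t0_jitter = 0.015, coreg_slope_jitter = 0.05,
                       or_amplitude = 30,
                       planted_mode = c("coregulated", "shuffled"),
                       seed = 1L) {
  planted_mode <- match.arg(planted_mode)
  cfg <- as.list(environment())
  stopifnot(all(diff(stage_boundaries) > 0),
            all(stage_boundaries > 0 & stage_boundaries < 1),
            phi > 0, n_cells > 0)
  n_special <- 1 + n_coreg + n_panneuronal + n_or + n_mito + n_root_markers
  if (n_special >= n_genes)
    stop("planted gene blocks (", n_special, ") exceed n_genes (",
         n_genes, ")")
  structure(cfg, class = "SimConfig")
}

#' Simulator presets
#'
#' `default` is the study condition used by the validation suite; `tiny`
#' is a fast variant for unit tests and examples; `stress` increases noise
#' (higher dispersion, stronger library-size spread, more damaged cells).
#'
#' @param preset one of `"default"`, `"tiny"`, `"stress"`.
#' @param ... overrides forwarded to [sim_config()].
#' @return `SimConfig`.
#' @export
sim_preset <- function(preset = c("default", "tiny", "stress"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    default = list(),
    tiny = list(n_cells = 300, n_genes = 200, n_coreg = 8,
                n_panneuronal = 6, n_or = 12, n_mito = 5),
    stress = list(phi = 0.6, lib_sdlog = 0.6, frac_damaged = 0.08))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

## template mean functions of latent time
tpl_value <- function(template, t, t0, slope, amplitude, baseline) {
  core <- switch(template,
    "sigmoid-on" = amplitude / (1 + exp(-slope * (t - t0))),
    "sigmoid-off" = amplitude / (1 + exp(slope * (t - t0))),
    "pulse" = amplitude * exp(-((t - t0)^2) / (2 * (2 / slope)^2)),
    "constant" = rep(amplitude, length(t)),
    stop("unknown template ", template))
  core + baseline
}

#' Simulate a maturation-lineage scRNA-seq dataset
#'
#' See [sim_config()] for the generative model. Counts for gene g in cell c
#' are NB(mean = L_c * mu_g(t_c), dispersion phi) with mu_g the gene's
#' template program; mature-stage cells additionally express exactly one
#' OR-like gene each at high amplitude (a floor on that draw guarantees the
#' chosen receptor is detectable); damaged cells have their mitochondrial
#' means inflated so the QC filter has true positives to find.
#'
#' @param cfg `SimConfig` from [sim_config()] / [sim_preset()].
#' @return `list(counts = CountMatrix, meta, truth)`. `meta` has barcode,
#'   true `latent_time`, `stage`, and `is_damaged`; `truth` ("SimTruth") has
#'   one row per gene with template parameters and planted-block flags.
#' @export
simulate_lineage <- function(cfg) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  n <- cfg$n_cells
  t <- stats::runif(n)
  stage <- cut(t, breaks = c(0, cfg$stage_boundaries, 1),
               labels = c("GBC", "INP", "iOSN", "mOSN"),
               include.lowest = TRUE)
  libsize <- stats::rlnorm(n, cfg$lib_meanlog, cfg$lib_sdlog)
  damaged <- stats::runif(n) < cfg$frac_damaged

  truth <- sim_truth(cfg)
  g <- nrow(truth)

  ## per-gene mean program over cells (cells x genes)
  mu <- matrix(0, n, g)
  for (j in seq_len(g)) {
    mu[, j] <- tpl_value(truth$template[j], t, truth$t0[j],
                         truth$slope[j], truth$amplitude[j],
                         truth$baseline[j])
  }
  ## OR mosaic: zero outside mOSN, one receptor per mature cell
  or_idx <- which(truth$is_or)
  if (length(or_idx)) {
    mu[, or_idx] <- 0
    mature <- which(stage == "mOSN")
    chosen <- or_idx[sample.int(length(or_idx), length(mature),
                                replace = TRUE)]
    mu[cbind(mature, chosen)] <- cfg$or_amplitude
  }
  ## damaged cells: inflate mitochondrial means well past typical QC cuts
  mito_idx <- which(truth$is_mito)
  if (any(damaged) && length(mito_idx))
    mu[damaged, mito_idx] <- mu[damaged, mito_idx] * 150

  mu <- mu * libsize
  counts <- matrix(stats::rnbinom(n * g, mu = mu, size = 1 / cfg$phi), n, g)
  ## guarantee the chosen receptor is observed in every mature cell
  if (length(or_idx)) {
    drawn <- counts[cbind(mature, chosen)]
    counts[cbind(mature, chosen)] <- pmax(drawn, 5L)
  }
  barcodes <- sprintf("cell_%04d", seq_len(n))
  m <- CountMatrix(counts, barcodes = barcodes, genes = truth$gene)
  meta <- data.frame(barcode = barcodes, latent_time = t,
                     stage = as.character(stage), is_damaged = damaged,
                     stringsAsFactors = FALSE)
  list(counts = m, meta = meta, truth = truth)
}

## draw the per-gene generative ground truth (assumes RNG already seeded)
sim_truth <- function(cfg) {
  n_bg <- cfg$n_genes - 1 - cfg$n_coreg - cfg$n_panneuronal - cfg$n_or -
    cfg$n_mito - cfg$n_root_markers
  gene <- c("Rtp1",
            sprintf("Coreg%03d", seq_len(cfg$n_coreg)),
            sprintf("Pan%03d", seq_len(cfg$n_panneuronal)),
            sprintf("Olfr%04d", seq_len(cfg$n_or)),
            sprintf("mt-Sim%02d", seq_len(cfg$n_mito)),
            sprintf("GbcMark%d", seq_len(cfg$n_root_markers)),
            sprintf("Gene%04d", seq_len(n_bg)))
  g <- length(gene)
  truth <- data.frame(gene = gene,
                      template = NA_character_, t0 = NA_real_,
                      slope = NA_real_, amplitude = NA_real_,
                      baseline = NA_real_,
                      is_reference = FALSE, is_coreg = FALSE,
                      is_panneuronal = FALSE, is_or = FALSE,
                      is_mito = FALSE, is_root_marker = FALSE,
                      stringsAsFactors = FALSE)
  blk <- function(flag, n_prev, n_blk)
    truth[[flag]][n_prev + seq_len(n_blk)] <<- TRUE
  at <- 0
  truth$is_reference[1] <- TRUE; at <- 1
  blk("is_coreg", at, cfg$n_coreg); at <- at + cfg$n_coreg
  blk("is_panneuronal", at, cfg$n_panneuronal); at <- at + cfg$n_panneuronal
  blk("is_or", at, cfg$n_or); at <- at + cfg$n_or
  blk("is_mito", at, cfg$n_mito); at <- at + cfg$n_mito
  blk("is_root_marker", at, cfg$n_root_markers)

  ## reference program
  i <- which(truth$is_reference)
  truth[i, c("template", "t0", "slope", "amplitude", "baseline")] <-
    list("sigmoid-on", cfg$reference_t0, cfg$reference_slope,
         cfg$reference_amplitude, 0.05 * cfg$reference_amplitude)

  ## planted coregulated block: shares the reference (t0, slope) within
  ## jitter; amplitude varies modestly (coexpression is about shape)
  i <- which(truth$is_coreg)
  if (cfg$planted_mode == "coregulated") {
    truth$template[i] <- "sigmoid-on"
    truth$t0[i] <- cfg$reference_t0 +
      stats::rnorm(length(i), 0, cfg$coreg_t0_jitter)
    truth$slope[i] <- cfg$reference_slope *
      exp(stats::rnorm(length(i), 0, cfg$coreg_slope_jitter))
    truth$amplitude[i] <- cfg$reference_amplitude *
      exp(stats::rnorm(length(i), 0, 0.15))
  } else {                       # negative control: far-from-reference
    truth$template[i] <- sample(c("sigmoid-off", "pulse"), length(i),
                                replace = TRUE)
    truth$t0[i] <- ifelse(truth$template[i] == "pulse",
                          stats::runif(length(i), 0.8, 0.95),
                          stats::runif(length(i), 0.05, 0.15))
    truth$slope[i] <- stats::runif(length(i), 10, 20)
    truth$amplitude[i] <- cfg$reference_amplitude *
      exp(stats::rnorm(length(i), 0, 0.15))
  }
  truth$baseline[i] <- 0.05 * truth$amplitude[i]

  ## pan-neuronal: maturation-onset genes with broadly varying timing
  i <- which(truth$is_panneuronal)
  truth$template[i] <- "sigmoid-on"
  truth$t0[i] <- stats::runif(length(i), 0.2, 0.55)
  truth$slope[i] <- stats::runif(length(i), 6, 18)
  truth$amplitude[i] <- stats::rlnorm(length(i), log(3), 0.3)
  truth$baseline[i] <- 0.05 * truth$amplitude[i]

  ## OR-like genes: handled as a mosaic at count generation
  i <- which(truth$is_or)
  truth[i, c("template", "t0", "slope", "amplitude", "baseline")] <-
    list("constant", NA_real_, NA_real_, 0, 0)

  ## mitochondrial block: constant housekeeping-level expression
  i <- which(truth$is_mito)
  truth$template[i] <- "constant"
  truth$amplitude[i] <- stats::rlnorm(length(i), log(1.5), 0.2)
  truth$baseline[i] <- 0

  ## progenitor markers: high at t = 0, switching off early
  i <- which(truth$is_root_marker)
  truth[i, c("template", "slope")] <- list("sigmoid-off", 15)
  truth$t0[i] <- 0.15
  truth$amplitude[i] <- 3
  truth$baseline[i] <- 0.05

  ## background genes: a mixture of dynamics across the lineage
  i <- which(is.na(truth$template))
  tpl <- sample(c("sigmoid-on", "sigmoid-off", "pulse", "constant"),
                length(i), replace = TRUE, prob = c(0.35, 0.2, 0.2, 0.25))
  truth$template[i] <- tpl
  truth$t0[i] <- stats::runif(length(i), 0.05, 0.95)
  truth$slope[i] <- stats::runif(length(i), 6, 20)
  truth$amplitude[i] <- stats::rlnorm(length(i), log(2), 0.6)
  truth$baseline[i] <- truth$amplitude[i] *
    stats::runif(length(i), 0.01, 0.1)
  truth
}

#' Simulate a companion "neuron vs other" tissue dataset
#'
#' A second dataset in the spirit of an olfactory-bulb reference: two
#' clusters, with the pan-neuronal planted genes strongly enriched in the
#' `Neuron` cluster and every other gene exchangeable between clusters.
#' Running [enrichment_scores()] on it yields the pan-neuronal exclusion
#' list for [filter_panneuronal()].
#'
#' @param truth `SimTruth` from [simulate_lineage()] (gene axis is reused).
#' @param n_cells total cells (default 600, half per cluster).
#' @param phi NB dispersion (default 0.3).
#' @param seed RNG seed.
#' @return `list(counts = CountMatrix, meta)` with `cluster` in
#'   `c("Neuron", "Other")`.
#' @export
simulate_bulb <- function(truth, n_cells = 600, phi = 0.3, seed = 1L) {
  set.seed(seed)
  g <- nrow(truth)
  cl <- rep(c("Neuron", "Other"), length.out = n_cells)
  base_mu <- ifelse(is.na(truth$amplitude), 0.5,
                    pmax(truth$amplitude * 0.3, 0.05))
  mu <- matrix(rep(base_mu, each = n_cells), n_cells, g)
  pan <- which(truth$is_panneuronal)
  mu[cl == "Neuron", pan] <- mu[cl == "Neuron", pan] * 20
  libsize <- stats::rlnorm(n_cells, 0, 0.2)
  counts <- matrix(stats::rnbinom(n_cells * g, mu = mu * libsize,
                                  size = 1 / phi), n_cells, g)
  barcodes <- sprintf("bulb_%04d", seq_len(n_cells))
  meta <- data.frame(barcode = barcodes, cluster = cl,
                     stringsAsFactors = FALSE)
  list(counts = CountMatrix(counts, barcodes = barcodes,
                            genes = truth$gene),
       meta = meta)
}

#' Write simulator output as a fixture directory
#'
#' Matrix Market triplet plus metadata and ground-truth TSVs, re-readable
#' with [read_counts()] with an exact count round trip.
#'
#' @param sim output of [simulate_lineage()].
#' @param out_dir target directory.
#' @param overwrite allow writing into a non-empty directory.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, out_dir, overwrite = FALSE) {
  if (dir.exists(out_dir) && length(dir(out_dir)) && !overwrite)
    stop("directory ", out_dir, " is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, out_dir, dialect = "mtx")
  data.table::fwrite(sim$meta, file.path(out_dir, "cell_meta.tsv"),
                     sep = "\t")
  if (!is.null(sim$truth))
    data.table::fwrite(sim$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t")
  invisible(out_dir)
}
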