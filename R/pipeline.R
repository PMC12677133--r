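#' Pipeline configuration
#'
#' Every tunable of the end-to-end run with its default: 10,000-count depth
#' normalization, 40 principal components, 10 nearest neighbors, 15
#' diffusion components, 50 pseudotime bins, top-50 integration. The
#' effective configuration is logged and hashed into every output table so
#' a run can be reproduced exactly.
#'
#' @param reference_gene gene whose trajectory anchors the RMSE ranking.
#' @param root_cluster progenitor cluster anchoring pseudotime 0.
#' @param root_markers marker genes used to pick the root cell within the
#'   root cluster.
#' @param target_depth per-cell total after depth normalization.
#' @param max_mito,min_counts QC thresholds (see [filter_cells()]).
#' @param n_hvg highly variable genes kept for embedding.
#' @param n_pcs,k,n_comps embedding / graph / diffusion sizes.
#' @param bins,min_cells_bin pseudotime binning (see [assign_bins()]).
#' @param top_k per-form top-list size for rank integration.
#' @param mito_patterns,global_exclude_patterns,embedding_exclude_patterns
#'   gene-symbol patterns for QC and exclusion ([exclude_genes()]).
#' @param panneuronal optional pan-neuronal exclusion symbols.
#' @param seed RNG seed recorded with the run (the pipeline itself is
#'   deterministic; the seed matters when the input is simulated).
#' @return `PipelineConfig` list.
#' @export
pipeline_config <- function(reference_gene = "Rtp1",
                            root_cluster = "GBC",
                            root_markers = NULL,
                            target_depth = 1e4,
                            max_mito = 0.2, min_counts = 500,
                            n_hvg = 2000, n_pcs = 40, k = 10,
                            n_comps = 15, bins = 50, min_cells_bin = 3,
                            top_k = 50,
                            mito_patterns = "mt-",
                            global_exclude_patterns = c("mt-", "Malat"),
                            embedding_exclude_patterns = or_gene_patterns(),
                            panneuronal = NULL,
                            seed = 1L) {
  structure(as.list(environment()), class = "PipelineConfig")
}

## stable short hash of the effective configuration
config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(utils::capture.output(utils::str(cfg)), f)
  unname(substr(tools::md5sum(f), 1, 12))
}

pipeline_version <- function() {
  as.character(utils::packageVersion("trajrank"))
}

stage_msg <- function(stage, ...) {
  message(sprintf("[trajrank:%s] %s", stage, paste0(...)))
}

#' Run the full coexpression-discovery pipeline
#'
#' Stages, in order: QC -> cell filtering -> global gene exclusion ->
#' depth normalization -> log transform -> HVG selection -> PCA -> kNN
#' graph -> diffusion map -> root selection -> diffusion pseudotime ->
#' binning -> four-form trajectories -> per-form RMSE vs the reference ->
#' rank integration -> pan-neuronal filtering. Any stage failure aborts
#' with a stage-named error. Output is deterministic given the input and
#' configuration.
#'
#' @param m a [CountMatrix].
#' @param clusters per-cell cluster labels: named vector (by barcode) or a
#'   data.frame with `barcode`/`cluster` columns.
#' @param cfg `PipelineConfig` (default [pipeline_config()]).
#' @return List with `meta` (QC + pseudotime + bin), `trajectories`
#'   (`TrajectorySet`), `rank_table`, `auc`, `onset`, `embedding`,
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(m, clusters, cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  t_start <- proc.time()[["elapsed"]]
  if (!cfg$reference_gene %in% colnames(m))
    stop("reference gene '", cfg$reference_gene, "' absent from the matrix")

  stage_msg("qc", "computing per-cell QC")
  meta <- run_stage("qc", compute_qc(m, cfg$mito_patterns, clusters))
  flt <- run_stage("qc", filter_cells(m, meta, cfg$max_mito, cfg$min_counts))
  stage_msg("qc", sprintf("%d/%d cells retained (max_mito=%g, min_counts=%d)",
                          nrow(flt$counts), nrow(m), cfg$max_mito,
                          cfg$min_counts))
  m2 <- run_stage("qc", exclude_genes(flt$counts,
                                      cfg$global_exclude_patterns,
                                      purpose = "global"))
  if (!cfg$reference_gene %in% colnames(m2))
    stop("reference gene was removed by global exclusion patterns")
  meta <- flt$meta

  stage_msg("normalize", "depth-normalizing to ", cfg$target_depth,
            " counts per cell")
  xn <- run_stage("normalize", normalize_depth(m2, cfg$target_depth))
  xl <- run_stage("normalize", log_transform(xn))

  stage_msg("embed", "selecting HVGs and embedding")
  emb_keep <- run_stage("embed", {
    hvg <- select_hvg(xn, min(cfg$n_hvg, ncol(xn)))
    or_keep <- exclude_genes(m2, cfg$embedding_exclude_patterns,
                             purpose = "embedding")
    hvg & or_keep
  })
  emb <- run_stage("embed", {
    n_pcs <- min(cfg$n_pcs, nrow(xl) - 1L, sum(emb_keep) - 1L)
    pca_embed(xl[, emb_keep, drop = FALSE], n_pcs = n_pcs)
  })

  stage_msg("dpt", "diffusion map and pseudotime (k=", cfg$k,
            ", n_comps=", cfg$n_comps, ")")
  dif <- run_stage("dpt", diffusion_map(knn_graph(emb, cfg$k), cfg$n_comps))
  root <- run_stage("dpt", select_root(xn, meta, cfg$root_cluster,
                                       cfg$root_markers, diffusion = dif))
  pt <- run_stage("dpt", compute_dpt(dif, root))
  meta$pseudotime <- unname(pt)

  stage_msg("bin", "binning into ", cfg$bins, " pseudotime bins")
  bins <- run_stage("bin", assign_bins(meta$pseudotime, cfg$bins,
                                       cfg$min_cells_bin))
  meta$bin <- bins$bin
  traj <- run_stage("forms", bin_trajectories(xn, xl, bins))

  stage_msg("rank", "RMSE ranking against ", cfg$reference_gene)
  rt <- run_stage("integrate",
                  integrate_ranks(traj, cfg$reference_gene, cfg$top_k))
  if (!is.null(cfg$panneuronal)) {
    rt <- run_stage("filter", filter_panneuronal(rt, cfg$panneuronal))
    stage_msg("filter", sum(rt$excluded_panneuronal),
              " pan-neuronal genes excluded")
  }

  auc <- run_stage("annotate", trajectory_auc(traj))
  onset <- run_stage("annotate", onset_category(auc))
  stage_msg("done", sprintf("finished in %.1f s",
                            proc.time()[["elapsed"]] - t_start))
  list(meta = meta, trajectories = traj, rank_table = rt, auc = auc,
       onset = onset, embedding = emb, root = root, config = cfg,
       config_hash = config_hash(cfg))
}

#' Export browsable trajectory tables
#'
#' Long-format record per (gene, count form, pseudotime bin) with the bin's
#' pseudotime midpoint, trajectory value, interpolation flag, and the
#' gene's integrated rank metadata — the contract a trajectory-browser
#' front end consumes. The JSON mirror contains exactly the TSV's records.
#'
#' @param t `TrajectorySet`.
#' @param rt RankTable.
#' @param genes optional subset of gene symbols (order honored); genes not
#'   present are collected in the `skipped` element rather than failing.
#' @param out_prefix if non-NULL, writes `<prefix>.tsv` and
#'   `<prefix>.json` with a provenance header.
#' @param header optional comment lines for the TSV.
#' @return `list(records, skipped, json)`; `records` is the long
#'   data.frame, `json` the serialized string.
#' @export
export_trajectories <- function(t, rt, genes = NULL, out_prefix = NULL,
                                header = NULL) {
  all_genes <- rownames(t$forms$NORM)
  if (is.null(genes)) genes <- all_genes
  skipped <- setdiff(genes, all_genes)
  genes <- genes[genes %in% all_genes]
  mids <- t$midpoints
  B <- length(mids)
  recs <- list()
  meta_idx <- match(genes, rt$gene)
  for (gi in seq_along(genes)) {
    g <- genes[gi]
    for (f in count_form_ids()) {
      tr <- t$forms[[f]]
      if (!g %in% rownames(tr)) next
      recs[[length(recs) + 1]] <- data.frame(
        gene = g, form = f, bin = seq_len(B) - 1L,
        pseudotime_midpoint = mids, value = unname(tr[g, ]),
        interpolated = t$interpolated,
        mean_rank = rt$mean_rank[meta_idx[gi]],
        topk_hits = rt$topk_hits[meta_idx[gi]],
        candidate_rank = rt$candidate_rank[meta_idx[gi]],
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  json <- jsonlite::toJSON(records, dataframe = "rows", digits = NA,
                           na = "null")
  if (!is.null(out_prefix)) {
    write_tsv_with_header(records, paste0(out_prefix, ".tsv"), header)
    writeLines(json, paste0(out_prefix, ".json"))
  }
  list(records = records, skipped = skipped, json = json)
}

#' Serialize a TrajectorySet as a long TSV
#'
#' @param t `TrajectorySet`.
#' @param path output file.
#' @param header optional comment lines.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(t, path, header = NULL) {
  mids <- t$midpoints
  B <- length(mids)
  out <- do.call(rbind, lapply(count_form_ids(), function(f) {
    tr <- t$forms[[f]]
    data.frame(gene = rep(rownames(tr), each = B), form = f,
               bin = rep(seq_len(B) - 1L, nrow(tr)),
               pseudotime_midpoint = rep(mids, nrow(tr)),
               value = as.vector(t(tr)),
               interpolated = rep(t$interpolated, nrow(tr)),
               stringsAsFactors = FALSE)
  }))
  write_tsv_with_header(out, path, header)
}

#' Read a plain key=value configuration file
#'
#' Lines of `key = value` (comments with `#`); values are parsed as
#' numbers, logicals, or comma-separated character vectors. Returns a
#' [pipeline_config()] with the file's overrides applied.
#'
#' @param path config file.
#' @param ... further overrides applied after the file.
#' @return `PipelineConfig`.
#' @export
read_pipeline_config <- function(path, ...) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed config line(s): ",
                     paste(lines[bad], collapse = "; "))
  vals <- lapply(kv, function(p) parse_config_value(p[2]))
  names(vals) <- vapply(kv, `[[`, "", 1)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  do.call(pipeline_config, utils::modifyList(vals, list(...)))
}

parse_config_value <- function(v) {
  if (grepl(",", v)) return(trimws(strsplit(v, ",")[[1]]))
  if (toupper(v) %in% c("TRUE", "FALSE")) return(as.logical(v))
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(num)
  v
}
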