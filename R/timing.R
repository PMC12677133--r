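#' Trajectory area under the curve (expression onset score)
#'
#' Integrates a gene's max-scaled trajectory over pseudotime (trapezoid
#' rule over bin midpoints) and normalizes by the midpoint span, so a gene
#' expressed at its maximum throughout scores 1 and a gene switching on at
#' pseudotime 0.5 scores about 0.5. Larger AUC therefore means earlier
#' onset along maturation.
#'
#' @param t a `TrajectorySet`.
#' @param form max-scaled count form to integrate (default `"LOG_MAX"`).
#' @return Named numeric vector in `[0, 1]`, genes with zero-flagged
#'   trajectories absent.
#' @export
trajectory_auc <- function(t, form = "LOG_MAX") {
  stopifnot(form %in% c("NORM_MAX", "LOG_MAX"))
  tr <- t$forms[[form]]
  x <- t$midpoints
  span <- max(x) - min(x)
  dx <- diff(x)
  left <- tr[, -ncol(tr), drop = FALSE]
  right <- tr[, -1, drop = FALSE]
  auc <- as.vector((left + right) %*% dx / 2) / span
  stats::setNames(auc, rownames(tr))
}

#' Classify genes into onset terciles
#'
#' Partitions genes into early / mid / late onset by AUC quantiles: the top
#' tercile of AUC (earliest onset) is `early`, the bottom `late`. With
#' fewer than 3 genes everything is `mid` (with a warning). Quantile
#' boundaries use type-7 quantiles; genes exactly on a boundary fall into
#' the earlier (higher-AUC) class.
#'
#' @param auc named vector from [trajectory_auc()].
#' @param quantiles lower/upper probability cut points (default 1/3, 2/3).
#' @return Named factor with levels `early`, `mid`, `late`.
#' @export
onset_category <- function(auc, quantiles = c(1 / 3, 2 / 3)) {
  stopifnot(length(quantiles) == 2, quantiles[1] < quantiles[2])
  if (length(auc) < 3) {
    warning("fewer than 3 genes; all classified 'mid'")
    return(stats::setNames(
      factor(rep("mid", length(auc)), levels = c("early", "mid", "late")),
      names(auc)))
  }
  qs <- stats::quantile(auc, probs = quantiles, names = FALSE)
  cls <- ifelse(auc >= qs[2], "early", ifelse(auc < qs[1], "late", "mid"))
  stats::setNames(factor(cls, levels = c("early", "mid", "late")),
                  names(auc))
}

#' Cell-type enrichment of every gene
#'
#' Compares each gene's depth-normalized expression in a target cluster
#' (e.g. mature OSNs) against all other cells: log2 fold change with a
#' pseudocount, a two-sided Wilcoxon rank-sum p-value, and
#' Benjamini-Hochberg FDR. The attached top list holds the `n_top` genes by
#' fold change among those with FDR < 0.05 — the construction used both for
#' the mOSN-enriched gene set and for deriving a pan-neuronal exclusion
#' list from a second (olfactory-bulb) dataset.
#'
#' @param x depth-normalized cell x gene matrix.
#' @param meta QC table with `cluster`.
#' @param target_cluster cluster defining the enrichment foreground.
#' @param n_top size of the attached top list (default 100).
#' @param eps pseudocount in the fold change (default 1e-9).
#' @return `data.frame` with `gene`, `mean_target`, `mean_rest`,
#'   `enrich_lfc`, `enrich_p`, `enrich_fdr`, `enrich_rank`; attribute
#'   `top_genes` carries the top list.
#' @export
enrichment_scores <- function(x, meta, target_cluster, n_top = 100,
                              eps = 1e-9) {
  stopifnot(nrow(x) == nrow(meta))
  in_t <- !is.na(meta$cluster) & meta$cluster == target_cluster
  if (sum(in_t) < 3)
    stop("target cluster '", target_cluster, "' has fewer than 3 cells")
  if (sum(!in_t) < 3) stop("fewer than 3 background cells")
  xt <- x[in_t, , drop = FALSE]
  xr <- x[!in_t, , drop = FALSE]
  mt <- Matrix::colMeans(xt)
  mr <- Matrix::colMeans(xr)
  lfc <- log2((mt + eps) / (mr + eps))
  p <- vapply(seq_len(ncol(x)), function(j) {
    a <- as.numeric(xt[, j]); b <- as.numeric(xr[, j])
    if (all(a == a[1]) && all(b == a[1])) return(1)
    # ties are ubiquitous in count data; the normal approximation applies
    suppressWarnings(stats::wilcox.test(a, b)$p.value)
  }, numeric(1))
  fdr <- stats::p.adjust(p, method = "BH")
  out <- data.frame(gene = colnames(x), mean_target = unname(mt),
                    mean_rest = unname(mr), enrich_lfc = unname(lfc),
                    enrich_p = unname(p), enrich_fdr = unname(fdr),
                    stringsAsFactors = FALSE)
  out$enrich_rank <- integer(nrow(out))
  out$enrich_rank[order(-out$enrich_lfc, out$gene)] <- seq_len(nrow(out))
  sig <- out[out$enrich_fdr < 0.05, , drop = FALSE]
  sig <- sig[order(-sig$enrich_lfc, sig$gene), , drop = FALSE]
  attr(out, "top_genes") <- utils::head(sig$gene, n_top)
  out
}

#' Correlate onset timing with external differential expression
#'
#' Pearson correlation (and its two-sided p-value) between trajectory AUC
#' and an external DE table's log fold change over the shared genes —
#' quantifying, e.g., whether early-onset genes are the ones enriched under
#' ER stress.
#'
#' @param auc named AUC vector from [trajectory_auc()].
#' @param de DE table with `gene` and `logfc` columns.
#' @return `list(r, p, n)`.
#' @export
correlate_onset_with_de <- function(auc, de) {
  shared <- intersect(names(auc), de$gene)
  if (length(shared) < 3) stop("fewer than 3 shared genes")
  lf <- de$logfc[match(shared, de$gene)]
  ct <- stats::cor.test(auc[shared], lf, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Gene-set over-representation test
#'
#' One-sided hypergeometric test per set: with universe size M, set size K
#' (after intersecting with the universe), selection size n and overlap k,
#' p = P(X >= k). BH correction across sets.
#'
#' @param selected gene symbols of interest (must lie in `universe`).
#' @param collection named list of gene sets.
#' @param universe background gene symbols.
#' @return `data.frame` with `set`, `set_size`, `overlap`, `pvalue`, `fdr`,
#'   sorted by p-value.
#' @export
ora_test <- function(selected, collection, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  bad <- setdiff(selected, universe)
  if (length(bad))
    stop("selected genes outside the universe: ",
         paste(utils::head(bad, 5), collapse = ", "))
  selected <- unique(selected)
  M <- length(universe)
  n <- length(selected)
  res <- lapply(names(collection), function(nm) {
    set <- intersect(collection[[nm]], universe)
    K <- length(set)
    k <- length(intersect(selected, set))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  out[order(out$pvalue, out$set), , drop = FALSE]
}

#' Read a differential-expression table
#'
#' TSV with required columns `gene`, `logfc`, `pvalue`; `fdr` is recomputed
#' by Benjamini-Hochberg when absent.
#'
#' @param path TSV file.
#' @return `data.frame` with `gene`, `logfc`, `pvalue`, `fdr`.
#' @export
read_de_table <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  names(dt) <- tolower(names(dt))
  need <- c("gene", "logfc", "pvalue")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("DE table missing column(s): ", paste(miss, collapse = ", "),
         "; header was: ", paste(names(dt), collapse = ", "))
  df <- as.data.frame(dt)
  if (!"fdr" %in% names(df))
    df$fdr <- stats::p.adjust(df$pvalue, method = "BH")
  df[, c("gene", "logfc", "pvalue", "fdr")]
}
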