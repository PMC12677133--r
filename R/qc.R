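#' Per-cell quality-control metrics
#'
#' Computes total counts and the mitochondrial fraction for every cell.
#' Mitochondrial genes are recognized by symbol prefix (mouse convention
#' `mt-`; pass `"MT-"` for human data). Cells with zero total counts get
#' `mito_frac = 0` and are flagged so downstream filtering can drop them.
#'
#' @param m a [CountMatrix].
#' @param mito_patterns character vector of gene-symbol prefixes treated as
#'   mitochondrial.
#' @param clusters optional named character vector (names = barcodes) or a
#'   data.frame with `barcode` and `cluster` columns supplying cluster
#'   labels from upstream annotation.
#' @return A `data.frame` (one row per cell, matrix order) with columns
#'   `barcode`, `cluster`, `total_counts`, `mito_frac`, `flag_zero_total`,
#'   plus `pseudotime` and `bin` placeholders filled later.
#' @export
compute_qc <- function(m, mito_patterns = "mt-", clusters = NULL) {
  stopifnot(length(mito_patterns) > 0)
  x <- cm_mat(m)
  total <- Matrix::rowSums(x)
  is_mito <- prefix_match(colnames(x), mito_patterns)
  mito <- if (any(is_mito)) {
    Matrix::rowSums(x[, is_mito, drop = FALSE])
  } else rep(0, nrow(x))
  frac <- ifelse(total > 0, mito / pmax(total, 1), 0)
  cl <- rep(NA_character_, nrow(x))
  if (!is.null(clusters)) {
    if (is.data.frame(clusters)) {
      clusters <- stats::setNames(as.character(clusters$cluster),
                                  clusters$barcode)
    }
    cl <- unname(clusters[rownames(x)])
  }
  data.frame(barcode = rownames(x), cluster = cl,
             total_counts = unname(total), mito_frac = unname(frac),
             flag_zero_total = unname(total == 0),
             pseudotime = NA_real_, bin = NA_integer_,
             stringsAsFactors = FALSE)
}

## prefix match against gene symbols; patterns are literal prefixes
prefix_match <- function(symbols, patterns) {
  hit <- rep(FALSE, length(symbols))
  for (p in patterns) hit <- hit | startsWith(symbols, p)
  hit
}

## regex-or-prefix match: a pattern containing regex metacharacters is used
## as an anchored regular expression, otherwise as a literal prefix
pattern_match <- function(symbols, patterns) {
  hit <- rep(FALSE, length(symbols))
  for (p in patterns) {
    if (grepl("[][(){}.*+?^$|\\\\]", p)) {
      hit <- hit | grepl(paste0("^(", p, ")"), symbols)
    } else {
      hit <- hit | startsWith(symbols, p)
    }
  }
  hit
}

#' Remove low-quality cells
#'
#' Keeps cells with `mito_frac <= max_mito` and `total_counts >= min_counts`.
#' Defaults follow common droplet-data practice; the thresholds are always
#' reported in the returned attributes so a run's effective QC is auditable.
#'
#' @param m a [CountMatrix].
#' @param meta matching QC table from [compute_qc()].
#' @param max_mito maximum tolerated mitochondrial fraction (default 0.2).
#' @param min_counts minimum per-cell total counts (default 500).
#' @return `list(counts = CountMatrix, meta = data.frame)` restricted to
#'   surviving cells, original order preserved; attribute `n_removed` on the
#'   meta records the drop count.
#' @export
filter_cells <- function(m, meta, max_mito = 0.2, min_counts = 500) {
  stopifnot(identical(meta$barcode, rownames(m)))
  keep <- meta$mito_frac <= max_mito & meta$total_counts >= min_counts
  if (!any(keep))
    stop("all ", nrow(meta), " cells removed by QC; review max_mito (",
         max_mito, ") and min_counts (", min_counts, ")")
  out_m <- CountMatrix(cm_mat(m)[keep, , drop = FALSE])
  out_meta <- meta[keep, , drop = FALSE]
  rownames(out_meta) <- NULL
  attr(out_meta, "n_removed") <- sum(!keep)
  list(counts = out_m, meta = out_meta)
}

#' Flag or remove genes by symbol pattern
#'
#' Two purposes mirror how noisy gene families are handled: `"global"`
#' removal (e.g. mitochondrial and Malat transcripts, dropped from the data
#' entirely) and `"embedding"`-only masking (e.g. odorant-receptor genes,
#' kept in trajectories but excluded from dimensionality reduction so the
#' one-receptor-per-neuron mosaic does not distort the manifold).
#'
#' @param m a [CountMatrix].
#' @param patterns symbol prefixes or anchored regular expressions.
#' @param purpose `"embedding"` returns a logical keep-mask over genes;
#'   `"global"` returns a reduced [CountMatrix].
#' @param whitelist symbols never excluded even if they match.
#' @return Logical mask (named by gene, `TRUE` = keep) or a [CountMatrix].
#' @export
exclude_genes <- function(m, patterns,
                          purpose = c("embedding", "global"),
                          whitelist = NULL) {
  purpose <- match.arg(purpose)
  stopifnot(length(patterns) > 0)
  genes <- colnames(m)
  drop <- pattern_match(genes, patterns)
  if (!is.null(whitelist)) drop <- drop & !(genes %in% whitelist)
  if (!any(drop))
    warning("gene exclusion patterns matched no genes")
  keep <- !drop
  names(keep) <- genes
  if (purpose == "embedding") return(keep)
  CountMatrix(cm_mat(m)[, keep, drop = FALSE])
}

#' Default odorant-receptor symbol patterns
#'
#' Mouse OR genes under both the legacy `Olfr` and the systematic `Or...`
#' nomenclature; the `Or` form is matched as `Or` + digit to avoid
#' swallowing unrelated symbols.
#' @return Character vector of patterns for [exclude_genes()].
#' @export
or_gene_patterns <- function() c("Olfr", "Or[0-9]")

#' Depth-normalize counts
#'
#' Rescales every cell to the same total (default 10,000 counts) so
#' expression is comparable across sequencing depths; within-cell
#' proportions are untouched.
#'
#' @param m a [CountMatrix] (or any nonnegative cell x gene matrix).
#' @param target per-cell total after scaling.
#' @return Sparse real matrix, same dimensions and dimnames.
#' @export
normalize_depth <- function(m, target = 1e4) {
  stopifnot(target > 0)
  x <- if (methods::is(m, "Matrix")) cm_mat(m) else
    Matrix::Matrix(m, sparse = TRUE)
  total <- Matrix::rowSums(x)
  if (any(total == 0))
    stop("zero-total cell(s) present, e.g. ",
         rownames(x)[which(total == 0)[1]],
         "; filter cells before normalizing")
  Matrix::Diagonal(x = target / total) %*% x
}

#' Log-transform expression values
#'
#' Elementwise `log(1 + x)`; zero-preserving (sparsity is kept) and strictly
#' monotone, the standard variance-stabilizing step after depth
#' normalization.
#'
#' @param x nonnegative matrix (sparse or dense).
#' @return Matrix of the same shape.
#' @export
log_transform <- function(x) {
  mn <- if (methods::is(x, "sparseMatrix")) {
    if (length(x@x)) min(x@x) else 0
  } else min(x)
  if (mn < 0) stop("log transform requires nonnegative entries")
  log1p(x)
}

#' Select highly variable genes
#'
#' Ranks genes by normalized dispersion: dispersion = variance / mean on the
#' depth-normalized matrix, z-scored within bins of comparable mean
#' expression so the mean-variance trend of count data does not dominate.
#' Ties break by gene symbol for determinism.
#'
#' @param x depth-normalized cell x gene matrix.
#' @param n_top number of genes to keep.
#' @param n_bins number of mean-expression bins (default 20).
#' @return Logical mask named by gene with exactly `n_top` `TRUE` entries.
#' @export
select_hvg <- function(x, n_top, n_bins = 20) {
  if (n_top <= 0) stop("n_top must be positive")
  if (n_top > ncol(x)) stop("n_top exceeds gene count")
  mu <- Matrix::colMeans(x)
  ex2 <- Matrix::colMeans(x^2)
  v <- (ex2 - mu^2) * nrow(x) / max(nrow(x) - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  grp <- cut(rank(mu, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  z <- disp
  for (g in unique(grp)) {
    i <- grp == g
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  z[v == 0] <- -Inf        # constant genes rank after any varying gene
  ord <- order(-z, colnames(x))
  keep <- rep(FALSE, ncol(x))
  keep[ord[seq_len(n_top)]] <- TRUE
  names(keep) <- colnames(x)
  keep
}

#' Build the four trajectory count forms
#'
#' From the depth-normalized (`NORM`) and log-transformed (`LOG`) binned
#' trajectories, derives per-gene max-scaled variants (`NORM_MAX`,
#' `LOG_MAX`) by dividing each gene's row by its maximum across bins.
#' Ranking over all four forms avoids biasing coexpression calls toward any
#' single normalization. Genes whose trajectory is identically zero cannot
#' be max-scaled; they are flagged and omitted from the max-scaled forms.
#'
#' @param norm_traj,log_traj gene x bin matrices sharing dimnames.
#' @return `list(forms = list(NORM, LOG, NORM_MAX, LOG_MAX), zero_genes)`,
#'   `zero_genes` being the symbols with all-zero trajectories.
#' @export
make_count_forms <- function(norm_traj, log_traj) {
  stopifnot(identical(dimnames(norm_traj), dimnames(log_traj)))
  rescale <- function(tr) {
    mx <- apply(tr, 1, max)
    zero <- mx <= 0
    scaled <- tr[!zero, , drop = FALSE] / mx[!zero]
    list(scaled = scaled, zero = rownames(tr)[zero])
  }
  nm <- rescale(norm_traj)
  lm_ <- rescale(log_traj)
  zero <- union(nm$zero, lm_$zero)
  list(forms = list(NORM = norm_traj, LOG = log_traj,
                    NORM_MAX = nm$scaled, LOG_MAX = lm_$scaled),
       zero_genes = zero)
}

#' The four count-form identifiers
#' @return `c("NORM", "LOG", "NORM_MAX", "LOG_MAX")`.
#' @export
count_form_ids <- function() c("NORM", "LOG", "NORM_MAX", "LOG_MAX")
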