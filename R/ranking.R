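#' RMSE of every gene's trajectory against a reference gene
#'
#' The coexpression statistic: for each gene g with binned trajectory
#' x_g and reference trajectory x_ref over B bins,
#' `rmse_g = sqrt(mean((x_g - x_ref)^2))`. The reference scores exactly 0
#' against itself; small values mean the gene tracks the reference across
#' maturation under the chosen count form.
#'
#' @param t a `TrajectorySet` from [bin_trajectories()].
#' @param form one of [count_form_ids()].
#' @param reference reference gene symbol.
#' @return Named numeric vector of RMSE values for every gene present in
#'   the form's matrix.
#' @export
rmse_to_reference <- function(t, form, reference) {
  stopifnot(form %in% count_form_ids())
  tr <- t$forms[[form]]
  if (!reference %in% rownames(tr)) {
    if (reference %in% t$zero_genes)
      stop("reference gene '", reference,
           "' has an all-zero trajectory and cannot anchor form ", form)
    stop("reference gene '", reference, "' not found in form ", form)
  }
  ref <- tr[reference, ]
  delta <- sweep(tr, 2, ref, "-")
  sqrt(rowMeans(delta^2))
}

#' Rank genes by ascending RMSE
#'
#' Rank 1 is the most reference-like gene (the reference itself). Ties are
#' broken by gene symbol so rankings are deterministic.
#'
#' @param rmse named numeric vector from [rmse_to_reference()].
#' @return Named integer vector of 1-based ranks, a permutation of
#'   `1..length(rmse)`.
#' @export
rank_per_form <- function(rmse) {
  if (length(rmse) < 2) stop("ranking needs at least 2 genes")
  ord <- order(rmse, names(rmse))
  r <- integer(length(rmse))
  r[ord] <- seq_along(rmse)
  stats::setNames(r, names(rmse))
}

#' Integrate per-form rankings into one candidate table
#'
#' A gene coexpressed with the reference should rank well regardless of how
#' the counts were represented. For each gene this computes the arithmetic
#' mean of its four ranks and `topk_hits`, the number of forms in which it
#' lands in the top `k`; the final ordering is by descending `topk_hits`,
#' then ascending mean rank, then symbol. Genes absent from the max-scaled
#' forms (all-zero trajectories) are averaged over the forms they have and
#' flagged.
#'
#' @param t a `TrajectorySet`.
#' @param reference reference gene symbol.
#' @param k top-list size per form (default 50).
#' @param include_anti also report RMSE against the vertically flipped
#'   max-scaled reference trajectory (`1 - ref`), a simple screen for
#'   antiregulated genes; adds an `rmse_anti` column.
#' @return A `data.frame` ("RankTable") with one row per gene: `gene`,
#'   `rmse_<form>` and `rank_<form>` per count form, `mean_rank`,
#'   `topk_hits`, `candidate_rank` (NA for flagged genes), and flags
#'   `is_reference`, `zero_trajectory`, `excluded_panneuronal`.
#' @export
integrate_ranks <- function(t, reference, k = 50, include_anti = FALSE) {
  forms <- count_form_ids()
  genes <- rownames(t$forms$NORM)
  rt <- data.frame(gene = genes, stringsAsFactors = FALSE)
  rank_mat <- matrix(NA_real_, length(genes), length(forms),
                     dimnames = list(genes, forms))
  hit_mat <- matrix(FALSE, length(genes), length(forms),
                    dimnames = list(genes, forms))
  for (f in forms) {
    rmse <- rmse_to_reference(t, f, reference)
    rk <- rank_per_form(rmse)
    rt[[paste0("rmse_", tolower(f))]] <- unname(rmse[genes])
    rt[[paste0("rank_", tolower(f))]] <- unname(rk[genes])
    rank_mat[names(rk), f] <- rk
    hit_mat[names(rk), f] <- rk <= k
  }
  rt$mean_rank <- rowMeans(rank_mat, na.rm = TRUE)
  rt$topk_hits <- rowSums(hit_mat)
  rt$is_reference <- rt$gene == reference
  rt$zero_trajectory <- rt$gene %in% t$zero_genes
  rt$excluded_panneuronal <- FALSE
  if (include_anti) {
    lm <- t$forms$LOG_MAX
    anti <- 1 - lm[reference, ]
    rt$rmse_anti <- NA_real_
    idx <- match(rownames(lm), rt$gene)
    rt$rmse_anti[idx] <- sqrt(rowMeans(sweep(lm, 2, anti, "-")^2))
  }
  ord <- order(-rt$topk_hits, rt$mean_rank, rt$gene)
  rt <- rt[ord, , drop = FALSE]
  rownames(rt) <- NULL
  rt$candidate_rank <- seq_len(nrow(rt))
  attr(rt, "reference") <- reference
  attr(rt, "k") <- k
  rt
}

#' Flag pan-neuronal genes out of the candidate list
#'
#' Genes broadly expressed in neurons outside the olfactory epithelium
#' (e.g. the top neuron-enriched genes of an olfactory-bulb dataset) track
#' maturation without being olfactory-specific; they are flagged and pushed
#' out of the candidate ordering, but kept in the table with their RMSE
#' values intact for audit.
#'
#' @param rt RankTable from [integrate_ranks()].
#' @param exclusion character vector of pan-neuronal gene symbols (one
#'   entry of a gene-set collection).
#' @return The RankTable with `excluded_panneuronal` set and
#'   `candidate_rank` recomputed over the surviving genes (NA for excluded).
#' @export
filter_panneuronal <- function(rt, exclusion) {
  rt$excluded_panneuronal <- rt$gene %in% exclusion
  keep <- !rt$excluded_panneuronal
  rt$candidate_rank <- NA_integer_
  rt$candidate_rank[keep] <- seq_len(sum(keep))
  rt
}

#' Top candidate genes from a RankTable
#'
#' @param rt RankTable.
#' @param n list size (default the table's `k` attribute, 50 if unset).
#' @param drop_reference exclude the reference gene itself (default TRUE).
#' @return Character vector of gene symbols in candidate order.
#' @export
top_candidates <- function(rt, n = NULL, drop_reference = TRUE) {
  if (is.null(n)) n <- attr(rt, "k") %||% 50
  sel <- rt[!is.na(rt$candidate_rank), , drop = FALSE]
  sel <- sel[order(sel$candidate_rank), , drop = FALSE]
  if (drop_reference) sel <- sel[!sel$is_reference, , drop = FALSE]
  utils::head(sel$gene, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a RankTable as TSV
#'
#' Layout mirrors a per-gene table of RMSE per count form plus the rank and
#' integration columns; a comment header records provenance.
#'
#' @param rt RankTable.
#' @param path output file.
#' @param header optional comment lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_rank_table <- function(rt, path, header = NULL) {
  write_tsv_with_header(rt, path, header)
}

write_tsv_with_header <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
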