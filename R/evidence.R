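#' Curated ER-stress transcription factors
#'
#' The nine transcription factors of the unfolded-protein response active
#' during OSN maturation, used to interrogate regulatory networks for
#' candidate-gene connections.
#'
#' @return Character vector of nine gene symbols.
#' @export
er_stress_tfs <- function() {
  c("Atf5", "Atf6", "Ddit3", "Ebf1", "Ebf2", "Ebf3", "Ebf4",
    "Nfe2l2", "Xbp1")
}

#' Read a regulatory-network edge list
#'
#' TSV of regulator-target edges, e.g. a mutual-information network from
#' ARACNE. Self-loops are dropped (counted in the attributes) and duplicate
#' (regulator, target) pairs are collapsed keeping the maximum weight.
#'
#' @param path TSV file with a header row.
#' @param columns named mapping from the roles `regulator`, `target`, and
#'   optionally `weight`, `p` to the file's column names.
#' @return `data.frame` ("EdgeList") with columns `regulator`, `target`,
#'   `weight` (1 when the file has none) and optionally `p`; attributes
#'   `n_self_loops` and `n_duplicates` summarize the cleanup.
#' @export
read_edge_list <- function(path,
                           columns = c(regulator = "regulator",
                                       target = "target",
                                       weight = "weight", p = "p")) {
  dt <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  need <- columns[c("regulator", "target")]
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop("edge list missing column(s) ", paste(miss, collapse = ", "),
         "; header was: ", paste(names(dt), collapse = ", "))
  e <- data.frame(regulator = as.character(dt[[need[["regulator"]]]]),
                  target = as.character(dt[[need[["target"]]]]),
                  stringsAsFactors = FALSE)
  wcol <- columns["weight"]
  e$weight <- if (!is.na(wcol) && wcol %in% names(dt))
    as.numeric(dt[[wcol]]) else 1
  pcol <- columns["p"]
  if (!is.na(pcol) && pcol %in% names(dt)) e$p <- as.numeric(dt[[pcol]])
  self <- e$regulator == e$target
  e <- e[!self, , drop = FALSE]
  key <- paste(e$regulator, e$target, sep = "\r")
  e <- e[order(key, -e$weight), , drop = FALSE]
  dup <- duplicated(paste(e$regulator, e$target, sep = "\r"))
  e <- e[!dup, , drop = FALSE]
  rownames(e) <- NULL
  attr(e, "n_self_loops") <- sum(self)
  attr(e, "n_duplicates") <- sum(dup)
  e
}

#' Count a gene's interactions with a transcription-factor list
#'
#' How many distinct members of `tf_list` are adjacent to `gene` in the
#' network. Mutual-information edges carry no reliable direction, so both
#' edge orientations count by default; set `directed = TRUE` to count only
#' TF-as-regulator edges.
#'
#' @param edges EdgeList from [read_edge_list()].
#' @param gene gene symbol to interrogate.
#' @param tf_list transcription-factor symbols (default [er_stress_tfs()]).
#' @param directed count only `regulator %in% tf_list & target == gene`.
#' @return `list(count, tfs, absent)`: the count, the matched TF names, and
#'   whether the gene has no edges at all in the network.
#' @export
count_tf_interactions <- function(edges, gene, tf_list = er_stress_tfs(),
                                  directed = FALSE) {
  stopifnot(length(tf_list) > 0)
  touching <- edges$regulator == gene | edges$target == gene
  if (!any(touching))
    return(list(count = 0L, tfs = character(0), absent = TRUE))
  sub <- edges[touching, , drop = FALSE]
  partners <- ifelse(sub$regulator == gene, sub$target, sub$regulator)
  if (directed) partners <- sub$regulator[sub$target == gene]
  tfs <- sort(intersect(unique(partners), tf_list))
  list(count = length(tfs), tfs = tfs, absent = FALSE)
}

#' Overlay an external differential-expression table onto candidates
#'
#' Annotates a RankTable with whether each candidate is significantly
#' differentially expressed in an external contrast (e.g. downregulated in
#' virally infected olfactory epithelium). Candidates are never reordered
#' or removed — this is evidence, not a filter.
#'
#' @param rt RankTable.
#' @param de DE table (`gene`, `logfc`, `pvalue`, `fdr`).
#' @param fdr_cut significance cutoff (default 0.05).
#' @param direction required sign of `logfc`: `"down"`, `"up"`, `"both"`.
#' @return The RankTable with `de_flag` (TRUE / FALSE / NA when the gene is
#'   absent from the DE table) and `de_logfc` columns.
#' @export
overlay_de_table <- function(rt, de, fdr_cut = 0.05,
                             direction = c("down", "up", "both")) {
  direction <- match.arg(direction)
  idx <- match(rt$gene, de$gene)
  lf <- de$logfc[idx]
  fdr <- de$fdr[idx]
  sign_ok <- switch(direction,
                    down = lf < 0,
                    up = lf > 0,
                    both = lf != 0)
  rt$de_logfc <- lf
  rt$de_flag <- ifelse(is.na(idx), NA, fdr < fdr_cut & sign_ok)
  rt
}
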