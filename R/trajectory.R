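#' PCA embedding of cells
#'
#' Principal components of the (typically HVG-masked, log-normalized)
#' expression matrix, genes centered and by default scaled to unit variance.
#' Wraps [stats::prcomp()]; components come out ordered by decreasing
#' explained variance.
#'
#' @param x cell x gene matrix (sparse accepted; densified internally).
#' @param n_pcs number of components to keep (default 40).
#' @param scale. scale genes to unit variance before decomposition
#'   (constant genes are left unscaled).
#' @return An `Embedding`: `list(scores, sdev, var_explained)` where
#'   `scores` is cells x `n_pcs` with barcode rownames.
#' @export
pca_embed <- function(x, n_pcs = 40, scale. = TRUE) {
  xd <- as.matrix(x)
  if (n_pcs > min(dim(xd)))
    stop("n_pcs (", n_pcs, ") exceeds min(cells, genes) = ", min(dim(xd)))
  if (scale.) {
    s <- apply(xd, 2, stats::sd)
    scale. <- ifelse(s > 0, s, 1)
  }
  p <- stats::prcomp(xd, center = TRUE, scale. = scale., rank. = n_pcs)
  ve <- p$sdev^2 / sum(p$sdev^2)
  structure(list(scores = p$x, sdev = p$sdev[seq_len(n_pcs)],
                 var_explained = ve[seq_len(n_pcs)]),
            class = "Embedding")
}

#' k-nearest-neighbor graph with adaptive Gaussian weights
#'
#' Connects each cell to its `k` Euclidean nearest neighbors in embedding
#' space, symmetrizes by union, and weights edges with a Gaussian kernel
#' whose per-cell bandwidth is the distance to the ceiling(k/2)-th neighbor
#' — denser regions get narrower kernels, the usual adaptive construction
#' for diffusion analysis.
#'
#' @param e an `Embedding` from [pca_embed()] (or a plain coordinate matrix).
#' @param k neighbors per cell (default 10).
#' @return `list(w, k)` where `w` is the symmetric sparse weight matrix
#'   (zero diagonal, weights in (0, 1]).
#' @export
knn_graph <- function(e, k = 10) {
  sc <- if (inherits(e, "Embedding")) e$scores else as.matrix(e)
  n <- nrow(sc)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k (", k, ") must be smaller than the cell count (", n, ")")
  d <- as.matrix(stats::dist(sc))
  diag(d) <- Inf
  nn_idx <- matrix(apply(d, 1, function(row) order(row)[seq_len(k)]),
                   nrow = n, byrow = TRUE)
  h <- ceiling(k / 2)
  sigma <- vapply(seq_len(n),
                  function(i) d[i, nn_idx[i, h]], numeric(1))
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1)
  i <- rep(seq_len(n), each = k)
  j <- as.vector(t(nn_idx))
  wij <- exp(-d[cbind(i, j)]^2 / (sigma[i] * sigma[j]))
  w <- Matrix::sparseMatrix(i = i, j = j, x = wij, dims = c(n, n))
  w <- pmax_sparse(w, Matrix::t(w))          # union symmetrization
  dimnames(w) <- list(rownames(sc), rownames(sc))
  list(w = w, k = k)
}

## elementwise max of two same-pattern-or-not sparse matrices
pmax_sparse <- function(a, b) {
  s <- (a + b + abs(a - b)) / 2
  Matrix::drop0(s)
}

#' Diffusion map of a cell graph
#'
#' Builds the diffusion operator from the kNN kernel with anisotropic
#' density normalization (kernel divided by the degree on both sides,
#' exponent 1) and row normalization, then extracts the leading eigenpairs
#' through the symmetric conjugate operator. The stationary eigenvector
#' (eigenvalue 1) is dropped; the remaining diffusion components are
#' unit-normalized.
#'
#' @param g graph from [knn_graph()].
#' @param n_comps number of diffusion components to keep (default 15).
#' @return A `DiffusionSpace`: `list(evals, psi)` with eigenvalues sorted
#'   decreasing and `psi` a cells x `n_comps` matrix.
#' @export
diffusion_map <- function(g, n_comps = 15) {
  w <- g$w
  n <- nrow(w)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                        weighted = TRUE))
  if (comp$no > 1)
    stop("cell graph is disconnected: ", comp$no, " components of sizes ",
         paste(sort(comp$csize, decreasing = TRUE), collapse = ", "))
  q <- Matrix::rowSums(w)
  k1 <- Matrix::Diagonal(x = 1 / q) %*% w %*% Matrix::Diagonal(x = 1 / q)
  d <- Matrix::rowSums(k1)
  dinv_sqrt <- Matrix::Diagonal(x = 1 / sqrt(d))
  ms <- dinv_sqrt %*% k1 %*% dinv_sqrt     # symmetric conjugate of P
  ms <- (ms + Matrix::t(ms)) / 2           # kill round-off asymmetry
  nev <- min(n_comps + 1, n)
  eig <- top_eigs_sym(function(v) as.matrix(ms %*% v), n = n, nev = nev)
  evals <- eig$values[-1]                  # drop stationary eigenpair
  vecs <- eig$vectors[, -1, drop = FALSE]
  psi <- as.matrix(dinv_sqrt %*% vecs)     # right eigenvectors of P
  psi <- sweep(psi, 2, sqrt(colSums(psi^2)), "/")
  rownames(psi) <- rownames(w)
  structure(list(evals = evals, psi = psi), class = "DiffusionSpace")
}

#' Leading eigenpairs of a symmetric operator
#'
#' Deterministic block orthogonal iteration with Rayleigh-Ritz extraction.
#' The operator is only accessed through matrix-vector products, so sparse
#' graphs stay sparse; the fixed analytic start basis makes results
#' reproducible without touching the RNG. Eigenvalues are assumed to lie in
#' `[-1, 1]` up to scaling `shift` (default 1 shifts the spectrum to be
#' nonnegative so the largest algebraic eigenvalues dominate the iteration).
#'
#' @param mult function taking an n x b matrix and returning the operator
#'   applied to each column.
#' @param n operator dimension.
#' @param nev number of leading (largest algebraic) eigenpairs.
#' @param ncv working block size (default `min(n, 2 * nev + 5)`).
#' @param tol convergence tolerance on Ritz values.
#' @param maxiter iteration cap.
#' @param shift spectral shift added during iteration.
#' @return `list(values, vectors)` sorted by decreasing eigenvalue.
#' @keywords internal
top_eigs_sym <- function(mult, n, nev, ncv = min(n, 2L * nev + 5L),
                         tol = 1e-12, maxiter = 5000L, shift = 1) {
  stopifnot(nev <= n, ncv >= nev)
  v <- qr.Q(qr(matrix(sin(seq_len(n * ncv)), n, ncv)))
  prev <- rep(Inf, nev)
  step <- function(v) mult(v) + shift * v
  for (it in seq_len(maxiter)) {
    v <- qr.Q(qr(step(v)))
    if (it %% 5 == 0 || it == maxiter) {
      av <- mult(v)
      b <- crossprod(v, av)
      b <- (b + t(b)) / 2
      e <- eigen(b, symmetric = TRUE)
      vals <- e$values[seq_len(nev)]
      if (max(abs(vals - prev)) < tol) {
        vecs <- (v %*% e$vectors)[, seq_len(nev), drop = FALSE]
        return(list(values = vals, vectors = vecs))
      }
      prev <- vals
      v <- v %*% e$vectors          # re-sort the block by Ritz value
    }
  }
  av <- mult(v)
  b <- crossprod(v, av); b <- (b + t(b)) / 2
  e <- eigen(b, symmetric = TRUE)
  warning("eigeniteration reached maxiter without tolerance ", tol)
  list(values = e$values[seq_len(nev)],
       vectors = (v %*% e$vectors)[, seq_len(nev), drop = FALSE])
}

#' Choose the root cell of the trajectory
#'
#' The root anchors pseudotime zero. Within the designated progenitor
#' cluster (globose basal cells for the olfactory lineage), picks the cell
#' with the highest mean normalized expression of the supplied marker
#' genes; with no markers, falls back to the cluster cell extremal in the
#' first diffusion component. Marker ties resolve to the lexicographically
#' smallest barcode.
#'
#' @param x depth-normalized cell x gene matrix.
#' @param meta QC table with `cluster` labels.
#' @param root_cluster cluster containing the root.
#' @param root_markers marker gene symbols (optional).
#' @param diffusion `DiffusionSpace`, required when no markers are given.
#' @return Integer row index of the root cell.
#' @export
select_root <- function(x, meta, root_cluster, root_markers = NULL,
                        diffusion = NULL) {
  in_cl <- which(!is.na(meta$cluster) & meta$cluster == root_cluster)
  if (!length(in_cl))
    stop("root cluster '", root_cluster, "' is empty; available: ",
         paste(sort(unique(stats::na.omit(meta$cluster))), collapse = ", "))
  if (!is.null(root_markers) && length(root_markers)) {
    mk <- intersect(root_markers, colnames(x))
    if (!length(mk)) stop("none of the root markers are in the matrix")
    score <- Matrix::rowMeans(x[in_cl, mk, drop = FALSE])
    best <- score == max(score)
    cand <- in_cl[best]
    return(cand[order(meta$barcode[cand])][1])
  }
  if (is.null(diffusion))
    stop("either root_markers or a DiffusionSpace must be supplied")
  dc1 <- diffusion$psi[in_cl, 1]
  in_cl[which.max(abs(dc1))]
}

#' Diffusion pseudotime from a root cell
#'
#' Each cell's pseudotime is its Euclidean distance from the root in the
#' space of diffusion components scaled by `lambda / (1 - lambda)` (the
#' accumulated-transition weighting), rescaled to `[0, 1]` by the maximum.
#' Components with eigenvalue numerically 1 after removal of the stationary
#' one are skipped with a warning.
#'
#' @param d `DiffusionSpace` from [diffusion_map()].
#' @param root root cell index from [select_root()].
#' @return Numeric vector of pseudotimes in `[0, 1]`, named by barcode;
#'   the root is exactly 0 and the farthest cell exactly 1.
#' @export
compute_dpt <- function(d, root) {
  stopifnot(root >= 1, root <= nrow(d$psi))
  ok <- d$evals < 1 - 1e-10
  if (!all(ok))
    warning(sum(!ok), " diffusion component(s) with eigenvalue ~1 skipped")
  lam <- d$evals[ok]
  z <- d$psi[, ok, drop = FALSE] %*% diag(lam / (1 - lam), nrow = sum(ok))
  delta <- sweep(z, 2, z[root, ], "-")
  pt <- sqrt(rowSums(delta^2))
  mx <- max(pt)
  if (mx == 0) stop("degenerate diffusion space: all pseudotimes zero")
  out <- stats::setNames(pt / mx, rownames(d$psi))
  attr(out, "scale") <- mx    # multiply back to recover raw DPT distances
  out
}

#' Assign cells to pseudotime bins
#'
#' Equal-width bins over `[0, 1]`; bin ids are 0-based so pseudotime 0 maps
#' to bin 0 and pseudotime 1 to bin `B - 1` (the last bin is closed on the
#' right). Bins holding fewer than `min_cells` members are marked sparse;
#' trajectory construction later fills them by interpolation.
#'
#' @param pseudotime per-cell values in `[0, 1]`.
#' @param B number of bins (default 50).
#' @param min_cells occupancy below which a bin counts as sparse (default 3).
#' @return `list(bin, edges, occupancy, sparse)`; `bin` is 0-based per cell,
#'   `occupancy` and `sparse` have length `B`.
#' @export
assign_bins <- function(pseudotime, B = 50, min_cells = 3) {
  if (B < 2) stop("B must be >= 2")
  if (B > length(pseudotime)) stop("more bins than cells")
  if (any(pseudotime < 0 | pseudotime > 1)) stop("pseudotime outside [0,1]")
  bin <- pmin(floor(pseudotime * B), B - 1)
  occupancy <- tabulate(bin + 1, nbins = B)
  list(bin = as.integer(bin),
       edges = seq(0, 1, length.out = B + 1),
       occupancy = occupancy,
       sparse = occupancy < min_cells)
}

#' Binned gene-expression trajectories in all four count forms
#'
#' For every gene, averages the depth-normalized (`NORM`) and log (`LOG`)
#' expression of the cells in each pseudotime bin. Sparse or empty bins are
#' filled by linear interpolation between the nearest well-populated bins
#' (constant extension at the ends) and flagged, so every gene trajectory
#' has identical length and per-form RMSE values stay comparable across
#' genes. [make_count_forms()] then adds the max-scaled variants.
#'
#' @param norm_x,log_x cell x gene matrices (same cells and genes).
#' @param bins result of [assign_bins()].
#' @return A `TrajectorySet`: `list(forms, zero_genes, edges, midpoints,
#'   occupancy, interpolated)`; each form is a gene x bin matrix.
#' @export
bin_trajectories <- function(norm_x, log_x, bins) {
  B <- length(bins$occupancy)
  good <- !bins$sparse
  if (sum(good) < 2)
    stop("fewer than 2 populated bins; decrease B or min_cells")
  n <- length(bins$bin)
  stopifnot(nrow(norm_x) == n, nrow(log_x) == n)
  memb <- Matrix::sparseMatrix(i = bins$bin + 1, j = seq_len(n), x = 1,
                               dims = c(B, n))
  occ <- pmax(bins$occupancy, 1)
  bin_mean <- function(x) {
    m <- as.matrix(memb %*% x) / occ       # B x genes
    tr <- t(m)                             # genes x bins
    interp_bins(tr, good, bins$edges)
  }
  norm_traj <- bin_mean(norm_x)
  log_traj <- bin_mean(log_x)
  cf <- make_count_forms(norm_traj, log_traj)
  mids <- (bins$edges[-1] + bins$edges[-(B + 1)]) / 2
  structure(list(forms = cf$forms, zero_genes = cf$zero_genes,
                 edges = bins$edges, midpoints = mids,
                 occupancy = bins$occupancy, interpolated = !good),
            class = "TrajectorySet")
}

## linearly interpolate non-populated bins from the nearest populated ones
interp_bins <- function(tr, good, edges) {
  B <- ncol(tr)
  if (all(good)) return(tr)
  gi <- which(good)
  for (b in which(!good)) {
    lo <- gi[gi < b]; hi <- gi[gi > b]
    if (!length(lo)) { tr[, b] <- tr[, hi[1]]; next }
    if (!length(hi)) { tr[, b] <- tr[, lo[length(lo)]]; next }
    l <- lo[length(lo)]; h <- hi[1]
    w <- (b - l) / (h - l)
    tr[, b] <- (1 - w) * tr[, l] + w * tr[, h]
  }
  tr
}
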