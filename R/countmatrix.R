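#' Construct a cell-by-gene count matrix
#'
#' `CountMatrix` is the package's container for raw unique-molecule counts:
#' a sparse nonnegative integer matrix with cells in rows (identified by
#' unique barcodes) and genes in columns (unique symbols). All downstream
#' operations iterate over nonzeros without densifying the full matrix.
#'
#' @param counts matrix-like object (dense or [Matrix::sparseMatrix]) of
#'   nonnegative counts, cells in rows.
#' @param barcodes character vector of unique cell identifiers; defaults to
#'   `rownames(counts)`.
#' @param genes character vector of unique gene symbols; defaults to
#'   `colnames(counts)`.
#' @return An object of class `CountMatrix`: a sparse matrix (dgCMatrix
#'   parent) carrying barcode row names and gene column names.
#' @export
CountMatrix <- function(counts, barcodes = rownames(counts),
                        genes = colnames(counts)) {
  if (is.matrix(counts)) counts <- Matrix::Matrix(counts, sparse = TRUE)
  m <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                               "generalMatrix"), "CsparseMatrix")
  if (is.null(barcodes) || is.null(genes))
    stop("CountMatrix requires barcode and gene names")
  if (length(barcodes) != nrow(m) || length(genes) != ncol(m))
    stop("axis lengths do not match matrix dimensions")
  dup <- unique(barcodes[duplicated(barcodes)])
  if (length(dup))
    stop("duplicate barcodes: ", paste(utils::head(dup, 5), collapse = ", "))
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbols: ",
         paste(utils::head(dup, 5), collapse = ", "))
  if (length(m@x) && min(m@x) < 0) stop("negative counts are not allowed")
  dimnames(m) <- list(as.character(barcodes), as.character(genes))
  methods::new("CountMatrix", m)
}

#' @rdname CountMatrix
#' @export
setClass("CountMatrix", contains = "dgCMatrix")

setMethod("show", "CountMatrix", function(object) {
  cat(sprintf("CountMatrix: %d cells x %d genes, %d nonzeros\n",
              nrow(object), ncol(object), length(object@x)))
  invisible(object)
})

## downcast so plain Matrix arithmetic applies
cm_mat <- function(m) methods::as(m, "dgCMatrix")

barcodes <- function(m) rownames(m)
gene_symbols <- function(m) colnames(m)

#' Read a count matrix from disk
#'
#' Two dialects are supported. `"mtx"` expects a directory in the usual
#' exchange layout — `matrix.mtx` (Matrix Market, genes in rows, cells in
#' columns), `barcodes.tsv`, `features.tsv` — as deposited for most
#' droplet-based experiments. `"tsv"` expects a single dense tab-separated
#' table with a header row; orientation is auto-detected from the first
#' header field (`gene` = genes x cells, `barcode` = cells x genes).
#'
#' @param path directory (mtx dialect) or file (tsv dialect).
#' @param dialect `"auto"` (directory implies mtx), `"mtx"`, or `"tsv"`.
#' @return A [CountMatrix] with cells in rows.
#' @export
read_counts <- function(path, dialect = c("auto", "mtx", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") dialect <- if (dir.exists(path)) "mtx" else "tsv"
  if (dialect == "mtx") read_counts_mtx(path) else read_counts_tsv(path)
}

read_counts_mtx <- function(dir) {
  if (!dir.exists(dir)) stop("no such directory: ", dir)
  need <- c(matrix = "matrix.mtx", barcodes = "barcodes.tsv",
            features = "features.tsv")
  paths <- file.path(dir, need)
  names(paths) <- names(need)
  missing <- !file.exists(paths)
  if (any(missing))
    stop("missing ", paste(names(need)[missing], collapse = ", "),
         " file(s) in ", dir)
  m <- Matrix::readMM(paths[["matrix"]])
  bc <- data.table::fread(paths[["barcodes"]], header = FALSE, sep = "\t")[[1]]
  ft <- data.table::fread(paths[["features"]], header = FALSE, sep = "\t")[[1]]
  if (nrow(m) != length(ft) || ncol(m) != length(bc))
    stop("matrix dimensions do not match features/barcodes files")
  CountMatrix(Matrix::t(m), barcodes = bc, genes = ft)
}

read_counts_tsv <- function(file) {
  if (!file.exists(file)) stop("no such file: ", file)
  dt <- data.table::fread(file, sep = "\t", header = TRUE)
  key <- tolower(names(dt)[1])
  ids <- dt[[1]]
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (key == "gene") {                  # genes x cells -> transpose
    m <- t(mat)
    CountMatrix(m, barcodes = colnames(dt)[-1], genes = ids)
  } else if (key == "barcode") {
    CountMatrix(mat, barcodes = ids, genes = colnames(dt)[-1])
  } else {
    stop("cannot detect orientation: first header field must be ",
         "'gene' or 'barcode', got '", names(dt)[1], "'")
  }
}

#' Write a count matrix to disk
#'
#' @param m a [CountMatrix].
#' @param path output directory (mtx dialect) or file (tsv dialect).
#' @param dialect `"mtx"` or `"tsv"`; tsv is written cells x genes with a
#'   `barcode` first column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(m, path, dialect = c("mtx", "tsv")) {
  dialect <- match.arg(dialect)
  x <- cm_mat(m)
  if (dialect == "mtx") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(Matrix::t(x), file.path(path, "matrix.mtx"))
    data.table::fwrite(data.table::data.table(rownames(x)),
                       file.path(path, "barcodes.tsv"),
                       col.names = FALSE, sep = "\t")
    data.table::fwrite(data.table::data.table(colnames(x)),
                       file.path(path, "features.tsv"),
                       col.names = FALSE, sep = "\t")
  } else {
    dt <- data.table::data.table(barcode = rownames(x))
    dt <- cbind(dt, data.table::as.data.table(as.matrix(x)))
    data.table::fwrite(dt, path, sep = "\t")
  }
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Thin wrapper around [fgsea::gmtPathways()] that applies the package's
#' symbol-case policy and validates the collection invariants (non-empty,
#' uniquely named sets).
#'
#' @param path GMT file.
#' @param uppercase if `TRUE`, normalize symbols to upper case (useful when
#'   mixing human and mouse conventions); default keeps case.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path, uppercase = FALSE) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the 'fgsea' package")
  sets <- fgsea::gmtPathways(path)
  if (uppercase) sets <- lapply(sets, toupper)
  if (any(lengths(sets) == 0)) stop("empty gene set in ", path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in ", path)
  sets
}
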