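#' Construct an expression matrix object
#'
#' Bundles a cells x genes matrix of raw, unnormalized counts with its cell
#' and gene identifiers and validates the invariants every downstream step
#' relies on: nonnegative entries, matching dimensions, unique identifiers.
#'
#' @param counts numeric matrix (cells in rows, genes in columns) of
#'   nonnegative counts. A `Matrix` sparse matrix is densified.
#' @param cell_ids character vector of unique cell identifiers; defaults to
#'   `rownames(counts)`.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   `colnames(counts)`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `counts` (dense matrix with dimnames), `cell_ids`, `gene_ids`.
#' @export
expression_matrix <- function(counts, cell_ids = rownames(counts),
                              gene_ids = colnames(counts)) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts))
    stop("`counts` must be a numeric matrix")
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(counts)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(counts)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts) || length(gene_ids) != ncol(counts))
    stop("id lengths do not match matrix dimensions")
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  if (anyNA(counts)) stop("counts contain NA")
  if (min(counts) < 0)
    stop("validation error: negative entries in count matrix")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(list(counts = counts, cell_ids = cell_ids, gene_ids = gene_ids),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes, %.1f%% nonzero\n",
              length(x$cell_ids), length(x$gene_ids),
              100 * mean(x$counts > 0)))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a count matrix from disk
#'
#' Supports three layouts: a dense CSV (header row of gene names, first
#' column of cell ids), a MatrixMarket sparse triplet in the 10x cellranger
#' convention (features x barcodes on disk, with `features.tsv` /
#' `barcodes.tsv` sidecars next to the `.mtx` file), and an AnnData `.h5ad`
#' container. Counts are returned exactly as stored; no normalization is
#' applied.
#'
#' h5ad files are converted through the `python` interpreter on the PATH
#' (requires the `anndata` package); only `X`, `obs_names` and `var_names`
#' are read — layers and obsm are ignored.
#'
#' @param path file path (for mtx, the path of the `.mtx` file; sidecars are
#'   looked up in the same directory).
#' @param format one of `"csv"`, `"mtx"`, `"h5ad"`; by default inferred from
#'   the file extension.
#' @return an [expression_matrix()] object.
#' @export
read_expression <- function(path, format = c("auto", "csv", "mtx", "h5ad")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", mtx = "mtx", h5ad = "h5ad",
                     stop("cannot infer format from extension: ", ext))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
    csv = read_expression_csv(path),
    mtx = read_expression_mtx(path),
    h5ad = read_expression_h5ad(path))
}

read_expression_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, row.names = 1)
  m <- as.matrix(df)
  if (!is.numeric(m))
    stop("parse error in ", path, ": non-numeric entries (field ",
         which(!vapply(df, is.numeric, TRUE))[1], ")")
  expression_matrix(m, cell_ids = rownames(df), gene_ids = colnames(df))
}

read_expression_mtx <- function(path) {
  m <- Matrix::readMM(path)
  dir <- dirname(path)
  feat <- file.path(dir, "features.tsv")
  if (!file.exists(feat)) feat <- file.path(dir, "genes.tsv")
  barc <- file.path(dir, "barcodes.tsv")
  if (!file.exists(feat) || !file.exists(barc))
    stop("mtx sidecar files features.tsv/barcodes.tsv not found in ", dir)
  genes <- utils::read.delim(feat, header = FALSE)[[1]]
  cells <- utils::read.delim(barc, header = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("mtx dimensions (", nrow(m), " x ", ncol(m),
         ") do not match sidecar lengths")
  # 10x layout stores features x barcodes; transpose to cells x genes
  expression_matrix(as.matrix(Matrix::t(m)), cell_ids = cells,
                    gene_ids = genes)
}

read_expression_h5ad <- function(path) {
  py <- Sys.which("python")
  if (py == "") stop("h5ad support requires a python interpreter on the PATH")
  out <- tempfile("h5ad_convert_")
  dir.create(out)
  on.exit(unlink(out, recursive = TRUE), add = TRUE)
  script <- sprintf("
import anndata, scipy.sparse as sp, scipy.io, numpy as np
ad = anndata.read_h5ad(%s)
X = ad.X
if not sp.issparse(X):
    X = sp.csr_matrix(np.asarray(X))
scipy.io.mmwrite(%s + '/matrix.mtx', X.T)
open(%s + '/features.tsv', 'w').write('\\n'.join(map(str, ad.var_names)) + '\\n')
open(%s + '/barcodes.tsv', 'w').write('\\n'.join(map(str, ad.obs_names)) + '\\n')
", deparse(path), deparse(out), deparse(out), deparse(out))
  status <- system2(py, c("-c", shQuote(script)), stdout = TRUE,
                    stderr = TRUE)
  if (!is.null(attr(status, "status")))
    stop("h5ad conversion failed:\n", paste(status, collapse = "\n"))
  read_expression_mtx(file.path(out, "matrix.mtx"))
}

#' Write a count matrix to disk
#'
#' Inverse of [read_expression()] for the `csv` and `mtx` layouts.
#'
#' @param x an [expression_matrix()] object.
#' @param path output path (`.csv`, or `.mtx` whose sidecars are written next
#'   to it).
#' @param format `"csv"` or `"mtx"`; inferred from the extension by default.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, format = c("auto", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), csv = "csv",
                     mtx = "mtx", stop("cannot infer format"))
  if (format == "csv") {
    df <- data.frame(cell_id = x$cell_ids, x$counts, check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    Matrix::writeMM(methods::as(Matrix::Matrix(t(x$counts), sparse = TRUE),
                                "generalMatrix"), path)
    dir <- dirname(path)
    writeLines(x$gene_ids, file.path(dir, "features.tsv"))
    writeLines(x$cell_ids, file.path(dir, "barcodes.tsv"))
  }
  invisible(path)
}

#' Quality-control filtering of cells and genes
#'
#' Removes low-coverage cells, then sparsely detected genes: cells expressing
#' (count > 0) fewer than `min_genes_per_cell` genes are dropped first, and
#' genes expressed in fewer than `min_cells_per_gene` of the *remaining*
#' cells are dropped second. The default thresholds (100 genes per cell, 10
#' cells per gene) are the standard ones for sequential-state references.
#'
#' @param x an [expression_matrix()] object.
#' @param min_genes_per_cell integer threshold on detected genes per cell.
#' @param min_cells_per_gene integer threshold on detecting cells per gene.
#' @return a filtered [expression_matrix()].
#' @export
qc_filter <- function(x, min_genes_per_cell = 100, min_cells_per_gene = 10) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  keep_cells <- rowSums(x$counts > 0) >= min_genes_per_cell
  if (!any(keep_cells)) stop("qc_filter removed all cells")
  m <- x$counts[keep_cells, , drop = FALSE]
  keep_genes <- colSums(m > 0) >= min_cells_per_gene
  if (!any(keep_genes)) stop("qc_filter removed all genes")
  expression_matrix(m[, keep_genes, drop = FALSE])
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion — variance over mean of `log1p`-transformed
#' counts — and keeps the `n_hvg` most dispersed. Ties at the cutoff are
#' broken toward the lexicographically smaller gene id; the original column
#' order is preserved among kept genes. When the matrix has at most `n_hvg`
#' genes all are kept with a warning.
#'
#' @param x an [expression_matrix()] object.
#' @param n_hvg number of genes to keep (default 600).
#' @param statistic ranking statistic: `"dispersion"` (variance/mean, the
#'   default) or `"variance"` of the log1p counts.
#' @return an [expression_matrix()] restricted to the selected genes.
#' @export
select_hvgs <- function(x, n_hvg = 600,
                        statistic = c("dispersion", "variance")) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  statistic <- match.arg(statistic)
  if (ncol(x$counts) <= n_hvg) {
    warning("matrix has <= n_hvg genes; keeping all ", ncol(x$counts))
    return(x)
  }
  lg <- log1p(x$counts)
  mu <- colMeans(lg)
  v <- apply(lg, 2, stats::var)
  score <- if (statistic == "dispersion") {
    ifelse(mu > 0, v / mu, 0)
  } else v
  ord <- order(-score, x$gene_ids)   # ties -> lexicographically smaller id
  keep <- sort(ord[seq_len(n_hvg)])  # preserve original gene order
  expression_matrix(x$counts[, keep, drop = FALSE])
}

#' Define an ordered set of cell states
#'
#' @param states character vector (length >= 2) of state names in their
#'   biological sequence — the order given here, never alphabetical order,
#'   defines the ordinal scale.
#' @param labels named character vector or two-column data.frame
#'   (`cell_id`, `state`) assigning each labelled cell to a state.
#' @return an `OrdinalStateSet`: list with `states` and `label_of_cell`
#'   (named integer vector of 1-based state indices).
#' @export
ordinal_states <- function(states, labels) {
  states <- as.character(states)
  if (length(states) < 2) stop("need at least 2 ordered states")
  if (anyDuplicated(states)) stop("duplicate state names")
  if (is.data.frame(labels)) {
    lab <- as.character(labels[[2]])
    names(lab) <- as.character(labels[[1]])
    labels <- lab
  }
  if (is.null(names(labels))) stop("labels must be named by cell_id")
  idx <- match(as.character(labels), states)
  if (anyNA(idx))
    stop("labels contain states outside the ordered list: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  names(idx) <- names(labels)
  structure(list(states = states, label_of_cell = idx),
            class = "OrdinalStateSet")
}

#' @export
print.OrdinalStateSet <- function(x, ...) {
  cat("OrdinalStateSet:", length(x$states), "ordered states (",
      paste(x$states, collapse = " < "), "),",
      length(x$label_of_cell), "labelled cells\n")
  invisible(x)
}

#' Read cell-state labels from a two-column TSV
#'
#' @param path TSV with columns cell_id and state name (no header).
#' @param states ordered character vector of state names, or the path of a
#'   plain-text file listing one state per line in biological order.
#' @return an [ordinal_states()] object.
#' @export
read_labels <- function(path, states) {
  if (length(states) == 1 && file.exists(states))
    states <- readLines(states)
  df <- utils::read.delim(path, header = FALSE, col.names = c("cell_id",
                                                              "state"))
  ordinal_states(states, df)
}
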