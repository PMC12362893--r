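#' Node-embedding table for the dual-layer cell graph
#'
#' Nodes of a cell graph are genes; their feature vectors inject prior
#' gene–gene association knowledge ("dual-layer" mode) or none at all.
#' Three fillers are supported, ordered from no information to most:
#' \describe{
#'   \item{`zeros`}{every gene gets the zero vector — the single-layer
#'     (expression-only) network.}
#'   \item{`one_hot`}{standard basis vectors; genes are distinguishable but
#'     unrelated, `dim` equals the number of genes.}
#'   \item{`distributed`}{vectors from a co-expression embedding table such
#'     as Gene2vec (typically 200-d).}
#' }
#'
#' @param mode one of `"zeros"`, `"one_hot"`, `"distributed"`.
#' @param gene_ids character vector of genes the table must cover.
#' @param dim embedding dimension; ignored for `one_hot` (= number of genes);
#'   default 16 for `zeros`.
#' @param table for `distributed` mode: numeric matrix with genes as
#'   rownames (e.g. from [read_gene_embeddings()]). Genes absent from the
#'   table get the zero vector with a warning.
#' @return a `NodeEmbeddingTable`: list with `mode`, `dim`, and `vectors`
#'   (genes x dim matrix, rownames = gene_ids).
#' @export
node_embeddings <- function(mode = c("zeros", "one_hot", "distributed"),
                            gene_ids, dim = NULL, table = NULL) {
  mode <- match.arg(mode)
  gene_ids <- as.character(gene_ids)
  m <- length(gene_ids)
  vectors <- switch(mode,
    zeros = {
      if (is.null(dim)) dim <- 16L
      matrix(0, m, dim)
    },
    one_hot = {
      dim <- m
      diag(1, m)
    },
    distributed = {
      if (is.null(table)) stop("distributed mode requires an embedding table")
      if (!is.matrix(table) || is.null(rownames(table)))
        stop("embedding table must be a matrix with gene rownames")
      dim <- ncol(table)
      hit <- match(gene_ids, rownames(table))
      v <- matrix(0, m, dim)
      v[!is.na(hit), ] <- table[hit[!is.na(hit)], , drop = FALSE]
      if (anyNA(hit))
        warning(sum(is.na(hit)), " gene(s) missing from the embedding ",
                "table; using zero vectors")
      v
    })
  rownames(vectors) <- gene_ids
  structure(list(mode = mode, dim = as.integer(dim), vectors = vectors),
            class = "NodeEmbeddingTable")
}

#' Read a distributed gene-embedding table
#'
#' Expects the Gene2vec distribution layout: headerless whitespace- or
#' tab-separated text, gene symbol in column 1 and the embedding components
#' in the remaining columns.
#'
#' @param path file path.
#' @return numeric matrix, genes as rownames.
#' @export
read_gene_embeddings <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric embedding components in ", path)
  if (anyDuplicated(genes)) {
    keep <- !duplicated(genes)
    genes <- genes[keep]
    m <- m[keep, , drop = FALSE]
  }
  rownames(m) <- genes
  colnames(m) <- NULL
  m
}
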