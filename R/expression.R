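#' Expression matrix container
#'
#' A lightweight container for a cells x genes expression matrix together
#' with cell/gene identifiers and a layer tag recording what the values
#' mean: `"raw"` (integer counts), `"normalized"` (per-cell scaled counts)
#' or `"lognorm"` (log1p of normalized values).
#'
#' @param values numeric matrix (base or `Matrix` sparse), cells in rows,
#'   genes in columns, all entries non-negative. The raw layer must be
#'   integer-valued.
#' @param cell_ids character vector of unique cell identifiers, length
#'   `nrow(values)`. Defaults to `cell_1..cell_N`.
#' @param gene_ids character vector of unique gene identifiers, length
#'   `ncol(values)`. Defaults to `gene_1..gene_G`.
#' @param layer one of `"raw"`, `"normalized"`, `"lognorm"`.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `cell_ids`, `gene_ids`, `layer`.
#' @export
expression_matrix <- function(values,
                              cell_ids = NULL,
                              gene_ids = NULL,
                              layer = c("raw", "normalized", "lognorm")) {
  layer <- match.arg(layer)
  if (!(is.matrix(values) || methods::is(values, "Matrix")))
    stop("'values' must be a base matrix or a Matrix sparse matrix")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene_", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) != nrow(values): ",
         length(cell_ids), " vs ", nrow(values))
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != ncol(values): ",
         length(gene_ids), " vs ", ncol(values))
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene_ids")
  mn <- min(values)
  if (is.na(mn)) stop("NA values in expression matrix")
  if (mn < 0) stop("negative values in expression matrix")
  if (layer == "raw") {
    v <- if (methods::is(values, "sparseMatrix")) values@x else values
    if (length(v) && any(abs(v - round(v)) > 1e-8))
      stop("raw layer must contain integer counts")
  }
  structure(list(values = values, cell_ids = cell_ids,
                 gene_ids = gene_ids, layer = layer),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes [%s]\n",
              nrow(x$values), ncol(x$values), x$layer))
  dens <- if (methods::is(x$values, "sparseMatrix"))
    length(x$values@x) / prod(dim(x$values))
  else mean(x$values != 0)
  cat(sprintf("  nonzero fraction: %.3f\n", dens))
  invisible(x)
}

# dense numeric view used by compute-heavy paths
em_dense <- function(m) {
  v <- as.matrix(m$values)
  storage.mode(v) <- "double"
  v
}

#' Filter cells and genes by a minimum total count
#'
#' Removes cells whose total count is below `min_count`, then genes whose
#' total count over the retained cells is below `min_count`. With the
#' default `min_count = 1` this drops empty cells and genes only. The
#' operation is idempotent.
#'
#' @param m an `ExpressionMatrix` with `layer = "raw"`.
#' @param min_count positive integer threshold on axis totals.
#' @return the filtered `ExpressionMatrix`.
#' @export
filter_min_count <- function(m, min_count = 1) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw") stop("filter_min_count expects the raw layer")
  if (min_count < 1) stop("min_count must be a positive integer")
  keep_cells <- Matrix::rowSums(m$values) >= min_count
  if (!any(keep_cells)) stop("filtering removed every cell")
  v <- m$values[keep_cells, , drop = FALSE]
  keep_genes <- Matrix::colSums(v) >= min_count
  if (!any(keep_genes)) stop("filtering removed every gene")
  expression_matrix(v[, keep_genes, drop = FALSE],
                    cell_ids = m$cell_ids[keep_cells],
                    gene_ids = m$gene_ids[keep_genes],
                    layer = "raw")
}

#' Per-cell normalization followed by log1p
#'
#' Scales every cell to a common total count, then applies the natural
#' log1p transform elementwise. This is the conventional minimal
#' preprocessing of scRNA-seq counts; `scale = 1e4` matches the default of
#' the standard toolkits.
#'
#' @param m an `ExpressionMatrix` with `layer = "raw"` and no zero-total
#'   cell (run [filter_min_count()] first).
#' @param scale target per-cell total (default 10000).
#' @return an `ExpressionMatrix` with `layer = "lognorm"`.
#' @export
normalize_and_log <- function(m, scale = 1e4) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$layer != "raw") stop("normalize_and_log expects the raw layer")
  if (scale <= 0) stop("scale must be positive")
  totals <- Matrix::rowSums(m$values)
  if (any(totals == 0))
    stop("zero-total cell(s) present; run filter_min_count first")
  v <- m$values * (scale / totals)   # recycles down columns: row scaling
  v <- log1p(v)
  expression_matrix(v, cell_ids = m$cell_ids, gene_ids = m$gene_ids,
                    layer = "lognorm")
}
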