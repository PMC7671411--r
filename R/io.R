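#' Read an expression matrix from disk
#'
#' Supports two on-disk forms: Matrix Market coordinate files with
#' barcode/gene sidecars (the 10x convention: genes as rows, cells as
#' columns, transposed on read), and dense delimited text with a header
#' row of gene ids and a first column of cell ids.
#'
#' @param path path to the `.mtx` file or the delimited file.
#' @param format `"auto"` (by extension), `"mtx"` or `"delimited"`.
#' @param barcodes,genes sidecar paths for mtx input; when `NULL`,
#'   `barcodes.tsv` and `genes.tsv`/`features.tsv` next to `path` are used.
#' @param genes_as_rows for mtx input, whether rows of the on-disk matrix
#'   are genes (default `TRUE`, the 10x dialect).
#' @param sep field separator for delimited input (`"auto"` lets
#'   `data.table::fread` detect it).
#' @return an `ExpressionMatrix` with `layer = "raw"`, oriented cells x
#'   genes regardless of on-disk orientation.
#' @export
read_expression <- function(path, format = c("auto", "mtx", "delimited"),
                            barcodes = NULL, genes = NULL,
                            genes_as_rows = TRUE, sep = "auto") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path, ignore.case = TRUE)) "mtx" else "delimited"
  if (format == "mtx")
    read_expression_mtx(path, barcodes, genes, genes_as_rows)
  else
    read_expression_delim(path, sep)
}

read_expression_mtx <- function(path, barcodes, genes, genes_as_rows) {
  check_mtx_header(path)
  v <- tryCatch(Matrix::readMM(path),
                error = function(e) stop("malformed Matrix Market file ",
                                         path, ": ", conditionMessage(e)))
  dirn <- dirname(path)
  if (is.null(barcodes)) barcodes <- file.path(dirn, "barcodes.tsv")
  if (is.null(genes)) {
    genes <- file.path(dirn, "genes.tsv")
    if (!file.exists(genes)) genes <- file.path(dirn, "features.tsv")
  }
  if (!file.exists(barcodes)) stop("barcode sidecar not found: ", barcodes)
  if (!file.exists(genes)) stop("gene sidecar not found: ", genes)
  bc <- utils::read.delim(barcodes, header = FALSE,
                          stringsAsFactors = FALSE)[[1]]
  gn_tab <- utils::read.delim(genes, header = FALSE, stringsAsFactors = FALSE)
  # 10x feature files carry (id, symbol, ...); use the first column
  gn <- gn_tab[[1]]
  if (genes_as_rows) v <- Matrix::t(v)
  if (nrow(v) != length(bc))
    stop("barcode sidecar has ", length(bc), " entries but matrix has ",
         nrow(v), " cells (", path, ")")
  if (ncol(v) != length(gn))
    stop("gene sidecar has ", length(gn), " entries but matrix has ",
         ncol(v), " genes (", path, ")")
  v <- methods::as(v, "CsparseMatrix")
  expression_matrix(v, cell_ids = bc, gene_ids = gn, layer = "raw")
}

# validates header vs number of triplet lines before handing to readMM
check_mtx_header <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- lines[!startsWith(lines, "%")]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("empty Matrix Market file: ", path)
  hdr <- suppressWarnings(as.numeric(strsplit(trimws(body[1]), "\\s+")[[1]]))
  if (length(hdr) != 3 || anyNA(hdr))
    stop("malformed Matrix Market size header in ", path, ": '", body[1], "'")
  nnz <- hdr[3]
  if (length(body) - 1 != nnz)
    stop("Matrix Market header in ", path, " declares ", nnz,
         " entries but file has ", length(body) - 1, " triplet lines")
  invisible(TRUE)
}

read_expression_delim <- function(path, sep) {
  dt <- if (identical(sep, "auto"))
    data.table::fread(path, header = TRUE, data.table = FALSE)
  else
    data.table::fread(path, header = TRUE, sep = sep, data.table = FALSE)
  if (ncol(dt) < 2)
    stop("delimited file ", path, " needs a cell-id column plus >=1 gene")
  cell_ids <- as.character(dt[[1]])
  v <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(v)) stop("non-numeric entries in ", path)
  if (anyNA(v)) stop("missing values in ", path)
  if (min(v) < 0) stop("negative entries in ", path)
  expression_matrix(v, cell_ids = cell_ids,
                    gene_ids = colnames(dt)[-1], layer = "raw")
}

#' Write cluster labels and an embedding to delimited files
#'
#' Writes `<prefix>_labels.tsv` (columns `cell_id`, `cluster`) and
#' `<prefix>_embedding.tsv` (`cell_id` plus one column per embedding
#' dimension). Both round-trip losslessly at 15 significant digits.
#'
#' @param labels vector of cluster labels, one per cell.
#' @param embedding numeric N x d matrix.
#' @param prefix output path prefix.
#' @param cell_ids optional cell identifiers; defaults to `cell_1..cell_N`.
#' @return invisibly, the two file paths written.
#' @export
write_results <- function(labels, embedding, prefix, cell_ids = NULL) {
  if (length(labels) == 0) stop("empty label vector")
  embedding <- as.matrix(embedding)
  if (length(labels) != nrow(embedding))
    stop("length(labels) = ", length(labels), " but embedding has ",
         nrow(embedding), " rows")
  if (is.null(cell_ids)) cell_ids <- paste0("cell_", seq_along(labels))
  lab_path <- paste0(prefix, "_labels.tsv")
  emb_path <- paste0(prefix, "_embedding.tsv")
  utils::write.table(data.frame(cell_id = cell_ids, cluster = labels),
                     lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  emb <- data.frame(cell_id = cell_ids,
                    signif(embedding, 15), check.names = FALSE)
  colnames(emb) <- c("cell_id", paste0("dim_", seq_len(ncol(embedding))))
  utils::write.table(emb, emb_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(labels = lab_path, embedding = emb_path))
}

#' Read a label TSV written by [write_results()]
#' @param path path to a two-column labels file.
#' @return named vector of labels (names are cell ids).
#' @export
read_labels <- function(path) {
  dt <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(dt[[2]], dt[[1]])
}

#' Read an embedding TSV written by [write_results()]
#' @param path path to the embedding file.
#' @return numeric matrix with cell ids as rownames.
#' @export
read_embedding <- function(path) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  m <- as.matrix(dt[, -1, drop = FALSE])
  rownames(m) <- as.character(dt[[1]])
  m
}

#' Write an expression matrix as dense delimited text
#' @param m an `ExpressionMatrix`.
#' @param path output path (TSV: header of gene ids, first column cell ids).
#' @return invisibly, `path`.
#' @export
write_expression <- function(m, path) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(cell_id = m$cell_ids, as.matrix(m$values),
                   check.names = FALSE)
  colnames(df) <- c("cell_id", m$gene_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
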