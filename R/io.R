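#' Read a count matrix (MTX directory or dense CSV)
#'
#' MTX input is a directory holding `matrix.mtx` with sidecars
#' `genes.tsv` and `barcodes.tsv` (one id per line); indices in the file
#' are 1-based per the MatrixMarket standard and map to the first
#' gene/first cell. CSV input is dense with gene ids in the first
#' column and cell ids as header.
#'
#' @param path directory (MTX) or `.csv` file.
#' @return genes x cells sparse dgCMatrix with dimnames.
#' @export
read_counts <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    gf <- file.path(path, "genes.tsv")
    bf <- file.path(path, "barcodes.tsv")
    for (f in c(mtx, gf, bf)) if (!file.exists(f))
      abort_validation("missing file: %s", f)
    m <- methods::as(Matrix::readMM(mtx), "CsparseMatrix")
    genes <- readLines(gf)
    cells <- readLines(bf)
    if (nrow(m) != length(genes) || ncol(m) != length(cells))
      abort_validation(
        "%s: matrix is %d x %d but sidecars list %d genes and %d cells",
        path, nrow(m), ncol(m), length(genes), length(cells))
    if (length(genes)) rownames(m) <- genes
    if (length(cells)) colnames(m) <- cells
    if (length(m) == 0L) warning("count matrix at ", path, " is empty")
    m
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, row.names = 1L, check.names = FALSE)
    m <- methods::as(Matrix::Matrix(as.matrix(df), sparse = TRUE),
                     "CsparseMatrix")
    if (length(m) == 0L) warning("count matrix at ", path, " is empty")
    m
  } else abort_validation("cannot read counts from '%s' (need dir or .csv)",
                          path)
}

#' Write a count matrix as MTX with gene/barcode sidecars
#'
#' @param counts genes x cells matrix with dimnames.
#' @param path output directory (created if needed).
#' @export
write_counts <- function(counts, path) {
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts))))
    abort_validation("counts need gene and cell ids as dimnames")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  Matrix::writeMM(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                              "CsparseMatrix"),
                  file.path(path, "matrix.mtx"))
  writeLines(rownames(counts) %||% character(0),
             file.path(path, "genes.tsv"))
  writeLines(colnames(counts) %||% character(0),
             file.path(path, "barcodes.tsv"))
  invisible(path)
}

#' Read / write a cell table as TSV
#' @param path TSV file.
#' @export
read_cell_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  check_columns(df, "cell_id", sprintf("cell table '%s'", path))
  if ("doublet_flag" %in% names(df))
    df$doublet_flag <- as.logical(df$doublet_flag)
  df
}

#' @rdname read_cell_table
#' @param cells cell table data.frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.table(cells, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write an embedding as CSV (cell ids in the first column)
#' @param path CSV file.
#' @export
read_embedding <- function(path) {
  as.matrix(utils::read.csv(path, row.names = 1L, check.names = FALSE))
}

#' @rdname read_embedding
#' @param embedding cells x dims matrix with rownames.
#' @export
write_embedding <- function(embedding, path) {
  utils::write.csv(as.data.frame(embedding), path, row.names = TRUE)
  invisible(path)
}

#' Export a cluster tree to JSON or Newick
#'
#' JSON carries the full payload (levels, per-level labels, node table,
#' centroids) and re-imports exactly via [import_tree_json()]; Newick
#' carries topology and node names only, with reserved characters
#' quoted per the Newick standard.
#'
#' @param tree a [cluster_tree].
#' @param path output file.
#' @param format `"json"` or `"newick"`.
#' @export
export_tree <- function(tree, path, format = c("json", "newick")) {
  format <- match.arg(format)
  if (format == "json") {
    payload <- list(
      cell_ids = tree$cell_ids,
      levels = tree$levels,
      labels = as.data.frame(tree$labels, stringsAsFactors = FALSE),
      nodes = tree$nodes,
      centroids = if (!is.null(tree$centroids)) list(
        node_id = rownames(tree$centroids),
        dims = colnames(tree$centroids),
        values = unname(apply(tree$centroids, 1L, c, simplify = FALSE))
      ),
      reconciliation_cost = tree$reconciliation_cost
    )
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    writeLines(tree_to_newick(tree), path)
  }
  invisible(path)
}

#' @rdname export_tree
#' @export
import_tree_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- as.matrix(p$labels)
  rownames(labels) <- p$cell_ids
  colnames(labels) <- p$levels
  tree <- cluster_tree(labels)
  if (!is.null(p$centroids) && length(p$centroids)) {
    vals <- p$centroids$values
    cents <- if (is.list(vals)) do.call(rbind, vals) else as.matrix(vals)
    dimnames(cents) <- list(p$centroids$node_id, p$centroids$dims)
    tree$centroids <- cents[tree$nodes$node_id, , drop = FALSE]
  }
  tree$reconciliation_cost <- as.integer(p$reconciliation_cost %||% 0L)
  tree
}

newick_quote <- function(x) {
  reserved <- grepl("[](),:;'[ \t]", x)
  x[reserved] <- paste0("'", gsub("'", "''", x[reserved]), "'")
  x
}

#' Newick string for a cluster tree (topology and names only)
#' @param tree a [cluster_tree].
#' @export
tree_to_newick <- function(tree) {
  recurse <- function(node) {
    kids <- tree_children(tree, node)
    if (!length(kids)) return(newick_quote(node))
    paste0("(", paste(vapply(sort(kids), recurse, character(1)),
                      collapse = ","), ")", newick_quote(node))
  }
  roots <- sort(tree$nodes$node_id[is.na(tree$nodes$parent)])
  paste0("(", paste(vapply(roots, recurse, character(1)), collapse = ","),
         ")root;")
}

#' Read / write per-level cluster labels as TSV
#'
#' Wide table: `cell_id` column plus one column per level.
#' @param path TSV file.
#' @export
read_labels <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          check.names = FALSE)
  check_columns(df, "cell_id", sprintf("label table '%s'", path))
  m <- as.matrix(df[, setdiff(names(df), "cell_id"), drop = FALSE])
  rownames(m) <- df$cell_id
  m
}

#' @rdname read_labels
#' @param labels matrix or named vector of labels.
#' @export
write_labels <- function(labels, path) {
  if (is.null(dim(labels)))
    labels <- matrix(labels, ncol = 1L,
                     dimnames = list(names(labels), "label"))
  df <- data.frame(cell_id = rownames(labels), labels,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a homology table (gene_a, gene_b, similarity) from TSV
#' @param path TSV file.
#' @export
read_homology <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_columns(df, c("gene_a", "gene_b", "similarity"),
                sprintf("homology table '%s'", path))
  df
}

#' Read / write a generic numeric matrix as TSV (row ids first column)
#' @param path TSV file.
#' @export
read_matrix_tsv <- function(path) {
  as.matrix(utils::read.delim(path, row.names = 1L, check.names = FALSE))
}

#' @rdname read_matrix_tsv
#' @param m matrix with dimnames.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), as.data.frame(m),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a generic data.frame as TSV
#' @param df data.frame.
#' @param path TSV file.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
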