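# Neutral single-cell container: a cells x genes count matrix with cell
# and gene metadata tables and named 2D embeddings. Readers accept
# MarketMatrix (MTX + genes/barcodes TSVs) or dense TSV counts and
# CSV/TSV metadata/embeddings; orientation is normalized to cells x genes
# on load.

#' Construct a single-cell dataset
#'
#' @param counts Non-negative count matrix, cells in rows, genes in
#'   columns (a sparse `Matrix` is densified). Dimnames are generated when
#'   missing.
#' @param cell_meta Data frame with one row per cell (categorical and
#'   numeric covariates such as condition, batch, cell type).
#' @param gene_meta Data frame with one row per gene; a logical `mito`
#'   column flags mitochondrial genes. When absent, genes whose id starts
#'   with `"MT-"` (case-insensitive) are flagged.
#' @param embeddings Named list of per-cell 2-column coordinate matrices.
#' @return An `sc_dataset` object.
#' @export
sc_dataset <- function(counts, cell_meta = NULL, gene_meta = NULL,
                       embeddings = list()) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    dw_stop("counts must be a numeric matrix (cells x genes)", "validation")
  }
  if (any(counts < 0)) dw_stop("counts must be non-negative", "validation")
  n_cells <- nrow(counts); n_genes <- ncol(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%0*d", nchar(n_cells), seq_len(n_cells))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("gene%0*d", nchar(n_genes), seq_len(n_genes))
  }
  if (anyDuplicated(colnames(counts))) dw_stop("gene ids must be unique", "validation")
  if (is.null(cell_meta)) cell_meta <- data.frame(row.names = rownames(counts))
  if (nrow(cell_meta) != n_cells) {
    dw_stop(sprintf("cell_meta has %d rows for %d cells", nrow(cell_meta), n_cells),
            "validation")
  }
  if (is.null(gene_meta)) {
    gene_meta <- data.frame(gene_id = colnames(counts), stringsAsFactors = FALSE)
  }
  if (!"gene_id" %in% names(gene_meta)) gene_meta$gene_id <- colnames(counts)
  if (nrow(gene_meta) != n_genes) {
    dw_stop(sprintf("gene_meta has %d rows for %d genes", nrow(gene_meta), n_genes),
            "validation")
  }
  if (!"mito" %in% names(gene_meta)) {
    gene_meta$mito <- grepl("^mt-", gene_meta$gene_id, ignore.case = TRUE)
  }
  gene_meta$mito <- as.logical(gene_meta$mito)
  embeddings <- lapply(embeddings, function(e) {
    e <- as.matrix(e)
    if (nrow(e) != n_cells || ncol(e) != 2L) {
      dw_stop("each embedding needs one (x, y) pair per cell", "validation")
    }
    colnames(e) <- c("x", "y")
    e
  })
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta, embeddings = embeddings),
            class = "sc_dataset")
}

#' @export
print.sc_dataset <- function(x, ...) {
  cat(sprintf("sc_dataset: %d cells x %d genes (%d mitochondrial)\n",
              nrow(x$counts), ncol(x$counts), sum(x$gene_meta$mito)))
  if (ncol(x$cell_meta)) {
    cat("  cell covariates:", paste(names(x$cell_meta), collapse = ", "), "\n")
  }
  if (length(x$embeddings)) {
    cat("  embeddings:", paste(names(x$embeddings), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.sc_dataset <- function(x) dim(x$counts)

read_delim_auto <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  utils::read.table(path, sep = sep, header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a single-cell dataset from files
#'
#' @param counts Path to counts: `.mtx` (MatrixMarket, with `genes` and
#'   `barcodes` TSVs giving the dimension names) or a dense TSV with cell
#'   ids in the first column and genes in the header.
#' @param genes,barcodes For MTX input: single-column TSVs of gene and
#'   cell ids. The matrix may be stored genes x cells (the common exchange
#'   convention) or cells x genes; orientation is inferred from the id
#'   counts.
#' @param cell_meta,gene_meta Optional CSV/TSV metadata paths.
#' @param embeddings Named character vector of TSV paths, each with
#'   columns x and y (or two unnamed columns) per cell.
#' @return An [sc_dataset()].
#' @export
read_sc_dataset <- function(counts, genes = NULL, barcodes = NULL,
                            cell_meta = NULL, gene_meta = NULL,
                            embeddings = character()) {
  if (!file.exists(counts)) dw_stop(sprintf("counts file not found: %s", counts), "io")
  if (tolower(tools::file_ext(counts)) == "mtx") {
    if (is.null(genes) || is.null(barcodes)) {
      dw_stop("MTX input needs 'genes' and 'barcodes' id files", "io")
    }
    M <- as.matrix(Matrix::readMM(counts))
    gid <- readLines(genes); bid <- readLines(barcodes)
    if (nrow(M) == length(gid) && ncol(M) == length(bid)) {
      M <- t(M) # stored genes x cells
    } else if (!(nrow(M) == length(bid) && ncol(M) == length(gid))) {
      dw_stop("MTX dimensions match neither genes x cells nor cells x genes", "io")
    }
    dimnames(M) <- list(bid, gid)
  } else {
    df <- read_delim_auto(counts)
    M <- as.matrix(df[, -1, drop = FALSE])
    rownames(M) <- df[[1]]
  }
  cm <- if (!is.null(cell_meta)) read_delim_auto(cell_meta)
  gm <- if (!is.null(gene_meta)) read_delim_auto(gene_meta)
  emb <- lapply(embeddings, function(p) {
    e <- read_delim_auto(p)
    cols <- if (all(c("x", "y") %in% names(e))) c("x", "y") else utils::tail(names(e), 2)
    as.matrix(e[, cols])
  })
  names(emb) <- names(embeddings)
  sc_dataset(M, cell_meta = cm, gene_meta = gm, embeddings = emb)
}

#' Write a dataset as plain-text fixture files
#'
#' Emits `matrix.mtx`, `genes.tsv`, `barcodes.tsv`, `cell_meta.tsv`,
#' `gene_meta.tsv` and one `embedding_<name>.tsv` per embedding — the file
#' set [read_sc_dataset()] consumes, closing the reader/writer loop.
#'
#' @param ds An [sc_dataset()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of written paths.
#' @export
write_sc_fixtures <- function(ds, dir) {
  stopifnot(inherits(ds, "sc_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    barcodes = file.path(dir, "barcodes.tsv"),
    cell_meta = file.path(dir, "cell_meta.tsv"),
    gene_meta = file.path(dir, "gene_meta.tsv")
  )
  # genes x cells, the common exchange orientation
  Matrix::writeMM(Matrix::Matrix(t(ds$counts), sparse = TRUE), paths["counts"])
  writeLines(colnames(ds$counts), paths["genes"])
  writeLines(rownames(ds$counts), paths["barcodes"])
  cm <- cbind(cell_id = rownames(ds$counts), ds$cell_meta)
  utils::write.table(cm, paths["cell_meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$gene_meta, paths["gene_meta"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (nm in names(ds$embeddings)) {
    p <- file.path(dir, sprintf("embedding_%s.tsv", nm))
    utils::write.table(data.frame(cell_id = rownames(ds$counts),
                                  ds$embeddings[[nm]]),
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[paste0("embedding_", nm)] <- p
  }
  invisible(paths)
}
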