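#' Single-cell count matrix with cell and gene metadata
#'
#' A `CountMatrix` bundles a sparse cells-by-genes matrix of non-negative
#' integer counts with a cell table (cell id, tissue label) and a gene table
#' (gene id, spike-in flag, spike-in concentration in amol/ul where known).
#' It is the common currency of the package: the synthetic generators emit
#' one, the quality filters take and return one, and the estimators consume
#' one.
#'
#' @param counts matrix or sparse Matrix of non-negative integer counts,
#'   cells as rows and genes as columns.  A genes-by-cells matrix is
#'   accepted and transposed when the metadata tables disambiguate the
#'   orientation.
#' @param cells data.frame with at least columns `cell_id` and `tissue`,
#'   one row per cell, in row order of `counts`.
#' @param genes data.frame with at least column `gene_id`, one row per gene,
#'   in column order of `counts`.  Columns `is_spikein` (logical) and
#'   `concentration` (numeric, amol/ul) are added (as `FALSE`/`NA`) when
#'   absent.
#'
#' @return An object of class `CountMatrix`: a list with elements `counts`
#'   (a `dgCMatrix`, cells x genes, dimnames set from the metadata),
#'   `cells` and `genes` (data.frames as above).
#' @export
CountMatrix <- function(counts, cells, genes) {
  if (!is.data.frame(cells) || is.null(cells$cell_id) || is.null(cells$tissue))
    stop("'cells' must be a data.frame with columns cell_id and tissue")
  if (!is.data.frame(genes) || is.null(genes$gene_id))
    stop("'genes' must be a data.frame with a gene_id column")
  if (anyNA(cells$tissue))
    stop("every cell must carry a tissue label")
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (nrow(counts) == nrow(genes) && ncol(counts) == nrow(cells) &&
      nrow(counts) != nrow(cells)) {
    counts <- Matrix::t(counts)   # accept genes x cells, store cells x genes
  }
  if (nrow(counts) != nrow(cells) || ncol(counts) != nrow(genes))
    stop("count matrix dimensions do not match the cell/gene tables")
  vals <- counts@x
  if (length(vals)) {
    if (any(vals < 0)) stop("counts must be non-negative")
    if (any(vals != round(vals))) stop("counts must be integral")
  }
  if (is.null(genes$is_spikein)) genes$is_spikein <- FALSE
  genes$is_spikein[is.na(genes$is_spikein)] <- FALSE
  if (is.null(genes$concentration)) genes$concentration <- NA_real_
  dimnames(counts) <- list(as.character(cells$cell_id),
                           as.character(genes$gene_id))
  structure(list(counts = counts, cells = cells, genes = genes),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%d spike-ins), %d tissue(s)\n",
              nrow(x$counts), ncol(x$counts), sum(x$genes$is_spikein),
              length(unique(x$cells$tissue))))
  invisible(x)
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' Number of cells per tissue
#' @param x a CountMatrix
#' @return named integer vector, one entry per tissue label
#' @export
cells_per_tissue <- function(x) {
  stopifnot(inherits(x, "CountMatrix"))
  tab <- table(x$cells$tissue)
  stats::setNames(as.integer(tab), names(tab))
}

#' Per-cell total counts
#'
#' @param x a CountMatrix
#' @param include_spikeins include spike-in genes in the totals
#'   (default `FALSE`: totals reflect endogenous transcripts only)
#' @return numeric vector of totals, one per cell
#' @export
cell_totals <- function(x, include_spikeins = FALSE) {
  stopifnot(inherits(x, "CountMatrix"))
  keep <- if (include_spikeins) rep(TRUE, ncol(x$counts)) else !x$genes$is_spikein
  Matrix::rowSums(x$counts[, keep, drop = FALSE])
}

#' Per-cell number of genes detected (count > 0)
#' @inheritParams cell_totals
#' @export
genes_detected <- function(x, include_spikeins = FALSE) {
  stopifnot(inherits(x, "CountMatrix"))
  keep <- if (include_spikeins) rep(TRUE, ncol(x$counts)) else !x$genes$is_spikein
  Matrix::rowSums(x$counts[, keep, drop = FALSE] > 0)
}

subset_countmatrix <- function(x, cells = NULL, genes = NULL) {
  if (is.null(cells)) cells <- seq_len(nrow(x$counts))
  if (is.null(genes)) genes <- seq_len(ncol(x$counts))
  out <- x
  out$counts <- x$counts[cells, genes, drop = FALSE]
  out$cells <- x$cells[cells, , drop = FALSE]
  out$genes <- x$genes[genes, , drop = FALSE]
  rownames(out$cells) <- NULL
  rownames(out$genes) <- NULL
  out
}

#' Write a count matrix to Matrix Market plus TSV sidecars
#'
#' The layout is a sparse `.mtx` file (cells as rows) plus two tab-delimited
#' sidecars, `cells.tsv` (`cell_id`, `tissue`, ...) and `genes.tsv`
#' (`gene_id`, `is_spikein`, `concentration`, ...), both with a header row.
#' [read_counts()] consumes the same layout losslessly.
#'
#' @param x a CountMatrix
#' @param dir output directory (created if missing)
#' @return invisibly, a named character vector of the three file paths
#' @export
write_counts <- function(x, dir) {
  stopifnot(inherits(x, "CountMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(matrix = file.path(dir, "counts.mtx"),
             cells = file.path(dir, "cells.tsv"),
             genes = file.path(dir, "genes.tsv"))
  Matrix::writeMM(x$counts, paths[["matrix"]])
  utils::write.table(x$cells, paths[["cells"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.table(x$genes, paths[["genes"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read a count matrix written by [write_counts()]
#'
#' Orientation is inferred from the sidecar row counts; spike-ins are
#' (re-)identified by gene-id prefix so that ERCC panels are flagged even
#' when the gene table lacks an `is_spikein` column.
#'
#' @param matrix_path path to the `.mtx` file
#' @param cells_path path to the cell sidecar TSV
#' @param genes_path path to the gene sidecar TSV
#' @param spikein_prefix gene-id prefix marking spike-in sequences
#'   (default `"ERCC-"`)
#' @return a [CountMatrix()]
#' @export
read_counts <- function(matrix_path, cells_path, genes_path,
                        spikein_prefix = "ERCC-") {
  for (p in c(matrix_path, cells_path, genes_path))
    if (!file.exists(p)) stop("file not found: ", p)
  m <- Matrix::readMM(matrix_path)
  cells <- utils::read.delim(cells_path, stringsAsFactors = FALSE)
  genes <- utils::read.delim(genes_path, stringsAsFactors = FALSE)
  if (is.null(cells$tissue)) stop("cell sidecar lacks a 'tissue' column")
  if (nrow(m) != nrow(cells)) {
    if (nrow(m) == nrow(genes) && ncol(m) == nrow(cells)) m <- Matrix::t(m)
    else stop("matrix dimensions are inconsistent with the sidecars")
  }
  pref_hit <- startsWith(as.character(genes$gene_id), spikein_prefix)
  if (is.null(genes$is_spikein)) genes$is_spikein <- pref_hit
  else genes$is_spikein <- genes$is_spikein | pref_hit
  CountMatrix(m, cells, genes)
}

#' FACS-protocol quality filter
#'
#' Per-cell counts strictly below `min_cell_count` are zeroed first (weak
#' signals are neglected); genes whose total count after zeroing is not
#' strictly greater than `min_gene_total` are then dropped.  Spike-ins are
#' zeroed like other genes but exempt from the gene-total drop, so they
#' remain available for diagnostics.  With `per_tissue = TRUE` (default)
#' the gene-total criterion is applied within each tissue and counts of a
#' gene are zeroed in tissues where it fails; a gene failing in every
#' tissue is dropped.
#'
#' @param x a CountMatrix
#' @param min_gene_total genes must exceed this total to be kept (strict `>`)
#' @param min_cell_count entries strictly below this are zeroed
#' @param per_tissue apply the gene-total criterion per tissue
#' @return the filtered CountMatrix, with a `filter_report` attribute
#'   (list: `entries_zeroed`, `genes_dropped`, `genes_kept`)
#' @export
filter_facs <- function(x, min_gene_total = 500, min_cell_count = 10,
                        per_tissue = TRUE) {
  stopifnot(inherits(x, "CountMatrix"))
  if (min_gene_total < 0 || min_cell_count < 0)
    stop("filter thresholds must be non-negative")
  m <- x$counts
  low <- m@x < min_cell_count
  n_zeroed <- sum(low)
  if (n_zeroed) {
    m@x[low] <- 0
    m <- Matrix::drop0(m)
  }
  spike <- x$genes$is_spikein
  if (per_tissue) {
    tissues <- unique(x$cells$tissue)
    pass_any <- rep(FALSE, ncol(m))
    for (k in tissues) {
      rows <- which(x$cells$tissue == k)
      tot <- Matrix::colSums(m[rows, , drop = FALSE])
      fail <- tot <= min_gene_total & !spike
      pass_any <- pass_any | !fail
      if (any(fail)) m[rows, which(fail)] <- 0   # gene treated as absent here
    }
    keep <- pass_any
  } else {
    tot <- Matrix::colSums(m)
    keep <- tot > min_gene_total | spike
  }
  m <- Matrix::drop0(m)
  out <- x
  out$counts <- m
  out <- subset_countmatrix(out, genes = which(keep))
  attr(out, "filter_report") <- list(entries_zeroed = n_zeroed,
                                     genes_dropped = sum(!keep),
                                     genes_kept = sum(keep))
  out
}

#' Droplet-protocol quality filter
#'
#' Removes cells with fewer than `min_total_reads` total reads or fewer
#' than `min_genes` genes detected (count > 0); both thresholds are
#' inclusive ("at least").  Spike-ins are excluded from both per-cell
#' totals and the detected-gene count.  Counts of surviving cells are
#' untouched.
#'
#' @param x a CountMatrix
#' @param min_total_reads minimum total reads per cell (inclusive)
#' @param min_genes minimum genes detected per cell (inclusive)
#' @return the filtered CountMatrix with a `filter_report` attribute
#'   (list: `cells_dropped`, `cells_kept`)
#' @export
filter_droplet <- function(x, min_total_reads = 1000, min_genes = 500) {
  stopifnot(inherits(x, "CountMatrix"))
  if (min_total_reads < 0 || min_genes < 0)
    stop("filter thresholds must be non-negative")
  tot <- cell_totals(x, include_spikeins = FALSE)
  det <- genes_detected(x, include_spikeins = FALSE)
  keep <- tot >= min_total_reads & det >= min_genes
  out <- subset_countmatrix(x, cells = which(keep))
  attr(out, "filter_report") <- list(cells_dropped = sum(!keep),
                                     cells_kept = sum(keep))
  out
}
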