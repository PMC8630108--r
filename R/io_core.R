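#' @importFrom Matrix readMM writeMM rowSums colSums t sparseMatrix
#' @importFrom methods as is
#' @importFrom stats median sd
NULL

# Default gene blacklist: highly but uninformatively expressed across all
# bone-marrow cell types in myeloma; removed before visualisation/DE.
BLACKLIST_GENES <- c(
  "SLC25A6", "CD99", "IL3RA", "CSF2RA", "MTRNR2L8", "MTRNR2L12",
  "ARL6IP4", "POLR2F", "GTPBP6", "EEF1A1", "H3F3A", "TMSB4X"
)

IG_PREFIXES <- c("IGH", "IGK", "IGL")

#' Construct an expression matrix container
#'
#' Bundles a raw integer count matrix (cells x genes) with per-cell and
#' per-gene annotations. Counts are stored sparse (`dgCMatrix`).
#'
#' @param counts non-negative integer matrix or sparse Matrix, cells in rows.
#' @param cell_meta data.frame with one row per cell (may carry `patient_id`,
#'   `timepoint`, `fraction`, `cell_type`, `doublet_score`). Row order must
#'   match `rownames(counts)`.
#' @param gene_meta data.frame with one row per gene (may carry logical
#'   `mito`, `blacklist` flags).
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `counts`, `cell_meta`, `gene_meta`.
#' @export
expression_matrix <- function(counts, cell_meta = NULL, gene_meta = NULL) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry cell (row) and gene (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")
  if (any(counts@x < 0)) stop("negative counts")
  if (any(counts@x != round(counts@x))) stop("non-integer counts")
  if (is.null(cell_meta))
    cell_meta <- data.frame(row.names = rownames(counts))
  if (is.null(gene_meta))
    gene_meta <- data.frame(row.names = colnames(counts))
  stopifnot(nrow(cell_meta) == nrow(counts), nrow(gene_meta) == ncol(counts))
  rownames(cell_meta) <- rownames(counts)
  rownames(gene_meta) <- colnames(counts)
  structure(list(counts = counts, cell_meta = cell_meta, gene_meta = gene_meta),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes (%d nonzero)\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  if (ncol(x$cell_meta))
    cat("cell_meta:", paste(colnames(x$cell_meta), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$counts)

#' Read a 10x-style MTX triplet count matrix
#'
#' Reads a Matrix Market coordinate file together with its barcode and
#' feature TSVs and returns a cells-by-genes [expression_matrix()]. 10x
#' convention stores genes in rows; set `cells_in_rows = TRUE` if the file
#' is already cells x genes.
#'
#' @param matrix_path path to the .mtx file.
#' @param barcodes_path one barcode per line.
#' @param features_path one feature id per line (first tab-separated column
#'   is used).
#' @param cells_in_rows on-disk orientation flag.
#' @param cell_meta optional per-cell annotation data.frame or TSV path
#'   (header; first column or a `cell_id` column keys the barcode).
#' @return an `ExpressionMatrix`.
#' @export
read_counts <- function(matrix_path, barcodes_path, features_path,
                        cells_in_rows = FALSE, cell_meta = NULL) {
  m <- Matrix::readMM(matrix_path)
  barcodes <- readLines(barcodes_path)
  feats <- read.delim(features_path, header = FALSE, stringsAsFactors = FALSE)[[1]]
  if (!cells_in_rows) m <- Matrix::t(m)
  if (nrow(m) != length(barcodes))
    stop(sprintf("matrix has %d cells but barcodes file lists %d",
                 nrow(m), length(barcodes)))
  if (ncol(m) != length(feats))
    stop(sprintf("matrix has %d genes but features file lists %d",
                 ncol(m), length(feats)))
  if (any(m@x != round(m@x))) stop("matrix contains non-integer values")
  dimnames(m) <- list(barcodes, feats)
  if (is.character(cell_meta)) {
    cm <- read.delim(cell_meta, stringsAsFactors = FALSE)
    key <- if ("cell_id" %in% colnames(cm)) cm$cell_id else cm[[1]]
    rownames(cm) <- key
    cell_meta <- cm[barcodes, setdiff(colnames(cm), "cell_id"), drop = FALSE]
  }
  expression_matrix(m, cell_meta = cell_meta)
}

#' Write an expression matrix as MTX + barcodes + features
#'
#' Inverse of [read_counts()]; writes genes in rows (10x convention).
#'
#' @param m an `ExpressionMatrix`.
#' @param dir output directory, created if absent.
#' @param prefix file-name prefix.
#' @return invisibly, the three paths written.
#' @export
write_counts <- function(m, dir, prefix = "") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(prefix, c("matrix.mtx", "barcodes.tsv", "features.tsv")))
  Matrix::writeMM(Matrix::t(m$counts), paths[1])
  writeLines(rownames(m$counts), paths[2])
  writeLines(colnames(m$counts), paths[3])
  invisible(paths)
}

#' Quality-control filtering of cells and genes
#'
#' Removes low-quality cell libraries: cells with fewer than `min_genes`
#' detected genes, more than `max_mito_frac` mitochondrial counts, or a
#' doublet score above `doublet_threshold` are discarded (boundary cells are
#' retained; removal is strict `<` / `>`). Optionally drops blacklist and
#' immunoglobulin genes from the gene axis, keeping their raw counts as
#' metadata.
#'
#' @param m an `ExpressionMatrix`.
#' @param min_genes minimum detected (nonzero) genes per cell.
#' @param max_mito_frac maximum mitochondrial count fraction, computed on the
#'   raw matrix before any gene removal.
#' @param doublet_threshold cells with `doublet_score` above this are removed;
#'   cells without a score are kept.
#' @param drop_blacklist drop the fixed 12-gene blacklist plus any gene
#'   flagged `blacklist` in `gene_meta`.
#' @param drop_immunoglobulin drop genes matching the IGH/IGK/IGL prefixes.
#' @param mito_prefix gene-name prefixes identifying mitochondrial genes when
#'   `gene_meta$mito` is absent.
#' @param ig_prefixes immunoglobulin gene-name prefixes.
#' @return a filtered `ExpressionMatrix`. Removed gene counts are stored in
#'   `$removed_counts` (a cells x removed-genes sparse matrix) and per-cell
#'   immunoglobulin totals in `cell_meta$ig_counts`.
#' @export
qc_filter <- function(m, min_genes = 400, max_mito_frac = 0.10,
                      doublet_threshold = 0.4, drop_blacklist = TRUE,
                      drop_immunoglobulin = TRUE, mito_prefix = "MT-",
                      ig_prefixes = IG_PREFIXES) {
  counts <- m$counts
  n_detected <- Matrix::rowSums(counts > 0)
  totals <- Matrix::rowSums(counts)
  mito <- if ("mito" %in% colnames(m$gene_meta)) {
    isTRUE_vec(m$gene_meta$mito)
  } else {
    startsWith_any(colnames(counts), mito_prefix)
  }
  mito_frac <- if (any(mito)) {
    as.numeric(Matrix::rowSums(counts[, mito, drop = FALSE])) / pmax(totals, 1)
  } else rep(0, nrow(counts))
  dscore <- m$cell_meta$doublet_score
  pass_doublet <- if (is.null(dscore)) rep(TRUE, nrow(counts)) else
    is.na(dscore) | dscore <= doublet_threshold
  keep <- n_detected >= min_genes & mito_frac <= max_mito_frac & pass_doublet
  if (!any(keep))
    stop(sprintf(paste0("QC removed all %d cells (failing min_genes: %d, ",
                        "mito: %d, doublet: %d)"),
                 nrow(counts), sum(n_detected < min_genes),
                 sum(mito_frac > max_mito_frac), sum(!pass_doublet)))

  gene_drop <- rep(FALSE, ncol(counts))
  if (drop_blacklist) {
    gene_drop <- gene_drop | colnames(counts) %in% BLACKLIST_GENES
    if ("blacklist" %in% colnames(m$gene_meta))
      gene_drop <- gene_drop | isTRUE_vec(m$gene_meta$blacklist)
  }
  ig <- if (drop_immunoglobulin) startsWith_any(colnames(counts), ig_prefixes)
        else rep(FALSE, ncol(counts))
  gene_drop <- gene_drop | ig

  out <- expression_matrix(counts[keep, !gene_drop, drop = FALSE],
                           cell_meta = m$cell_meta[keep, , drop = FALSE],
                           gene_meta = m$gene_meta[!gene_drop, , drop = FALSE])
  if (any(gene_drop))
    out$removed_counts <- counts[keep, gene_drop, drop = FALSE]
  if (any(ig))
    out$cell_meta$ig_counts <-
      as.numeric(Matrix::rowSums(counts[keep, ig, drop = FALSE]))
  out
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

startsWith_any <- function(x, prefixes) {
  hit <- rep(FALSE, length(x))
  for (p in prefixes) hit <- hit | startsWith(x, p)
  hit
}

#' Total-count log-normalization
#'
#' `value(c,g) = ln(count(c,g) / total(c) * scale_factor + 1)`. Zero counts
#' stay zero, so sparsity is preserved.
#'
#' @param m an `ExpressionMatrix`.
#' @param scale_factor library-size scale (default 1e4 counts per cell).
#' @return a cells x genes sparse matrix of normalized values with attribute
#'   `scale_factor`.
#' @export
normalize_log <- function(m, scale_factor = 1e4) {
  counts <- if (inherits(m, "ExpressionMatrix")) m$counts else
    as(as(m, "CsparseMatrix"), "generalMatrix")
  totals <- Matrix::rowSums(counts)
  if (any(totals == 0))
    stop("cells with zero total counts present; run qc_filter() first")
  norm <- counts
  # dgCMatrix: x holds nonzeros column-wise; scale each by its cell's total
  cell_of_x <- norm@i + 1L
  norm@x <- log1p(norm@x / totals[cell_of_x] * scale_factor)
  attr(norm, "scale_factor") <- scale_factor
  norm
}

#' Read a gene-order file with arm annotation
#'
#' The gene-order file is the 4-column headerless TSV used by expression-CNA
#' tools (gene, chromosome, start, end). Arm membership is derived from a
#' 3-column arm-boundary TSV (chrom, arm, boundary): a gene belongs to the
#' arm whose boundary its start does not exceed (boundaries listed in
#' genomic order, last arm open-ended).
#'
#' @param order_path gene-order TSV path.
#' @param arm_path arm-boundary TSV path (headerless: chrom, arm, boundary).
#' @return a `GeneOrder` data.frame (gene, chrom, start, end, arm), sorted by
#'   chromosome then start, ties broken by gene id.
#' @export
read_gene_order <- function(order_path, arm_path = NULL) {
  go <- read.delim(order_path, header = FALSE, stringsAsFactors = FALSE,
                   col.names = c("gene", "chrom", "start", "end"))
  arms <- if (!is.null(arm_path))
    read.delim(arm_path, header = FALSE, stringsAsFactors = FALSE,
               col.names = c("chrom", "arm", "boundary"))
  else NULL
  gene_order(go, arms)
}

#' Build a GeneOrder table
#'
#' @param go data.frame with columns gene, chrom, start, end.
#' @param arms optional data.frame with columns chrom, arm, boundary.
#' @return sorted `GeneOrder` data.frame with an `arm` column
#'   (`chrom` + p/q label, e.g. "1q"; NA when no arm table given).
#' @export
gene_order <- function(go, arms = NULL) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% colnames(go)))
  if (any(go$start > go$end)) stop("gene with start > end")
  if (anyDuplicated(go$gene)) stop("duplicate gene ids in gene order")
  go$chrom <- as.character(go$chrom)
  ord <- order(chrom_rank(go$chrom), go$start, go$gene)
  go <- go[ord, , drop = FALSE]
  go$arm <- NA_character_
  if (!is.null(arms)) {
    arms$chrom <- as.character(arms$chrom)
    for (ch in unique(go$chrom)) {
      a <- arms[arms$chrom == ch, , drop = FALSE]
      if (!nrow(a)) next
      a <- a[order(a$boundary), , drop = FALSE]
      idx <- go$chrom == ch
      bin <- findInterval(go$start[idx], c(-Inf, a$boundary), left.open = TRUE)
      bin <- pmin(bin, nrow(a))  # beyond last boundary -> last arm
      go$arm[idx] <- paste0(ch, a$arm[bin])
    }
  }
  rownames(go) <- go$gene
  class(go) <- c("GeneOrder", "data.frame")
  go
}

chrom_rank <- function(chrom) {
  x <- sub("^chr", "", chrom)
  suppressWarnings(num <- as.numeric(x))
  num[is.na(num)] <- 100 + as.integer(factor(x[is.na(num)]))
  num
}

#' Write a gene-order table and its arm boundaries to disk
#'
#' @param go a `GeneOrder`.
#' @param order_path gene-order TSV destination (4 columns, no header).
#' @param arm_path optional arm-boundary TSV destination.
#' @param arms data.frame (chrom, arm, boundary) to write when `arm_path`
#'   is given.
#' @export
write_gene_order <- function(go, order_path, arm_path = NULL, arms = NULL) {
  write.table(go[, c("gene", "chrom", "start", "end")], order_path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  if (!is.null(arm_path) && !is.null(arms))
    write.table(arms, arm_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(order_path)
}
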