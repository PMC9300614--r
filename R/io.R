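#' @importFrom Matrix readMM writeMM sparseMatrix colSums rowSums t
#' @importFrom utils read.table write.table
NULL

# Containers ---------------------------------------------------------------
# Lightweight S3 containers; counts are cell x feature sparse matrices
# (Matrix::dgCMatrix) with barcodes on rows and features on columns.

#' Construct a cell-by-peak count matrix
#'
#' @param counts sparse (or dense) nonnegative integer matrix, cells x peaks
#' @param barcodes character vector of unique cell barcodes (rows)
#' @param peaks GRanges of unique peak intervals (columns)
#' @return object of class `peak_matrix`
#' @export
peak_matrix <- function(counts, barcodes, peaks) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(barcodes) || ncol(counts) != length(peaks)) {
    stop(sprintf(
      "dimension mismatch: counts %dx%d vs %d barcodes, %d peaks",
      nrow(counts), ncol(counts), length(barcodes), length(peaks)
    ))
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  key <- paste0(GenomicRanges::seqnames(peaks), ":", GenomicRanges::start(peaks), "-",
                GenomicRanges::end(peaks))
  if (anyDuplicated(key)) stop("duplicate peak intervals")
  if (length(counts@x) && min(counts@x) < 0) stop("negative counts")
  rownames(counts) <- barcodes
  structure(list(counts = counts, barcodes = barcodes, peaks = peaks),
            class = "peak_matrix")
}

#' Construct a cell-by-gene expression count matrix
#'
#' @param counts sparse nonnegative matrix, cells x genes
#' @param barcodes character vector of unique barcodes
#' @param gene_ids character vector of unique gene identifiers
#' @return object of class `expression_matrix`
#' @export
expression_matrix <- function(counts, barcodes, gene_ids) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  if (nrow(counts) != length(barcodes) || ncol(counts) != length(gene_ids)) {
    stop("dimension mismatch between counts and indices")
  }
  if (anyDuplicated(barcodes)) stop("duplicate barcodes")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (length(counts@x) && min(counts@x) < 0) stop("negative counts")
  rownames(counts) <- barcodes
  colnames(counts) <- gene_ids
  structure(list(counts = counts, barcodes = barcodes, gene_ids = gene_ids),
            class = "expression_matrix")
}

#' @export
print.peak_matrix <- function(x, ...) {
  cat(sprintf("peak_matrix: %d cells x %d peaks, %d nonzero\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes, %d nonzero\n",
              nrow(x$counts), ncol(x$counts), length(x$counts@x)))
  invisible(x)
}

# Readers -------------------------------------------------------------------

#' Read a BED3/BED6 file into a GRanges
#'
#' Coordinates on disk are 0-based half-open; malformed lines are reported
#' with their line number.
#'
#' @param path BED file path
#' @return GRanges (strand taken from column 6 when present)
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", which(nf < 3L)[1L]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad)) stop(sprintf("malformed BED line %d: non-numeric coordinates", bad[1L]))
  strand <- rep(".", length(chrom))
  has6 <- nf >= 6L
  if (any(has6)) strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  granges0(chrom, start, end, strand)
}

#' Write intervals as BED
#'
#' BED3 by default; `bed6 = TRUE` adds name ("." ), score (0) and strand
#' columns. Writers emit rows in the input order so output is deterministic.
#'
#' @param gr GRanges
#' @param path output path
#' @param bed6 write six columns instead of three
#' @param extra_columns optional data.frame of additional columns appended
#'   after the BED fields
#' @return the path, invisibly
#' @export
write_bed <- function(gr, path, bed6 = FALSE, extra_columns = NULL) {
  df <- granges_to_bed(gr)
  out <- if (bed6) {
    cbind(df[c("chrom", "start", "end")],
          name = ".", score = 0L, strand = df$strand)
  } else {
    df[c("chrom", "start", "end")]
  }
  if (!is.null(extra_columns)) out <- cbind(out, extra_columns)
  write.table(format(out, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a Cellranger-like MatrixMarket triple into a peak matrix
#'
#' The triple is a MatrixMarket `.mtx` (features x cells or cells x peaks,
#' see `cells_in_rows`), a barcodes file (one barcode per line) and a peaks
#' BED. Row/column order of the files is preserved.
#'
#' @param matrix_path MatrixMarket file, cells x peaks orientation by default
#' @param barcodes_path one barcode per line
#' @param peaks_path BED3+ file of peak intervals
#' @param cells_in_rows if `FALSE` the matrix on disk is peaks x cells and is
#'   transposed on read (the Cellranger convention is features x cells)
#' @return a `peak_matrix`
#' @export
read_peak_matrix <- function(matrix_path, barcodes_path, peaks_path,
                             cells_in_rows = TRUE) {
  m <- Matrix::readMM(matrix_path)
  if (!cells_in_rows) m <- Matrix::t(m)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  peaks <- read_bed(peaks_path)
  if (nrow(m) != length(barcodes) || ncol(m) != length(peaks)) {
    stop(sprintf(
      "format error: matrix is %dx%d but barcodes=%d, peaks=%d",
      nrow(m), ncol(m), length(barcodes), length(peaks)
    ))
  }
  peak_matrix(m, barcodes, peaks)
}

#' Read a MatrixMarket triple into an expression matrix
#'
#' @param matrix_path MatrixMarket file, cells x genes by default
#' @param barcodes_path one barcode per line
#' @param features_path one gene id per line (first tab-separated field used)
#' @inheritParams read_peak_matrix
#' @return an `expression_matrix`
#' @export
read_expression_matrix <- function(matrix_path, barcodes_path, features_path,
                                   cells_in_rows = TRUE) {
  m <- Matrix::readMM(matrix_path)
  if (!cells_in_rows) m <- Matrix::t(m)
  barcodes <- readLines(barcodes_path)
  barcodes <- barcodes[nzchar(barcodes)]
  feats <- readLines(features_path)
  feats <- vapply(strsplit(feats[nzchar(feats)], "\t"), `[[`, "", 1L)
  if (nrow(m) != length(barcodes) || ncol(m) != length(feats)) {
    stop("format error: matrix dimensions do not match barcode/feature files")
  }
  expression_matrix(m, barcodes, feats)
}

#' Read a gene annotation table
#'
#' Expected TSV header: `gene_id, chrom, strand, tss, exon1_start, exon1_end,
#' body_start, body_end`; all coordinates 0-based half-open, `tss` a 0-based
#' base position. Duplicated gene ids, strands outside `+`/`-`, exons outside
#' the gene body and TSSs outside the body are rejected.
#'
#' @param path TSV path
#' @return data.frame of validated gene records
#' @export
read_gene_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "strand", "tss",
                "exon1_start", "exon1_end", "body_start", "body_end")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("annotation missing columns: ", paste(missing, collapse = ", "))
  }
  validate_gene_annotation(df)
}

#' Validate a gene annotation data.frame
#' @param df annotation data.frame (see [read_gene_annotation()])
#' @return the validated data.frame
#' @export
validate_gene_annotation <- function(df) {
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop("duplicate gene_id: ", paste(unique(dup), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-"))) {
    bad <- df$gene_id[!df$strand %in% c("+", "-")]
    stop("strand must be '+' or '-' (gene ", bad[1L], ")")
  }
  if (any(df$body_start < 0) || any(df$body_start >= df$body_end)) {
    stop("invalid gene body coordinates")
  }
  if (any(df$exon1_start < df$body_start) || any(df$exon1_end > df$body_end) ||
      any(df$exon1_start >= df$exon1_end)) {
    stop("first exon must lie within the gene body")
  }
  if (any(df$tss < df$body_start) || any(df$tss > df$body_end - 1L)) {
    stop("tss must lie within the gene body")
  }
  df
}

#' TSS positions of genes as width-1 GRanges
#' @param annotation gene annotation data.frame
#' @return GRanges of single-base TSS positions
#' @export
tss_ranges <- function(annotation) {
  gr <- granges0(annotation$chrom, annotation$tss, annotation$tss + 1,
                 annotation$strand)
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  gr
}

#' First-exon intervals as GRanges
#' @param annotation gene annotation data.frame
#' @return GRanges with a `gene_id` metadata column
#' @export
first_exon_ranges <- function(annotation) {
  gr <- granges0(annotation$chrom, annotation$exon1_start, annotation$exon1_end,
                 annotation$strand)
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id
  gr
}

#' Write a MatrixMarket triple (matrix + barcodes + features)
#' @param counts sparse cells x features matrix
#' @param barcodes character vector
#' @param features character vector (gene ids) or GRanges (peaks, written BED)
#' @param dir output directory (created)
#' @param prefix file name prefix
#' @return invisibly, the directory
#' @export
write_mtx_triple <- function(counts, barcodes, features, dir, prefix = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"),
                  file.path(dir, paste0(prefix, "matrix.mtx")))
  writeLines(barcodes, file.path(dir, paste0(prefix, "barcodes.tsv")))
  if (methods::is(features, "GRanges")) {
    write_bed(features, file.path(dir, paste0(prefix, "peaks.bed")))
  } else {
    writeLines(features, file.path(dir, paste0(prefix, "features.tsv")))
  }
  invisible(dir)
}
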