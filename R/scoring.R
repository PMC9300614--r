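# Promoter accessibility (PA) and gene activity score (GAS)
# --------------------------------------------------------------------------
# Both scores are sums of peak counts over gene-associated regions.  A peak
# is attributed to a gene by >= 1 bp overlap with any of the gene's regions
# and contributes once per gene even when it overlaps several components
# (union semantics); a peak overlapping two genes' regions contributes to
# both genes.

#' Strand-aware 2 kb promoter windows
#'
#' On `+` genes the window is `[tss - upstream, tss)`, on `-` genes
#' `[tss, tss + upstream)` (0-based half-open), clamped at the chromosome
#' start.
#'
#' @param annotation gene annotation data.frame
#' @param upstream window size in bp
#' @return GRanges with a `gene_id` metadata column
#' @export
promoter_windows <- function(annotation, upstream = 2000) {
  plus <- annotation$strand == "+"
  start <- ifelse(plus, pmax(0, annotation$tss - upstream), annotation$tss)
  end <- ifelse(plus, annotation$tss, annotation$tss + upstream)
  keep <- start < end  # a "+" gene with tss = 0 has an empty window
  gr <- granges0(annotation$chrom[keep], start[keep], end[keep],
                 annotation$strand[keep])
  S4Vectors::mcols(gr)$gene_id <- annotation$gene_id[keep]
  gr
}

#' Construct a cell-by-gene score matrix
#' @param values nonnegative cells x genes matrix
#' @param barcodes,gene_ids index vectors
#' @param kind one of "PA", "GAS", "ENH"
#' @return object of class `score_matrix`
#' @export
score_matrix <- function(values, barcodes, gene_ids,
                         kind = c("PA", "GAS", "ENH")) {
  kind <- match.arg(kind)
  values <- methods::as(methods::as(values, "CsparseMatrix"), "generalMatrix")
  stopifnot(nrow(values) == length(barcodes), ncol(values) == length(gene_ids))
  rownames(values) <- barcodes
  colnames(values) <- gene_ids
  structure(list(values = values, barcodes = barcodes, gene_ids = gene_ids,
                 kind = kind), class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("score_matrix (%s): %d cells x %d genes\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

# 0/1 peak-by-gene membership for a list of per-gene region sets
membership_matrix <- function(peaks, region_list, gene_ids) {
  i <- integer(0); j <- integer(0)
  for (k in seq_along(region_list)) {
    gr <- region_list[[k]]
    if (length(gr) == 0L) next
    hits <- GenomicRanges::findOverlaps(peaks, gr, ignore.strand = TRUE)
    gi <- match(S4Vectors::mcols(gr)$gene_id[S4Vectors::subjectHits(hits)],
                gene_ids)
    i <- c(i, S4Vectors::queryHits(hits))
    j <- c(j, gi)
  }
  if (length(i)) {
    keep <- !duplicated(cbind(i, j))
    Matrix::sparseMatrix(i = i[keep], j = j[keep], x = 1,
                         dims = c(length(peaks), length(gene_ids)))
  } else {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(peaks), length(gene_ids)))
  }
}

#' Promoter accessibility per cell and gene
#'
#' PA(cell, gene) is the sum of counts over peaks overlapping the gene's
#' 2 kb upstream promoter window (default mode). The alternative
#' `"gene_body_plus_promoter"` mode additionally includes the gene body.
#'
#' @param matrix a `peak_matrix`
#' @param annotation gene annotation data.frame
#' @param mode which promoter definition to use
#' @param upstream promoter window size
#' @return `score_matrix` of kind "PA"
#' @export
promoter_accessibility <- function(matrix, annotation,
                                   mode = c("upstream", "gene_body_plus_promoter"),
                                   upstream = 2000) {
  mode <- match.arg(mode)
  check_shared_chromosomes(matrix$peaks, unique(annotation$chrom),
                           "peaks", "annotation")
  pw <- promoter_windows(annotation, upstream = upstream)
  regions <- list(pw)
  if (mode == "gene_body_plus_promoter") {
    body <- granges0(annotation$chrom, annotation$body_start,
                     annotation$body_end, annotation$strand)
    S4Vectors::mcols(body)$gene_id <- annotation$gene_id
    regions <- c(regions, list(body))
  }
  mm <- membership_matrix(matrix$peaks, regions, annotation$gene_id)
  if (sum(mm) == 0) {
    warning("no peaks overlap any promoter window")
  }
  vals <- matrix$counts %*% mm
  score_matrix(vals, matrix$barcodes, annotation$gene_id, "PA")
}

#' Gene activity score per cell and gene
#'
#' GAS(cell, gene) sums counts over the union of peaks overlapping the
#' gene's promoter window, its first exon, and any assigned presumptive
#' enhancers; a peak spanning several of those components still counts
#' once.
#'
#' @param matrix a `peak_matrix`
#' @param annotation gene annotation data.frame
#' @param enhancers_per_gene optional named list `gene_id -> GRanges` of
#'   enhancer intervals; names must be known gene ids
#' @param upstream promoter window size
#' @return `score_matrix` of kind "GAS"
#' @export
gene_activity_score <- function(matrix, annotation, enhancers_per_gene = NULL,
                                upstream = 2000) {
  check_shared_chromosomes(matrix$peaks, unique(annotation$chrom),
                           "peaks", "annotation")
  regions <- list(promoter_windows(annotation, upstream = upstream),
                  first_exon_ranges(annotation))
  if (!is.null(enhancers_per_gene) && length(enhancers_per_gene)) {
    unknown <- setdiff(names(enhancers_per_gene), annotation$gene_id)
    if (length(unknown)) {
      stop("enhancers assigned to unknown gene: ",
           paste(unknown, collapse = ", "))
    }
    enh <- unlist(GenomicRanges::GRangesList(enhancers_per_gene))
    S4Vectors::mcols(enh)$gene_id <-
      rep(names(enhancers_per_gene), lengths(enhancers_per_gene))
    regions <- c(regions, list(enh))
  }
  mm <- membership_matrix(matrix$peaks, regions, annotation$gene_id)
  vals <- matrix$counts %*% mm
  score_matrix(vals, matrix$barcodes, annotation$gene_id, "GAS")
}

#' Enhancer-only accessibility score per cell and gene
#'
#' Sums counts over peaks overlapping the gene's assigned enhancer
#' intervals only (the "enhancer counts" modality of the trend analysis).
#'
#' @inheritParams gene_activity_score
#' @return `score_matrix` of kind "ENH"
#' @export
enhancer_score <- function(matrix, annotation, enhancers_per_gene) {
  unknown <- setdiff(names(enhancers_per_gene), annotation$gene_id)
  if (length(unknown)) {
    stop("enhancers assigned to unknown gene: ", paste(unknown, collapse = ", "))
  }
  if (length(enhancers_per_gene)) {
    enh <- unlist(GenomicRanges::GRangesList(enhancers_per_gene))
    S4Vectors::mcols(enh)$gene_id <-
      rep(names(enhancers_per_gene), lengths(enhancers_per_gene))
    regions <- list(enh)
  } else {
    regions <- list()
  }
  mm <- membership_matrix(matrix$peaks, regions, annotation$gene_id)
  vals <- matrix$counts %*% mm
  score_matrix(vals, matrix$barcodes, annotation$gene_id, "ENH")
}
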