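# Co-accessibility linking and the expression -> binarised-peak predictor
# --------------------------------------------------------------------------
# The co-accessibility score here is a declared stand-in for graphical-
# lasso-based estimators: cells are pooled into metacells (pseudotime order
# within each (region, state) group), metacell counts are binarised, and
# the score of a peak pair is the Pearson correlation of those binary
# profiles. Externally computed link tables with the same columns can be
# substituted anywhere a link table is consumed.

#' Pool cells into metacells and binarise
#'
#' Cells are ordered by pseudotime within each (region, state) group and
#' chunked into metacells of `metacell_size`; a remainder smaller than the
#' chunk size is merged into the last metacell. Metacell counts are summed
#' and binarised (> 0).
#'
#' @param matrix a `peak_matrix`
#' @param cells cell table with `region`, `state`, `pseudotime`
#' @param metacell_size cells per metacell
#' @return list with `binary` (metacell x peak 0/1 matrix) and `groups`
#'   (the (region, state) label of each metacell)
#' @export
metacell_binarize <- function(matrix, cells, metacell_size = 50) {
  stopifnot(identical(matrix$barcodes, cells$barcode))
  if (nrow(cells) < 2 * metacell_size) {
    stop("need at least 2 * metacell_size cells")
  }
  key <- paste(cells$region, cells$state, sep = "|")
  assign <- integer(nrow(cells))
  labels <- character(0)
  next_id <- 0L
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(cells$pseudotime[idx])]
    n_mc <- max(1L, length(idx) %/% metacell_size)
    mc <- pmin(((seq_along(idx) - 1L) %/% metacell_size) + 1L, n_mc)
    assign[idx] <- next_id + mc
    labels <- c(labels, rep(k, n_mc))
    next_id <- next_id + n_mc
  }
  G <- Matrix::sparseMatrix(i = seq_len(nrow(cells)), j = assign, x = 1,
                            dims = c(nrow(cells), next_id))
  pooled <- as.matrix(Matrix::t(G) %*% matrix$counts)
  list(binary = (pooled > 0) * 1, groups = labels)
}

#' Co-accessibility scores for same-chromosome peak pairs
#'
#' Scores every same-chromosome peak pair whose midpoints lie within
#' `window` bp as the Pearson correlation of binarised metacell profiles.
#' Peaks constant across metacells (never or always detected) have no
#' defined correlation and are excluded from pairing.
#'
#' @param matrix a `peak_matrix`
#' @param cells cell table
#' @param window maximum midpoint separation in bp
#' @param metacell_size cells per metacell
#' @return data.frame of links: peak indices `peak_a` < `peak_b` (by
#'   coordinate), their coordinates, and `score` in \[-1, 1\]
#' @export
coaccessibility_scores <- function(matrix, cells, window = 500000,
                                   metacell_size = 50) {
  mb <- metacell_binarize(matrix, cells, metacell_size)
  B <- mb$binary
  usable <- apply(B, 2, function(v) min(v) != max(v))
  bed <- granges_to_bed(matrix$peaks)
  mid <- interval_midpoint(matrix$peaks)

  out <- list()
  for (chr in unique(bed$chrom)) {
    idx <- which(bed$chrom == chr & usable)
    if (length(idx) < 2L) next
    idx <- idx[order(mid[idx])]
    m <- mid[idx]
    cm <- cor(B[, idx, drop = FALSE])
    pa <- integer(0); pb <- integer(0)
    for (i in seq_len(length(idx) - 1L)) {
      j <- i + 1L
      while (j <= length(idx) && m[j] - m[i] <= window) {
        pa <- c(pa, i); pb <- c(pb, j)
        j <- j + 1L
      }
    }
    if (!length(pa)) next
    out[[chr]] <- data.frame(
      peak_a = idx[pa], peak_b = idx[pb],
      chrom_a = chr, start_a = bed$start[idx[pa]], end_a = bed$end[idx[pa]],
      chrom_b = chr, start_b = bed$start[idx[pb]], end_b = bed$end[idx[pb]],
      score = cm[cbind(pa, pb)],
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(peak_a = integer(0), peak_b = integer(0),
                      chrom_a = character(0), start_a = numeric(0),
                      end_a = numeric(0), chrom_b = character(0),
                      start_b = numeric(0), end_b = numeric(0),
                      score = numeric(0)))
  }
  res <- do.call(rbind, unname(out))
  rownames(res) <- NULL
  res
}

#' Filter links by score threshold
#'
#' Retains links with `score >= min_score` (inclusive: a score of exactly
#' 0.25 is kept).
#'
#' @param links link data.frame with a `score` column
#' @param min_score retention threshold
#' @return the filtered data.frame
#' @export
filter_links <- function(links, min_score = 0.25) {
  links[links$score >= min_score, , drop = FALSE]
}

#' Classify links into TSS-to-cRE connections
#'
#' A link becomes a TSS-cRE connection when exactly one anchor overlaps at
#' least one gene TSS (the TSS point, optionally widened by `tss_slop`)
#' and the other anchor overlaps no promoter window of any gene. One row
#' is emitted per overlapped gene (an anchor on two genes' TSSs yields two
#' connections sharing the cRE). Links with both or neither anchor on a
#' TSS are dropped.
#'
#' @param links filtered link data.frame
#' @param annotation gene annotation data.frame
#' @param tss_slop bp added each side of the TSS point before overlap
#' @param upstream promoter window size used for the cRE exclusion
#' @return data.frame of TSS-cRE connections: `gene_id`, cRE coordinates,
#'   `score`, `provenance = "coaccess"`
#' @export
classify_tss_links <- function(links, annotation, tss_slop = 0,
                               upstream = 2000) {
  if (!nrow(links)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      score = numeric(0), provenance = character(0)))
  }
  tss <- tss_ranges(annotation)
  if (tss_slop > 0) {
    tss <- granges0(annotation$chrom, pmax(0, annotation$tss - tss_slop),
                    annotation$tss + 1 + tss_slop)
    S4Vectors::mcols(tss)$gene_id <- annotation$gene_id
  }
  pw <- promoter_windows(annotation, upstream = upstream)

  a <- granges0(links$chrom_a, links$start_a, links$end_a)
  b <- granges0(links$chrom_b, links$start_b, links$end_b)
  a_tss <- IRanges::overlapsAny(a, tss, ignore.strand = TRUE)
  b_tss <- IRanges::overlapsAny(b, tss, ignore.strand = TRUE)
  a_prom <- IRanges::overlapsAny(a, pw, ignore.strand = TRUE)
  b_prom <- IRanges::overlapsAny(b, pw, ignore.strand = TRUE)

  use_a_gene <- a_tss & !b_tss & !b_prom  # gene side = a, cre = b
  use_b_gene <- b_tss & !a_tss & !a_prom  # gene side = b, cre = a

  rows <- list()
  emit <- function(gene_anchor, which_idx, cre_cols) {
    hits <- GenomicRanges::findOverlaps(gene_anchor[which_idx], tss,
                                        ignore.strand = TRUE)
    li <- which_idx[S4Vectors::queryHits(hits)]
    data.frame(
      gene_id = S4Vectors::mcols(tss)$gene_id[S4Vectors::subjectHits(hits)],
      chrom = links[[cre_cols[1]]][li],
      start = links[[cre_cols[2]]][li],
      end = links[[cre_cols[3]]][li],
      score = links$score[li],
      provenance = "coaccess",
      stringsAsFactors = FALSE
    )
  }
  if (any(use_a_gene)) {
    rows <- c(rows, list(emit(a, which(use_a_gene),
                              c("chrom_b", "start_b", "end_b"))))
  }
  if (any(use_b_gene)) {
    rows <- c(rows, list(emit(b, which(use_b_gene),
                              c("chrom_a", "start_a", "end_a"))))
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      score = numeric(0), provenance = character(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene_id, out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Subset a peak matrix to a set of barcodes
#' @param matrix a `peak_matrix`
#' @param barcodes barcodes to keep (order preserved from `matrix`)
#' @return a `peak_matrix`
#' @export
subset_cells <- function(matrix, barcodes) {
  keep <- matrix$barcodes %in% barcodes
  peak_matrix(matrix$counts[keep, , drop = FALSE], matrix$barcodes[keep],
              matrix$peaks)
}

#' Count retained links per group after downsampling to equal cell numbers
#'
#' Each group (by region or state) is downsampled without replacement to
#' the smallest group's size, co-accessibility is recomputed within the
#' group, and links with `score >= min_score` are counted.
#'
#' @param matrix a `peak_matrix`
#' @param cells cell table
#' @param groupby `"region"` or `"state"`
#' @param min_score retention threshold
#' @param window,metacell_size passed to [coaccessibility_scores()]
#' @param seed RNG seed for the downsampling
#' @return named integer vector of link counts per group
#' @export
count_links_by_group <- function(matrix, cells, groupby = c("region", "state"),
                                 min_score = 0.25, window = 500000,
                                 metacell_size = 50, seed = 1L) {
  groupby <- match.arg(groupby)
  g <- cells[[groupby]]
  sizes <- table(g)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  m <- min(sizes)
  if (m < 2 * metacell_size) {
    stop(sprintf("smallest group has %d cells; need >= %d", m, 2 * metacell_size))
  }
  set.seed(seed)
  counts <- integer(0)
  for (gr in sort(unique(g))) {
    bc <- cells$barcode[g == gr]
    bc <- sort(sample(bc, m))
    sub <- subset_cells(matrix, bc)
    sub_cells <- cells[match(sub$barcodes, cells$barcode), , drop = FALSE]
    links <- coaccessibility_scores(sub, sub_cells, window = window,
                                    metacell_size = metacell_size)
    counts[gr] <- nrow(filter_links(links, min_score))
  }
  counts
}

#' Predict gene-peak pairs from expression and binarised accessibility
#'
#' For each gene whose TSS-overlapping peak has a nonzero total count, every
#' non-promoter peak whose midpoint lies within `window / 2` of the TSS is
#' tested with a logistic model `P(peak count > 0) ~ 1 + normalised
#' expression` against the intercept-only null (likelihood-ratio,
#' chi-square 1 df). P-values are Benjamini-Hochberg adjusted across all
#' pairs genome-wide; pairs with `adj_p <= alpha` are retained.
#'
#' @param expression an `expression_matrix` (same barcodes as `matrix`)
#' @param matrix a `peak_matrix`
#' @param annotation gene annotation data.frame
#' @param window full TSS window span in bp (the tested peaks lie within
#'   a window of this total width centred on the TSS)
#' @param alpha FDR threshold
#' @param upstream promoter window size used to exclude promoter peaks
#' @return data.frame of tested pairs: `gene_id`, `peak_id`, coordinates,
#'   `slope_sign`, `p_value`, `adj_p`, `retained`
#' @export
predict_gene_peak_pairs <- function(expression, matrix, annotation,
                                    window = 500000, alpha = 0.05,
                                    upstream = 2000) {
  if (!setequal(expression$barcodes, matrix$barcodes)) {
    stop("expression and peak matrices must share barcodes")
  }
  expr <- expression$counts[match(matrix$barcodes, expression$barcodes), ,
                            drop = FALSE]
  xnorm <- normalize_log1p(expr)

  peaks <- matrix$peaks
  bed <- granges_to_bed(peaks)
  mid <- interval_midpoint(peaks)
  pw <- promoter_windows(annotation, upstream = upstream)
  is_prom <- IRanges::overlapsAny(peaks, pw, ignore.strand = TRUE)
  tss <- tss_ranges(annotation)
  on_tss <- IRanges::overlapsAny(peaks, tss, ignore.strand = TRUE)
  peak_tot <- Matrix::colSums(matrix$counts)

  tss_hits <- GenomicRanges::findOverlaps(tss, peaks, ignore.strand = TRUE)
  has_tss_signal <- tapply(
    peak_tot[S4Vectors::subjectHits(tss_hits)] > 0,
    annotation$gene_id[S4Vectors::queryHits(tss_hits)], any
  )

  rows <- list()
  for (gi in seq_len(nrow(annotation))) {
    gid <- annotation$gene_id[gi]
    if (is.na(has_tss_signal[gid]) || !has_tss_signal[gid]) next
    x <- as.numeric(xnorm[, match(gid, expression$gene_ids)])
    if (var(x) == 0) next
    cand <- which(!is_prom & bed$chrom == annotation$chrom[gi] &
                    abs(mid - annotation$tss[gi]) <= window / 2)
    for (j in cand) {
      y <- as.numeric(matrix$counts[, j] > 0)
      if (length(unique(y)) < 2L) next
      t <- lr_test_peak(y, x)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gid, peak_id = j,
        chrom = bed$chrom[j], start = bed$start[j], end = bed$end[j],
        slope_sign = sign(t$slope), p_value = t$p_value,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(gene_id = character(0), peak_id = integer(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), slope_sign = numeric(0),
                      p_value = numeric(0), adj_p = numeric(0),
                      retained = logical(0)))
  }
  out <- do.call(rbind, rows)
  out$adj_p <- p.adjust(out$p_value, method = "BH")
  out$retained <- out$adj_p <= alpha
  rownames(out) <- NULL
  out
}
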