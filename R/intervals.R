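#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand reduce findOverlaps
#' @importFrom IRanges IRanges overlapsAny subsetByOverlaps
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
NULL

# Internal coordinate convention
# --------------------------------------------------------------------------
# All on-disk coordinates (BED, annotation TSV, ground-truth tables) are
# 0-based half-open.  In memory, intervals live in GRanges, which is 1-based
# closed; the two helpers below are the ONLY place the +1/-1 happens.
# Chromosome names are compared as exact strings (no "chr" normalisation).

#' Build a GRanges from 0-based half-open coordinates
#'
#' @param chrom character vector of chromosome names
#' @param start,end numeric vectors, 0-based half-open (`start < end`)
#' @param strand optional strand vector in `+`, `-`, `.` (`.` maps to `*`)
#' @return a `GRanges` holding the same bases
#' @export
granges0 <- function(chrom, start, end, strand = NULL) {
  if (length(chrom) == 0L) {
    return(GenomicRanges::GRanges())
  }
  if (any(!is.finite(start)) || any(!is.finite(end))) {
    stop("interval coordinates must be finite")
  }
  if (any(start < 0)) {
    stop("negative interval start coordinate")
  }
  if (any(start >= end)) {
    bad <- which(start >= end)[1L]
    stop(sprintf("invalid interval: start %s >= end %s", start[bad], end[bad]))
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom))) {
    stop("chromosome names must be nonempty")
  }
  str <- if (is.null(strand)) "*" else ifelse(strand == ".", "*", strand)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end), strand = str)
}

#' Convert a GRanges back to 0-based half-open columns
#'
#' @param gr a `GRanges`
#' @return data.frame with `chrom`, `start`, `end`, `strand` (0-based half-open)
#' @export
granges_to_bed <- function(gr) {
  data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr) - 1L,
    end    = GenomicRanges::end(gr),
    strand = sub("\\*", ".", as.character(GenomicRanges::strand(gr))),
    stringsAsFactors = FALSE
  )
}

#' Warn about chromosomes present in one interval set but not another
#'
#' Silent chromosome-name mismatches ("chr1" vs "1") are the dominant class
#' of interval bug; every cross-set operation funnels through this check.
#'
#' @param a,b GRanges (or character vectors of chromosome names)
#' @param label_a,label_b names used in the warning message
#' @return invisibly, the character vector of unshared chromosome names
#' @export
check_shared_chromosomes <- function(a, b, label_a = "set A", label_b = "set B") {
  ca <- if (is.character(a)) unique(a) else unique(as.character(GenomicRanges::seqnames(a)))
  cb <- if (is.character(b)) unique(b) else unique(as.character(GenomicRanges::seqnames(b)))
  only_a <- setdiff(ca, cb)
  only_b <- setdiff(cb, ca)
  if (length(only_a) || length(only_b)) {
    warning(sprintf(
      "chromosome mismatch: %s only in %s; %s only in %s",
      if (length(only_a)) paste(only_a, collapse = ",") else "<none>", label_a,
      if (length(only_b)) paste(only_b, collapse = ",") else "<none>", label_b
    ))
  }
  invisible(c(only_a, only_b))
}

#' Fraction of intervals in A overlapping at least one interval in B
#'
#' Overlap is >= 1 bp. Returns the counts needed for a Venn-style report.
#'
#' @param set_a,set_b GRanges
#' @param label short description of the comparison
#' @return list with `label`, `n_a`, `n_b`, `n_intersect` (number of A
#'   intervals hitting B) and `percent_a_overlapping` (NA when A is empty)
#' @export
percent_overlap <- function(set_a, set_b, label = "") {
  n_a <- length(set_a)
  n_b <- length(set_b)
  hit <- if (n_a == 0L) logical(0) else IRanges::overlapsAny(set_a, set_b, ignore.strand = TRUE)
  n_int <- sum(hit)
  list(
    label = label,
    n_a = n_a,
    n_b = n_b,
    n_intersect = n_int,
    percent_a_overlapping = if (n_a == 0L) NA_real_ else 100 * n_int / n_a
  )
}

#' Extend intervals by a flank and merge overlapping/bookended results
#'
#' Each interval is grown by `flank` bases on both sides (clamped at the
#' chromosome origin), then overlapping or directly adjacent intervals are
#' merged. Output is sorted and pairwise disjoint. Strand is ignored.
#'
#' @param gr GRanges
#' @param flank nonnegative integer, bases added each side
#' @return merged GRanges
#' @export
extend_and_merge <- function(gr, flank = 500) {
  stopifnot(flank >= 0)
  if (length(gr) == 0L) return(GenomicRanges::GRanges())
  ext <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr),
    IRanges::IRanges(
      pmax(1L, GenomicRanges::start(gr) - as.integer(flank)),
      GenomicRanges::end(gr) + as.integer(flank)
    )
  )
  GenomicRanges::reduce(GenomicRanges::sort(ext), min.gapwidth = 1L)
}

#' Midpoints of intervals (0-based positions)
#' @param gr GRanges
#' @return numeric vector of midpoint coordinates
#' @keywords internal
interval_midpoint <- function(gr) {
  (GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2
}
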