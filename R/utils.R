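#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions, ~0 for
#' independent ones. Used to score recovery of planted gene groups.
#'
#' @param a,b label vectors of equal length (any atomic type)
#' @return the adjusted Rand index
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Precision and recall of predicted gene-enhancer links
#'
#' Predictions and truth are matched as (gene, interval) pairs; a predicted
#' cRE matches a planted enhancer of the same gene when the intervals
#' overlap by >= 1 bp. Duplicated predictions for the same pair count once.
#'
#' @param predicted data.frame with `gene_id`, `chrom`, `start`, `end`
#' @param truth data.frame of planted links, same columns
#' @return list with `precision`, `recall`, `n_predicted`, `n_true`
#' @export
link_recovery <- function(predicted, truth) {
  if (!nrow(predicted)) {
    return(list(precision = NA_real_, recall = 0,
                n_predicted = 0L, n_true = nrow(truth)))
  }
  pred_key <- paste0(predicted$gene_id, "|", predicted$chrom, ":",
                     predicted$start, "-", predicted$end)
  predicted <- predicted[!duplicated(pred_key), , drop = FALSE]

  pg <- granges0(predicted$chrom, predicted$start, predicted$end)
  tg <- granges0(truth$chrom, truth$start, truth$end)
  hits <- GenomicRanges::findOverlaps(pg, tg, ignore.strand = TRUE)
  same_gene <- predicted$gene_id[S4Vectors::queryHits(hits)] ==
    truth$gene_id[S4Vectors::subjectHits(hits)]
  matched_pred <- unique(S4Vectors::queryHits(hits)[same_gene])
  matched_true <- unique(S4Vectors::subjectHits(hits)[same_gene])
  list(
    precision = length(matched_pred) / nrow(predicted),
    recall = length(matched_true) / nrow(truth),
    n_predicted = nrow(predicted),
    n_true = nrow(truth)
  )
}
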