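# Two-route enhancer prediction and histone-mark validation
# --------------------------------------------------------------------------
# Route 1 ("coaccess"): TSS-cRE connections from co-accessibility links.
# Route 2 ("model"): gene-peak pairs from the expression -> binarised-peak
# logistic predictor. Each route's cRE intervals are extended +/- 500 bp
# and merged; the union or the base-pair intersection of the two routes is
# then filtered against H3K27ac peaks to give the high-confidence list.

#' Per-gene percentile ranks with capped infinities
#'
#' Infinite values (e.g. -log10 of an adjusted p-value of zero) are replaced
#' by `cap_multiplier` times the greatest finite value of the whole score
#' table (or of the gene's own values with `cap_scope = "per_gene"`), then
#' values are percentile-ranked within each gene: rank with average ties
#' divided by the number of values, giving ranks in (0, 1].
#'
#' @param scores named list, gene id -> numeric vector (may contain `Inf`)
#' @param cap_multiplier multiplier applied to the maximum finite value
#' @param cap_scope `"global"` (default) or `"per_gene"`
#' @return named list of rank vectors, same shape as `scores`
#' @export
percentile_rank_per_gene <- function(scores, cap_multiplier = 2,
                                     cap_scope = c("global", "per_gene")) {
  cap_scope <- match.arg(cap_scope)
  if (!length(scores)) return(scores)
  all_vals <- unlist(scores, use.names = FALSE)
  if (!any(is.finite(all_vals))) {
    stop("all score values are infinite; no finite maximum to cap against")
  }
  global_cap <- cap_multiplier * max(all_vals[is.finite(all_vals)])
  lapply(scores, function(v) {
    if (any(is.infinite(v))) {
      cap <- if (cap_scope == "global") global_cap else {
        if (!any(is.finite(v))) {
          global_cap
        } else {
          cap_multiplier * max(v[is.finite(v)])
        }
      }
      v[is.infinite(v)] <- cap
    }
    rank(v, ties.method = "average") / length(v)
  })
}

#' Combine the two prediction routes
#'
#' Inputs are the already extended/merged interval sets of each route.
#' `"union"` concatenates and re-merges, recording which route(s)
#' contributed to each merged interval; `"intersect"` returns the base-pair
#' intersection with provenance `"both"` (only cREs common to both routes
#' survive).
#'
#' @param coaccess_cres,model_cres GRanges (disjoint, merged)
#' @param mode `"union"` or `"intersect"`
#' @return GRanges with a `provenance` metadata column
#' @export
combine_predictions <- function(coaccess_cres, model_cres,
                                mode = c("union", "intersect")) {
  mode <- match.arg(mode)
  if (mode == "union") {
    merged <- GenomicRanges::reduce(
      GenomicRanges::sort(c(GenomicRanges::granges(coaccess_cres),
                            GenomicRanges::granges(model_cres))),
      min.gapwidth = 1L
    )
    from_a <- IRanges::overlapsAny(merged, coaccess_cres, ignore.strand = TRUE)
    from_b <- IRanges::overlapsAny(merged, model_cres, ignore.strand = TRUE)
    S4Vectors::mcols(merged)$provenance <-
      ifelse(from_a & from_b, "both", ifelse(from_a, "coaccess", "model"))
    merged
  } else {
    common <- GenomicRanges::intersect(
      GenomicRanges::granges(coaccess_cres),
      GenomicRanges::granges(model_cres),
      ignore.strand = TRUE
    )
    if (length(common)) S4Vectors::mcols(common)$provenance <- "both"
    common
  }
}

#' Annotate candidates with the genes whose predictions they derive from
#'
#' Genes are carried through by interval overlap with a per-gene link table
#' (columns `gene_id`, `chrom`, `start`, `end`, optionally `rank`).
#'
#' @param candidates GRanges
#' @param link_table data.frame of gene-assigned intervals
#' @return `candidates` with `genes` (comma-joined ids) and, when ranks are
#'   present, `best_rank` metadata columns
#' @export
annotate_candidate_genes <- function(candidates, link_table) {
  if (!length(candidates)) return(candidates)
  src <- granges0(link_table$chrom, link_table$start, link_table$end)
  hits <- GenomicRanges::findOverlaps(candidates, src, ignore.strand = TRUE)
  genes <- rep(NA_character_, length(candidates))
  best <- rep(NA_real_, length(candidates))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    genes_split <- split(link_table$gene_id[sh], qh)
    genes[as.integer(names(genes_split))] <-
      vapply(genes_split, function(g) paste(sort(unique(g)), collapse = ","), "")
    if (!is.null(link_table$rank)) {
      best_split <- split(link_table$rank[sh], qh)
      best[as.integer(names(best_split))] <-
        vapply(best_split, max, numeric(1))
    }
  }
  S4Vectors::mcols(candidates)$genes <- genes
  if (!is.null(link_table$rank)) S4Vectors::mcols(candidates)$best_rank <- best
  candidates
}

#' Retain candidates supported by H3K27ac
#'
#' Keeps candidates overlapping (>= 1 bp) the union of all provided H3K27ac
#' sets (e.g. several ages or regions); the `h3k27ac_supported` flag is set
#' on the result.
#'
#' @param candidates GRanges
#' @param histone_sets list of histone peak sets
#'   (`list(mark, region, intervals)`)
#' @return the supported subset of `candidates`
#' @export
filter_by_h3k27ac <- function(candidates, histone_sets) {
  k27 <- Filter(function(h) h$mark == "H3K27ac", histone_sets)
  if (!length(k27)) stop("no H3K27ac set provided")
  pool <- GenomicRanges::reduce(do.call(c, lapply(k27, `[[`, "intervals")))
  hit <- IRanges::overlapsAny(candidates, pool, ignore.strand = TRUE)
  out <- candidates[hit]
  if (length(out)) S4Vectors::mcols(out)$h3k27ac_supported <- TRUE
  out
}

#' Region-level ATAC vs histone-mark overlap reports
#'
#' Three Venn-style comparisons per region: (1) promoter-overlapping ATAC
#' peaks vs promoter-overlapping H3K4me3 peaks; (2) non-promoter ATAC peaks
#' vs non-promoter H3K27ac peaks; (3) the subset of non-promoter ATAC peaks
#' that serve as the cRE of at least one TSS-cRE connection vs the same
#' H3K27ac set. The reported percentage is the fraction of the A-set
#' overlapping the mark.
#'
#' @param atac_peaks GRanges of all ATAC peaks
#' @param prom_windows GRanges of promoter windows
#' @param tss_links TSS-cRE connection table (may be empty; comparison 3 is
#'   then reported with a missing percentage)
#' @param histone_sets list of histone peak sets for one region
#' @param region region label (histone sets are filtered to it)
#' @return list of three overlap reports (see [percent_overlap()])
#' @export
histone_overlap_reports <- function(atac_peaks, prom_windows, tss_links,
                                    histone_sets, region) {
  sets <- Filter(function(h) h$region == region, histone_sets)
  get_mark <- function(mark, comparison) {
    hs <- Filter(function(h) h$mark == mark, sets)
    if (!length(hs)) {
      stop(sprintf("missing %s set for region %s (comparison '%s' skipped)",
                   mark, region, comparison))
    }
    GenomicRanges::reduce(do.call(c, lapply(hs, `[[`, "intervals")))
  }
  k4 <- get_mark("H3K4me3", "promoter ATAC vs H3K4me3")
  k27 <- get_mark("H3K27ac", "non-promoter ATAC vs H3K27ac")

  at_prom <- IRanges::overlapsAny(atac_peaks, prom_windows, ignore.strand = TRUE)
  prom_atac <- atac_peaks[at_prom]
  nonprom_atac <- atac_peaks[!at_prom]
  k4_prom <- IRanges::subsetByOverlaps(k4, prom_windows, ignore.strand = TRUE)
  k27_nonprom <- k27[!IRanges::overlapsAny(k27, prom_windows, ignore.strand = TRUE)]

  rep1 <- percent_overlap(prom_atac, k4_prom,
                          sprintf("%s: promoter ATAC vs H3K4me3", region))
  rep2 <- percent_overlap(nonprom_atac, k27_nonprom,
                          sprintf("%s: non-promoter ATAC vs H3K27ac", region))

  if (!is.null(tss_links) && nrow(tss_links)) {
    cres <- granges0(tss_links$chrom, tss_links$start, tss_links$end)
    linked <- nonprom_atac[IRanges::overlapsAny(nonprom_atac, cres,
                                                ignore.strand = TRUE)]
  } else {
    linked <- GenomicRanges::GRanges()
  }
  rep3 <- percent_overlap(linked, k27_nonprom,
                          sprintf("%s: TSS-linked non-promoter ATAC vs H3K27ac", region))
  list(promoter_k4 = rep1, nonpromoter_k27ac = rep2, linked_k27ac = rep3)
}

#' Full two-route enhancer prediction on one dataset
#'
#' Convenience wrapper: classifies TSS-cRE connections from the filtered
#' co-accessibility links, takes the retained gene-peak pairs from the
#' model route, excludes TSS-overlapping peaks, extends each route's cRE
#' intervals +/- `flank` bp and merges, combines routes, and (optionally)
#' filters by H3K27ac.
#'
#' @param links co-accessibility link table (unfiltered)
#' @param pairs gene-peak pair table from [predict_gene_peak_pairs()]
#' @param annotation gene annotation data.frame
#' @param histone_sets optional histone sets for the H3K27ac filter
#' @param mode `"intersect"` (high-confidence, default) or `"union"`
#' @param min_score co-accessibility threshold
#' @param flank extension before merging
#' @return GRanges of enhancer candidates with provenance
#' @export
predict_enhancers <- function(links, pairs, annotation, histone_sets = NULL,
                              mode = c("intersect", "union"),
                              min_score = 0.25, flank = 500) {
  mode <- match.arg(mode)
  tl <- classify_tss_links(filter_links(links, min_score), annotation)
  tss <- tss_ranges(annotation)

  coaccess_cres <- if (nrow(tl)) {
    gr <- granges0(tl$chrom, tl$start, tl$end)
    extend_and_merge(gr[!IRanges::overlapsAny(gr, tss, ignore.strand = TRUE)],
                     flank = flank)
  } else {
    GenomicRanges::GRanges()
  }

  kept <- pairs[pairs$retained, , drop = FALSE]
  model_cres <- if (nrow(kept)) {
    gr <- granges0(kept$chrom, kept$start, kept$end)
    extend_and_merge(gr[!IRanges::overlapsAny(gr, tss, ignore.strand = TRUE)],
                     flank = flank)
  } else {
    GenomicRanges::GRanges()
  }

  cand <- combine_predictions(coaccess_cres, model_cres, mode = mode)
  if (!is.null(histone_sets)) cand <- filter_by_h3k27ac(cand, histone_sets)
  cand
}
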