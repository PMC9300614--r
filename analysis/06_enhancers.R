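#!/usr/bin/env Rscript
# Stage 6 — two-route enhancer prediction and histone validation.
#
# Route 1: cRE anchors of the co-accessibility TSS links. Route 2: peaks
# predicted from expression by the logistic gene-peak model (FDR <= 0.05).
# Each route's intervals are extended +/- 500 bp and merged; the
# high-confidence list is their base-pair intersection filtered against
# H3K27ac. Closes with the per-region ATAC-vs-histone overlap reports.

library(epilink)

atac <- read_peak_matrix("results/dataset/atac/matrix.mtx",
                         "results/dataset/atac/barcodes.tsv",
                         "results/dataset/atac/peaks.bed")
rna <- read_expression_matrix("results/dataset/rna/matrix.mtx",
                              "results/dataset/rna/barcodes.tsv",
                              "results/dataset/rna/features.tsv")
cells <- read.table("results/dataset/cells.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
ann <- read_gene_annotation("results/dataset/annotation.tsv")
truth <- read.table("results/dataset/ground_truth/true_links.tsv",
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)

histone <- list()
for (f in list.files("results/dataset/histone", full.names = TRUE)) {
  parts <- strsplit(sub("\\.bed$", "", basename(f)), "_")[[1]]
  histone[[length(histone) + 1]] <- list(region = parts[1], mark = parts[2],
                                         intervals = read_bed(f))
}

links <- coaccessibility_scores(atac, cells)
pairs <- predict_gene_peak_pairs(rna, atac, ann, window = 500000,
                                 alpha = 0.05)
cat(sprintf("gene-peak model: %d pairs tested, %d retained at FDR <= 0.05\n",
            nrow(pairs), sum(pairs$retained)))

cand <- predict_enhancers(links, pairs, ann, histone, mode = "intersect",
                          min_score = 0.25, flank = 500)
cat(sprintf("high-confidence enhancer candidates: %d\n", length(cand)))

tg <- granges0(truth$chrom, truth$start, truth$end)
cat(sprintf("planted-enhancer coverage: %.1f%%; spurious intervals: %.1f%%\n",
            100 * mean(IRanges::overlapsAny(tg, cand)),
            100 * mean(!IRanges::overlapsAny(cand, tg))))

tl <- classify_tss_links(filter_links(links), ann)
pw <- promoter_windows(ann)
rows <- list()
for (region in c("MGE", "LGE", "CGE", "CTX")) {
  reps <- histone_overlap_reports(atac$peaks, pw, tl, histone, region)
  for (r in reps) {
    rows[[length(rows) + 1]] <- data.frame(
      comparison = r$label, n_a = r$n_a, n_b = r$n_b,
      n_intersect = r$n_intersect,
      percent = round(r$percent_a_overlapping, 1)
    )
  }
}
overlaps <- do.call(rbind, rows)
print(overlaps)

write_bed(cand, "results/enhancer_candidates.bed", bed6 = FALSE,
          extra_columns = data.frame(
            provenance = S4Vectors::mcols(cand)$provenance))
write.table(overlaps, "results/histone_overlap_reports.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("candidate and overlap tables written under results/\n")
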