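#!/usr/bin/env Rscript
# Stage 2 — barcode quality control.
#
# Screens total fragment counts and the promoter read fraction with Tukey
# far-out fences (k = 3); a barcode leaves the dataset when any metric
# falls strictly outside its fences. Scores the filter against the
# generator's planted outliers and writes the removal report.

library(epilink)

cells <- read.table("results/dataset/cells.tsv", header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
outliers <- readLines("results/dataset/ground_truth/outliers.tsv")

res <- filter_barcodes(cells, c("total_counts", "promoter_ratio"), k = 3)
removed <- setdiff(cells$barcode, res$kept)
normal <- setdiff(cells$barcode, outliers)

cat(sprintf("removed %d / %d barcodes\n", length(removed), nrow(cells)))
cat(sprintf("planted-outlier recall: %.1f%%\n",
            100 * mean(outliers %in% removed)))
cat(sprintf("normal barcodes removed: %.2f%%\n",
            100 * mean(normal %in% removed)))
for (m in names(res$fences)) {
  f <- res$fences[[m]]
  cat(sprintf("  %s fences: [%.3g, %.3g]\n", m, f$lower, f$upper))
}

write.table(res$report, "results/qc_removal_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(res$kept, "results/qc_kept_barcodes.txt")
cat("report written to results/qc_removal_report.tsv\n")
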