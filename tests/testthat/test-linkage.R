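toy_cells <- function(n, regions = "MGE", states = c("AP", "BP")) {
  grid <- expand.grid(region = regions, state = states,
                      stringsAsFactors = FALSE)
  per <- ceiling(n / nrow(grid))
  df <- grid[rep(seq_len(nrow(grid)), each = per)[1:n], ]
  data.frame(barcode = sprintf("bc%03d", 1:n), region = df$region,
             state = df$state, pseudotime = seq_len(n) / n,
             stringsAsFactors = FALSE)
}

test_that("metacell pooling is deterministic and merges the remainder", {
  set.seed(2)
  cells <- toy_cells(23, states = "AP")
  counts <- Matrix::Matrix(matrix(rpois(23 * 4, 1), 23, 4), sparse = TRUE)
  pm <- peak_matrix(counts, cells$barcode,
                    granges0(rep("chr1", 4), c(0, 10, 20, 30) * 100,
                             c(5, 15, 25, 35) * 100))
  mb <- metacell_binarize(pm, cells, metacell_size = 10)
  # 23 cells at size 10 -> 2 metacells, remainder of 3 merged into the last
  expect_equal(nrow(mb$binary), 2)
  expect_identical(mb$binary, metacell_binarize(pm, cells, 10)$binary)
  expect_error(metacell_binarize(pm, cells, metacell_size = 20), "2 \\* metacell")
})

test_that("co-accessibility equals the brute-force correlation oracle", {
  set.seed(13)
  n_cells <- 120
  n_peaks <- 40
  cells <- toy_cells(n_cells)
  # a low rate so pooled metacell counts are a genuine 0/1 mixture
  counts <- Matrix::Matrix(matrix(rpois(n_cells * n_peaks, 0.05),
                                  n_cells, n_peaks), sparse = TRUE)
  starts <- sort(sample.int(2e5, n_peaks))
  pm <- peak_matrix(counts, cells$barcode,
                    granges0(rep("chr1", n_peaks), starts * 10, starts * 10 + 400))
  links <- coaccessibility_scores(pm, cells, window = 5e5, metacell_size = 20)

  mb <- metacell_binarize(pm, cells, 20)
  mid <- (GenomicRanges::start(pm$peaks) - 1 + GenomicRanges::end(pm$peaks)) / 2
  # brute force: every same-chrom pair within the window, plain cor()
  expected <- list()
  for (i in 1:(n_peaks - 1)) {
    for (j in (i + 1):n_peaks) {
      if (abs(mid[j] - mid[i]) > 5e5) next
      vi <- mb$binary[, i]; vj <- mb$binary[, j]
      if (min(vi) == max(vi) || min(vj) == max(vj)) next
      expected[[length(expected) + 1]] <- c(i, j, cor(vi, vj))
    }
  }
  expected <- do.call(rbind, expected)
  got <- links[order(links$peak_a, links$peak_b), ]
  expect_gt(nrow(got), 50)  # the instance must actually exercise the path
  expect_equal(nrow(got), nrow(expected))
  expect_equal(got$peak_a, expected[, 1])
  expect_equal(got$peak_b, expected[, 2])
  expect_equal(got$score, expected[, 3])
})

test_that("degenerate peak pairs behave per the score definition", {
  cells <- toy_cells(40)
  # peaks 1,2 identical pattern; peak 3 constant; peak 4 on another chrom
  base <- c(rep(1, 20), rep(0, 20))
  counts <- Matrix::Matrix(cbind(base, base, 1, base), sparse = TRUE)
  pm <- peak_matrix(counts, cells$barcode,
                    granges0(c("chr1", "chr1", "chr1", "chr9"),
                             c(0, 1000, 2000, 0), c(500, 1500, 2500, 500)))
  links <- coaccessibility_scores(pm, cells, metacell_size = 10)
  expect_equal(links$score[links$peak_a == 1 & links$peak_b == 2], 1)
  expect_false(3 %in% c(links$peak_a, links$peak_b))  # constant excluded
  expect_false(4 %in% c(links$peak_a, links$peak_b))  # other chromosome
})

test_that("filter_links is inclusive at the threshold and idempotent", {
  links <- data.frame(score = c(0.25, 0.249, 0.9, -0.5))
  f <- filter_links(links)
  expect_equal(f$score, c(0.25, 0.9))
  expect_identical(filter_links(f), f)
  expect_equal(nrow(filter_links(links[0, , drop = FALSE])), 0)
})

test_that("TSS-cRE classification follows the one-anchor rule", {
  ann <- toy_annotation()
  mk <- function(a, b, score = 0.5) {
    data.frame(peak_a = 1, peak_b = 2, chrom_a = "chr1", start_a = a[1],
               end_a = a[2], chrom_b = "chr1", start_b = b[1], end_b = b[2],
               score = score)
  }
  # promoter peak (spans gA TSS at 10000) to intergenic peak -> one link
  one <- classify_tss_links(mk(c(9900, 10100), c(50000, 50400)), ann)
  expect_equal(nrow(one), 1)
  expect_equal(one$gene_id, "gA")
  expect_equal(one$start, 50000)

  # promoter peak to promoter peak (gB promoter window 30001..32001) -> dropped
  both <- classify_tss_links(mk(c(9900, 10100), c(30000, 30400)), ann)
  expect_equal(nrow(both), 0)

  # neither anchor on a TSS -> dropped
  none <- classify_tss_links(mk(c(40000, 40100), c(50000, 50400)), ann)
  expect_equal(nrow(none), 0)

  # an anchor spanning two TSSs emits two links with the same cRE
  ann2 <- ann
  ann2$tss[2] <- 10050
  ann2$body_start[2] <- 8000
  ann2$body_end[2] <- 10051
  ann2$exon1_start[2] <- 9900
  ann2$exon1_end[2] <- 10051
  two <- classify_tss_links(mk(c(9990, 10060), c(50000, 50400)), ann2)
  expect_equal(sort(two$gene_id), c("gA", "gB"))
  expect_equal(unique(two$start), 50000)
})

test_that("classified cREs never overlap any promoter window", {
  sim <- default_sim()
  links <- coaccessibility_scores(sim$atac, sim$cells)
  tl <- classify_tss_links(filter_links(links), sim$annotation)
  pw <- promoter_windows(sim$annotation)
  cres <- granges0(tl$chrom, tl$start, tl$end)
  expect_false(any(IRanges::overlapsAny(cres, pw, ignore.strand = TRUE)))
})

test_that("per-group link counting downsamples deterministically", {
  sim <- default_sim()
  c1 <- count_links_by_group(sim$atac, sim$cells, "region", seed = 7)
  c2 <- count_links_by_group(sim$atac, sim$cells, "region", seed = 7)
  expect_identical(c1, c2)
  expect_named(c1, c("CGE", "CTX", "LGE", "MGE"))
  # the dense region carries the planted 3x enhancer load
  expect_true(all(c1["MGE"] > c1[c("LGE", "CGE", "CTX")]))

  small <- sim$cells[sim$cells$state == "AP", ][1:80, ]
  pm <- subset_cells(sim$atac, small$barcode)
  small <- small[match(pm$barcodes, small$barcode), ]
  small$region[1:10] <- "tiny"
  expect_error(count_links_by_group(pm, small, "region", seed = 1), "need >=")
})

test_that("gene-peak prediction honours the testable-gene and FDR rules", {
  sim <- default_sim()
  pairs <- predict_gene_peak_pairs(sim$rna, sim$atac, sim$annotation)
  expect_true(all(pairs$retained == (pairs$adj_p <= 0.05)))
  expect_true(all(pairs$adj_p >= pairs$p_value - 1e-12))

  # a gene whose TSS peak has zero counts everywhere is never tested
  zeroed <- sim$atac
  tssg <- tss_ranges(sim$annotation)
  gid <- sim$annotation$gene_id[1]
  tss_peaks <- which(IRanges::overlapsAny(
    zeroed$peaks, tssg[S4Vectors::mcols(tssg)$gene_id == gid],
    ignore.strand = TRUE))
  zeroed$counts[, tss_peaks] <- 0
  pairs0 <- predict_gene_peak_pairs(sim$rna, zeroed, sim$annotation)
  expect_false(gid %in% pairs0$gene_id)

  bad_rna <- sim$rna
  bad_rna$barcodes[1] <- "someone_else"
  rownames(bad_rna$counts) <- bad_rna$barcodes
  expect_error(predict_gene_peak_pairs(bad_rna, sim$atac, sim$annotation),
               "share barcodes")
})
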