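test_that("MatrixMarket triple reads preserve order and values", {
  dir <- withr::local_tempdir()
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "2 2 2", "1 1 3", "2 2 1"),
             file.path(dir, "m.mtx"))
  writeLines(c("bc1", "bc2"), file.path(dir, "barcodes.tsv"))
  writeLines(c("chr1\t100\t200", "chr1\t300\t400"), file.path(dir, "peaks.bed"))
  pm <- read_peak_matrix(file.path(dir, "m.mtx"), file.path(dir, "barcodes.tsv"),
                         file.path(dir, "peaks.bed"))
  expect_equal(as.matrix(pm$counts),
               matrix(c(3, 0, 0, 1), 2, 2, dimnames = list(c("bc1", "bc2"), NULL)))
  expect_equal(granges_to_bed(pm$peaks)$start, c(100, 300))

  # dimension mismatch is a format error
  writeLines("bc1", file.path(dir, "short.tsv"))
  expect_error(
    read_peak_matrix(file.path(dir, "m.mtx"), file.path(dir, "short.tsv"),
                     file.path(dir, "peaks.bed")),
    "format error"
  )

  # degenerate 0x0 matrix with matching empty indices
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "0 0 0"),
             file.path(dir, "e.mtx"))
  writeLines(character(0), file.path(dir, "eb.tsv"))
  writeLines(character(0), file.path(dir, "ep.bed"))
  pm0 <- read_peak_matrix(file.path(dir, "e.mtx"), file.path(dir, "eb.tsv"),
                          file.path(dir, "ep.bed"))
  expect_equal(dim(pm0$counts), c(0L, 0L))
})

test_that("BED parsing is 0-based half-open and reports bad lines", {
  dir <- withr::local_tempdir()
  writeLines("chr1\t100\t200", file.path(dir, "a.bed"))
  gr <- read_bed(file.path(dir, "a.bed"))
  expect_equal(GenomicRanges::start(gr), 101L)  # 1-based internal
  expect_equal(granges_to_bed(gr),
               data.frame(chrom = "chr1", start = 100, end = 200, strand = "."))

  writeLines(c("chr1\t1\t5", "chr1\toops"), file.path(dir, "bad.bed"))
  expect_error(read_bed(file.path(dir, "bad.bed")), "line 2")
})

test_that("BED writing round-trips and supports BED6", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "x.bed")
  expect_equal(readLines(write_bed(granges0("chr2", 0, 50), path)),
               "chr2\t0\t50")

  write_bed(granges0("chr1", 10, 20, "-"), path, bed6 = TRUE)
  expect_equal(readLines(path), "chr1\t10\t20\t.\t0\t-")

  # property: round-trip of 100 random intervals is exact
  set.seed(42)
  df <- random_intervals(100)
  gr <- granges0(df$chrom, df$start, df$end)
  write_bed(gr, path)
  back <- read_bed(path)
  expect_identical(granges_to_bed(back)[c("chrom", "start", "end")],
                   data.frame(chrom = df$chrom, start = df$start, end = df$end))

  expect_error(granges0("chr1", -5, 10), "negative")
})

test_that("gene annotation validation rejects malformed records", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "ann.tsv")
  ok <- toy_annotation()
  write.table(ok, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- read_gene_annotation(path)
  expect_equal(ann$gene_id, c("gA", "gB", "gC"))
  # minus-strand gene with tss == body_end - 1 is accepted
  expect_equal(ann$tss[2], ann$body_end[2] - 1)

  dup <- rbind(ok, ok[1, ])
  expect_error(validate_gene_annotation(dup), "gA")

  bad_strand <- ok; bad_strand$strand[1] <- "."
  expect_error(validate_gene_annotation(bad_strand), "strand")

  bad_exon <- ok; bad_exon$exon1_end[1] <- ok$body_end[1] + 100
  expect_error(validate_gene_annotation(bad_exon), "exon")
})

test_that("overlap predicates agree with a brute-force oracle", {
  set.seed(7)
  a <- random_intervals(600)
  b <- random_intervals(600)
  ga <- granges0(a$chrom, a$start, a$end)
  gb <- granges0(b$chrom, b$start, b$end)
  expect_equal(IRanges::overlapsAny(ga, gb, ignore.strand = TRUE),
               brute_overlaps_any(a, b))

  rep <- percent_overlap(ga, gb)
  expect_equal(rep$percent_a_overlapping, 100 * mean(brute_overlaps_any(a, b)))
  expect_lte(rep$n_intersect, min(rep$n_a, rep$n_b))
})

test_that("percent_overlap handles the documented cases", {
  a <- granges0(c("chr1", "chr1"), c(0, 20), c(10, 30))
  expect_equal(percent_overlap(a, granges0("chr1", 5, 6))$percent_a_overlapping, 50)
  expect_equal(percent_overlap(a, a)$percent_a_overlapping, 100)
  expect_true(is.na(percent_overlap(GenomicRanges::GRanges(), a)$percent_a_overlapping))
})

test_that("chromosome mismatches between inputs are reported", {
  expect_warning(
    check_shared_chromosomes(granges0("chr1", 0, 10), granges0("1", 0, 10)),
    "mismatch"
  )
})

test_that("extend_and_merge extends, clamps, merges and is idempotent", {
  gr <- granges0(c("chr1", "chr1"), c(100, 1000), c(200, 1100))
  merged <- extend_and_merge(gr, flank = 500)
  expect_equal(granges_to_bed(merged)[c("start", "end")],
               data.frame(start = 0, end = 1600))

  one <- extend_and_merge(granges0("chr1", 5000, 5100), flank = 500)
  expect_equal(granges_to_bed(one)[c("start", "end")],
               data.frame(start = 4500, end = 5600))

  # sorted, disjoint, covers at least the input, idempotent at flank 0
  set.seed(11)
  df <- random_intervals(300)
  g <- granges0(df$chrom, df$start, df$end)
  m <- extend_and_merge(g, flank = 500)
  expect_true(all(diff(GenomicRanges::start(m)) > 0 |
                    diff(as.integer(GenomicRanges::seqnames(m))) != 0))
  expect_gte(sum(GenomicRanges::width(m)),
             sum(GenomicRanges::width(GenomicRanges::reduce(g))))
  expect_identical(granges_to_bed(extend_and_merge(m, flank = 0)),
                   granges_to_bed(m))
})
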