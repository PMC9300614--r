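test_that("generator output is deterministic given (design, seed)", {
  d <- simulation_design(n_genes = 20, cells_per_group = 20,
                         n_background_peaks = 30, chrom_count = 2,
                         chrom_length = 4e7)
  a <- simulate_multiome(d, seed = 5)
  b <- simulate_multiome(d, seed = 5)
  expect_identical(a$annotation, b$annotation)
  expect_identical(as.matrix(a$atac$counts), as.matrix(b$atac$counts))
  expect_identical(as.matrix(a$rna$counts), as.matrix(b$rna$counts))
  expect_identical(a$cells, b$cells)
  expect_identical(a$truth$true_links, b$truth$true_links)
})

test_that("simulated genome respects promoter/enhancer geometry", {
  d <- simulation_design(n_genes = 1, enhancers_per_gene = c(1L, 1L),
                         chrom_count = 1, chrom_length = 3e6,
                         n_background_peaks = 5)
  g <- simulate_genome(d, seed = 3)
  expect_gte(length(g$peaks), 3)
  pw <- promoter_windows(g$annotation)
  role <- S4Vectors::mcols(g$peaks)$role
  hits <- IRanges::overlapsAny(g$peaks, pw, ignore.strand = TRUE)
  expect_equal(sum(hits & role == "promoter"), 1)

  # enhancers and background never touch a promoter window
  sim <- default_sim()
  pw <- promoter_windows(sim$annotation)
  role <- S4Vectors::mcols(sim$peaks)$role
  nonprom <- sim$peaks[role %in% c("enhancer", "background")]
  expect_false(any(IRanges::overlapsAny(nonprom, pw, ignore.strand = TRUE)))

  # every planted enhancer lies within 500 kb of its gene's TSS
  tl <- sim$truth$true_links
  tss <- sim$annotation$tss[match(tl$gene_id, sim$annotation$gene_id)]
  expect_true(all(abs((tl$start + tl$end) / 2 - tss) <= 5e5))
})

test_that("accessibility leads expression by rna_lag along AP->BP->N", {
  sim <- default_sim()
  pr <- sim$truth$gene_program
  # wherever a gene is expressed in state s+1 it must already be
  # accessibility-active in state s (the definition of the planted lag)
  for (r in unique(pr$region)) {
    sub <- pr[pr$region == r, ]
    for (g in unique(sub$gene_id[sub$expr_active])) {
      gs <- sub[sub$gene_id == g, ]
      expr <- gs$expr_active[match(c("AP", "BP", "N"), gs$state)]
      acc <- gs$acc_active[match(c("AP", "BP", "N"), gs$state)]
      expect_true(all(acc >= expr))
      if (expr[2]) expect_true(acc[1])  # expressed in BP -> accessible in AP
      if (expr[3]) expect_true(acc[2])
    }
    break  # one region suffices; programs are region-factorised
  }
})

test_that("planted outliers fall outside Tukey far-out fences", {
  sim <- default_sim()
  normal <- !(sim$cells$barcode %in% sim$truth$planted_outliers)
  f <- tukey_fences(sim$cells$total_counts[normal])
  out_tot <- sim$cells$total_counts[!normal]
  expect_gte(mean(out_tot > f$upper), 0.95)
})

test_that("histone emission follows activity and the false-negative rate", {
  d <- simulation_design(n_genes = 30, cells_per_group = 10,
                         n_background_peaks = 20, chrom_count = 2,
                         chrom_length = 4e7,
                         h3k27ac_false_negative_rate = 0)
  g <- simulate_genome(d, seed = 2)
  hs0 <- simulate_histone_peaks(g, d, seed = 9)
  pr <- g$truth$gene_program
  tl <- g$truth$true_links

  # fnr = 0: every true enhancer of a region-active gene is H3K27ac-marked
  for (r in c("MGE", "CTX")) {
    act <- unique(pr$gene_id[pr$region == r & pr$expr_active])
    el <- tl[tl$gene_id %in% act, ]
    if (!nrow(el)) next
    k27 <- Filter(function(h) h$mark == "H3K27ac" && h$region == r, hs0)[[1]]
    expect_true(all(IRanges::overlapsAny(
      granges0(el$chrom, el$start, el$end), k27$intervals)))
  }

  # fnr = 1: no true enhancer is marked
  d1 <- d; d1$h3k27ac_false_negative_rate <- 1
  hs1 <- simulate_histone_peaks(g, d1, seed = 9)
  k27 <- Filter(function(h) h$mark == "H3K27ac", hs1)
  expect_true(all(vapply(k27, function(h) length(h$intervals) == 0L, logical(1))))

  # region-restricted gene: K4me3 at home, K27me3 elsewhere
  prof <- g$truth$gene_profile
  cand <- prof$gene_id[prof$scope == "MGE"]
  if (length(cand)) {
    gid <- cand[1]
    prom <- g$peaks[S4Vectors::mcols(g$peaks)$role == "promoter" &
                      S4Vectors::mcols(g$peaks)$gene_id == gid]
    k4_mge <- Filter(function(h) h$mark == "H3K4me3" && h$region == "MGE", hs0)[[1]]
    k27me3_lge <- Filter(function(h) h$mark == "H3K27me3" && h$region == "LGE", hs0)[[1]]
    expect_true(IRanges::overlapsAny(prom, k4_mge$intervals))
    expect_true(IRanges::overlapsAny(prom, k27me3_lge$intervals))
  }
})

test_that("datasets round-trip through disk byte-identically", {
  d <- simulation_design(n_genes = 15, cells_per_group = 10,
                         n_background_peaks = 20, chrom_count = 2,
                         chrom_length = 3e7)
  sim <- simulate_multiome(d, seed = 4)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_dataset(sim, dir1)
  write_dataset(sim, dir2)

  rel <- list.files(dir1, recursive = TRUE)
  expect_identical(rel, list.files(dir2, recursive = TRUE))
  for (f in rel) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }

  back <- read_peak_matrix(file.path(dir1, "atac", "matrix.mtx"),
                           file.path(dir1, "atac", "barcodes.tsv"),
                           file.path(dir1, "atac", "peaks.bed"))
  expect_equal(as.matrix(back$counts), as.matrix(sim$atac$counts))
  gt <- read.table(file.path(dir1, "ground_truth", "true_links.tsv"),
                   header = TRUE, sep = "\t")
  expect_equal(nrow(gt), nrow(sim$truth$true_links))
  manifest <- yaml::read_yaml(file.path(dir1, "manifest.yaml"))
  expect_equal(manifest$master_seed, 4)
})

test_that("planted links induce co-accessibility above a distance-matched null", {
  sim <- default_sim()
  links <- coaccessibility_scores(sim$atac, sim$cells)
  key <- function(ch, s, e) paste0(ch, ":", s, "-", e)
  bed <- granges_to_bed(sim$atac$peaks)
  role <- S4Vectors::mcols(sim$atac$peaks)$role
  gene <- S4Vectors::mcols(sim$atac$peaks)$gene_id
  pk_key <- key(bed$chrom, bed$start, bed$end)

  tl <- sim$truth$true_links
  prom_key <- setNames(pk_key[role == "promoter"], gene[role == "promoter"])
  true_pair <- paste(pmin(prom_key[tl$gene_id], key(tl$chrom, tl$start, tl$end)),
                     pmax(prom_key[tl$gene_id], key(tl$chrom, tl$start, tl$end)))
  link_pair <- paste(pmin(pk_key[links$peak_a], pk_key[links$peak_b]),
                     pmax(pk_key[links$peak_a], pk_key[links$peak_b]))
  is_true <- link_pair %in% true_pair
  # null: same-window pairs not planted together (includes cross-element
  # pairs of unrelated genes and background)
  null_scores <- links$score[!is_true &
                               (role[links$peak_a] == "background" |
                                  role[links$peak_b] == "background")]
  expect_gt(mean(links$score[is_true]),
            quantile(null_scores, 0.95, names = FALSE))
})

test_that("linked enhancers track their promoter better than random peaks", {
  hold <- vapply(1:10, function(s) {
    d <- simulation_design()
    g <- simulate_genome(d, seed = s)
    cnt <- simulate_counts(g, d, seed = s + 1L)
    role <- S4Vectors::mcols(g$peaks)$role
    gene <- S4Vectors::mcols(g$peaks)$gene_id
    tl <- cnt$truth$true_links
    prof <- cnt$truth$gene_profile
    # pick a linked gene with a regulated (non-CpG-island-like) promoter
    regulated <- prof$gene_id[!prof$constitutive_promoter]
    gid <- tl$gene_id[tl$gene_id %in% regulated][1]
    prom_j <- which(role == "promoter" & gene == gid)
    enh_j <- which(role == "enhancer" & gene == gid)[1]
    other <- which(role == "background")[1]
    B <- as.matrix(cnt$atac$counts[, c(prom_j, enh_j, other)] > 0) * 1
    cor(B[, 1], B[, 2]) > cor(B[, 1], B[, 3])
  }, logical(1))
  expect_gte(sum(hold), 9)
})
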