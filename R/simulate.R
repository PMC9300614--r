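#' @importFrom stats rpois rlnorm runif rbinom
NULL

REGIONS <- c("MGE", "LGE", "CGE", "CTX")
STATES <- c("AP", "BP", "N")

# Temporal activity profiles a gene can follow along AP -> BP -> N, with the
# sampling weights used by the generator.  The fully flat profile (active in
# every state of every region) is deliberately absent: a globally invariant
# gene is constant under metacell binarisation and carries no information
# for any statistic under test, so the simulated gene complement mirrors the
# developmentally dynamic genes a variable-feature selection would retain.
GENE_PROFILES <- list(
  AP    = c("AP"),
  AP_BP = c("AP", "BP"),
  BP    = c("BP"),
  BP_N  = c("BP", "N"),
  N     = c("N"),
  ALL   = c("AP", "BP", "N")
)
# Weights plant progressively more repression along AP -> BP -> N: genes
# switching on at BP outnumber those switching off by ~1.4x, while genes
# switching on at N are outnumbered ~3.8x by those switching off there.
GENE_PROFILE_WEIGHTS <- c(AP = 0.18, AP_BP = 0.24, BP = 0.14,
                          BP_N = 0.12, N = 0.10, ALL = 0.22)

#' Simulation design for the synthetic multiome generator
#'
#' Defaults define the study conditions every recovery test runs under:
#' 4 forebrain regions x 3 maturation states x 150 cells (1800 cells),
#' 200 genes with 0-3 planted enhancers each plus background peaks
#' (~1100-1200 peaks in total). Rates are per-cell Poisson intensities
#' multiplied by a LogNormal cell depth.
#'
#' @param n_genes number of genes
#' @param enhancers_per_gene integer range (min, max) of planted enhancers
#'   per gene
#' @param cells_per_group cells per (region, state) pair
#' @param chrom_count,chrom_length chromosomes and their common length (bp)
#' @param depth_lognormal `c(meanlog, sdlog)` of the per-cell depth factor
#' @param open_rate_high Poisson rate of an accessible element per unit depth
#' @param open_rate_low rate of an inaccessible element
#' @param background_rate rate of ubiquitous background peaks
#' @param n_background_peaks number of background intergenic peaks
#' @param expr_rate_high,expr_rate_low RNA rates for expressed / silent genes
#' @param promoter_constitutive_fraction fraction of genes whose promoter
#'   peak is constitutively accessible (CpG-island-like): open at a fixed
#'   moderate rate in every cell regardless of the expression program, so
#'   their regulation is only visible at the gene body and enhancers
#' @param activity_grading `c(min, max)` of the uniform per-(gene, region,
#'   state) activity level multiplying both the expression and the
#'   accessibility rate of active elements: expression is graded, not
#'   binary, and chromatin openness tracks the level. `c(1, 1)` disables
#'   grading
#' @param rna_lag states by which accessibility precedes expression (0 or 1)
#' @param outlier_fraction fraction of barcodes given extreme depth
#' @param outlier_depth_factor `c(min, max)` multiplicative depth inflation
#'   of planted outliers
#' @param h3k27ac_false_negative_rate chance a true enhancer lacks its
#'   region-matched H3K27ac peak
#' @param dense_region region whose genes carry extra enhancers
#'   (3x link density), used to test per-group link counting
#' @param dense_enhancer_factor enhancer multiplicity factor for that region
#' @param dispersion reserved hook for count overdispersion (0 = pure
#'   Poisson; nonzero values are not yet implemented)
#' @param seed default random seed
#' @return a `simulation_design` list
#' @export
simulation_design <- function(n_genes = 200,
                              enhancers_per_gene = c(0L, 3L),
                              cells_per_group = 150,
                              chrom_count = 5,
                              chrom_length = 6e7,
                              depth_lognormal = c(meanlog = 0, sdlog = 0.4),
                              open_rate_high = 0.5,
                              open_rate_low = 0.002,
                              background_rate = 0.1,
                              n_background_peaks = 400,
                              expr_rate_high = 5,
                              expr_rate_low = 0.05,
                              activity_grading = c(0.3, 1),
                              promoter_constitutive_fraction = 0.3,
                              rna_lag = 1L,
                              outlier_fraction = 0.05,
                              outlier_depth_factor = c(6, 12),
                              h3k27ac_false_negative_rate = 0.1,
                              dense_region = "MGE",
                              dense_enhancer_factor = 3,
                              dispersion = 0,
                              seed = 1L) {
  design <- list(
    n_genes = as.integer(n_genes),
    enhancers_per_gene = as.integer(enhancers_per_gene),
    cells_per_group = as.integer(cells_per_group),
    regions = REGIONS, states = STATES,
    chrom_count = as.integer(chrom_count),
    chrom_length = chrom_length,
    depth_lognormal = depth_lognormal,
    open_rate_high = open_rate_high,
    open_rate_low = open_rate_low,
    background_rate = background_rate,
    n_background_peaks = as.integer(n_background_peaks),
    expr_rate_high = expr_rate_high,
    expr_rate_low = expr_rate_low,
    activity_grading = activity_grading,
    promoter_constitutive_fraction = promoter_constitutive_fraction,
    rna_lag = as.integer(rna_lag),
    outlier_fraction = outlier_fraction,
    outlier_depth_factor = outlier_depth_factor,
    h3k27ac_false_negative_rate = h3k27ac_false_negative_rate,
    dense_region = dense_region,
    dense_enhancer_factor = dense_enhancer_factor,
    dispersion = dispersion,
    seed = as.integer(seed)
  )
  validate_design(design)
  structure(design, class = "simulation_design")
}

validate_design <- function(d) {
  stopifnot(
    d$n_genes >= 1,
    d$open_rate_low > 0, d$open_rate_low < d$open_rate_high,
    d$rna_lag %in% c(0L, 1L),
    d$outlier_fraction >= 0, d$outlier_fraction < 0.5,
    d$h3k27ac_false_negative_rate >= 0, d$h3k27ac_false_negative_rate <= 1,
    length(d$enhancers_per_gene) == 2L,
    d$enhancers_per_gene[1] >= 0,
    d$enhancers_per_gene[1] <= d$enhancers_per_gene[2],
    d$cells_per_group >= 1,
    d$promoter_constitutive_fraction >= 0,
    d$promoter_constitutive_fraction < 1,
    length(d$activity_grading) == 2L,
    d$activity_grading[1] > 0,
    d$activity_grading[1] <= d$activity_grading[2]
  )
  if (d$dispersion != 0) stop("count overdispersion hook not implemented")
  invisible(d)
}

state_index <- function(state) match(state, STATES)

#' Simulate a genome: gene annotation, peak set and ground-truth programs
#'
#' Genes are placed non-overlapping on evenly spaced slots (>1 Mb apart so
#' that planted cross-gene peak pairs always exceed the co-accessibility
#' window). Each gene receives a promoter peak spanning its 2 kb upstream
#' window plus the TSS base, a first-exon peak, and 0-3 intergenic enhancer
#' peaks within 10-200 kb of the TSS that overlap no promoter window or gene
#' body. Background intergenic peaks overlap no promoter window. Every gene
#' is assigned a (region scope, temporal profile) activity program;
#' accessibility activity is the expression activity shifted `rna_lag`
#' states earlier (chromatin opens before transcription).
#'
#' @param design a [simulation_design()]
#' @param seed random seed (defaults to `design$seed`)
#' @return list with `annotation` (data.frame), `peaks` (GRanges with
#'   `role`/`gene_id` metadata), and `truth` (gene programs, true links,
#'   early/late gene sets)
#' @export
simulate_genome <- function(design, seed = design$seed) {
  validate_design(design)
  set.seed(seed)
  per_chrom <- ceiling(design$n_genes / design$chrom_count)
  slot_width <- design$chrom_length / per_chrom
  if (slot_width < 1.4e6) {
    stop(sprintf(
      "sizing error: %d genes on %d chromosomes of %.0f bp leaves %.0f bp per gene (< 1.4 Mb)",
      design$n_genes, design$chrom_count, design$chrom_length, slot_width
    ))
  }

  n <- design$n_genes
  gene_id <- sprintf("gene%03d", seq_len(n))
  chrom_i <- ((seq_len(n) - 1L) %/% per_chrom) + 1L
  chrom <- sprintf("chr%d", chrom_i)
  slot <- ((seq_len(n) - 1L) %% per_chrom)
  anchor <- floor(slot * slot_width + 0.35 * slot_width +
                    runif(n, 0, 0.15 * slot_width))
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body_len <- sample(2000:10000, n, replace = TRUE)
  exon_len <- pmin(300L, body_len)

  tss <- anchor
  body_start <- ifelse(strand == "+", anchor, anchor - body_len + 1)
  body_end <- ifelse(strand == "+", anchor + body_len, anchor + 1)
  exon1_start <- ifelse(strand == "+", anchor, anchor + 1 - exon_len)
  exon1_end <- ifelse(strand == "+", anchor + exon_len, anchor + 1)

  annotation <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand, tss = tss,
    exon1_start = exon1_start, exon1_end = exon1_end,
    body_start = body_start, body_end = body_end,
    stringsAsFactors = FALSE
  )
  validate_gene_annotation(annotation)

  # activity programs
  profile <- sample(names(GENE_PROFILES), n, replace = TRUE,
                    prob = GENE_PROFILE_WEIGHTS)
  scope <- ifelse(runif(n) < 0.5, "ALL", NA)
  need_specific <- is.na(scope) | profile == "ALL"
  scope[need_specific] <- sample(REGIONS, sum(need_specific), replace = TRUE)

  program <- expand.grid(gene_id = gene_id, region = REGIONS, state = STATES,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gi <- match(program$gene_id, gene_id)
  in_scope <- scope[gi] == "ALL" | scope[gi] == program$region
  in_profile <- mapply(function(g, s) s %in% GENE_PROFILES[[profile[g]]],
                       gi, program$state)
  program$expr_active <- in_scope & in_profile
  # accessibility precedes expression: active if expressed now or
  # rna_lag states later
  si <- state_index(program$state)
  nxt <- pmin(si + design$rna_lag, length(STATES))
  key <- paste(program$gene_id, program$region, sep = "|")
  expr_by <- split(seq_len(nrow(program)), key)
  program$acc_active <- program$expr_active
  # graded activity: each active (gene, region, state) has a level in the
  # design range scaling both RNA and chromatin rates (expression is graded,
  # not binary, and accessibility magnitude tracks it)
  u <- runif(nrow(program), design$activity_grading[1],
             design$activity_grading[2])
  program$expr_level <- u
  program$acc_level <- u
  if (design$rna_lag > 0) {
    nxt_key <- paste(program$gene_id, program$region, STATES[nxt], sep = "|")
    cur_key <- paste(program$gene_id, program$region, program$state, sep = "|")
    expr_lookup <- program$expr_active
    names(expr_lookup) <- cur_key
    u_lookup <- setNames(u, cur_key)
    program$acc_active <- program$expr_active | unname(expr_lookup[nxt_key])
    # an element open ahead of expression anticipates the coming level
    program$acc_level <- ifelse(program$expr_active, u,
                                unname(u_lookup[nxt_key]))
  }

  # promoter windows needed to keep enhancers/background clear of them
  prom_start <- ifelse(strand == "+", pmax(0, tss - 2000), tss)
  prom_end <- ifelse(strand == "+", tss, tss + 2000)
  # promoter peak additionally spans the TSS base so it overlaps the TSS
  # point, as real ATAC promoter peaks do
  ppeak_start <- ifelse(strand == "+", pmax(0, tss - 2000), tss)
  ppeak_end <- ifelse(strand == "+", tss + 1, tss + 2000)

  peaks <- data.frame(
    chrom = chrom, start = ppeak_start, end = ppeak_end,
    role = "promoter", gene_id = gene_id, stringsAsFactors = FALSE
  )
  peaks <- rbind(peaks, data.frame(
    chrom = chrom, start = exon1_start, end = exon1_end,
    role = "exon1", gene_id = gene_id, stringsAsFactors = FALSE
  ))

  # planted enhancers
  n_enh_base <- sample(design$enhancers_per_gene[1]:design$enhancers_per_gene[2],
                       n, replace = TRUE)
  dense <- scope == design$dense_region
  n_enh <- ifelse(dense, pmin(n_enh_base * design$dense_enhancer_factor, 9L),
                  n_enh_base)
  occupied <- list()  # per chrom: matrix of (start, end) to avoid
  avoid <- rbind(
    data.frame(chrom = chrom, start = prom_start, end = prom_end),
    data.frame(chrom = chrom, start = body_start, end = body_end)
  )
  avoid_by_chrom <- split(avoid[c("start", "end")], avoid$chrom)
  taken_by_chrom <- split(peaks[c("start", "end")], peaks$chrom)

  clashes <- function(chr, s, e) {
    a <- avoid_by_chrom[[chr]]
    t <- taken_by_chrom[[chr]]
    (!is.null(a) && any(s < a$end & e > a$start)) ||
      (!is.null(t) && any(s < t$end & e > t$start))
  }

  enh_rows <- vector("list", n)
  for (g in seq_len(n)) {
    k <- n_enh[g]
    if (k == 0L) next
    got <- 0L
    rows <- data.frame()
    tries <- 0L
    while (got < k && tries < 200L) {
      tries <- tries + 1L
      off <- runif(1, 1e4, 2e5) * sample(c(-1, 1), 1)
      w <- sample(300:800, 1)
      s <- floor(tss[g] + off)
      e <- s + w
      if (s < 0 || e > design$chrom_length) next
      if (clashes(chrom[g], s, e)) next
      rows <- rbind(rows, data.frame(
        chrom = chrom[g], start = s, end = e,
        role = "enhancer", gene_id = gene_id[g], stringsAsFactors = FALSE
      ))
      taken_by_chrom[[chrom[g]]] <-
        rbind(taken_by_chrom[[chrom[g]]], data.frame(start = s, end = e))
      got <- got + 1L
    }
    enh_rows[[g]] <- rows
  }
  enh <- do.call(rbind, enh_rows)
  if (!is.null(enh) && nrow(enh)) peaks <- rbind(peaks, enh)

  # background intergenic peaks, clear of promoter windows and gene bodies
  bg <- data.frame()
  tries <- 0L
  while (nrow(bg) < design$n_background_peaks && tries < design$n_background_peaks * 20L) {
    tries <- tries + 1L
    chr <- sprintf("chr%d", sample.int(design$chrom_count, 1))
    w <- sample(300:800, 1)
    s <- floor(runif(1, 0, design$chrom_length - w))
    e <- s + w
    if (clashes(chr, s, e)) next
    bg <- rbind(bg, data.frame(chrom = chr, start = s, end = e,
                               role = "background", gene_id = NA_character_,
                               stringsAsFactors = FALSE))
    taken_by_chrom[[chr]] <- rbind(taken_by_chrom[[chr]],
                                   data.frame(start = s, end = e))
  }
  peaks <- rbind(peaks, bg)
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  peaks <- peaks[ord, , drop = FALSE]
  rownames(peaks) <- NULL

  gr <- granges0(peaks$chrom, peaks$start, peaks$end)
  S4Vectors::mcols(gr)$role <- peaks$role
  S4Vectors::mcols(gr)$gene_id <- peaks$gene_id

  true_links <- peaks[peaks$role == "enhancer",
                      c("gene_id", "chrom", "start", "end")]
  rownames(true_links) <- NULL

  # planted trend sets hold genes whose program is monotone in BOTH
  # modalities: with rna_lag = 1 a gene expressed in BP and N is already
  # accessible in AP (accessibility = expression shifted earlier), so its
  # accessibility trajectory is flat and it belongs to neither set
  const_prom <- runif(n) < design$promoter_constitutive_fraction

  early <- gene_id[profile %in% c("AP", "AP_BP")]
  late <- gene_id[profile %in% "N"]

  truth <- list(
    gene_program = program,
    true_links = true_links,
    planted_outliers = character(0),
    early_genes = early,
    late_genes = late,
    gene_profile = data.frame(gene_id = gene_id, profile = profile,
                              scope = scope,
                              constitutive_promoter = const_prom,
                              stringsAsFactors = FALSE)
  )
  list(annotation = annotation, peaks = gr, truth = truth)
}

#' Simulate cell-by-peak and cell-by-gene counts plus the cell table
#'
#' Per cell, a LogNormal depth factor d multiplies Poisson rates: peak
#' counts use the high rate when the peak's gene is accessibility-active in
#' the cell's (region, state) and the low rate otherwise (background peaks
#' use a constant moderate rate); RNA counts are keyed to expression
#' activity, which lags accessibility by `rna_lag` states. A fraction of
#' barcodes get an inflated depth factor (planted outliers). Pseudotime is
#' the state rank plus Uniform(0,1) jitter.
#'
#' @param genome result of [simulate_genome()]
#' @param design the [simulation_design()]
#' @param seed random seed (defaults to `design$seed + 1`)
#' @return list with `atac` (peak_matrix), `rna` (expression_matrix),
#'   `cells` (data.frame), and `truth` updated with planted outliers
#' @export
simulate_counts <- function(genome, design, seed = design$seed + 1L) {
  validate_design(design)
  if (design$cells_per_group < 1) stop("empty design group")
  set.seed(seed)
  peaks <- genome$peaks
  annotation <- genome$annotation
  program <- genome$truth$gene_program
  n_peaks <- length(peaks)
  role <- S4Vectors::mcols(peaks)$role
  pk_gene <- S4Vectors::mcols(peaks)$gene_id

  groups <- expand.grid(state = STATES, region = REGIONS,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  groups <- groups[order(match(groups$region, REGIONS),
                         match(groups$state, STATES)), ]
  rownames(groups) <- NULL
  n_groups <- nrow(groups)
  m <- design$cells_per_group
  n_cells <- n_groups * m

  barcode <- character(n_cells)
  region <- character(n_cells)
  state <- character(n_cells)
  cluster_id <- integer(n_cells)
  for (g in seq_len(n_groups)) {
    idx <- ((g - 1L) * m + 1L):(g * m)
    barcode[idx] <- sprintf("cell_%s_%s_%03d", groups$region[g],
                            groups$state[g], seq_len(m))
    region[idx] <- groups$region[g]
    state[idx] <- groups$state[g]
    cluster_id[idx] <- g
  }

  prof <- genome$truth$gene_profile
  const_prom <- setNames(prof$constitutive_promoter, prof$gene_id)

  mu <- design$depth_lognormal[[1]]
  sig <- design$depth_lognormal[[2]]
  d_atac <- rlnorm(n_cells, mu, sig)
  d_rna <- rlnorm(n_cells, mu, sig)
  n_out <- round(design$outlier_fraction * n_cells)
  outliers <- sort(sample.int(n_cells, n_out))
  d_atac[outliers] <- d_atac[outliers] *
    runif(n_out, design$outlier_depth_factor[1], design$outlier_depth_factor[2])

  # per-group accessibility rate vector over peaks
  acc_key <- paste(program$gene_id, program$region, program$state, sep = "|")
  acc_active <- setNames(program$acc_active, acc_key)
  expr_active <- setNames(program$expr_active, acc_key)
  acc_level <- setNames(program$acc_level, acc_key)
  expr_level <- setNames(program$expr_level, acc_key)

  gene_ids <- annotation$gene_id
  n_genes <- length(gene_ids)

  trip_i <- list(); trip_j <- list(); trip_x <- list()
  rtrip_i <- list(); rtrip_j <- list(); rtrip_x <- list()
  for (g in seq_len(n_groups)) {
    idx <- which(cluster_id == g)
    keyp <- paste(pk_gene, groups$region[g], groups$state[g], sep = "|")
    # promoters and enhancers open ahead of expression (regulatory lag);
    # first-exon accessibility is transcription-coupled, hence synchronous
    # with the expression program
    open <- !is.na(pk_gene) &
      ifelse(role == "exon1", expr_active[keyp], acc_active[keyp])
    lvl <- ifelse(role == "exon1", expr_level[keyp], acc_level[keyp])
    rate <- ifelse(role == "background", design$background_rate,
                   ifelse(open, design$open_rate_high * lvl,
                          design$open_rate_low))
    # CpG-island-like promoters: open at a fixed moderate rate everywhere
    rate[role == "promoter" & const_prom[pk_gene]] <-
      0.6 * design$open_rate_high
    lam <- outer(d_atac[idx], rate)
    cnt <- matrix(rpois(length(lam), lam), nrow = length(idx))
    nz <- which(cnt > 0, arr.ind = TRUE)
    trip_i[[g]] <- idx[nz[, 1]]
    trip_j[[g]] <- nz[, 2]
    trip_x[[g]] <- cnt[nz]

    keyg <- paste(gene_ids, groups$region[g], groups$state[g], sep = "|")
    on <- expr_active[keyg]
    rrate <- ifelse(on, design$expr_rate_high * expr_level[keyg],
                    design$expr_rate_low)
    rlam <- outer(d_rna[idx], rrate)
    rcnt <- matrix(rpois(length(rlam), rlam), nrow = length(idx))
    rnz <- which(rcnt > 0, arr.ind = TRUE)
    rtrip_i[[g]] <- idx[rnz[, 1]]
    rtrip_j[[g]] <- rnz[, 2]
    rtrip_x[[g]] <- rcnt[rnz]
  }

  counts <- Matrix::sparseMatrix(
    i = unlist(trip_i), j = unlist(trip_j), x = unlist(trip_x),
    dims = c(n_cells, n_peaks)
  )
  rna_counts <- Matrix::sparseMatrix(
    i = unlist(rtrip_i), j = unlist(rtrip_j), x = unlist(rtrip_x),
    dims = c(n_cells, n_genes)
  )

  atac <- peak_matrix(counts, barcode, peaks)
  rna <- expression_matrix(rna_counts, barcode, gene_ids)

  pseudotime <- (state_index(state) - 1) + runif(n_cells)
  total_counts <- Matrix::rowSums(counts)
  pw <- promoter_windows(annotation)
  in_prom <- IRanges::overlapsAny(peaks, pw, ignore.strand = TRUE)
  prom_counts <- Matrix::rowSums(counts[, in_prom, drop = FALSE])
  promoter_ratio <- ifelse(total_counts > 0, prom_counts / total_counts, 0)

  cells <- data.frame(
    barcode = barcode, region = region, state = state,
    cluster_id = cluster_id, pseudotime = pseudotime,
    total_counts = total_counts, promoter_ratio = promoter_ratio,
    total_rna = Matrix::rowSums(rna_counts),
    stringsAsFactors = FALSE
  )

  truth <- genome$truth
  truth$planted_outliers <- barcode[outliers]
  list(atac = atac, rna = rna, cells = cells, truth = truth)
}

#' Simulate region-matched histone-mark peak sets
#'
#' Per region: H3K4me3 at promoters of genes expressed in that region (any
#' state), H3K27me3 at promoters of genes silent there, H3K27ac at the true
#' enhancers of expressed genes, each enhancer dropped independently with
#' the design's false-negative rate. Histone peaks are slightly wider than
#' the ATAC elements they mark (promoters +/-300 bp, enhancers +/-200 bp).
#'
#' @param genome result of [simulate_genome()]
#' @param design the [simulation_design()]
#' @param seed random seed (defaults to `design$seed + 2`)
#' @return list of histone peak sets, each `list(mark, region, intervals)`
#' @export
simulate_histone_peaks <- function(genome, design, seed = design$seed + 2L) {
  set.seed(seed)
  annotation <- genome$annotation
  program <- genome$truth$gene_program
  links <- genome$truth$true_links
  peaks <- genome$peaks
  role <- S4Vectors::mcols(peaks)$role
  pk_gene <- S4Vectors::mcols(peaks)$gene_id
  prom_peaks <- peaks[role == "promoter"]
  prom_gene <- pk_gene[role == "promoter"]

  out <- list()
  for (r in REGIONS) {
    act <- program[program$region == r & program$expr_active, "gene_id"]
    act <- unique(act)
    inact <- setdiff(annotation$gene_id, act)

    k4 <- extend_and_merge(prom_peaks[prom_gene %in% act], flank = 300)
    k27me3 <- extend_and_merge(prom_peaks[prom_gene %in% inact], flank = 300)

    el <- links[links$gene_id %in% act, , drop = FALSE]
    if (nrow(el)) {
      keep <- rbinom(nrow(el), 1, 1 - design$h3k27ac_false_negative_rate) == 1
      el <- el[keep, , drop = FALSE]
    }
    k27ac <- if (nrow(el)) {
      extend_and_merge(granges0(el$chrom, el$start, el$end), flank = 200)
    } else {
      GenomicRanges::GRanges()
    }

    out <- c(out, list(
      list(mark = "H3K4me3", region = r, intervals = k4),
      list(mark = "H3K27me3", region = r, intervals = k27me3),
      list(mark = "H3K27ac", region = r, intervals = k27ac)
    ))
  }
  out
}

#' Run the full generator: genome, counts, cell table, histone sets
#'
#' @param design a [simulation_design()]
#' @param seed master seed; the three stages use `seed`, `seed + 1`,
#'   `seed + 2`
#' @return list with `annotation`, `peaks`, `atac`, `rna`, `cells`,
#'   `histone`, `truth`, `design`, `seed`
#' @export
simulate_multiome <- function(design = simulation_design(), seed = design$seed) {
  genome <- simulate_genome(design, seed = seed)
  cnt <- simulate_counts(genome, design, seed = seed + 1L)
  histone <- simulate_histone_peaks(genome, design, seed = seed + 2L)
  list(annotation = genome$annotation, peaks = genome$peaks,
       atac = cnt$atac, rna = cnt$rna, cells = cnt$cells,
       histone = histone, truth = cnt$truth, design = design, seed = seed)
}

#' True enhancer intervals per gene, as a named list of GRanges
#' @param truth the `truth` element of a simulation
#' @return named list gene_id -> GRanges of planted enhancers
#' @export
true_enhancer_map <- function(truth) {
  tl <- truth$true_links
  if (!nrow(tl)) return(list())
  sp <- split(tl, tl$gene_id)
  lapply(sp, function(df) granges0(df$chrom, df$start, df$end))
}

#' Write a simulated dataset to disk in the package's exchange formats
#'
#' Emits the Cellranger-like MatrixMarket triples for ATAC and RNA, the cell
#' table, per-region histone BED files, ground-truth TSVs and a YAML
#' manifest holding the design and seed, so a rerun with the same manifest
#' reproduces the files byte for byte.
#'
#' @param sim result of [simulate_multiome()]
#' @param dir output directory (created)
#' @return invisibly, `dir`
#' @export
write_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_mtx_triple(sim$atac$counts, sim$atac$barcodes, sim$atac$peaks,
                   file.path(dir, "atac"))
  write_mtx_triple(sim$rna$counts, sim$rna$barcodes, sim$rna$gene_ids,
                   file.path(dir, "rna"))
  write.table(sim$cells, file.path(dir, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(sim$annotation, file.path(dir, "annotation.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  gt_dir <- file.path(dir, "ground_truth")
  dir.create(gt_dir, showWarnings = FALSE)
  write.table(sim$truth$gene_program, file.path(gt_dir, "gene_program.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(sim$truth$true_links, file.path(gt_dir, "true_links.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$truth$planted_outliers, file.path(gt_dir, "outliers.tsv"))
  write.table(sim$truth$gene_profile, file.path(gt_dir, "gene_profile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  h_dir <- file.path(dir, "histone")
  dir.create(h_dir, showWarnings = FALSE)
  for (hs in sim$histone) {
    write_bed(hs$intervals,
              file.path(h_dir, sprintf("%s_%s.bed", hs$region, hs$mark)))
  }

  manifest <- c(sim$design, list(master_seed = sim$seed))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}
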