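# Shared fixtures, built once per test run and cached across test files.

.fixture_cache <- new.env(parent = emptyenv())

# Default-design simulation at a fixed seed; the study conditions every
# recovery test runs under.
default_sim <- function(seed = 1) {
  key <- paste0("sim", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- simulate_multiome(simulation_design(), seed = seed)
  }
  .fixture_cache[[key]]
}

# DA table for the default simulation (the most expensive single stage).
default_da <- function() {
  if (is.null(.fixture_cache$da)) {
    sim <- default_sim()
    .fixture_cache$da <- find_da_peaks(sim$atac, sim$cells)
  }
  .fixture_cache$da
}

# Full linking pipeline on the default design at one seed, cached.
pipeline_run <- function(seed) {
  key <- paste0("pipe", seed)
  if (is.null(.fixture_cache[[key]])) {
    sim <- default_sim(seed)
    links <- coaccessibility_scores(sim$atac, sim$cells)
    pairs <- predict_gene_peak_pairs(sim$rna, sim$atac, sim$annotation)
    .fixture_cache[[key]] <- list(sim = sim, links = links, pairs = pairs)
  }
  .fixture_cache[[key]]
}

# A small handmade genome: two genes on one chromosome, one on another.
toy_annotation <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(10000, 30000, 5000),
    exon1_start = c(10000, 29800, 5000),
    exon1_end = c(10300, 30001, 5200),
    body_start = c(10000, 25000, 5000),
    body_end = c(15000, 30001, 9000),
    stringsAsFactors = FALSE
  )
}

# Random 0-based intervals on a couple of chromosomes.
random_intervals <- function(n, max_pos = 100000, max_width = 500,
                             chroms = c("chr1", "chr2")) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# Brute-force: does interval i of A overlap (>=1 bp) any interval of B?
brute_overlaps_any <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    any(a$chrom[i] == b$chrom & a$start[i] < b$end & a$end[i] > b$start)
  }, logical(1))
}
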