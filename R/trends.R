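#' @importFrom stats approx cutree sd setNames
NULL

# Pseudotime-binned trend analysis of RNA / GAS / enhancer signal
# --------------------------------------------------------------------------

#' Assign cells to equal-width pseudotime bins
#'
#' Bins partition `[min, max]` into `n_bins` equal-width intervals,
#' left-closed (a value on an interior edge goes to the right bin); the
#' right edge of the last bin is inclusive.
#'
#' @param cells cell table with a `pseudotime` column (or a numeric vector)
#' @param n_bins number of bins (>= 2)
#' @return integer bin index in `1..n_bins` per cell
#' @export
bin_pseudotime <- function(cells, n_bins = 10) {
  v <- if (is.data.frame(cells)) cells$pseudotime else cells
  if (any(!is.finite(v))) stop("pseudotime must be finite")
  if (n_bins < 2) stop("need at least 2 bins")
  rng <- range(v)
  if (rng[1] == rng[2]) stop("all pseudotimes are equal; cannot bin")
  w <- (rng[2] - rng[1]) / n_bins
  pmin(floor((v - rng[1]) / w) + 1L, n_bins)
}

#' Per-gene z-scored trajectories over pseudotime bins
#'
#' Per gene: the mean signal of cells in each bin, then centred and scaled
#' across bins. Scaling uses the sample standard deviation (divisor n - 1,
#' the `scale()` convention); the population variant (divisor n) is
#' available. A constant trajectory gives an all-zero vector and is
#' flagged. Empty bins are filled by linear interpolation from
#' neighbouring bins (constant extension at the ends) and flagged.
#'
#' @param score a `score_matrix` (or `expression_matrix`)
#' @param cells cell table aligned with the score rows
#' @param bins bin index per cell from [bin_pseudotime()]
#' @param n_bins number of bins
#' @param sd_type `"sample"` (divisor n - 1) or `"population"` (divisor n)
#' @return list with `z` (gene x bin matrix), `constant_genes`,
#'   `interpolated_bins`
#' @export
zscore_trajectories <- function(score, cells, bins, n_bins = max(bins),
                                sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  values <- if (!is.null(score$values)) score$values else score$counts
  gene_ids <- if (!is.null(score$gene_ids)) score$gene_ids else colnames(values)
  stopifnot(nrow(values) == length(bins))

  G <- Matrix::sparseMatrix(i = seq_along(bins), j = bins, x = 1,
                            dims = c(length(bins), n_bins))
  occupancy <- Matrix::colSums(G)
  sums <- as.matrix(Matrix::t(G) %*% values)         # bin x gene
  means <- sums / ifelse(occupancy > 0, occupancy, NA)

  interpolated <- which(occupancy == 0)
  if (length(interpolated)) {
    filled <- seq_len(n_bins)[occupancy > 0]
    for (g in seq_len(ncol(means))) {
      means[interpolated, g] <- approx(filled, means[filled, g],
                                       xout = interpolated, rule = 2)$y
    }
  }

  center <- colMeans(means)
  dev <- sweep(means, 2, center)
  s <- if (sd_type == "population") {
    sqrt(colMeans(dev^2))
  } else {
    apply(means, 2, sd)
  }
  constant <- s == 0
  s[constant] <- 1
  z <- t(sweep(dev, 2, s, "/"))
  rownames(z) <- gene_ids
  colnames(z) <- paste0("bin", seq_len(n_bins))
  list(z = z, constant_genes = gene_ids[constant],
       interpolated_bins = interpolated)
}

#' Cluster concatenated RNA/GAS/enhancer trajectories into trend groups
#'
#' Per gene the three z-vectors are concatenated; agglomerative clustering
#' with correlation distance and average linkage is cut at the k (2..8)
#' maximising the mean silhouette width (ties to the smallest k). Groups
#' smaller than `min_group` are discarded to `"other"`. Each retained
#' group is labeled by its mean first-bin minus last-bin z (averaged over
#' modalities): falling by more than `label_margin` is `"early"`, rising
#' is `"late"`, otherwise `"transition"`.
#'
#' @param z_rna,z_gas,z_enh gene x bin z matrices (shared gene ids)
#' @param min_group minimum retained group size
#' @param k_range candidate numbers of groups
#' @param label_margin z-difference separating early/late from transition
#' @return data.frame with `gene_id`, `group` (integer, NA for other),
#'   `label`
#' @export
cluster_trajectories <- function(z_rna, z_gas, z_enh, min_group = 6,
                                 k_range = 2:8, label_margin = 0.5) {
  genes <- Reduce(intersect, list(rownames(z_rna), rownames(z_gas),
                                  rownames(z_enh)))
  concat <- cbind(z_rna[genes, , drop = FALSE],
                  z_gas[genes, , drop = FALSE],
                  z_enh[genes, , drop = FALSE])
  n <- length(genes)
  if (n < min_group) {
    return(data.frame(gene_id = genes, group = NA_integer_, label = "other",
                      stringsAsFactors = FALSE))
  }
  d <- correlation_distance(concat)
  hc <- hclust(as.dist(d), method = "average")

  best_k <- NA_integer_
  best_sil <- -Inf
  for (k in k_range) {
    if (k >= n) break
    ct <- cutree(hc, k = k)
    if (length(unique(ct)) < 2L) next
    sil <- cluster::silhouette(ct, dmatrix = d)
    ms <- mean(sil[, "sil_width"])
    if (ms > best_sil + 1e-12) {  # strict improvement: ties keep smaller k
      best_sil <- ms
      best_k <- k
    }
  }
  ct <- cutree(hc, k = best_k)

  n_bins <- ncol(z_rna)
  first_cols <- c(1, n_bins + 1, 2 * n_bins + 1)
  last_cols <- c(n_bins, 2 * n_bins, 3 * n_bins)
  label <- character(n)
  group <- rep(NA_integer_, n)
  for (g in unique(ct)) {
    members <- which(ct == g)
    if (length(members) < min_group) {
      label[members] <- "other"
      next
    }
    fall <- mean(concat[members, first_cols, drop = FALSE]) -
      mean(concat[members, last_cols, drop = FALSE])
    label[members] <- if (fall > label_margin) "early"
      else if (fall < -label_margin) "late" else "transition"
    group[members] <- g
  }
  data.frame(gene_id = genes, group = group, label = label,
             stringsAsFactors = FALSE)
}

#' Shared gene ordering for matched RNA/GAS/enhancer heatmaps
#'
#' One dendrogram is built from the concatenated z matrices (correlation
#' distance, average linkage) and its leaf order is applied to all three
#' modalities, so the matched heatmaps stay row-aligned.
#'
#' @param z_rna,z_gas,z_enh gene x bin z matrices
#' @return list with `order` (gene ids in leaf order) and the `hclust` tree
#' @export
matched_heatmap_order <- function(z_rna, z_gas, z_enh) {
  genes <- Reduce(intersect, list(rownames(z_rna), rownames(z_gas),
                                  rownames(z_enh)))
  concat <- cbind(z_rna[genes, , drop = FALSE],
                  z_gas[genes, , drop = FALSE],
                  z_enh[genes, , drop = FALSE])
  d <- correlation_distance(concat)
  hc <- hclust(as.dist(d), method = "average")
  list(order = genes[hc$order], tree = hc)
}

#' Differentially expressed genes between two maturation states
#'
#' One-vs-one logistic likelihood-ratio test (state identity predicted by
#' normalised expression, log RNA depth as covariate) for each gene, over
#' the cells of the two states only; BH adjustment across genes. The fold
#' change is the mean log1p-normalised expression in `to` minus `from`, so
#' positive values mean up-regulation along the transition.
#'
#' Genes whose absolute fold change is below `min_lfc` are not tested
#' (`p_value`/`adj_p` are NA): per-cell scaling induces small spurious
#' shifts in silent genes when the two states express different numbers of
#' genes (composition bias), and the fold-change floor — the standard
#' default of single-cell marker detection — excludes them before testing.
#'
#' @param expression an `expression_matrix`
#' @param cells cell table with `state`
#' @param from,to state labels (e.g. "AP", "BP")
#' @param min_lfc minimum absolute log fold change for a gene to be tested
#' @return data.frame with `gene_id`, `avg_log_fc`, `p_value`, `adj_p`
#' @export
find_state_degs <- function(expression, cells, from, to, min_lfc = 0.25) {
  stopifnot(identical(expression$barcodes, cells$barcode))
  sel <- cells$state %in% c(from, to)
  if (!any(cells$state == from) || !any(cells$state == to)) {
    stop("both states must be present")
  }
  counts <- expression$counts[sel, , drop = FALSE]
  xnorm <- normalize_log1p(counts)
  y <- as.numeric(cells$state[sel] == to)
  log_depth <- log(pmax(Matrix::rowSums(counts), 1))

  n_genes <- ncol(counts)
  p <- rep(NA_real_, n_genes)
  lfc <- numeric(n_genes)
  for (j in seq_len(n_genes)) {
    x <- as.numeric(xnorm[, j])
    lfc[j] <- mean(x[y == 1]) - mean(x[y == 0])
    if (abs(lfc[j]) < min_lfc) next
    p[j] <- if (var(x) == 0) 1 else
      lr_test_peak(y, x, covariate = log_depth)$p_value
  }
  data.frame(gene_id = expression$gene_ids, avg_log_fc = lfc, p_value = p,
             adj_p = p.adjust(p, method = "BH"), stringsAsFactors = FALSE)
}

#' Count enhancers activated and decommissioned across maturation transitions
#'
#' Per transition, an enhancer counts as activated when linked to at least
#' one significantly up-regulated gene (`adj_p <= alpha`, positive fold
#' change) and as decommissioned when linked to a down-regulated gene; an
#' enhancer linked to both counts in both tallies, and each distinct
#' enhancer interval counts once per tally.
#'
#' @param deg_tables named list of DEG tables (one per transition, from
#'   [find_state_degs()]); names like `"AP->BP"`
#' @param enhancer_links data.frame linking genes to enhancer intervals
#'   (`gene_id`, `chrom`, `start`, `end`)
#' @param alpha DEG significance threshold
#' @return data.frame with `transition`, `n_activated`, `n_decommissioned`,
#'   `ratio` (Inf, flagged by `ratio_defined = FALSE`, when nothing is
#'   decommissioned)
#' @export
count_enhancer_transitions <- function(deg_tables, enhancer_links,
                                       alpha = 0.05) {
  key <- paste0(enhancer_links$chrom, ":", enhancer_links$start, "-",
                enhancer_links$end)
  rows <- lapply(names(deg_tables), function(tr) {
    deg <- deg_tables[[tr]]
    sig <- !is.na(deg$adj_p) & deg$adj_p <= alpha
    up <- deg$gene_id[sig & deg$avg_log_fc > 0]
    down <- deg$gene_id[sig & deg$avg_log_fc < 0]
    n_act <- length(unique(key[enhancer_links$gene_id %in% up]))
    n_dec <- length(unique(key[enhancer_links$gene_id %in% down]))
    data.frame(
      transition = tr, n_activated = n_act, n_decommissioned = n_dec,
      ratio = if (n_dec > 0) n_act / n_dec else Inf,
      ratio_defined = n_dec > 0,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
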