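#' @importFrom stats pchisq p.adjust cor as.dist hclust median var glm.fit
#'   binomial
NULL

# -- logistic likelihood-ratio machinery ------------------------------------

binomial_loglik <- function(y, p) {
  eps <- 1e-12
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Ridge-stabilised logistic fit: Newton iterations on the penalised
# log-likelihood with an L2 penalty on slope coefficients only. Gives
# bounded, deterministic estimates on separating or degenerate inputs.
ridge_logistic <- function(X, y, lambda = 1e-4, max_iter = 100, tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(lambda, p)
  pen[1] <- 0  # intercept unpenalised
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    grad <- drop(crossprod(X, y - mu)) - pen * beta
    hess <- crossprod(X * w, X) + diag(pen + 1e-12, p)
    step <- tryCatch(solve(hess, grad), error = function(e) rep(0, p))
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  list(coefficients = beta,
       loglik = binomial_loglik(y, 1 / (1 + exp(-drop(X %*% beta)))))
}

fit_logistic <- function(X, y, lambda = 1e-4) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  separated <- any(mu < 1e-10 | mu > 1 - 1e-10) ||
    !fit$converged || any(abs(fit$coefficients) > 30, na.rm = TRUE) ||
    anyNA(fit$coefficients)
  if (separated) {
    r <- ridge_logistic(X, y, lambda = lambda)
    list(loglik = r$loglik, coefficients = r$coefficients, ridge = TRUE)
  } else {
    list(loglik = binomial_loglik(y, mu), coefficients = fit$coefficients,
         ridge = FALSE)
  }
}

#' Logistic likelihood-ratio test for one peak
#'
#' Fits `y ~ 1 + x + covariate` against the null `y ~ 1 + covariate` by
#' maximum likelihood (`y` the in-cluster indicator, `x` the normalised
#' peak signal, the covariate typically log total counts, conditioning the
#' test on sequencing depth). The statistic is twice the log-likelihood
#' difference, referred to a chi-square with 1 df. Non-convergent or
#' perfectly separating fits are refit with a small L2 penalty (1e-4) on
#' the slopes and flagged.
#'
#' @param y binary response (two classes required)
#' @param x numeric predictor; a constant `x` gives statistic 0, p = 1
#' @param covariate optional numeric nuisance covariate
#' @param ridge_lambda penalty used by the stabilised fallback fit
#' @return list with `statistic`, `p_value`, `slope` (coefficient of `x`)
#'   and `ridge` (logical flag)
#' @export
lr_test_peak <- function(y, x, covariate = NULL, ridge_lambda = 1e-4) {
  y <- as.numeric(y)
  if (length(unique(y)) < 2L) stop("response has a single class")
  if (any(!is.finite(x))) stop("non-finite values in x")
  if (var(x) == 0) {
    return(list(statistic = 0, p_value = 1, slope = 0, ridge = FALSE))
  }
  X_null <- if (is.null(covariate)) cbind(1, numeric(length(y)))[, 1, drop = FALSE] else
    cbind(1, covariate)
  X_full <- cbind(X_null, x)
  f_null <- fit_logistic(X_null, y, lambda = ridge_lambda)
  f_full <- fit_logistic(X_full, y, lambda = ridge_lambda)
  if (f_full$ridge && !f_null$ridge) {
    # compare like with like so the statistic stays nonnegative
    f_null <- fit_logistic(X_null, y, lambda = ridge_lambda)
  }
  stat <- max(0, 2 * (f_full$loglik - f_null$loglik))
  list(
    statistic = stat,
    p_value = pchisq(stat, df = 1, lower.tail = FALSE),
    slope = unname(f_full$coefficients[length(f_full$coefficients)]),
    ridge = f_full$ridge || f_null$ridge
  )
}

# -- normalisation ----------------------------------------------------------

#' Depth-normalised log1p signal matrix
#'
#' Scales each cell to the median total count, then applies log1p. Sparsity
#' is preserved (zeros map to zero).
#'
#' @param counts sparse cells x features count matrix
#' @return sparse matrix of log1p normalised signal
#' @export
normalize_log1p <- function(counts) {
  counts <- methods::as(methods::as(counts, "CsparseMatrix"), "generalMatrix")
  depth <- Matrix::rowSums(counts)
  nf <- ifelse(depth > 0, median(depth[depth > 0]) / depth, 0)
  out <- counts
  if (length(out@x)) {
    # dgCMatrix stores by column; @i holds 0-based row indices
    out@x <- log1p(out@x * nf[out@i + 1L])
  }
  out
}

# -- one-vs-rest DA calling -------------------------------------------------

#' Differentially accessible peaks per cluster
#'
#' One-vs-rest logistic LR test per (cluster, peak) with log total counts
#' as covariate. A peak is tested for a cluster only when
#' `max(pct_in, pct_out) >= min_pct`; `avg_log_fc` is the difference of
#' mean log1p depth-normalised signal in vs out of the cluster. P-values
#' are Benjamini-Hochberg adjusted within each cluster; DA calls satisfy
#' `adj_p <= alpha` and `avg_log_fc > 0`.
#'
#' @param matrix a `peak_matrix`
#' @param cells cell table with `barcode` and `cluster_id`
#' @param min_pct detection-fraction floor for testing a peak
#' @param alpha FDR threshold for the DA call
#' @return data.frame of all tested (cluster, peak) pairs with `peak_id`
#'   (column index), coordinates, `avg_log_fc`, `pct_in`, `pct_out`,
#'   `p_value`, `adj_p`, `ridge` and the logical `is_da`
#' @export
find_da_peaks <- function(matrix, cells, min_pct = 0.2, alpha = 0.05) {
  stopifnot(identical(matrix$barcodes, cells$barcode))
  clusters <- sort(unique(cells$cluster_id))
  if (length(clusters) < 2L) stop("need at least 2 clusters")
  counts <- matrix$counts
  depth <- Matrix::rowSums(counts)
  if (any(tabulate(match(cells$cluster_id, clusters)) == 0L)) {
    stop("empty cluster")
  }
  xnorm <- normalize_log1p(counts)
  log_depth <- log(pmax(depth, 1))
  detected <- counts
  detected@x <- rep(1, length(detected@x))

  # per-cluster detection fractions and mean normalised signal
  cl_index <- match(cells$cluster_id, clusters)
  n_cl <- length(clusters)
  G <- Matrix::sparseMatrix(i = seq_len(nrow(counts)), j = cl_index, x = 1,
                            dims = c(nrow(counts), n_cl))
  sizes <- Matrix::colSums(G)
  det_sum <- as.matrix(Matrix::t(G) %*% detected)    # cluster x peak
  sig_sum <- as.matrix(Matrix::t(G) %*% xnorm)
  pct <- det_sum / sizes
  mean_sig <- sig_sum / sizes
  tot_det <- colSums(det_sum)
  tot_sig <- colSums(sig_sum)
  n_cells <- nrow(counts)

  res <- vector("list", n_cl)
  bed <- granges_to_bed(matrix$peaks)
  for (ci in seq_len(n_cl)) {
    pct_in <- pct[ci, ]
    pct_out <- (tot_det - det_sum[ci, ]) / (n_cells - sizes[ci])
    lfc <- mean_sig[ci, ] - (tot_sig - sig_sum[ci, ]) / (n_cells - sizes[ci])
    test_idx <- which(pmax(pct_in, pct_out) >= min_pct)
    if (!length(test_idx)) next
    y <- as.numeric(cl_index == ci)
    pvals <- numeric(length(test_idx))
    stats_ <- numeric(length(test_idx))
    ridge <- logical(length(test_idx))
    for (k in seq_along(test_idx)) {
      j <- test_idx[k]
      t <- lr_test_peak(y, as.numeric(xnorm[, j]), covariate = log_depth)
      pvals[k] <- t$p_value
      stats_[k] <- t$statistic
      ridge[k] <- t$ridge
    }
    adj <- p.adjust(pvals, method = "BH")
    res[[ci]] <- data.frame(
      peak_id = test_idx,
      chrom = bed$chrom[test_idx], start = bed$start[test_idx],
      end = bed$end[test_idx],
      cluster_id = clusters[ci],
      avg_log_fc = lfc[test_idx],
      pct_in = pct_in[test_idx], pct_out = pct_out[test_idx],
      statistic = stats_, p_value = pvals, adj_p = adj, ridge = ridge,
      is_da = adj <= alpha & lfc[test_idx] > 0,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Cross-cluster DA-peak overlap matrix
#'
#' `percent[d, c]` is the percentage of cluster `c`'s DA peaks that have at
#' least one read among the cells of cluster `d` (cluster-pooled counts, no
#' minimum read threshold). Columns are the DA-owning clusters, rows the
#' clusters the peaks are re-detected in; the diagonal is 100 whenever the
#' cluster has any DA peak. Clusters without DA peaks give an NA column.
#'
#' @param da data.frame from [find_da_peaks()] (only `is_da` rows are used)
#' @param matrix a `peak_matrix`
#' @param cells cell table
#' @return list with `percent` (cluster x cluster matrix) and `peak_counts`
#' @export
overlap_matrix <- function(da, matrix, cells) {
  stopifnot(identical(matrix$barcodes, cells$barcode))
  da <- da[da$is_da, , drop = FALSE]
  clusters <- sort(unique(cells$cluster_id))
  n_cl <- length(clusters)
  pooled <- pooled_cluster_counts(matrix, cells, clusters)
  percent <- matrix(NA_real_, n_cl, n_cl,
                    dimnames = list(as.character(clusters), as.character(clusters)))
  peak_counts <- setNames(integer(n_cl), as.character(clusters))
  for (ci in seq_len(n_cl)) {
    pk <- da$peak_id[da$cluster_id == clusters[ci]]
    peak_counts[ci] <- length(pk)
    if (!length(pk)) next
    sub <- pooled[, pk, drop = FALSE] > 0
    percent[, ci] <- 100 * rowMeans(sub)
  }
  list(percent = percent, peak_counts = peak_counts)
}

pooled_cluster_counts <- function(matrix, cells, clusters = sort(unique(cells$cluster_id))) {
  cl_index <- match(cells$cluster_id, clusters)
  G <- Matrix::sparseMatrix(i = seq_len(nrow(matrix$counts)), j = cl_index,
                            x = 1, dims = c(nrow(matrix$counts), length(clusters)))
  out <- as.matrix(Matrix::t(G) %*% matrix$counts)
  rownames(out) <- as.character(clusters)
  out
}

#' Hierarchically cluster DA-overlap profiles
#'
#' Each cluster's profile is its column of the percent matrix (how its DA
#' peaks are re-detected across clusters). Distance is 1 - Pearson
#' correlation; linkage is average (UPGMA). Zero-variance profiles get the
#' maximal distance 2 to all others; NA profiles (clusters without DA
#' peaks) are dropped with a message.
#'
#' @param om result of [overlap_matrix()]
#' @return an `hclust` object (leaf labels are cluster ids)
#' @export
cluster_overlap_profiles <- function(om) {
  prof <- t(om$percent)  # rows: DA-owning clusters
  ok <- !apply(prof, 1, function(r) anyNA(r))
  if (sum(ok) < 3L) stop("need at least 3 clusters with DA-peak profiles")
  if (any(!ok)) {
    message("dropping clusters without DA peaks: ",
            paste(rownames(prof)[!ok], collapse = ", "))
  }
  prof <- prof[ok, , drop = FALSE]
  d <- correlation_distance(prof)
  hclust(as.dist(d), method = "average")
}

# 1 - Pearson correlation between rows; zero-variance rows get distance 2
correlation_distance <- function(m) {
  v <- apply(m, 1, var)
  d <- matrix(2, nrow(m), nrow(m), dimnames = list(rownames(m), rownames(m)))
  ok <- v > 0
  if (sum(ok) >= 2) {
    d[ok, ok] <- 1 - cor(t(m[ok, , drop = FALSE]))
  }
  diag(d) <- 0
  d
}

#' Binarised cluster-level peak signal
#'
#' Entry (cluster, peak) is 1 iff the cluster's pooled count at the peak is
#' positive ("open" vs "closed").
#'
#' @param matrix a `peak_matrix`
#' @param cells cell table
#' @param da optional [find_da_peaks()] table; if given, only DA peaks
#'   (columns) are returned
#' @return binary cluster x peak matrix
#' @export
binarize_by_cluster <- function(matrix, cells, da = NULL) {
  pooled <- pooled_cluster_counts(matrix, cells)
  out <- (pooled > 0) * 1L
  if (!is.null(da)) {
    keep <- sort(unique(da$peak_id[da$is_da]))
    out <- out[, keep, drop = FALSE]
  }
  out
}
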