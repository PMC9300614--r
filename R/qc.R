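#' @importFrom stats quantile
NULL

#' Tukey far-out fences
#'
#' Computes `[Q1 - k (Q3 - Q1), Q3 + k (Q3 - Q1)]` with `k = 3` (the
#' "far out" multiplier). Quartiles use the linear-interpolation definition
#' (R quantile type 7) by default; the type is recorded in the result so a
#' removal report states the convention used.
#'
#' @param values numeric vector, at least 4 finite values
#' @param k fence multiplier
#' @param quantile_type quantile algorithm passed to [stats::quantile()]
#' @return list with `lower`, `upper`, `q1`, `q3`, `k`, `quantile_type`
#' @export
tukey_fences <- function(values, k = 3, quantile_type = 7) {
  if (length(values) < 4L) stop("need at least 4 values for fences")
  if (any(!is.finite(values))) stop("non-finite values in fence input")
  q <- quantile(values, c(0.25, 0.75), type = quantile_type, names = FALSE)
  iqr <- q[2] - q[1]
  list(lower = q[1] - k * iqr, upper = q[2] + k * iqr,
       q1 = q[1], q3 = q[2], k = k, quantile_type = quantile_type)
}

#' Remove barcodes with any outlying QC metric
#'
#' Fences are computed once per metric on the full input (a single pass,
#' never recomputed on the filtered set); a barcode is removed iff any
#' listed metric falls strictly outside its fences — boundary values are
#' kept.
#'
#' @param cells cell table (data.frame with a `barcode` column)
#' @param metric_names character vector of metric columns to screen
#' @param k fence multiplier
#' @param quantile_type quartile convention, see [tukey_fences()]
#' @return list with `kept` (barcodes), `report` (one row per violation:
#'   barcode, metric, value, fence bound violated), and `fences` per metric
#' @export
filter_barcodes <- function(cells, metric_names, k = 3, quantile_type = 7) {
  missing <- setdiff(metric_names, names(cells))
  if (length(missing)) {
    stop("unknown metric: ", paste(missing, collapse = ", "))
  }
  fences <- lapply(metric_names, function(m) {
    tukey_fences(cells[[m]], k = k, quantile_type = quantile_type)
  })
  names(fences) <- metric_names

  viol <- list()
  out <- rep(FALSE, nrow(cells))
  for (m in metric_names) {
    f <- fences[[m]]
    v <- cells[[m]]
    low <- v < f$lower
    high <- v > f$upper
    bad <- low | high
    out <- out | bad
    if (any(bad)) {
      viol[[m]] <- data.frame(
        barcode = cells$barcode[bad], metric = m, value = v[bad],
        bound = ifelse(low[bad], "lower", "upper"),
        fence = ifelse(low[bad], f$lower, f$upper),
        stringsAsFactors = FALSE
      )
    }
  }
  report <- if (length(viol)) do.call(rbind, viol) else
    data.frame(barcode = character(0), metric = character(0),
               value = numeric(0), bound = character(0), fence = numeric(0))
  rownames(report) <- NULL
  list(kept = cells$barcode[!out], report = report, fences = fences)
}

#' Fixed-range barcode filter on library size and promoter ratio
#'
#' Keeps barcodes with `log10(total counts)` and promoter ratio inside the
#' given closed ranges (defaults: log10(UMI) in \[3, 6\], promoter ratio in
#' \[0.05, 0.6\]). Suited to genome-wide libraries; a restricted peak panel
#' will have smaller totals.
#'
#' @param cells cell table with the named columns
#' @param log10_umi_range closed range for log10 of total counts
#' @param promoter_ratio_range closed range for the promoter read fraction
#' @param total_col,ratio_col column names holding the two statistics
#' @return character vector of kept barcodes
#' @export
range_filter <- function(cells, log10_umi_range = c(3, 6),
                         promoter_ratio_range = c(0.05, 0.6),
                         total_col = "total_counts",
                         ratio_col = "promoter_ratio") {
  tot <- cells[[total_col]]
  if (any(tot <= 0)) stop("total counts must be positive for range_filter")
  lu <- log10(tot)
  pr <- cells[[ratio_col]]
  keep <- lu >= log10_umi_range[1] & lu <= log10_umi_range[2] &
    pr >= promoter_ratio_range[1] & pr <= promoter_ratio_range[2]
  cells$barcode[keep]
}
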