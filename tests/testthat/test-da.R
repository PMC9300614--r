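test_that("the LR statistic degenerates correctly and handles separation", {
  set.seed(5)
  y <- rep(c(0, 1), each = 20)
  expect_equal(lr_test_peak(y, rep(2, 40)),
               list(statistic = 0, p_value = 1, slope = 0, ridge = FALSE))
  expect_error(lr_test_peak(rep(1, 10), rnorm(10)), "single class")

  # perfect separation: finite statistic via the ridge-stabilised refit,
  # checked against a direct penalised-likelihood optimiser
  ys <- c(0, 0, 0, 0, 0, 1, 1, 1, 1, 1)
  xs <- c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14)
  t <- lr_test_peak(ys, xs)
  expect_true(t$ridge)
  expect_true(is.finite(t$statistic))
  # with 10 balanced cells the LR statistic is bounded by 2 * 10 * log(2),
  # so the smallest attainable chi-square p is ~2e-4
  expect_lt(t$p_value, 1e-3)

  pen_ll <- function(beta, X, y, lambda = 1e-4) {
    eta <- drop(X %*% beta)
    sum(y * eta - log1p(exp(eta))) - 0.5 * lambda * sum(beta[-1]^2)
  }
  X <- cbind(1, xs)
  opt <- optim(c(0, 0), function(b) -pen_ll(b, X, ys), method = "BFGS")
  opt0 <- optim(0, function(b) -pen_ll(b, cbind(1, numeric(10))[, 1, drop = FALSE], ys),
                method = "BFGS")
  # compare the unpenalised log-likelihood difference implied by the fits
  expect_equal(t$statistic, 2 * (pen_ll(opt$par, X, ys, 0) -
                                   pen_ll(c(opt0$par, 0), X, ys, 0)),
               tolerance = 1e-3)
})

test_that("find_da_peaks recovers a planted marker and applies the filters", {
  set.seed(21)
  n_per <- 60
  cells <- data.frame(
    barcode = sprintf("bc%03d", 1:(3 * n_per)),
    cluster_id = rep(1:3, each = n_per),
    stringsAsFactors = FALSE
  )
  # peak 1: marker of cluster 1; peak 2: rare everywhere (below min_pct);
  # peak 3: anti-marker of cluster 1 (negative fold change);
  # peak 4: uniform noise
  p1 <- c(rpois(n_per, 3), rpois(2 * n_per, 0.05))
  p2 <- rbinom(3 * n_per, 1, 0.08)
  p3 <- c(rpois(n_per, 0.05), rpois(2 * n_per, 3))
  p4 <- rpois(3 * n_per, 1)
  pm <- peak_matrix(
    Matrix::Matrix(cbind(p1, p2, p3, p4), sparse = TRUE), cells$barcode,
    granges0(rep("chr1", 4), c(0, 1000, 2000, 3000), c(500, 1500, 2500, 3500))
  )
  da <- find_da_peaks(pm, cells)
  calls1 <- da[da$cluster_id == 1 & da$is_da, ]
  expect_true(1 %in% calls1$peak_id)
  expect_false(2 %in% da$peak_id[da$cluster_id == 1])  # never tested
  # peak 3 in cluster 1: significant but negative fold change -> not DA
  row3 <- da[da$cluster_id == 1 & da$peak_id == 3, ]
  expect_true(nrow(row3) == 1 && !row3$is_da && row3$avg_log_fc < 0)
  expect_true(all(da$adj_p >= da$p_value - 1e-12))

  expect_error(find_da_peaks(pm, transform(cells, cluster_id = 1)), "2 clusters")
})

test_that("overlap_matrix equals a brute-force recount and has a 100 diagonal", {
  sim <- default_sim()
  da <- default_da()
  om <- overlap_matrix(da, sim$atac, sim$cells)
  expect_true(all(diag(om$percent)[om$peak_counts > 0] == 100))
  expect_true(all(om$percent >= 0 & om$percent <= 100, na.rm = TRUE))

  # brute-force re-count for a couple of cluster pairs
  calls <- da[da$is_da, ]
  counts <- as.matrix(sim$atac$counts)
  for (c_own in c(1, 7)) {
    pks <- calls$peak_id[calls$cluster_id == c_own]
    for (d_in in c(2, 12)) {
      cells_d <- which(sim$cells$cluster_id == d_in)
      brute <- 100 * mean(vapply(pks, function(j) sum(counts[cells_d, j]) > 0,
                                 logical(1)))
      expect_equal(om$percent[as.character(d_in), as.character(c_own)], brute)
    }
  }
})

test_that("DA burden decreases from progenitors to neurons", {
  sim <- default_sim()
  da <- default_da()
  calls <- da[da$is_da, ]
  grp <- expand.grid(state = c("AP", "BP", "N"),
                     region = c("MGE", "LGE", "CGE", "CTX"),
                     stringsAsFactors = FALSE)
  grp <- grp[order(match(grp$region, c("MGE", "LGE", "CGE", "CTX")),
                   match(grp$state, c("AP", "BP", "N"))), ]
  st <- grp$state[calls$cluster_id]
  mean_per_state <- tapply(rep(1, nrow(calls)), st, sum) / 4
  expect_gt(mean_per_state["AP"], mean_per_state["BP"])
  expect_gt(mean_per_state["BP"], mean_per_state["N"])
})

test_that("overlap profiles cluster by correlation distance, average linkage", {
  om <- list(percent = matrix(0, 3, 3), peak_counts = c(a = 2, b = 2, c = 2))
  # identical profiles merge at height 0
  prof <- rbind(c(100, 80, 10), c(100, 80, 10), c(10, 20, 100))
  om$percent <- t(prof)
  dimnames(om$percent) <- list(1:3, 1:3)
  hc <- cluster_overlap_profiles(om)
  expect_equal(hc$height[1], 0)

  # A,B strongly correlated, C anti-correlated: (A,B) merge before C joins
  profs <- rbind(A = c(1, 2, 3, 4), B = c(1.1, 2, 3.2, 4), C = c(4, 3, 2, 1))
  d <- 1 - cor(t(profs))
  hand <- hclust(as.dist(d), method = "average")
  om2 <- list(percent = t(profs), peak_counts = c(1, 1, 1))
  hc2 <- cluster_overlap_profiles(om2)
  expect_equal(hc2$merge, hand$merge)
  expect_equal(hc2$height, hand$height)
  expect_equal(hc2$merge[1, ], c(-1, -2))  # A and B first
})

test_that("binarised cluster signal is 1 exactly where pooled counts exist", {
  cells <- data.frame(barcode = sprintf("b%d", 1:6),
                      cluster_id = rep(1:3, each = 2))
  counts <- rbind(c(0, 2), c(0, 1), c(0, 0), c(0, 0), c(3, 0), c(0, 0))
  pm <- peak_matrix(Matrix::Matrix(counts, sparse = TRUE), cells$barcode,
                    granges0(c("chr1", "chr1"), c(0, 100), c(50, 150)))
  b <- binarize_by_cluster(pm, cells)
  expect_equal(unname(b), rbind(c(0, 1), c(0, 0), c(1, 0)))
})
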