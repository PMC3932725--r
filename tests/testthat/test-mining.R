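toy_table <- function(x, ids = sprintf("r%02d", seq_len(nrow(x)))) {
  rownames(x) <- ids
  x
}

test_that("rank transform uses ascending average ranks and conserves rank sums", {
  m <- toy_table(cbind(a = c(0.3, 0.1, 0.2), b = c(0.5, 0.5, 0.1)))
  r <- rank_transform(m)
  expect_equal(unname(r[, "a"]), c(3, 1, 2))
  expect_equal(unname(r[, "b"]), c(2.5, 2.5, 1))
  set.seed(9)
  for (k in 1:20) {
    n <- sample(3:40, 1)
    x <- toy_table(cbind(a = sample(1:5, n, TRUE), b = runif(n)))
    rr <- rank_transform(x)
    expect_equal(colSums(rr), c(a = n * (n + 1) / 2, b = n * (n + 1) / 2))
  }
})

test_that("missing-cell policies drop or impute as documented", {
  m <- toy_table(cbind(a = c(0.1, NA, 0.3, 0.4), b = c(1, 2, 3, 4)))
  dropped <- rank_transform(m, "drop_row")
  expect_equal(nrow(dropped), 3)
  expect_equal(attr(dropped, "dropped_rows"), "r02")
  imput <- rank_transform(m, "column_mean_rank")
  expect_equal(nrow(imput), 4)
  expect_equal(unname(imput["r02", "a"]), 2)  # (3 + 1) / 2 over observed
  expect_error(rank_transform(toy_table(cbind(a = c(NA, NA, NA), b = 1:3))),
               "a")
})

test_that("Spearman matrix matches hand values and the brute-force oracle", {
  m <- toy_table(cbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1)))
  rho <- spearman_matrix(m)
  expect_equal(rho["a", "a"], 1)
  expect_equal(rho["a", "b"], 0.8)
  expect_equal(rho["a", "c"], -1)
  expect_true(isSymmetric(rho))
  set.seed(13)
  for (k in 1:30) {
    n <- sample(3:6, 1); p <- sample(2:3, 1)
    x <- toy_table(matrix(sample(1:4, n * p, TRUE), n, p,
                          dimnames = list(NULL, letters[1:p])))
    if (any(apply(x, 2, function(col) length(unique(col)) == 1))) next
    rho <- spearman_matrix(x)
    for (i in 1:(p - 1)) for (j in (i + 1):p)
      expect_equal(rho[i, j], oracle_spearman(x[, i], x[, j]),
                   tolerance = 1e-12)
  }
})

test_that("constant columns are flagged undefined", {
  m <- toy_table(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  rho <- spearman_matrix(m)
  expect_equal(attr(rho, "undefined"), "b")
  expect_true(is.na(rho["a", "b"]))
  expect_error(robust_pca(m), "constant column")
  expect_error(cluster_metrics(rho), "b")
})

test_that("robust PCA recovers duplicated-column structure", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  m <- toy_table(cbind(a = v, b = v))
  p <- robust_pca(m)
  expect_equal(p$eigenvalues, c(2, 0), tolerance = 1e-9)
  m3 <- toy_table(cbind(a = v, b = 2 * v + 1, c = exp(v)))
  p3 <- robust_pca(m3)  # all three are increasing transforms of v
  expect_equal(p3$eigenvalues, c(3, 0, 0), tolerance = 1e-9)
  expect_true(all(abs(colSums(p3$loadings^2) - 1) < 1e-9))
})

test_that("rank-covariance and Spearman-correlation routes coincide on tie-free tables", {
  set.seed(21)
  for (k in 1:10) {
    n <- sample(8:20, 1); p <- sample(3:5, 1)
    x <- toy_table(matrix(rnorm(n * p), n, p,
                          dimnames = list(NULL, letters[1:p])))
    r <- rank_transform(x)
    rho <- spearman_matrix(x)
    centered <- scale(r, center = TRUE, scale = FALSE)
    cov_pop <- crossprod(centered) / n
    # identical population variance (n^2 - 1)/12 in every tie-free column
    expect_equal(cov_pop, (n^2 - 1) / 12 * rho, tolerance = 1e-9,
                 ignore_attr = TRUE)
    ev_cov <- eigen(cov_pop, symmetric = TRUE)
    ev_rho <- eigen(rho, symmetric = TRUE)
    expect_equal(ev_cov$values, (n^2 - 1) / 12 * ev_rho$values,
                 tolerance = 1e-9)
    for (j in seq_len(p))
      expect_equal(abs(ev_cov$vectors[, j]), abs(ev_rho$vectors[, j]),
                   tolerance = 1e-6)
    expect_equal(sum(ev_rho$values), p, tolerance = 1e-9)
  }
})

test_that("mining is invariant to strictly increasing column transforms", {
  set.seed(31)
  x <- toy_table(matrix(runif(60), 12, 5, dimnames = list(NULL, letters[1:5])))
  base <- mine_table(x)
  y <- x
  y[, 1] <- exp(y[, 1]); y[, 2] <- y[, 2]^3 + 10
  y[, 3] <- atan(y[, 3]); y[, 4] <- 1000 * y[, 4] - 5
  trans <- mine_table(y)
  expect_equal(trans$ranks, base$ranks)
  expect_equal(trans$spearman, base$spearman)
  expect_equal(trans$pca$eigenvalues, base$pca$eigenvalues)
  expect_equal(trans$ranking, base$ranking)
})

test_that("oriented PC1 ranking honors consensus and ignores component sign", {
  # all metrics agree exactly -> ranking equals that common ordering
  v <- c(0.9, 0.1, 0.5, 0.7, 0.3)
  m <- toy_table(cbind(a = v, b = v^2, c = sqrt(v)))
  mining <- mine_table(m)
  expect_equal(mining$ranking$run_id, rownames(m)[order(-v)])
  expect_equal(mining$ranking$rank, 1:5)
  # flipping every loading sign leaves the oriented ranking unchanged
  p <- mining$pca
  flipped <- p
  flipped$loadings <- -p$loadings
  flipped$scores <- -p$scores
  expect_equal(orient_and_rank(flipped, mining$ranks)$run_id,
               mining$ranking$run_id)
})

test_that("metric clustering merges identical columns first and isolates outliers", {
  v <- c(3, 1, 4, 1, 5, 9, 2, 6)
  set.seed(5)
  m <- toy_table(cbind(a = v, b = v, c = v + rnorm(8, 0, 2), d = -v))
  rho <- spearman_matrix(m)
  hc <- cluster_metrics(rho)
  first <- sort(hc$labels[abs(hc$merge[1, ])])
  expect_equal(first, c("a", "b"))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  # the anticorrelated column enters only at the final merge, as a singleton
  expect_true(-match("d", hc$labels) %in% hc$merge[nrow(hc$merge), ])
  expect_true("d" %in% hc$labels[hc$order][c(1, length(hc$labels))])
  # p = 2: single merge at 1 - rho
  m2 <- toy_table(cbind(a = v, b = c(1, 2, 4, 3, 5, 8, 2.5, 6)))
  rho2 <- spearman_matrix(m2)
  hc2 <- cluster_metrics(rho2)
  expect_equal(nrow(hc2$merge), 1)
  expect_equal(hc2$height, 1 - rho2["a", "b"], tolerance = 1e-12)
})

test_that("consistency report flags planted inconsistent metrics", {
  v <- 1:8
  m <- toy_table(cbind(a = v, b = v + 0.1, c = v * 2, d = rev(v)))
  rho <- spearman_matrix(m)
  rep_all <- consistency_report(rho, subset = c("a", "b", "c"))
  expect_equal(rep_all$min_pairwise, 1)
  expect_equal(rep_all$flagged, "d")
  ident <- consistency_report(spearman_matrix(toy_table(cbind(a = v, b = v))))
  expect_equal(ident$min_pairwise, 1)
  single <- consistency_report(rho, subset = "a")
  expect_true(is.na(single$min_pairwise))
})

test_that("mining outputs serialize to the documented files", {
  set.seed(77)
  x <- toy_table(matrix(runif(44), 11, 4, dimnames = list(NULL, letters[1:4])))
  mining <- mine_table(x)
  dir <- withr::local_tempdir()
  paths <- write_mining(mining, dir)
  expect_true(all(file.exists(file.path(dir, c("ranking.csv", "loadings.csv",
                                               "eigenvalues.csv",
                                               "dendrogram.txt")))))
  rk <- read.csv(file.path(dir, "ranking.csv"))
  expect_equal(sort(rk$rank), 1:11)
  expect_true(grepl(";$", readLines(file.path(dir, "dendrogram.txt"))))
})
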