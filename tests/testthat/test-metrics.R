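vimg <- function(v) mm_image(v, shape = c(length(v), 1L))

test_that("difference metrics match hand computations", {
  r <- vimg(c(0, 0, 1, 1)); s <- vimg(c(0, 1, 0, 1))
  expect_equal(metric_msd(r, s)$raw, 0.5)
  expect_equal(metric_adi(r, s)$raw, 0.5)
  expect_equal(metric_msd(r, r)$raw, 0)
  expect_equal(metric_msd(r, r)$score, 1)
  # clamp boundary: maximal disagreement at the full dynamic range
  m <- metric_msd(vimg(c(0, 4)), vimg(c(4, 0)))
  expect_equal(m$raw, 16)
  expect_equal(m$score, 0)
  expect_equal(metric_adi(vimg(c(0, 2, 4)), vimg(c(4, 2, 0)))$raw, 8 / 3)
  expect_error(metric_msd(r, vimg(1:6)), "shape mismatch")
})

test_that("difference-image entropy behaves as an entropy", {
  r <- vimg(c(0, 0, 1, 1)); s <- vimg(c(0, 1, 0, 1))
  e <- metric_edi(r, s, bins = 3)
  expect_equal(e$raw, 1.5)  # p = (1/4, 1/2, 1/4)
  expect_equal(metric_edi(r, r, bins = 64)$raw, 0)
  expect_equal(metric_edi(r, r, bins = 64)$score, 1)
  # difference uniform over exactly B distinct values -> maximal entropy
  u <- metric_edi(vimg(c(0, 0, 0)), vimg(c(0, 1, 2)), bins = 3)
  expect_equal(u$raw, log2(3))
  expect_equal(u$score, 0)
})

test_that("mutual-information family matches hand entropies", {
  r <- vimg(c(0, 0, 1, 1))
  ident <- metric_mi_family(r, r, bins = c(2, 2))
  expect_equal(ident$mif$raw, 1)  # H_R = H_S = H_RS = 1 bit
  expect_equal(ident$nmi$raw, 2)
  expect_equal(ident$red$raw, 0.5)
  expect_equal(ident$uni$raw, 0)
  expect_equal(ident$aum$raw, 0)
  expect_true(all(vapply(ident, `[[`, numeric(1), "score") == 1))
  indep <- metric_mi_family(r, vimg(c(0, 1, 0, 1)), bins = c(2, 2))
  expect_equal(indep$mif$raw, 0)  # joint uniform over 4 cells
  expect_equal(indep$nmi$raw, 1)
  expect_equal(indep$red$raw, 0)
  expect_equal(indep$uni$raw, 1)
  expect_equal(indep$aum$raw, 1)
  expect_true(all(vapply(indep, `[[`, numeric(1), "score") == 0))
})

test_that("printed identities among the entropy ratios agree", {
  set.seed(7)
  for (k in 1:25) {
    vr <- runif(32); vs <- runif(32)
    r <- vimg(vr); s <- vimg(vs)
    fam <- metric_mi_family(r, s, bins = c(8, 8))
    rng <- range(c(vr, vs))
    jh <- joint_histogram(r, s, bins = c(8, 8), range_r = rng, range_s = rng)
    h_r <- shannon_entropy(jh$marginal_r); h_s <- shannon_entropy(jh$marginal_s)
    h_rs <- shannon_entropy(jh)
    expect_equal(fam$uni$raw, 2 - (h_r + h_s) / h_rs, tolerance = 1e-12)
    expect_equal(fam$red$raw, 1 - h_rs / (h_r + h_s), tolerance = 1e-12)
    expect_equal(fam$nmi$raw, (h_r + h_s) / h_rs, tolerance = 1e-12)
  }
})

test_that("constant images degrade gracefully in the MI family", {
  c1 <- vimg(rep(2, 8))
  same <- metric_mi_family(c1, c1, bins = c(4, 4))
  expect_true(all(vapply(same, `[[`, logical(1), "degenerate")))
  expect_true(all(vapply(same, `[[`, numeric(1), "score") == 1))
  diff <- metric_mi_family(c1, vimg(rep(5, 8)), bins = c(4, 4))
  expect_true(all(vapply(diff, `[[`, numeric(1), "score") == 0))
})

test_that("normalized cross-correlation is exact on linear relations", {
  r <- vimg(c(1, 2, 3, 4))
  expect_equal(metric_ncc(r, vimg(2 * c(1, 2, 3, 4) + 1))$raw, 1)
  expect_equal(metric_ncc(r, vimg(-c(1, 2, 3, 4)))$raw, -1)
  expect_equal(metric_ncc(r, vimg(-c(1, 2, 3, 4)))$score, 0)
  expect_equal(metric_ncc(r, vimg(c(1, 2, 4, 3)))$raw, 0.8)
  expect_error(metric_ncc(r, vimg(rep(1, 4))), "constant")
  expect_s3_class(tryCatch(metric_ncc(vimg(rep(0, 4)), r), error = identity),
                  "mm_degenerate_input")
})

test_that("correlation ratio matches hand computation and edge cases", {
  r <- vimg(c(0, 0, 1, 1))
  # s deterministic per bin of r -> all conditional variances vanish
  expect_equal(metric_cor(r, vimg(c(5, 5, 3, 3)), bins = 2)$raw, 1)
  # constant r: a single bin explains nothing
  expect_equal(metric_cor(vimg(rep(1, 4)), vimg(c(1, 2, 3, 4)), bins = 2)$raw, 0)
  expect_equal(metric_cor(r, vimg(c(1, 3, 2, 2)), bins = 2)$raw, 0)
  expect_error(metric_cor(r, vimg(rep(2, 4)), bins = 2), "constant")
})

test_that("Woods criterion matches hand computation and skips zero-mean bins", {
  r <- vimg(c(0, 0, 1, 1))
  expect_equal(metric_woo(r, vimg(c(5, 5, 3, 3)), bins = 2)$raw, 1)
  w <- metric_woo(r, vimg(c(1, 3, 2, 2)), bins = 2)
  expect_equal(w$raw, 0.75)  # 1 - (1/4)(2 * (1/2) + 2 * 0)
  expect_equal(w$details$skipped_bins, 0)
  # huge relative within-bin spread drives the raw negative; score clamps
  big <- metric_woo(r, vimg(c(-9, 10, 5, 5)), bins = 2)
  expect_lt(big$raw, 0)
  expect_equal(big$score, 0)
  # both bin means vanish -> every bin skipped -> degenerate input
  expect_s3_class(tryCatch(metric_woo(r, vimg(c(-1, 1, -2, 2)), bins = 2),
                           error = identity), "mm_degenerate_input")
})

test_that("all 11 scores are exactly 1 on identity pairs of quantized images", {
  set.seed(101)
  for (k in 1:20) {
    img <- rand_lattice_image(64, levels = 32)
    if (diff(range(img$voxels)) == 0) next
    row <- evaluate_pair(img, img)  # default 64-bin configuration
    for (m in metric_names())
      expect_equal(row[[m]]$score, 1, tolerance = 1e-9,
                   label = paste("identity score of", m))
  }
})

test_that("symmetric metrics are symmetric; cor and woo condition on the reference", {
  set.seed(33)
  sym <- c("msd", "adi", "edi", "mif", "nmi", "ncc", "red", "uni", "aum")
  for (k in 1:10) {
    r <- vimg(runif(48)); s <- vimg(runif(48))
    ab <- evaluate_pair(r, s); ba <- evaluate_pair(s, r)
    for (m in sym)
      expect_equal(ab[[m]]$raw, ba[[m]]$raw, tolerance = 1e-12,
                   label = paste("symmetry of", m))
  }
  # asymmetric by construction: conditioning swaps change the value
  r <- vimg(c(0, 0, 1, 1, 2, 2)); s <- vimg(c(1, 2, 3, 3, 9, 4))
  expect_false(isTRUE(all.equal(metric_cor(r, s, bins = 3)$raw,
                                metric_cor(s, r, bins = 3)$raw)))
})

test_that("scores stay in [0,1] over randomized pairs", {
  set.seed(55)
  for (k in 1:200) {
    n <- sample(c(16, 32, 64), 1)
    r <- if (k %% 2) vimg(runif(n, -3, 5)) else rand_lattice_image(n, 6)
    s <- if (k %% 3) vimg(rnorm(n)) else rand_lattice_image(n, 6)
    row <- evaluate_pair(r, s)
    for (m in metric_names()) {
      if (is.null(row[[m]])) next
      expect_gte(row[[m]]$score, 0)
      expect_lte(row[[m]]$score, 1)
    }
  }
})

test_that("every metric agrees with the brute-force oracle on random small pairs", {
  set.seed(77)
  worst <- 0
  for (k in 1:300) {
    vr <- sample(0:3, 8, replace = TRUE)
    vs <- sample(0:3, 8, replace = TRUE)
    worst <- max(worst, compare_pair_to_oracle(vr, vs))
  }
  expect_lt(worst, 1e-9)
})

test_that("the battery assembles an n x 11 table with identity row all ones", {
  ref <- rand_lattice_image(128, levels = 24)
  cands <- list(identity = ref,
                noisy = vimg(as.numeric(ref$voxels) +
                               round(runif(128, -2, 2))),
                flat = vimg(rep(3, 128)))
  tab <- evaluate_battery(ref, cands)
  expect_s3_class(tab, "mm_metric_table")
  expect_equal(dim(score_matrix(tab)), c(3L, 11L))
  expect_equal(colnames(tab)[-1], metric_names())
  expect_true(all(abs(score_matrix(tab)["identity", ] - 1) < 1e-9))
  # the constant candidate degrades to missing cells for ncc/cor, never fakes
  miss <- attr(tab, "missing")
  expect_true(miss[3, "ncc"] && miss[3, "cor"])
  expect_false(any(miss[1:2, ]))
  expect_error(evaluate_battery(ref, list(bad = vimg(1:10))), "bad")
})

test_that("metric tables round-trip through CSV", {
  ref <- rand_lattice_image(64, levels = 16)
  tab <- evaluate_battery(ref, list(a = ref, b = rand_lattice_image(64, 16)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_table(tab, path)
  back <- read_metric_table(path)
  expect_equal(score_matrix(back), score_matrix(tab))
  expect_true(file.exists(sub("\\.csv$", "_raw.csv", path)))
})
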