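# Independent brute-force oracles: literal loops over voxels and exact
# intensity values, written directly from the metric definitions and kept
# deliberately naive. Valid on small lattice-valued images whose distinct
# values (and pairwise differences) are separated by the equal-width binning
# used in the implementation under test.

lattice_image <- function(values, shape = c(length(values), 1L)) {
  mm_image(values, shape = shape)
}

rand_lattice_image <- function(n_vox, levels, shape = c(n_vox, 1L)) {
  lattice_image(sample(0:(levels - 1), n_vox, replace = TRUE), shape)
}

entropy_of_counts <- function(counts) {
  n <- sum(counts)
  h <- 0
  for (c in counts) {
    if (c > 0) {
      p <- c / n
      h <- h - p * log2(p)
    }
  }
  h
}

oracle_clamp <- function(x) min(max(x, 0), 1)

# all 11 metrics on a pair of intensity vectors; NULL entries mark
# degenerate inputs (same rule as the battery: zero-variance inputs for
# ncc/cor, no usable bin means for woo)
oracle_pair <- function(vr, vs, diff_bins = 7) {
  n <- length(vr)
  out <- list()
  D <- max(c(vr, vs)) - min(c(vr, vs))

  msd <- sum((vr - vs)^2) / n
  out$msd <- list(raw = msd,
                  score = if (D == 0) 1 else oracle_clamp(1 - msd / D^2))
  adi <- sum(abs(vr - vs)) / n
  out$adi <- list(raw = adi,
                  score = if (D == 0) 1 else oracle_clamp(1 - adi / D))

  d <- vr - vs
  h_d <- entropy_of_counts(as.numeric(table(d)))
  out$edi <- list(raw = h_d, score = oracle_clamp(1 - h_d / log2(diff_bins)))

  # joint distribution over exact value pairs
  lev_r <- sort(unique(vr)); lev_s <- sort(unique(vs))
  joint <- matrix(0, length(lev_r), length(lev_s))
  for (x in seq_len(n))
    joint[match(vr[x], lev_r), match(vs[x], lev_s)] <-
      joint[match(vr[x], lev_r), match(vs[x], lev_s)] + 1
  h_r <- entropy_of_counts(rowSums(joint))
  h_s <- entropy_of_counts(colSums(joint))
  h_rs <- entropy_of_counts(as.numeric(joint))
  if (min(h_r, h_s) <= 0) {
    sc <- if (all(vr == vs)) 1 else 0
    for (m in c("mif", "nmi", "red", "uni", "aum"))
      out[[m]] <- list(raw = NA_real_, score = sc)
  } else {
    i_rs <- max(h_r + h_s - h_rs, 0)
    out$mif <- list(raw = i_rs, score = oracle_clamp(i_rs / min(h_r, h_s)))
    out$nmi <- list(raw = i_rs / h_rs + 1, score = oracle_clamp(i_rs / h_rs))
    out$red <- list(raw = i_rs / (h_r + h_s),
                    score = oracle_clamp(2 * i_rs / (h_r + h_s)))
    out$uni <- list(raw = 1 - i_rs / h_rs, score = oracle_clamp(i_rs / h_rs))
    out$aum <- list(raw = 1 - i_rs / max(h_r, h_s),
                    score = oracle_clamp(i_rs / max(h_r, h_s)))
  }

  mr <- sum(vr) / n; ms <- sum(vs) / n
  vrr <- sum((vr - mr)^2) / n; vss <- sum((vs - ms)^2) / n
  if (vrr <= 0 || vss <= 0) {
    out$ncc <- NULL
  } else {
    ncc <- sum((vr - mr) * (vs - ms)) / n / sqrt(vrr * vss)
    ncc <- min(max(ncc, -1), 1)
    out$ncc <- list(raw = ncc, score = (ncc + 1) / 2)
  }

  # correlation ratio and Woods, conditioning on exact intensity values of vr
  if (vss <= 0) {
    out$cor <- NULL
  } else {
    acc <- 0
    for (i in lev_r) {
      si <- vs[vr == i]
      mu_i <- sum(si) / length(si)
      var_i <- sum((si - mu_i)^2) / length(si)
      acc <- acc + length(si) * var_i
    }
    raw <- 1 - acc / (n * vss)
    out$cor <- list(raw = raw, score = oracle_clamp(raw))
  }

  acc <- 0; kept <- 0
  for (i in lev_r) {
    si <- vs[vr == i]
    mu_i <- sum(si) / length(si)
    if (abs(mu_i) > 1e-8) {
      sd_i <- sqrt(sum((si - mu_i)^2) / length(si))
      acc <- acc + length(si) * sd_i / mu_i
      kept <- kept + 1
    }
  }
  out$woo <- if (kept == 0) NULL
             else list(raw = 1 - acc / n, score = oracle_clamp(1 - acc / n))
  out[c("msd", "adi", "edi", "mif", "nmi", "ncc", "cor", "woo",
        "red", "uni", "aum")]
}

# battery settings under which the implementation's equal-width binning is
# exact for lattice images with <= 4 levels
oracle_config <- function() battery_config(bins = 4, joint_bins = c(4, 4),
                                           diff_bins = 7)

# compare one implementation pair against the oracle; returns max abs
# deviation over defined cells (and checks degenerate cells line up)
compare_pair_to_oracle <- function(vr, vs, tol = 1e-9) {
  r <- lattice_image(vr); s <- lattice_image(vs)
  impl <- evaluate_pair(r, s, config = oracle_config())
  orac <- oracle_pair(vr, vs)
  dev <- 0
  for (m in names(impl)) {
    io <- orac[[m]]; ii <- impl[[m]]
    if (is.null(io) || is.null(ii)) {
      if (!(is.null(io) && is.null(ii)))
        stop("degenerate flag mismatch for ", m, " on r=",
             paste(vr, collapse = ","), " s=", paste(vs, collapse = ","))
      next
    }
    dev <- max(dev, abs(ii$score - io$score))
    if (!is.na(io$raw) && !is.na(ii$raw))
      dev <- max(dev, abs(ii$raw - io$raw))
    else if (is.na(io$raw) != is.na(ii$raw))
      stop("raw NA mismatch for ", m)
  }
  dev
}

# brute-force Spearman: average ranks by counting, then a literal Pearson
oracle_spearman <- function(x, y) {
  rank_by_count <- function(v) {
    vapply(v, function(vi)
      sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- rank_by_count(x); ry <- rank_by_count(y)
  n <- length(x)
  mx <- sum(rx) / n; my <- sum(ry) / n
  num <- sum((rx - mx) * (ry - my))
  den <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  num / den
}
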