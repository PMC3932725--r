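# The eleven-metric battery. Each metric returns both its raw value and a
# score in [0, 1] with 1 optimal, so values are comparable across metrics.
# Raw formulas use population (1/N) normalisation throughout.

#' Fixed metric order of the battery
#'
#' @return character vector of the 11 metric names in canonical column order.
#' @export
metric_names <- function() {
  c("msd", "adi", "edi", "mif", "nmi", "ncc", "cor", "woo", "red", "uni", "aum")
}

metric_result <- function(metric_name, raw, score, direction,
                          degenerate = FALSE, details = list()) {
  structure(
    list(metric_name = metric_name, raw = raw, score = score,
         direction = direction, degenerate = degenerate, details = details),
    class = "mm_metric_result")
}

#' @export
print.mm_metric_result <- function(x, ...) {
  cat(sprintf("<metric %s> raw = %s, score = %s%s\n", x$metric_name,
              format(x$raw), format(x$score),
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}

degenerate_error <- function(metric, msg) {
  stop(structure(
    class = c("mm_degenerate_input", "error", "condition"),
    list(message = paste0(metric, ": ", msg), call = sys.call(-1))))
}

clamp01 <- function(x, warn_for = NULL, slack = 1e-9) {
  if (!is.null(warn_for) && (x < -slack || x > 1 + slack))
    warning("score for ", warn_for, " outside [0,1] (", format(x),
            "); clamped", call. = FALSE)
  min(max(x, 0), 1)
}

# union of both images' intensity ranges: identical images then bin
# identically, and the dynamic range D is shared by both.
shared_range <- function(vr, vs) base::range(c(vr, vs))

#' Mean square difference of intensities
#'
#' raw = (1/N) sum_x (R(x) - S(x))^2. Score = 1 - raw / D^2 where D is the
#' shared dynamic range of the pair, clamped to [0, 1].
#'
#' @param r,s images of identical shape (reference, candidate).
#' @param mask optional logical mask.
#' @return an `mm_metric_result`.
#' @export
metric_msd <- function(r, s, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  vr <- image_values(r, mask); vs <- image_values(s, mask)
  raw <- mean((vr - vs)^2)
  D <- diff(shared_range(vr, vs))
  score <- if (D <= 0) 1 else clamp01(1 - raw / D^2)
  metric_result("msd", raw, score, "distance")
}

#' Mean absolute difference of intensities
#'
#' raw = (1/N) sum_x |R(x) - S(x)|. Score = 1 - raw / D, clamped.
#'
#' @inheritParams metric_msd
#' @return an `mm_metric_result`.
#' @export
metric_adi <- function(r, s, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  vr <- image_values(r, mask); vs <- image_values(s, mask)
  raw <- mean(abs(vr - vs))
  D <- diff(shared_range(vr, vs))
  score <- if (D <= 0) 1 else clamp01(1 - raw / D)
  metric_result("adi", raw, score, "distance")
}

#' Shannon entropy of the difference image
#'
#' The difference image D(x) = R(x) - S(x) is binned into `bins` equal-width
#' bins over its own range; raw is the Shannon entropy (bits) of that
#' distribution. A perfectly reproduced image gives a constant difference and
#' entropy 0; a maximally disordered difference approaches log2(bins). Score
#' = 1 - raw / log2(bins).
#'
#' @inheritParams metric_msd
#' @param bins bins for the difference distribution (default 64).
#' @return an `mm_metric_result`.
#' @export
metric_edi <- function(r, s, bins = 64, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  d <- image_values(r, mask) - image_values(s, mask)
  bins <- as.integer(bins)
  h <- marginal_histogram(mm_image(d, shape = c(length(d), 1L)), bins = bins)
  raw <- shannon_entropy(h)
  score <- if (bins <= 1L) 1 else clamp01(1 - raw / log2(bins), warn_for = "edi")
  metric_result("edi", raw, score, "distance")
}

#' Mutual-information family (mif, nmi, red, uni, aum)
#'
#' All five entropy-ratio metrics from one joint histogram over a shared
#' intensity range:
#' \itemize{
#'   \item mif: I(R,S) = H(R) + H(S) - H(R,S); score I / min(H_R, H_S).
#'   \item nmi: raw = I/H(R,S) + 1 = (H_R + H_S)/H_RS; score nmi - 1.
#'   \item red: raw = I / (H_R + H_S); score 2 * red.
#'   \item uni: raw = 1 - I/H(R,S); score 1 - uni.
#'   \item aum: raw = 1 - I/max(H_R, H_S); score 1 - aum.
#' }
#' When either image is constant its marginal entropy is zero and the ratios
#' are undefined: results are flagged degenerate with score 1 if the images
#' are voxelwise identical and 0 otherwise.
#'
#' @inheritParams metric_msd
#' @param bins `c(B_R, B_S)` joint bins (default `c(64, 64)`).
#' @return named list of five `mm_metric_result`s
#'   (`mif`, `nmi`, `red`, `uni`, `aum`).
#' @export
metric_mi_family <- function(r, s, bins = c(64, 64), mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  vr <- image_values(r, mask); vs <- image_values(s, mask)
  rng <- shared_range(vr, vs)
  jh <- joint_histogram(r, s, bins = bins, range_r = rng, range_s = rng,
                        mask = mask)
  h_r <- shannon_entropy(jh$marginal_r)
  h_s <- shannon_entropy(jh$marginal_s)
  h_rs <- shannon_entropy(jh)
  if (min(h_r, h_s) <= 0) {
    sc <- if (isTRUE(all.equal(vr, vs))) 1 else 0
    res <- lapply(c(mif = "mif", nmi = "nmi", red = "red",
                    uni = "uni", aum = "aum"), function(nm)
      metric_result(nm, NA_real_, sc,
                    if (nm %in% c("uni", "aum")) "distance" else "similarity",
                    degenerate = TRUE))
    return(res)
  }
  i_rs <- max(h_r + h_s - h_rs, 0)
  list(
    mif = metric_result("mif", i_rs, clamp01(i_rs / min(h_r, h_s),
                                             warn_for = "mif"), "similarity",
                        details = list(h_r = h_r, h_s = h_s, h_rs = h_rs)),
    nmi = metric_result("nmi", i_rs / h_rs + 1,
                        clamp01(i_rs / h_rs, warn_for = "nmi"), "similarity"),
    red = metric_result("red", i_rs / (h_r + h_s),
                        clamp01(2 * i_rs / (h_r + h_s), warn_for = "red"),
                        "similarity"),
    uni = metric_result("uni", 1 - i_rs / h_rs,
                        clamp01(i_rs / h_rs, warn_for = "uni"), "distance"),
    aum = metric_result("aum", 1 - i_rs / max(h_r, h_s),
                        clamp01(i_rs / max(h_r, h_s), warn_for = "aum"),
                        "distance"))
}

#' Normalized cross-correlation
#'
#' Voxelwise Pearson correlation with means and standard deviations taken
#' over the whole image (population moments). raw in [-1, 1]; score
#' (raw + 1)/2. A constant image has zero variance and raises a degenerate
#' input error.
#'
#' @inheritParams metric_msd
#' @return an `mm_metric_result`.
#' @export
metric_ncc <- function(r, s, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  vr <- image_values(r, mask); vs <- image_values(s, mask)
  sr <- sqrt(mean(vr^2) - mean(vr)^2)
  ss <- sqrt(mean(vs^2) - mean(vs)^2)
  if (sr <= 0 || ss <= 0)
    degenerate_error("ncc", "constant image has zero standard deviation")
  raw <- (mean(vr * vs) - mean(vr) * mean(vs)) / (sr * ss)
  raw <- min(max(raw, -1), 1)
  metric_result("ncc", raw, (raw + 1) / 2, "similarity")
}

#' Correlation ratio
#'
#' raw = 1 - (1/N) sum_i N(i) sigma2(i) / sigma2, conditioning the candidate
#' S on equal-width intensity bins of the reference R. 1 means S is a
#' deterministic function of R's bins; 0 means the bins explain none of S's
#' variance. In [0, 1] by the law of total variance; score = raw. Asymmetric
#' in (R, S) by construction.
#'
#' @inheritParams metric_msd
#' @param bins bins for the reference image (default 64).
#' @return an `mm_metric_result`.
#' @export
metric_cor <- function(r, s, bins = 64, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  cs <- conditional_stats(r, s, bins = bins, mask = mask)
  if (cs$var_s <= 0)
    degenerate_error("cor", "candidate image is constant (zero variance)")
  occ <- which(cs$counts > 0)
  raw <- 1 - sum(cs$counts[occ] * cs$sigma2[occ]) / (cs$n * cs$var_s)
  metric_result("cor", raw, clamp01(raw), "similarity")
}

#' Woods criterion
#'
#' raw = 1 - (1/N) sum_i N(i) sigma(i) / mu(i): one minus the count-weighted
#' mean coefficient of variation of the candidate within each reference
#' intensity bin. Bins whose |mu(i)| <= eps are skipped (their count is
#' reported in `details$skipped_bins`); if every occupied bin is skipped the
#' input is degenerate. Negative raws (large within-bin spread) clamp to
#' score 0. Asymmetric in (R, S).
#'
#' @inheritParams metric_cor
#' @param eps threshold below which a bin mean is treated as zero
#'   (default 1e-8).
#' @return an `mm_metric_result`.
#' @export
metric_woo <- function(r, s, bins = 64, eps = 1e-8, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s); check_same_shape(r, s)
  cs <- conditional_stats(r, s, bins = bins, mask = mask)
  occ <- which(cs$counts > 0)
  keep <- occ[abs(cs$mu[occ]) > eps]
  if (length(keep) == 0L)
    degenerate_error("woo", "all bin means below eps; coefficient of variation undefined")
  raw <- 1 - sum(cs$counts[keep] * cs$sigma[keep] / cs$mu[keep]) / cs$n
  metric_result("woo", raw, clamp01(raw), "similarity",
                details = list(skipped_bins = length(occ) - length(keep)))
}

# ---- battery ----------------------------------------------------------------

#' Battery configuration
#'
#' @param bins histogram bins for the reference-conditioned metrics
#'   (cor, woo).
#' @param joint_bins `c(B_R, B_S)` for the mutual-information family.
#' @param diff_bins bins for the difference-image entropy.
#' @param woods_eps zero-mean threshold of the Woods criterion.
#' @param mask optional logical mask applied to every metric.
#' @return a list of settings for [evaluate_battery()].
#' @export
battery_config <- function(bins = 64, joint_bins = c(64, 64), diff_bins = 64,
                           woods_eps = 1e-8, mask = NULL) {
  list(bins = bins, joint_bins = joint_bins, diff_bins = diff_bins,
       woods_eps = woods_eps, mask = mask)
}

#' Evaluate the full metric battery on one pair
#'
#' @inheritParams metric_msd
#' @param config a [battery_config()].
#' @return named list of 11 `mm_metric_result`s in [metric_names()] order;
#'   degenerate-input failures (constant images for ncc/cor/woo) appear as
#'   `NULL` entries.
#' @export
evaluate_pair <- function(r, s, config = battery_config()) {
  m <- config$mask
  res <- list(
    msd = metric_msd(r, s, mask = m),
    adi = metric_adi(r, s, mask = m),
    edi = metric_edi(r, s, bins = config$diff_bins, mask = m))
  res <- c(res, metric_mi_family(r, s, bins = config$joint_bins, mask = m))
  safely <- function(expr) tryCatch(expr, mm_degenerate_input = function(e) NULL)
  res$ncc <- safely(metric_ncc(r, s, mask = m))
  res$cor <- safely(metric_cor(r, s, bins = config$bins, mask = m))
  res$woo <- safely(metric_woo(r, s, bins = config$bins,
                               eps = config$woods_eps, mask = m))
  res[metric_names()]
}

#' Evaluate a battery of candidates against a reference
#'
#' Produces the n x p score table at the heart of the meta-algorithm: one row
#' per candidate, one column per metric, scores in [0, 1] with 1 optimal.
#' Raw metric values, degenerate flags and missing-cell flags ride along as
#' attributes; failed (degenerate-input) cells are NA, never fabricated.
#'
#' @param reference the reference image R.
#' @param candidates list of candidate images (all sharing R's shape);
#'   names, if present, become candidate ids.
#' @param config a [battery_config()].
#' @param candidate_ids optional character ids overriding names.
#' @return a `data.frame` of class `mm_metric_table`: `candidate_id` plus the
#'   11 score columns in [metric_names()] order. Attributes: `raw_values`
#'   (data.frame), `missing` and `degenerate` (logical matrices), `config`.
#' @export
evaluate_battery <- function(reference, candidates, config = battery_config(),
                             candidate_ids = NULL) {
  reference <- as_mm_image(reference)
  if (is_mm_image(candidates)) candidates <- list(candidates)
  n <- length(candidates)
  if (n < 1L) stop("need at least one candidate")
  if (is.null(candidate_ids))
    candidate_ids <- if (!is.null(names(candidates)) &&
                         all(nzchar(names(candidates)))) names(candidates)
                     else sprintf("cand_%03d", seq_len(n))
  p <- metric_names()
  scores <- raws <- matrix(NA_real_, n, length(p), dimnames = list(NULL, p))
  miss <- degen <- matrix(FALSE, n, length(p), dimnames = list(NULL, p))
  for (i in seq_len(n)) {
    ci <- as_mm_image(candidates[[i]])
    if (!identical(ci$shape, reference$shape))
      stop("candidate '", candidate_ids[i], "' shape ",
           paste(ci$shape, collapse = "x"), " does not match reference shape ",
           paste(reference$shape, collapse = "x"))
    row <- evaluate_pair(reference, ci, config)
    for (m in p) {
      if (is.null(row[[m]])) {
        miss[i, m] <- TRUE
      } else {
        scores[i, m] <- row[[m]]$score
        raws[i, m] <- row[[m]]$raw
        degen[i, m] <- isTRUE(row[[m]]$degenerate)
      }
    }
  }
  out <- data.frame(candidate_id = candidate_ids, scores,
                    stringsAsFactors = FALSE)
  attr(out, "raw_values") <- data.frame(candidate_id = candidate_ids, raws,
                                        stringsAsFactors = FALSE)
  attr(out, "missing") <- miss
  attr(out, "degenerate") <- degen
  attr(out, "config") <- config
  class(out) <- c("mm_metric_table", "data.frame")
  out
}

#' Extract the numeric score matrix of a metric table
#'
#' @param m an `mm_metric_table` (or any data.frame with `candidate_id` plus
#'   metric columns).
#' @return numeric matrix, rownames = candidate ids.
#' @export
score_matrix <- function(m) {
  cols <- setdiff(colnames(m), "candidate_id")
  x <- as.matrix(as.data.frame(m)[, cols, drop = FALSE])
  rownames(x) <- if ("candidate_id" %in% colnames(m)) m$candidate_id
                 else rownames(m)
  storage.mode(x) <- "double"
  x
}

#' Write / read a metric table as CSV
#'
#' Scores go to `path`; raw values, when present, to a sibling file
#' `<path stem>_raw.csv`. Columns are `candidate_id` then the 11 metrics in
#' fixed order.
#'
#' @param m an `mm_metric_table`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_metric_table <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  raw <- attr(m, "raw_values")
  if (!is.null(raw)) {
    raw_path <- paste0(tools::file_path_sans_ext(path), "_raw.csv")
    utils::write.csv(raw, raw_path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("mm_metric_table", "data.frame")
  out
}
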