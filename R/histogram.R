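# Histogram and entropy primitives shared by the statistical metrics.
# Equal-width binning over a stated range; bins are half-open with the last
# bin closed, so values equal to range max land in the last bin.

bin_index <- function(v, lo, hi, bins) {
  bins <- as.integer(bins)
  if (bins < 1L) stop("bins must be >= 1")
  if (hi <= lo) return(rep(1L, length(v)))  # degenerate range: single cell
  idx <- floor((v - lo) / (hi - lo) * bins) + 1L
  idx[idx > bins] <- bins
  idx[idx < 1L] <- 1L
  as.integer(idx)
}

#' Marginal intensity histogram
#'
#' Equal-width binned counts N(i) of an image's intensities, with bin
#' probabilities p(i) = N(i)/N. Values equal to the range maximum fall in the
#' last (closed) bin.
#'
#' @param img an `mm_image` (or coercible).
#' @param bins number of bins (default 64).
#' @param range optional `c(min, max)`; defaults to the image intensity range.
#' @param mask optional logical mask of voxels to keep.
#' @return object of class `mm_histogram`: `bin_count`, `bin_edges`, `counts`,
#'   `p`, `n`.
#' @export
marginal_histogram <- function(img, bins = 64, range = NULL, mask = NULL) {
  img <- as_mm_image(img)
  v <- image_values(img, mask)
  if (length(v) == 0L) stop("cannot histogram an empty image / empty mask")
  if (is.null(range)) range <- base::range(v)
  if (length(range) != 2L || range[1] > range[2])
    stop("range must be c(min, max) with min <= max")
  bins <- as.integer(bins)
  counts <- tabulate(bin_index(v, range[1], range[2], bins), nbins = bins)
  structure(
    list(bin_count = bins,
         bin_edges = seq(range[1], range[2], length.out = bins + 1L),
         counts = counts, p = counts / length(v), n = length(v)),
    class = "mm_histogram")
}

#' Joint intensity histogram of two images
#'
#' Binned co-occurrence counts of intensity pairs at corresponding voxels;
#' the basis of joint entropy and mutual information. Marginalising the joint
#' over either axis reproduces the marginal histogram of each image at the
#' same binning.
#'
#' @param r,s two `mm_image`s of identical shape.
#' @param bins `c(B_R, B_S)` (default `c(64, 64)`); a scalar is recycled.
#' @param range_r,range_s optional ranges per axis; default each image's own
#'   range (metric code passes a shared range so identical images bin
#'   identically).
#' @param mask optional logical mask applied to both images.
#' @return object of class `mm_joint_histogram`: `counts` (B_R x B_S matrix),
#'   `p`, `n`, and `marginal_r` / `marginal_s` (`mm_histogram`s).
#' @export
joint_histogram <- function(r, s, bins = c(64, 64),
                            range_r = NULL, range_s = NULL, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s)
  check_same_shape(r, s)
  bins <- as.integer(rep_len(bins, 2L))
  vr <- image_values(r, mask); vs <- image_values(s, mask)
  if (length(vr) == 0L) stop("cannot histogram an empty image / empty mask")
  if (is.null(range_r)) range_r <- base::range(vr)
  if (is.null(range_s)) range_s <- base::range(vs)
  ir <- bin_index(vr, range_r[1], range_r[2], bins[1])
  is <- bin_index(vs, range_s[1], range_s[2], bins[2])
  counts <- matrix(tabulate((is - 1L) * bins[1] + ir, nbins = prod(bins)),
                   nrow = bins[1], ncol = bins[2])
  structure(
    list(bins = bins, counts = counts, p = counts / length(vr), n = length(vr),
         marginal_r = marginal_histogram(r, bins[1], range_r, mask),
         marginal_s = marginal_histogram(s, bins[2], range_s, mask)),
    class = "mm_joint_histogram")
}

#' Shannon entropy in bits
#'
#' H = -sum p log2 p over cells with p > 0. Accepts a marginal histogram, a
#' joint histogram, or a plain probability vector/matrix. Empty support gives
#' 0.
#'
#' @param x an `mm_histogram`, `mm_joint_histogram`, or numeric
#'   probabilities.
#' @return nonnegative entropy in bits, at most log2(number of cells).
#' @export
shannon_entropy <- function(x) {
  p <- if (inherits(x, c("mm_histogram", "mm_joint_histogram"))) x$p else x
  p <- as.numeric(p)
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' Conditional statistics of one image given another's intensity bins
#'
#' For each equal-width bin i of the reference image's intensities, the mean
#' mu(i), population standard deviation sigma(i) and variance sigma2(i) of
#' the second image's exact intensities at the same voxel positions; plus the
#' global population mean and variance of the second image. These are the
#' ingredients of the correlation-ratio and Woods criteria. Population (1/N)
#' normalisation throughout.
#'
#' @param r reference image whose intensities are binned.
#' @param s image whose per-bin statistics are taken.
#' @param bins number of bins for `r` (default 64).
#' @param range optional binning range for `r`.
#' @param mask optional logical mask applied to both.
#' @return object of class `mm_conditional_stats`: per-bin `counts`, `mu`,
#'   `sigma`, `sigma2` (NA for empty bins), plus `n`, `mean_s`, `var_s`.
#' @export
conditional_stats <- function(r, s, bins = 64, range = NULL, mask = NULL) {
  r <- as_mm_image(r); s <- as_mm_image(s)
  check_same_shape(r, s)
  vr <- image_values(r, mask); vs <- image_values(s, mask)
  if (length(vr) == 0L) stop("cannot compute conditional stats on empty input")
  if (is.null(range)) range <- base::range(vr)
  bins <- as.integer(bins)
  idx <- bin_index(vr, range[1], range[2], bins)
  n_i <- tabulate(idx, nbins = bins)
  mu <- sigma2 <- rep(NA_real_, bins)
  occ <- sort(unique(idx))
  mu[occ] <- as.numeric(rowsum(vs, idx, reorder = TRUE)) / n_i[occ]
  # two-pass (centered) variance: exact zero for bin-constant data
  dev2 <- (vs - mu[idx])^2
  sigma2[occ] <- as.numeric(rowsum(dev2, idx, reorder = TRUE)) / n_i[occ]
  n <- length(vs)
  structure(
    list(bin_count = bins, counts = n_i, mu = mu,
         sigma = sqrt(sigma2), sigma2 = sigma2,
         n = n, mean_s = mean(vs),
         var_s = mean(vs^2) - mean(vs)^2),
    class = "mm_conditional_stats")
}
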