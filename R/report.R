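# Visual analytics over the metric table and mining outputs: parallel
# coordinates across the 11 metric axes, a clustered correlation heatmap,
# and a scatter of candidates along the first two principal components.
# Plotting is strictly read-only: the per-column rescale used for display is
# never written back to the data.

# per-column min-max rescale to [0,1] for display; constant columns map to
# 0.5 so the rescale never divides by zero
rescale_columns <- function(x) {
  apply(x, 2, function(col) {
    rng <- range(col, na.rm = TRUE)
    if (!is.finite(diff(rng)) || diff(rng) == 0) return(rep(0.5, length(col)))
    (col - rng[1]) / diff(rng)
  })
}

group_palette <- function(groups) {
  lev <- unique(groups)
  stats::setNames(grDevices::hcl.colors(max(length(lev), 2L), "Dark 3")[
    seq_along(lev)], lev)
}

#' Parallel-coordinates plot of a metric table
#'
#' One polyline per candidate across one vertical axis per metric, in the
#' fixed battery order. Each column is independently min-max rescaled to
#' [0, 1] for display (so columns represent different real intervals — the
#' unscaled scores are what the store and CSVs hold).
#'
#' @param m an `mm_metric_table` (or score matrix).
#' @param groups optional per-row group labels (e.g. algorithm) for
#'   coloring.
#' @param file output image path (`.png`); NULL draws on the active device.
#' @param rescale per-column min-max rescale for display (default TRUE).
#' @param main plot title.
#' @return the file path (or NULL), invisibly.
#' @export
parallel_coordinates <- function(m, groups = NULL, file = NULL,
                                 rescale = TRUE, main = "Metric battery") {
  x <- if (is.matrix(m)) m else score_matrix(m)
  if (nrow(x) == 0L) stop("empty metric table")
  disp <- if (rescale) rescale_columns(x) else x
  if (nrow(x) == 1L) disp <- matrix(0.5, 1, ncol(x),
                                    dimnames = dimnames(x))
  cols <- if (is.null(groups)) rep("#33555599", nrow(x))
          else grDevices::adjustcolor(group_palette(groups)[groups], 0.6)
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 500)
    on.exit(grDevices::dev.off())
  }
  graphics::matplot(t(disp), type = "l", lty = 1, col = cols,
                    xaxt = "n", xlab = "", ylab = "rescaled score",
                    main = main, ylim = c(0, 1))
  graphics::axis(1, at = seq_len(ncol(x)), labels = colnames(x), las = 2)
  if (!is.null(groups)) {
    pal <- group_palette(groups)
    graphics::legend("bottomleft", legend = names(pal), col = pal, lty = 1,
                     cex = 0.8, bg = "white")
  }
  invisible(file)
}

#' Clustered correlation heatmap of the metrics
#'
#' Heatmap of the (Spearman) correlation matrix with rows and columns in
#' dendrogram leaf order, so families of mutually consistent metrics appear
#' as blocks and inconsistent metrics stand apart.
#'
#' @param c p x p correlation matrix.
#' @param dendrogram optional `hclust` from [cluster_metrics()] (computed if
#'   missing).
#' @param file output image path (`.png`); NULL draws on the active device.
#' @return the file path, invisibly.
#' @export
correlation_heatmap <- function(c, dendrogram = NULL, file = NULL) {
  if (is.null(dendrogram)) dendrogram <- cluster_metrics(c)
  ord <- dendrogram$order
  cc <- c[ord, ord]
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  p <- ncol(cc)
  graphics::image(seq_len(p), seq_len(p), t(cc[p:1, ]),
                  zlim = c(-1, 1),
                  col = grDevices::hcl.colors(64, "Blue-Red 3", rev = TRUE),
                  axes = FALSE, xlab = "", ylab = "",
                  main = "Metric correlation (clustered)")
  graphics::axis(1, at = seq_len(p), labels = colnames(cc), las = 2)
  graphics::axis(2, at = seq_len(p), labels = rev(colnames(cc)), las = 2)
  invisible(file)
}

#' Candidate scatter along the first two principal components
#'
#' @param p an `mm_pca_result`.
#' @param groups optional per-candidate group labels for coloring.
#' @param file output image path (`.png`); NULL draws on the active device.
#' @return the file path, invisibly.
#' @export
pc_scatter <- function(p, groups = NULL, file = NULL) {
  stopifnot(inherits(p, "mm_pca_result"))
  s <- p$scores
  cols <- if (is.null(groups)) "#335555"
          else group_palette(groups)[groups]
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(s[, 1], if (ncol(s) >= 2) s[, 2] else rep(0, nrow(s)),
                 col = cols, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)",
                                100 * p$eigenvalues[1] / sum(p$eigenvalues)),
                 ylab = if (ncol(s) >= 2)
                   sprintf("PC2 (%.1f%%)",
                           100 * p$eigenvalues[2] / sum(p$eigenvalues))
                 else "",
                 main = "Candidates in rank-PCA space")
  if (!is.null(groups)) {
    pal <- group_palette(groups)
    graphics::legend("topleft", legend = names(pal), col = pal, pch = 19,
                     cex = 0.8, bg = "white")
  }
  invisible(file)
}
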