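# The analysis core of the meta-algorithm: replace each metric column by its
# within-column ranks, take the Spearman rank correlation matrix, and
# eigen-decompose it. Rank replacement makes the analysis invariant to any
# strictly increasing rescaling of a metric (a nonparametric, outlier-
# resistant "robust" PCA); the first principal component carries the latent
# consensus ordering of the candidates.

#' Rank-transform a metric table
#'
#' Each column's scores are replaced by their within-column ranks, ascending
#' (rank 1 = smallest score, so a higher score gets a higher rank); ties get
#' the average rank. Every tie-free column is then a permutation of 1..n and
#' every column sums to n(n+1)/2.
#'
#' @param m an `mm_metric_table`, data.frame or numeric matrix of scores.
#' @param missing_policy `"drop_row"` (default: drop candidates with any
#'   missing cell, with a recorded count) or `"column_mean_rank"` (impute the
#'   column mean rank (n+1)/2 for missing cells).
#' @return numeric rank matrix (class `mm_rank_table` via attribute-free
#'   matrix) with rownames = candidate ids and attribute `dropped_rows`.
#' @export
rank_transform <- function(m, missing_policy = c("drop_row", "column_mean_rank")) {
  missing_policy <- match.arg(missing_policy)
  x <- if (is.matrix(m)) m else score_matrix(m)
  if (nrow(x) < 2L) stop("rank transform needs at least 2 rows")
  all_missing <- colSums(!is.na(x)) == 0L
  if (any(all_missing))
    stop("column(s) entirely missing: ",
         paste(colnames(x)[all_missing], collapse = ", "))
  dropped <- character(0)
  if (missing_policy == "drop_row") {
    keep <- stats::complete.cases(x)
    dropped <- rownames(x)[!keep]
    x <- x[keep, , drop = FALSE]
    if (nrow(x) < 2L) stop("fewer than 2 complete rows after dropping missing")
  }
  n <- nrow(x)
  r <- apply(x, 2, function(col) {
    rk <- rank(col, ties.method = "average", na.last = "keep")
    rk[is.na(rk)] <- (sum(!is.na(col)) + 1) / 2  # column mean rank
    rk
  })
  rownames(r) <- rownames(x)
  attr(r, "dropped_rows") <- dropped
  r
}

#' Spearman rank correlation matrix of the metric columns
#'
#' Equals the Pearson correlation of the rank-transformed columns. Columns
#' with zero rank variance (constant scores) have undefined correlations:
#' their entries are NA and the column names are recorded in attribute
#' `undefined`.
#'
#' @param m metric table / matrix (scores or ranks — ranks are recomputed,
#'   which is idempotent).
#' @param missing_policy passed to [rank_transform()].
#' @return p x p symmetric matrix, unit diagonal, entries in [-1, 1].
#' @export
spearman_matrix <- function(m, missing_policy = "drop_row") {
  r <- rank_transform(m, missing_policy = missing_policy)
  if (nrow(r) < 3L) stop("Spearman correlation needs at least 3 rows")
  sds <- apply(r, 2, stats::sd)
  undef <- colnames(r)[sds == 0]
  rho <- suppressWarnings(stats::cor(r, method = "pearson"))
  diag(rho) <- 1
  attr(rho, "undefined") <- undef
  rho
}

#' Robust PCA of a rank table
#'
#' Eigen-decomposition of the Spearman rank correlation matrix; candidate
#' scores are the column-centered ranks projected onto the loadings. For a
#' tie-free table this coincides (up to the known scale (n^2 - 1)/12) with
#' PCA of the rank covariance, since every rank column has identical,
#' a-priori-known variance.
#'
#' @param r rank matrix from [rank_transform()] (a raw metric table is
#'   accepted and rank-transformed first).
#' @param m optional: pass the original table when `r` is already ranks.
#' @return object of class `mm_pca_result`: `eigenvalues` (descending),
#'   `loadings` (p x p, unit columns, sign fixed so the largest-magnitude
#'   loading of each component is positive), `scores` (n x p),
#'   `spearman` (the correlation matrix), `orientation` (per-component sign
#'   flips applied by the convention).
#' @export
robust_pca <- function(r) {
  if (!is.matrix(r)) r <- rank_transform(r)
  if (nrow(r) < 3L) stop("robust PCA needs at least 3 rows")
  rho <- spearman_matrix(r)
  if (length(attr(rho, "undefined")))
    stop("constant column(s) make the correlation matrix undefined: ",
         paste(attr(rho, "undefined"), collapse = ", "))
  e <- eigen(rho, symmetric = TRUE)
  if (max(e$values) <= 1e-12) stop("degenerate (rank-zero) correlation matrix")
  flips <- apply(e$vectors, 2, function(v) {
    j <- which.max(abs(v))
    if (v[j] < 0) -1 else 1
  })
  loadings <- sweep(e$vectors, 2, flips, `*`)
  dimnames(loadings) <- list(colnames(r), paste0("PC", seq_len(ncol(r))))
  centered <- scale(r, center = TRUE, scale = FALSE)
  scores <- centered %*% loadings
  structure(
    list(eigenvalues = e$values, loadings = loadings, scores = scores,
         spearman = rho, orientation = flips),
    class = "mm_pca_result")
}

#' Orient PC1 and rank the candidates
#'
#' The sign of a principal component is arbitrary; by convention PC1 is
#' flipped if its candidate scores correlate negatively with the row-mean
#' rank (the naive consensus), so that larger PC1 means better. Candidates
#' are then sorted descending by oriented PC1 score; ties break by row-mean
#' rank, then by id.
#'
#' @param p an `mm_pca_result`.
#' @param r the rank matrix the PCA was computed from.
#' @return data.frame of class `mm_ranking`: `run_id`, `rank` (1 = best),
#'   `pc1`, `pc2`, `mean_rank`.
#' @export
orient_and_rank <- function(p, r) {
  stopifnot(inherits(p, "mm_pca_result"))
  mean_rank <- rowMeans(r)
  pc1 <- p$scores[, 1]
  cc <- suppressWarnings(stats::cor(pc1, mean_rank))
  if (!is.na(cc) && cc < 0) pc1 <- -pc1
  ids <- rownames(r)
  if (is.null(ids)) ids <- sprintf("cand_%03d", seq_len(nrow(r)))
  ord <- order(-pc1, -mean_rank, ids)
  out <- data.frame(run_id = ids[ord],
                    rank = seq_along(ord),
                    pc1 = pc1[ord],
                    pc2 = if (ncol(p$scores) >= 2) p$scores[ord, 2] else NA_real_,
                    mean_rank = mean_rank[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("mm_ranking", "data.frame")
  out
}

#' One-call mining of a metric table
#'
#' Rank transform, Spearman matrix, robust PCA and oriented ranking in one
#' step.
#'
#' @param m metric table.
#' @param missing_policy passed to [rank_transform()].
#' @return list: `ranks`, `spearman`, `pca`, `ranking`.
#' @export
mine_table <- function(m, missing_policy = "drop_row") {
  r <- rank_transform(m, missing_policy = missing_policy)
  p <- robust_pca(r)
  list(ranks = r, spearman = p$spearman, pca = p,
       ranking = orient_and_rank(p, r))
}

#' Hierarchical clustering of the metrics
#'
#' Agglomerative (average-linkage) clustering of the metric columns with
#' distance 1 - correlation; reveals families of mutually consistent metrics
#' and isolates outlier metrics that disagree with the rest.
#'
#' @param c p x p correlation matrix (e.g. from [spearman_matrix()]).
#' @return an `hclust` object; `$labels[$order]` is the deterministic leaf
#'   order.
#' @export
cluster_metrics <- function(c) {
  bad <- colnames(c)[colSums(is.na(c)) > 0]
  if (length(bad))
    stop("undefined correlations for metric(s): ", paste(bad, collapse = ", "))
  d <- stats::as.dist(1 - c)
  stats::hclust(d, method = "average")
}

#' Metric consistency report
#'
#' Reports the minimum pairwise correlation within a named metric subset
#' (the candidate "consistent core") and flags metrics whose mean
#' correlation with that subset falls below a threshold — the signature of
#' an inconsistent (often anticorrelated) metric.
#'
#' @param c p x p correlation matrix.
#' @param subset metric names forming the core (default: all columns).
#' @param threshold flag metrics whose mean correlation with the subset is
#'   below this (default 0).
#' @return list: `min_pairwise` (NA when the subset has < 2 members),
#'   `flagged` (character vector), `mean_correlation` (named, all metrics vs
#'   the subset).
#' @export
consistency_report <- function(c, subset = colnames(c), threshold = 0) {
  subset <- intersect(subset, colnames(c))
  min_pair <- if (length(subset) < 2L) NA_real_ else {
    sub <- c[subset, subset, drop = FALSE]
    min(sub[upper.tri(sub)])
  }
  mean_cor <- vapply(colnames(c), function(m) {
    others <- setdiff(subset, m)
    if (!length(others)) return(NA_real_)
    mean(c[m, others])
  }, numeric(1))
  list(min_pairwise = min_pair,
       flagged = names(mean_cor)[!is.na(mean_cor) & mean_cor < threshold],
       mean_correlation = mean_cor)
}

#' Write mining outputs to CSV / text
#'
#' @param mining result of [mine_table()].
#' @param dir output directory; writes `ranking.csv`, `loadings.csv`,
#'   `eigenvalues.csv` and `dendrogram.txt` (nested Newick-like text).
#' @return invisibly, the output paths.
#' @export
write_mining <- function(mining, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("ranking.csv", "loadings.csv", "eigenvalues.csv",
                            "dendrogram.txt"))
  utils::write.csv(as.data.frame(mining$ranking), paths[1], row.names = FALSE)
  utils::write.csv(data.frame(metric = rownames(mining$pca$loadings),
                              mining$pca$loadings), paths[2], row.names = FALSE)
  utils::write.csv(data.frame(component = seq_along(mining$pca$eigenvalues),
                              eigenvalue = mining$pca$eigenvalues),
                   paths[3], row.names = FALSE)
  hc <- cluster_metrics(mining$spearman)
  writeLines(hclust_newick(hc), paths[4])
  invisible(paths)
}

# nested-parenthesis rendering of an hclust tree with merge heights
hclust_newick <- function(hc) {
  render <- function(i) {
    if (i < 0) return(hc$labels[-i])
    pair <- hc$merge[i, ]
    sprintf("(%s,%s):%.6g", render(pair[1]), render(pair[2]), hc$height[i])
  }
  paste0(render(nrow(hc$merge)), ";")
}
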