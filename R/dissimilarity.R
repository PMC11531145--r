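#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{BC(u, v) = 1 - 2 \sum_k \min(u_k, v_k) / (\sum_k u_k + \sum_k v_k)}.
#'
#' @param counts Community matrix.
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(counts) {
  counts <- validate_community(counts)
  vegan::vegdist(counts, method = "bray")
}

#' Jaccard dissimilarity on presence/absence
#'
#' \eqn{1 - |A \cap B| / |A \cup B|} on the presence sets of two samples.
#'
#' @param counts Community matrix (converted to presence/absence internally).
#' @return A `dist` object with sample labels.
#' @export
jaccard_binary <- function(counts) {
  counts <- validate_community(counts)
  vegan::vegdist(to_binary(counts), method = "jaccard", binary = TRUE)
}

#' Principal coordinate analysis with a cumulative-contribution cutoff
#'
#' Classical scaling of the double-centred squared-dissimilarity matrix.
#' Negative eigenvalues are dropped (no Cailliez/Lingoes correction) and the
#' cumulative contribution of an axis is its eigenvalue share among the
#' positive eigenvalues only. Axes are retained until the cumulative
#' contribution reaches `cum_threshold`.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param cum_threshold Cumulative contribution to reach (default 0.90).
#' @param max_axes Optional hard cap on the number of axes retained.
#' @return An object of class `pcoa_ordination`: list with `coordinates`
#'   (samples x k), `eigenvalues` (all positive eigenvalues, descending) and
#'   `cumulative_contribution`.
#' @export
pcoa_axes <- function(d, cum_threshold = 0.90, max_axes = Inf) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("dissimilarity matrix must be symmetric")
  n <- nrow(dm)
  if (n < 2) stop("need at least two samples")
  ids <- rownames(dm)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  g <- -0.5 * dm^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  g <- g + mean(-0.5 * dm^2) - mean(g)  # complete double centring
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10
  if (!any(pos) || max(e$values) <= 0)
    stop("degenerate ordination: no positive eigenvalues (all dissimilarities zero?)")
  ev <- e$values[pos]
  vec <- e$vectors[, pos, drop = FALSE]
  contrib <- cumsum(ev) / sum(ev)
  k <- which(contrib >= cum_threshold - 1e-12)[1]
  k <- as.integer(min(k, max_axes, length(ev)))
  coords <- sweep(vec[, seq_len(k), drop = FALSE], 2, sqrt(ev[seq_len(k)]), `*`)
  rownames(coords) <- ids
  colnames(coords) <- paste0("PCo", seq_len(k))
  structure(list(coordinates = coords,
                 eigenvalues = ev,
                 cumulative_contribution = contrib,
                 n_axes = k,
                 cum_threshold = cum_threshold),
            class = "pcoa_ordination")
}

#' @export
print.pcoa_ordination <- function(x, ...) {
  cat(sprintf("PCoA ordination: %d samples, %d axes retained (cumulative contribution %.1f%% >= %.0f%%)\n",
              nrow(x$coordinates), x$n_axes,
              100 * x$cumulative_contribution[x$n_axes], 100 * x$cum_threshold))
  invisible(x)
}

#' Spatial eigenvectors of sampling positions
#'
#' Moran-eigenvector-style spatial predictors: the principal coordinates of
#' the pairwise Euclidean distances between sampling positions. The
#' double-centred matrix of \eqn{-d^2/2} is eigendecomposed and the
#' eigenvectors with positive eigenvalues are returned in descending order.
#' Columns are zero-mean and mutually orthogonal.
#'
#' @param metadata Sample metadata (positions and coordinates are taken from
#'   unique `position_id`/`x`/`y` rows), or a data frame with columns
#'   `position_id`, `x`, `y`.
#' @param n_vectors Optional cap on the number of eigenvectors returned.
#' @return An object of class `spatial_eigenvectors`: list with
#'   `position_ids`, `vectors` (positions x m) and `eigenvalues`.
#' @export
spatial_eigenvectors <- function(metadata, n_vectors = Inf) {
  pos <- unique(tibble::as_tibble(metadata)[, c("position_id", "x", "y")])
  if (anyDuplicated(pos$position_id))
    stop("inconsistent coordinates for some position_id")
  if (nrow(pos) < 3) stop("need at least three distinct positions")
  xy <- as.matrix(pos[, c("x", "y")])
  d <- as.matrix(stats::dist(xy))
  if (all(d == 0)) stop("all positions are coincident")
  g <- -0.5 * d^2
  g <- sweep(g, 1, rowMeans(g))
  g <- sweep(g, 2, colMeans(g))
  g <- g + mean(-0.5 * d^2) - mean(g)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos_idx <- e$values > max(e$values) * 1e-10
  ev <- e$values[pos_idx]
  vec <- e$vectors[, pos_idx, drop = FALSE]
  m <- min(length(ev), n_vectors)
  vec <- vec[, seq_len(m), drop = FALSE]
  rownames(vec) <- pos$position_id
  colnames(vec) <- paste0("EV", seq_len(m))
  structure(list(position_ids = pos$position_id,
                 vectors = vec,
                 eigenvalues = ev[seq_len(m)]),
            class = "spatial_eigenvectors")
}

#' @export
print.spatial_eigenvectors <- function(x, ...) {
  cat(sprintf("Spatial eigenvectors: %d positions, %d positive-eigenvalue columns\n",
              length(x$position_ids), ncol(x$vectors)))
  invisible(x)
}
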