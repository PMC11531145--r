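#' Mantel correlogram of community dissimilarity against distance classes
#'
#' Root communities are pooled to position-level presence/absence, Jaccard
#' dissimilarities are computed between positions, and for each geographic
#' distance class the Mantel correlation between the dissimilarity matrix
#' and the class-membership indicator is evaluated (sign flipped so that
#' positive values mean positive spatial autocorrelation: nearby positions
#' more similar than average). Significance is assessed by permuting
#' position identities (`n_perm` permutations, two-tailed) and
#' Benjamini-Hochberg q-values are reported across classes. Distance-class
#' breaks follow Sturges' rule on the pairwise-distance distribution unless
#' `n_classes` or `breaks` is given.
#'
#' @param community Community matrix (root samples; pooled to positions).
#' @param metadata Sample metadata for the community's samples.
#' @param n_classes Number of equal-width distance classes (default:
#'   Sturges' rule).
#' @param breaks Optional explicit class breaks (overrides `n_classes`).
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @param guild_map Optional tibble (`otu_id`, `guild`) for guild subsets.
#' @param guild Optional guild name; the community is restricted to that
#'   guild's OTUs before pooling.
#' @return A tibble of class `mantel_correlogram`: `class_mid_m`, `r`,
#'   `p_value`, `q_value`, `n_pairs`, plus the breaks as an attribute.
#' @export
mantel_correlogram <- function(community, metadata, n_classes = NULL,
                               breaks = NULL, n_perm = 1000, seed = 1,
                               guild_map = NULL, guild = NULL) {
  md <- validate_metadata(metadata)
  community <- validate_community(community)
  if (!is.null(guild)) {
    if (is.null(guild_map)) stop("`guild` requires `guild_map`")
    otus <- guild_map$otu_id[guild_map$guild %in% guild]
    otus <- intersect(otus, colnames(community))
    if (length(otus) == 0) stop("no OTUs in guild ", paste(guild, collapse = "/"))
    community <- community[, otus, drop = FALSE]
  }
  md <- md[match(rownames(community), md$sample_id), ]
  # pool to position-level presence (idempotent for position-level input)
  pos <- sort(unique(md$position_id))
  if (length(pos) < 3) stop("need at least three positions")
  agg <- rowsum((community > 0) + 0L, md$position_id)
  pooled <- (agg[pos, , drop = FALSE] > 0) + 0L
  keep <- rowSums(pooled) > 0
  if (!all(keep)) {
    warning(sum(!keep), " position(s) with empty pooled community dropped")
    pooled <- pooled[keep, , drop = FALSE]
    pos <- pos[keep]
  }
  coords <- unique(md[, c("position_id", "x", "y")])
  coords <- coords[match(pos, coords$position_id), ]
  dgeo <- as.matrix(stats::dist(coords[, c("x", "y")]))
  deco <- as.matrix(vegan::vegdist(pooled, method = "jaccard", binary = TRUE))
  np <- nrow(pooled)
  lower <- which(lower.tri(dgeo))
  gvec <- dgeo[lower]
  if (is.null(breaks)) {
    if (is.null(n_classes)) n_classes <- ceiling(log2(length(gvec))) + 1
    breaks <- seq(min(gvec), max(gvec), length.out = n_classes + 1)
  }
  cls <- cut(gvec, breaks, include.lowest = TRUE)
  n_pairs <- as.integer(table(cls))
  ok <- n_pairs >= 2
  if (!all(ok)) warning(sum(!ok), " distance class(es) with < 2 pairs dropped")
  ind <- vapply(levels(cls)[ok], function(l) as.numeric(cls == l),
                numeric(length(gvec)))
  evec <- deco[lower]
  if (stats::sd(evec) == 0) {
    out <- tibble::tibble(
      class_mid_m = (utils::head(breaks, -1) + breaks[-1])[ok] / 2,
      r = NA_real_, p_value = NA_real_, q_value = NA_real_,
      n_pairs = n_pairs[ok])
    attr(out, "breaks") <- breaks
    attr(out, "flag") <- "zero community variance"
    class(out) <- c("mantel_correlogram", class(out))
    return(out)
  }
  # Mantel r per class, sign flipped; vectorised over classes
  r_obs <- -as.vector(stats::cor(evec, ind))
  r_perm <- matrix(NA_real_, n_perm, ncol(ind))
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      pm <- sample.int(np)
      r_perm[b, ] <- -as.vector(stats::cor(deco[pm, pm][lower], ind))
    }
  })
  p <- (colSums(abs(r_perm) >= abs(matrix(r_obs, n_perm, ncol(ind),
                                          byrow = TRUE)) - 1e-12) + 1) /
    (n_perm + 1)
  mids <- ((utils::head(breaks, -1) + breaks[-1]) / 2)[ok]
  out <- tibble::tibble(class_mid_m = mids, r = r_obs, p_value = p,
                        q_value = bh_fdr(p), n_pairs = n_pairs[ok])
  attr(out, "breaks") <- breaks
  class(out) <- c("mantel_correlogram", class(out))
  out
}
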