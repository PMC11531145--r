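#' Extract the signed association network from an SLR fit
#'
#' Edges are the non-zero off-diagonal entries of the sparse component;
#' weights are partial correlations \eqn{-S_{uv}/\sqrt{S_{uu} S_{vv}}}, so
#' edge signs are opposite to the signs of `S`. Positive and negative edges
#' form the two sub-networks. Pairs of arbuscular mycorrhizal OTUs are
#' flagged (their co-occurrence can reflect multi-genome individuals rather
#' than interactions).
#'
#' @param fit An `slr_fit`.
#' @param guilds Optional tibble (`otu_id`, `guild`).
#' @param edge_tol Absolute threshold below which entries of `S` count as
#'   zero.
#' @return An object of class `association_network`: list with `edges`
#'   (tibble: otu1, otu2, weight, sign, amf_pair) and `nodes` (tibble:
#'   otu_id, guild, degree_positive, degree_negative).
#' @export
extract_network <- function(fit, guilds = NULL, edge_tol = 1e-8) {
  stopifnot(inherits(fit, "slr_fit"))
  S <- fit$S
  ids <- fit$otu_ids
  if (is.null(ids)) ids <- paste0("V", seq_len(nrow(S)))
  idx <- which(abs(S) > edge_tol & upper.tri(S), arr.ind = TRUE)
  w <- fit$partial_cor[idx]
  g_of <- function(o) {
    if (is.null(guilds)) return(NA_character_)
    guilds$guild[match(o, guilds$otu_id)]
  }
  edges <- tibble::tibble(
    otu1 = ids[idx[, 1]], otu2 = ids[idx[, 2]],
    weight = w, sign = ifelse(w > 0, "positive", "negative"))
  edges$amf_pair <- !is.null(guilds) &
    g_of(edges$otu1) %in% "AMF" & g_of(edges$otu2) %in% "AMF"
  deg <- function(sgn) {
    e <- edges[edges$sign == sgn, ]
    tab <- table(factor(c(e$otu1, e$otu2), levels = ids))
    as.integer(tab)
  }
  nodes <- tibble::tibble(otu_id = ids, guild = g_of(ids),
                          degree_positive = deg("positive"),
                          degree_negative = deg("negative"))
  structure(list(edges = edges, nodes = nodes, lambda = fit$lambda,
                 rank = fit$rank),
            class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("Association network: %d nodes, %d positive / %d negative edges (rank %d latent component)\n",
              nrow(x$nodes), sum(x$edges$sign == "positive"),
              sum(x$edges$sign == "negative"), x$rank))
  invisible(x)
}

#' Louvain modules of the positive association sub-network
#'
#' Runs the Louvain algorithm on the positive-edge sub-network (weights =
#' partial correlations). Deterministic for a fixed seed; nodes without
#' positive edges become singleton modules.
#'
#' @param network An `association_network`.
#' @param seed Integer seed.
#' @return A list with `membership` (tibble: otu_id, module) and
#'   `modularity`.
#' @export
louvain_modules <- function(network, seed = 1) {
  stopifnot(inherits(network, "association_network"))
  pos <- network$edges[network$edges$sign == "positive", ]
  g <- igraph::graph_from_data_frame(
    pos[, c("otu1", "otu2", "weight")], directed = FALSE,
    vertices = network$nodes$otu_id)
  cl <- with_seed(seed, igraph::cluster_louvain(g,
                                                weights = igraph::E(g)$weight))
  list(membership = tibble::tibble(otu_id = igraph::V(g)$name,
                                   module = as.integer(igraph::membership(cl))),
       modularity = igraph::modularity(cl))
}

#' Kendall rank correlation (tau-b) with tie correction
#'
#' Pair-counting tau-b and the normal-approximation two-tailed p-value with
#' the standard tie-corrected variance.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A list with `tau`, `p_value`, `concordant`, `discordant`.
#' @export
kendall_tau <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  n <- length(x)
  dx <- sign(outer(x, x, `-`))
  dy <- sign(outer(y, y, `-`))
  up <- upper.tri(dx)
  prod_ <- dx[up] * dy[up]
  C <- sum(prod_ > 0); D <- sum(prod_ < 0)
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  denom <- sqrt((n0 - n1) * (n0 - n2))
  tau <- if (denom > 0) (C - D) / denom else NA_real_
  v0 <- n * (n - 1) * (2 * n + 5)
  vt <- sum(tx * (tx - 1) * (2 * tx + 5))
  vu <- sum(ty * (ty - 1) * (2 * ty + 5))
  v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
  v2 <- if (n > 2)
    sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2)) else 0
  varS <- (v0 - vt - vu) / 18 + v1 + v2
  z <- if (varS > 0) (C - D) / sqrt(varS) else 0
  list(tau = tau, p_value = 2 * stats::pnorm(-abs(z)),
       concordant = C, discordant = D)
}

#' Concordance between network degree and jSDM covariance attribution
#'
#' Kendall rank correlation between each OTU's degree in the positive and
#' negative association sub-networks and its covariance log-likelihood
#' ratio from the jSDM factor attribution (full model versus the
#' covariance-free model). Optional occurrence and abundance vectors are
#' correlated with degree the same way.
#'
#' @param network An `association_network`.
#' @param attribution A `factor_attribution` (its `Cov` rows are used), or a
#'   named numeric vector of covariance LLRs.
#' @param occurrence,abundance Optional named vectors (per OTU).
#' @return A tibble: `comparison`, `sign`, `tau`, `p_value`, `n`.
#' @export
degree_vs_llr <- function(network, attribution, occurrence = NULL,
                          abundance = NULL) {
  stopifnot(inherits(network, "association_network"))
  if (inherits(attribution, "factor_attribution")) {
    d <- attribution$llr[attribution$llr$factor == "Cov", ]
    llr <- stats::setNames(d$llr, d$otu_id)
  } else llr <- attribution
  nodes <- network$nodes
  rows <- list()
  for (sgn in c("positive", "negative")) {
    deg <- if (sgn == "positive") nodes$degree_positive else nodes$degree_negative
    names(deg) <- nodes$otu_id
    pair_with <- function(v, lab) {
      common <- intersect(names(deg), names(v))
      if (length(common) < 3) return(NULL)
      kt <- kendall_tau(deg[common], v[common])
      tibble::tibble(comparison = lab, sign = sgn, tau = kt$tau,
                     p_value = kt$p_value, n = length(common))
    }
    rows <- c(rows, list(pair_with(llr, "degree_vs_cov_llr")))
    if (!is.null(occurrence)) rows <- c(rows, list(pair_with(occurrence, "degree_vs_occurrence")))
    if (!is.null(abundance)) rows <- c(rows, list(pair_with(abundance, "degree_vs_log_abundance")))
  }
  dplyr::bind_rows(rows)
}
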