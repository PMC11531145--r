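#' Build the fungus-plant bipartite count table
#'
#' \eqn{N(i, j)} is the number of root samples on host plant \eqn{j} in
#' which OTU \eqn{i} occurs (presence/absence data). OTUs occurring in fewer
#' than `min_otu_occurrence` root samples and host plants with fewer than
#' `min_host_samples` root samples are discarded before any statistic is
#' computed.
#'
#' @param root_binary Binary root community matrix (counts are accepted and
#'   converted).
#' @param metadata Sample metadata covering the root samples.
#' @param min_otu_occurrence Minimum root-sample occurrence per OTU.
#' @param min_host_samples Minimum root samples per host plant.
#' @return An object of class `bipartite_counts`: list with `N` (OTUs x
#'   plants), `A_otu`, `A_plant`, `m`, and the retained sample metadata.
#' @export
build_bipartite <- function(root_binary, metadata, min_otu_occurrence = 30,
                            min_host_samples = 30) {
  md <- validate_metadata(metadata)
  occ <- to_binary(root_binary)
  md <- md[md$kind == "root" & md$sample_id %in% rownames(occ), ]
  host_n <- table(md$host_plant)
  md <- md[md$host_plant %in% names(host_n)[host_n >= min_host_samples], ]
  occ <- occ[md$sample_id, , drop = FALSE]
  occ <- occ[, colSums(occ) >= min_otu_occurrence, drop = FALSE]
  if (ncol(occ) == 0 || nrow(occ) == 0)
    stop("no OTUs or samples pass the occurrence filters")
  H <- host_dummies(md$host_plant)
  N <- crossprod(occ, H)
  structure(list(N = N, A_otu = rowSums(N), A_plant = colSums(N),
                 m = sum(N), metadata = md, occ = occ),
            class = "bipartite_counts")
}

host_dummies <- function(host) {
  lev <- sort(unique(host))
  H <- matrix(0L, length(host), length(lev), dimnames = list(NULL, lev))
  H[cbind(seq_along(host), match(host, lev))] <- 1L
  H
}

# Kullback-Leibler specialisation of each row of N against the column
# availabilities q (fixed). Returns d per row; 0 log 0 = 0.
kl_rows <- function(N, q) {
  A <- rowSums(N)
  P <- N / A
  t1 <- P * log(sweep(P, 2, q, `/`))
  t1[N == 0] <- 0
  rowSums(t1)
}

# Greedy integer redistribution of each row total over the columns to
# minimise d: start from the floor of the proportional allocation, then add
# the remaining units one at a time to the column with the smallest KL
# increment (vectorised across rows).
dmin_rows <- function(A, q) {
  J <- length(q)
  n <- length(A)
  C <- floor(outer(A, q))
  rem <- A - rowSums(C)
  expect <- outer(A, q)            # A_i * q_j
  while (any(rem > 0)) {
    act <- which(rem > 0)
    cur <- C[act, , drop = FALSE]
    e <- expect[act, , drop = FALSE]
    # KL increment of adding one unit to column j (unnormalised by A)
    d1 <- (cur + 1) * log((cur + 1) / e) - ifelse(cur > 0, cur * log(cur / e), 0)
    j <- max.col(-d1, ties.method = "first")
    C[cbind(act, j)] <- C[cbind(act, j)] + 1L
    rem[act] <- rem[act] - 1L
  }
  kl_rows(C, q)
}

# d is maximised by concentrating the whole row on the rarest column.
dmax_rows <- function(A, q) rep(log(1 / min(q)), length(A))

#' Bluethgen d' specialisation index
#'
#' The Kullback-Leibler specialisation of each row's interaction
#' distribution against the availability of the columns,
#' \eqn{d_i = \sum_j p'_{ij} \ln(p'_{ij} / q_j)} with
#' \eqn{p'_{ij} = N_{ij} / A_i} and \eqn{q_j = A_j / m}, rescaled to
#' \eqn{d' = (d - d_{min}) / (d_{max} - d_{min})} where the extremes are
#' taken over integer redistributions of the row total with fixed margins.
#'
#' @param N A bipartite count matrix (or `bipartite_counts` object).
#' @param margin 1 for row-wise d' (fungal specialisation on plants), 2 for
#'   column-wise (plant specialisation on fungi).
#' @param allow_empty Return `NA` rows for zero-total rows instead of
#'   erroring (used by the permutation engine, where a partner's margin can
#'   legitimately be empty).
#' @return A tibble with `id`, `d`, `d_min`, `d_max`, `d_prime`. `d_prime`
#'   is `NA` (flagged) when only one partner column exists.
#' @export
dprime <- function(N, margin = 1, allow_empty = FALSE) {
  if (inherits(N, "bipartite_counts")) N <- N$N
  if (margin == 2) N <- t(N)
  empty <- rowSums(N) == 0
  if (any(empty) && !allow_empty)
    stop("rows with zero total have undefined d'")
  Nn <- N[!empty, , drop = FALSE]
  q <- colSums(N) / sum(N)
  fill <- function(v) {
    out <- rep(NA_real_, nrow(N)); out[!empty] <- unname(v); out
  }
  d <- kl_rows(Nn, q)
  if (ncol(N) < 2 || any(q == 0)) {
    keep_q <- q > 0
    if (sum(keep_q) < 2) {
      fd <- fill(d)
      return(tibble::tibble(id = rownames(N), d = fd, d_min = fd,
                            d_max = fd, d_prime = NA_real_))
    }
    Nn <- Nn[, keep_q, drop = FALSE]
    q <- q[keep_q]
    d <- kl_rows(Nn, q)
  }
  A <- rowSums(Nn)
  dmin <- dmin_rows(A, q)
  dmax <- dmax_rows(A, q)
  dp <- ifelse(dmax > dmin, (d - dmin) / (dmax - dmin), 0)
  out <- list(d = fill(d), d_min = fill(dmin), d_max = fill(dmax),
              d_prime = fill(pmin(pmax(dp, 0), 1)))
  tibble::tibble(id = rownames(N), d = out$d, d_min = out$d_min,
                 d_max = out$d_max, d_prime = out$d_prime)
}

#' Shuffle host-plant labels within sampling positions
#'
#' Permutes the host labels of root samples within each sampling position,
#' preserving the per-position multiset of labels exactly (the constrained
#' null of the host-preference randomisation).
#'
#' @param metadata Root-sample metadata (`position_id`, `host_plant`).
#' @param seed Optional seed; when `NULL` the current RNG stream is used.
#' @return A character vector of permuted host labels, aligned with the
#'   rows of `metadata`.
#' @export
shuffle_within_position <- function(metadata, seed = NULL) {
  doit <- function() {
    host <- metadata$host_plant
    for (idx in split(seq_along(host), metadata$position_id)) {
      if (length(idx) > 1) host[idx] <- host[idx][sample.int(length(idx))]
    }
    host
  }
  if (is.null(seed)) doit() else with_seed(seed, doit())
}

# Shared permutation engine for the d'-based and pair-level preference
# statistics: one stream of within-position label shuffles per seed.
preference_engine <- function(root_binary, metadata, n_perm = 10000, seed = 1,
                              min_otu_occurrence = 30, min_host_samples = 30) {
  bp <- build_bipartite(root_binary, metadata, min_otu_occurrence,
                        min_host_samples)
  occ <- bp$occ
  md <- bp$metadata
  n_otu <- ncol(occ); plants <- colnames(bp$N)
  q_p <- bp$A_plant / bp$m
  q_o <- bp$A_otu / bp$m
  obs_o <- dprime(bp$N, margin = 1, allow_empty = TRUE)
  obs_p <- dprime(bp$N, margin = 2, allow_empty = TRUE)
  dp_o <- matrix(NA_real_, n_otu, n_perm)
  dp_p <- matrix(NA_real_, length(plants), n_perm)
  Npair <- array(NA_real_, c(n_otu, length(plants), n_perm))
  pos_split <- split(seq_len(nrow(md)), md$position_id)
  host <- md$host_plant
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      hb <- host
      for (idx in pos_split)
        if (length(idx) > 1) hb[idx] <- hb[idx][sample.int(length(idx))]
      Hb <- host_dummies_fixed(hb, plants)
      Nb <- crossprod(occ, Hb)
      Npair[, , b] <- Nb
      # OTU margins are preserved by the shuffle; plant margins shift with
      # sample richness, so each permuted matrix is rescaled with its own
      # redistribution bounds
      dp_o[, b] <- dprime_fast(Nb)
      dp_p[, b] <- dprime_fast(t(Nb))
    }
  })
  list(bipartite = bp, obs_otu = obs_o, obs_plant = obs_p,
       dp_otu = dp_o, dp_plant = dp_p, Npair = Npair,
       n_perm = n_perm, seed = seed)
}

host_dummies_fixed <- function(host, lev) {
  H <- matrix(0L, length(host), length(lev), dimnames = list(NULL, lev))
  H[cbind(seq_along(host), match(host, lev))] <- 1L
  H
}

# d' of every row of N, without the tibble wrapper (permutation hot path);
# zero-margin rows yield NA, zero-margin columns are dropped (they carry no
# interactions by construction)
dprime_fast <- function(N) {
  out <- rep(NA_real_, nrow(N))
  rows <- rowSums(N) > 0
  q <- colSums(N) / sum(N)
  cols <- q > 0
  if (sum(cols) < 2 || !any(rows)) return(out)
  Nn <- N[rows, cols, drop = FALSE]
  q <- q[cols]
  d <- kl_rows(Nn, q)
  dmin <- dmin_rows(rowSums(Nn), q)
  dmax <- log(1 / min(q))
  dp <- ifelse(dmax > dmin, (d - dmin) / (dmax - dmin), 0)
  out[rows] <- unname(pmin(pmax(dp, 0), 1))
  out
}

perm_scores <- function(obs, perm_mat) {
  mu <- rowMeans(perm_mat, na.rm = TRUE)
  sdv <- apply(perm_mat, 1, stats::sd, na.rm = TRUE)
  ok <- is.finite(obs) & is.finite(mu) & is.finite(sdv) & sdv > 0
  z <- ifelse(ok, (obs - mu) / sdv, 0)
  centred_obs <- abs(obs - mu)
  exceed <- rowSums(abs(perm_mat - mu) >= centred_obs - 1e-12, na.rm = TRUE)
  n_eff <- rowSums(is.finite(perm_mat))
  p <- ifelse(ok, (exceed + 1) / (n_eff + 1), 1)
  list(mu = mu, sd = sdv, z = z, p = p, degenerate = !ok)
}

#' Standardised host-preference scores
#'
#' For each fungal OTU, the observed d' is compared with its distribution
#' under within-position shuffles of the host labels:
#' \eqn{z = (d'_{obs} - mean(d'_{null})) / sd(d'_{null})}. Two-tailed
#' p-values come from the permutation ranks of d' and are converted to
#' Benjamini-Hochberg false discovery rates. Plants' preferences for fungi
#' are evaluated the same way on the transposed table, using the same
#' permutation stream.
#'
#' @inheritParams build_bipartite
#' @param n_perm Number of permutations.
#' @param seed Integer seed; equal seeds give identical permutation streams
#'   across the preference statistics.
#' @return An object of class `preference_result` with tibbles `otu` and
#'   `plant` (columns `id`, `d_prime`, `null_mean`, `null_sd`, `z`,
#'   `p_value`, `q_value`, `degenerate`) and the pair-level scores `pair`
#'   (see [two_dim_preference()]).
#' @export
standardized_preference <- function(root_binary, metadata, n_perm = 10000,
                                    seed = 1, min_otu_occurrence = 30,
                                    min_host_samples = 30) {
  eng <- preference_engine(root_binary, metadata, n_perm, seed,
                           min_otu_occurrence, min_host_samples)
  sc_o <- perm_scores(eng$obs_otu$d_prime, eng$dp_otu)
  sc_p <- perm_scores(eng$obs_plant$d_prime, eng$dp_plant)
  tab <- function(obs, sc) tibble::tibble(
    id = obs$id, d_prime = obs$d_prime, null_mean = sc$mu, null_sd = sc$sd,
    z = sc$z, p_value = sc$p, q_value = bh_fdr(sc$p), degenerate = sc$degenerate)
  pair <- pair_scores(eng)
  structure(list(otu = tab(eng$obs_otu, sc_o), plant = tab(eng$obs_plant, sc_p),
                 pair = pair, bipartite = eng$bipartite,
                 n_perm = n_perm, seed = seed),
            class = "preference_result")
}

pair_scores <- function(eng) {
  Nobs <- eng$bipartite$N
  K <- eng$n_perm
  flat <- matrix(eng$Npair, ncol = K)           # (OTU x plant) rows, perms cols
  mu <- rowMeans(flat)
  sdv <- sqrt(rowSums((flat - mu)^2) / (K - 1))
  obs <- as.vector(Nobs)
  z <- ifelse(sdv > 0, (obs - mu) / sdv, 0)
  exceed <- rowSums(abs(flat - mu) >= abs(obs - mu) - 1e-12)
  p <- (exceed + 1) / (K + 1)
  shape <- function(v) matrix(v, nrow(Nobs), ncol(Nobs), dimnames = dimnames(Nobs))
  list(score = shape(z), p_value = shape(p), q_value = shape(bh_fdr(p)),
       degenerate = shape(sdv == 0), null_mean = shape(mu),
       null_sd = shape(sdv))
}

#' Two-dimensional (pair-level) preference
#'
#' Standardised score of each fungus-plant pair's co-observation count
#' against the position-constrained permutation null:
#' \eqn{[N_{obs}(i,j) - mean(N_{null}(i,j))] / sd(N_{null}(i,j))}, with
#' two-tailed permutation p-values and Benjamini-Hochberg q-values across
#' cells. Shares the permutation stream of [standardized_preference()] for
#' equal seeds.
#'
#' @inheritParams standardized_preference
#' @return An object of class `two_dim_preference`: list with matrices
#'   `score`, `p_value`, `q_value`, `degenerate`, `null_mean`, `null_sd`.
#' @export
two_dim_preference <- function(root_binary, metadata, n_perm = 10000,
                               seed = 1, min_otu_occurrence = 30,
                               min_host_samples = 30) {
  eng <- preference_engine(root_binary, metadata, n_perm, seed,
                           min_otu_occurrence, min_host_samples)
  structure(c(pair_scores(eng), list(n_perm = n_perm, seed = seed)),
            class = "two_dim_preference")
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjusted p-values, monotone in the input.
#'
#' @param pvals Numeric vector of p-values.
#' @return q-values of the same length.
#' @export
bh_fdr <- function(pvals) stats::p.adjust(pvals, method = "BH")

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf("Host-preference permutation test: %d OTUs x %d plants, %d permutations\n",
              nrow(x$otu), nrow(x$plant), x$n_perm))
  cat(sprintf("  OTUs with q < 0.05: %d | plants with q < 0.05: %d\n",
              sum(x$otu$q_value < 0.05), sum(x$plant$q_value < 0.05)))
  invisible(x)
}
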