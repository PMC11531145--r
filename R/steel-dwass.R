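#' Steel-Dwass all-pairs nonparametric comparison
#'
#' All-pairs Steel-Dwass-Critchlow-Fligner tests: for every pair of groups a
#' Wilcoxon rank-sum statistic is computed on the pooled pair (average ranks
#' for ties, tie-corrected variance) and referred to the studentized-range
#' distribution with the number of eligible groups as the family size.
#' Groups with fewer than `min_group_size` observations are excluded.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`.
#' @param min_group_size Minimum group size for inclusion (default 5).
#' @param alpha Significance level used for the letter display.
#' @return An object of class `steel_dwass`: list with `pairs` (tibble:
#'   group1, group2, statistic, p_value), `letters` (compact letter
#'   display), and `groups` (tibble of group sizes and medians).
#' @export
steel_dwass <- function(values, groups, min_group_size = 5, alpha = 0.05) {
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- as.character(groups)[ok]
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_group_size]
  if (length(keep) < 2)
    stop("fewer than two groups meet the minimum group size")
  sel <- groups %in% keep
  values <- values[sel]; groups <- groups[sel]
  gl <- sort(unique(groups))
  k <- length(gl)
  combs <- utils::combn(gl, 2)
  res <- apply(combs, 2, function(pr) {
    xi <- values[groups == pr[1]]
    xj <- values[groups == pr[2]]
    ni <- length(xi); nj <- length(xj); N <- ni + nj
    rk <- rank(c(xi, xj))
    W <- sum(rk[seq_len(ni)])
    E <- ni * (N + 1) / 2
    V <- ni * nj / (N * (N - 1)) * (sum(rk^2) - N * (N + 1)^2 / 4)
    t_stat <- if (V <= 0) 0 else (W - E) / sqrt(V)
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = Inf,
                       lower.tail = FALSE)
    c(statistic = t_stat, p_value = p)
  })
  pairs <- tibble::tibble(group1 = combs[1, ], group2 = combs[2, ],
                          statistic = unname(res["statistic", ]),
                          p_value = unname(res["p_value", ]))
  letters <- cld_letters(gl, pairs, alpha)
  grp <- tibble::tibble(
    group = gl,
    n = as.integer(table(factor(groups, gl))),
    median = vapply(gl, function(g) stats::median(values[groups == g]), numeric(1)),
    letters = letters[gl])
  structure(list(pairs = pairs, letters = letters, groups = grp,
                 alpha = alpha), class = "steel_dwass")
}

# Compact letter display by insert-and-absorb: start with one set holding
# all groups; for every significantly different pair, split any set that
# contains both; absorb subsets; label sets alphabetically.
cld_letters <- function(gl, pairs, alpha) {
  sets <- list(gl)
  sig <- pairs[pairs$p_value < alpha, , drop = FALSE]
  if (nrow(sig) > 0) for (i in seq_len(nrow(sig))) {
    a <- sig$group1[i]; b <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (u in seq_along(new_sets)) for (v in seq_along(new_sets)) {
      if (u != v && keep[u] && keep[v] &&
          all(new_sets[[u]] %in% new_sets[[v]]) &&
          !(u < v && identical(new_sets[[u]], new_sets[[v]])))
        if (length(new_sets[[u]]) < length(new_sets[[v]]) ||
            (identical(new_sets[[u]], new_sets[[v]]) && u > v))
          keep[u] <- FALSE
    }
    sets <- new_sets[keep]
  }
  lab <- stats::setNames(rep("", length(gl)), gl)
  for (j in seq_along(sets))
    for (g in sets[[j]]) lab[g] <- paste0(lab[g], letters[j])
  lab[lab == ""] <- NA_character_
  lab
}

#' @export
print.steel_dwass <- function(x, ...) {
  cat("Steel-Dwass all-pairs comparison\n")
  print(x$groups)
  invisible(x)
}
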