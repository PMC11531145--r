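#' Estimated sample coverage of a count vector
#'
#' Sample coverage is the probability that the next sequencing read belongs
#' to an OTU already observed in the sample. It is estimated from the
#' singleton and doubleton counts (Chao-Jost estimator):
#' \deqn{\hat C = 1 - \frac{f_1}{n}\,\frac{(n-1) f_1}{(n-1) f_1 + 2 f_2},}
#' where \eqn{n} is the read total and \eqn{f_1}, \eqn{f_2} are the numbers
#' of OTUs observed exactly once and twice.
#'
#' @param x A count vector for one sample, or a community matrix (coverage is
#'   then computed per row).
#' @return A coverage value in \[0, 1\], or a named vector per sample.
#' @export
sample_coverage <- function(x) {
  if (is.matrix(x)) {
    return(vapply(seq_len(nrow(x)), function(i) sample_coverage(x[i, ]),
                  numeric(1), USE.NAMES = FALSE) |>
             stats::setNames(rownames(x)))
  }
  n <- sum(x)
  if (n <= 0) stop("sample coverage is undefined for a zero-sum count vector")
  f1 <- sum(x == 1)
  f2 <- sum(x == 2)
  if (f1 == 0) return(1)
  a <- (n - 1) * f1
  1 - (f1 / n) * (a / (a + 2 * f2))
}

# Expected coverage of a without-replacement subsample of depth m,
# obtained by plugging the hypergeometric expectations of f1 and f2 into
# the coverage estimator.
expected_coverage_at_depth <- function(x, m) {
  x <- x[x > 0]
  n <- sum(x)
  if (m >= n) return(sample_coverage(x))
  if (m <= 1) return(0)
  # P(X_k = j) for X_k ~ Hypergeometric(total n, successes x_k, draws m)
  ef1 <- sum(exp(lchoose(n - x, m - 1) - lchoose(n, m) + log(x)))
  ef2 <- sum(exp(lchoose(n - x, m - 2) - lchoose(n, m) + lchoose(x, 2)))
  if (ef1 == 0) return(1)
  a <- (m - 1) * ef1
  1 - (ef1 / m) * (a / (a + 2 * ef2))
}

# Smallest depth whose expected coverage reaches the target (bisection on a
# monotone-in-practice grid; falls back to linear scan near the boundary).
depth_for_coverage <- function(x, target) {
  n <- sum(x)
  if (target <= 0) return(1L)
  lo <- 1L; hi <- as.integer(n)
  if (expected_coverage_at_depth(x, hi) < target)
    stop("full-depth coverage below target")
  while (hi - lo > 1L) {
    mid <- as.integer((lo + hi) %/% 2)
    if (expected_coverage_at_depth(x, mid) >= target) hi <- mid else lo <- mid
  }
  hi
}

# One multivariate-hypergeometric draw: subsample m reads without replacement.
subsample_counts <- function(x, m) {
  n <- sum(x)
  if (m >= n) return(x)
  picked <- sample.int(n, m)
  breaks <- c(0, cumsum(as.numeric(x)))
  tab <- tabulate(findInterval(picked, breaks, left.open = TRUE), nbins = length(x))
  as.integer(tab)
}

#' Coverage-based rarefaction of a community matrix
#'
#' Each sample is subsampled without replacement to the smallest depth whose
#' expected coverage reaches `target_coverage`. The default target is the
#' minimum estimated coverage across samples, so the shallowest-coverage
#' sample is returned unchanged and all samples are standardised to a common
#' coverage rather than a common depth. One draw is taken per sample;
#' results are reproducible for a fixed `seed`.
#'
#' @param counts Community matrix.
#' @param target_coverage Coverage target in \[0, 1\]; default
#'   `min(sample_coverage(counts))`.
#' @param seed Integer seed for the subsampling draws.
#' @return A rarefied community matrix (elementwise no greater than `counts`).
#' @export
coverage_rarefy <- function(counts, target_coverage = NULL, seed = 1) {
  counts <- validate_community(counts)
  if (nrow(counts) == 0) return(counts)
  cov <- sample_coverage(counts)
  if (is.null(target_coverage)) target_coverage <- min(cov)
  offending <- rownames(counts)[cov < target_coverage]
  if (length(offending) > 0)
    stop("full-depth coverage below target for sample(s): ",
         paste(offending, collapse = ", "))
  out <- counts
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (i in seq_len(nrow(counts))) {
    if (cov[i] <= target_coverage + 1e-12) next   # boundary sample: unchanged
    m <- depth_for_coverage(counts[i, ], target_coverage)
    out[i, ] <- subsample_counts(counts[i, ], m)
  }
  out
}

#' Sample-based OTU accumulation curve
#'
#' Mean number of distinct OTUs detected as samples are accumulated in
#' random order, averaged over `n_trials` orderings.
#'
#' @param counts Community matrix.
#' @param n_trials Number of random sample orderings.
#' @param seed Integer seed.
#' @return A tibble with columns `n_samples`, `mean_richness`.
#' @export
accumulation_curve <- function(counts, n_trials = 100, seed = 1) {
  counts <- validate_community(counts)
  stopifnot(nrow(counts) >= 1)
  pres <- counts > 0
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  n <- nrow(pres)
  acc <- matrix(0, n_trials, n)
  for (t in seq_len(n_trials)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, ncol(pres))
    for (k in seq_len(n)) {
      seen <- seen | pres[ord[k], ]
      acc[t, k] <- sum(seen)
    }
  }
  tibble::tibble(n_samples = seq_len(n), mean_richness = colMeans(acc))
}
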