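#' Centred log-ratio transform of a count matrix
#'
#' `log(counts + pseudocount)` centred per sample, the standard
#' compositional-data mapping before covariance estimation. Every row of the
#' result sums to zero.
#'
#' @param counts Community matrix (un-rarefied counts recommended).
#' @param pseudocount Added to all counts before the log (default 1).
#' @return A numeric samples x OTUs matrix of class `clr_matrix`.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  counts <- validate_community(counts)
  lg <- log(counts + pseudocount)
  out <- lg - rowMeans(lg)
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("clr_matrix", class(out))
  out
}

soft_threshold <- function(m, t) sign(m) * pmax(abs(m) - t, 0)

# ADMM for the latent-variable graphical lasso
#   min -logdet(R) + tr(Sigma R) + lambda ||S||_1,off + gamma tr(L)
#   s.t. R = S - L, L >= 0 (PSD), R > 0,
# with scaled dual variable U and fixed step rho. `gamma = Inf` (or
# latent = FALSE) fixes L = 0 and reduces to the plain graphical lasso.
admm_slr <- function(Sigma, lambda, gamma, rho = 1, max_iter = 500,
                     tol = 1e-5, init = NULL, latent = TRUE) {
  p <- nrow(Sigma)
  S <- if (is.null(init)) diag(diag(Sigma) + lambda) else init$S
  L <- if (is.null(init) || !latent) matrix(0, p, p) else init$L
  U <- if (is.null(init)) matrix(0, p, p) else init$U
  R <- S - L
  obj <- rep(NA_real_, max_iter)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # R-update: eigendecomposition solution of rho R - R^-1 = rho(S-L-U) - Sigma
    W <- rho * (S - L - U) - Sigma
    eW <- eigen((W + t(W)) / 2, symmetric = TRUE)
    rv <- (eW$values + sqrt(eW$values^2 + 4 * rho)) / (2 * rho)
    R <- eW$vectors %*% (rv * t(eW$vectors))
    # S-update: soft-threshold off-diagonals of R + L + U
    M <- R + L + U
    S_new <- soft_threshold(M, lambda / rho)
    diag(S_new) <- diag(M)
    # L-update: PSD projection of S - R - U shifted by gamma/rho
    if (latent) {
      N <- S_new - R - U - diag(gamma / rho, p)
      eN <- eigen((N + t(N)) / 2, symmetric = TRUE)
      lv <- pmax(eN$values, 0)
      L_new <- eN$vectors %*% (lv * t(eN$vectors))
    } else L_new <- L
    prim <- sqrt(sum((R - S_new + L_new)^2))
    dual <- rho * sqrt(sum((S_new - L_new - (S - L))^2))
    S <- S_new; L <- L_new
    U <- U + R - S + L
    # objective at the feasible point Theta = S - L (logged, not optimised:
    # ADMM iterates are not monotone in the raw objective)
    eTh <- eigen((S - L + t(S - L)) / 2, symmetric = TRUE, only.values = TRUE)$values
    obj[it] <- if (min(eTh) <= 0) Inf else
      -sum(log(eTh)) + sum(Sigma * (S - L)) +
      lambda * (sum(abs(S)) - sum(abs(diag(S)))) +
      (if (latent && is.finite(gamma)) gamma * sum(diag(L)) else 0)
    sc <- max(1, sqrt(sum(R^2)))
    if (prim / sc < tol && dual / sc < tol) { converged <- TRUE; break }
  }
  list(S = (S + t(S)) / 2, L = (L + t(L)) / 2, R = R, U = U,
       objective = obj[!is.na(obj)], iterations = it, converged = converged)
}

numeric_rank <- function(L, tol = 1e-8) {
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(1, max(ev)))
}

#' Sparse + low-rank inverse-covariance fit
#'
#' Solves the latent-variable graphical lasso
#' \deqn{\min_{S, L} -\log\det(S - L) + tr(\hat\Sigma (S - L)) +
#'   \lambda \|S\|_{1,off} + \gamma\, tr(L), \quad S - L \succ 0,\; L \succeq 0}
#' by ADMM. The trace penalty \eqn{\gamma} is tuned by bisection so that
#' `rank(L)` equals `target_rank` (ties broken toward smaller \eqn{\gamma});
#' `target_rank = 0` gives the plain graphical lasso. The sparse component
#' `S` carries the direct associations; its partial correlations are
#' \eqn{\rho_{uv} = -S_{uv} / \sqrt{S_{uu} S_{vv}}}.
#'
#' @param sigma Covariance/correlation estimate of the CLR data (symmetric
#'   positive semidefinite), or a `clr_matrix` (its correlation matrix is
#'   used).
#' @param n Number of samples behind `sigma` (needed for the BIC; inferred
#'   when `sigma` is a `clr_matrix`).
#' @param lambda Sparsity penalty.
#' @param target_rank Desired rank of the latent component, in \[0, 20\].
#' @param gamma Optional fixed trace penalty (skips the bisection).
#' @param control List: `rho`, `max_iter`, `tol`, `rank_tol`,
#'   `bisect_iter`.
#' @return An object of class `slr_fit`: `S`, `L`, `Theta = S - L`, `rank`,
#'   `lambda`, `gamma`, `partial_cor`, `bic`, `n_edges`, `objective`,
#'   `converged`.
#' @export
slr_fit <- function(sigma, n = NULL, lambda, target_rank = 0, gamma = NULL,
                    control = list()) {
  if (inherits(sigma, "clr_matrix")) {
    n <- nrow(sigma)
    sigma <- stats::cor(unclass(sigma))
  }
  stopifnot(!is.null(n), isSymmetric(unname(sigma), tol = 1e-8),
            target_rank >= 0, target_rank <= 20)
  ctl <- utils::modifyList(list(rho = 1, max_iter = 500, tol = 1e-6,
                                rank_tol = 1e-8, bisect_iter = 30), control)
  p <- nrow(sigma)
  if (target_rank == 0 && is.null(gamma)) {
    sol <- admm_slr(sigma, lambda, gamma = Inf, rho = ctl$rho,
                    max_iter = ctl$max_iter, tol = ctl$tol, latent = FALSE)
    gamma_used <- Inf
  } else if (!is.null(gamma)) {
    sol <- admm_slr(sigma, lambda, gamma, rho = ctl$rho,
                    max_iter = ctl$max_iter, tol = ctl$tol)
    gamma_used <- gamma
  } else {
    lo <- 1e-4; hi <- 2 * max(abs(sigma))
    sol_lo <- admm_slr(sigma, lambda, lo, rho = ctl$rho,
                       max_iter = ctl$max_iter, tol = ctl$tol)
    if (numeric_rank(sol_lo$L, ctl$rank_tol) < target_rank) {
      sol <- sol_lo; gamma_used <- lo
    } else {
      sol <- NULL; gamma_used <- NA
      best <- list(gap = Inf)
      init <- sol_lo
      for (i in seq_len(ctl$bisect_iter)) {
        mid <- (lo + hi) / 2
        cand <- admm_slr(sigma, lambda, mid, rho = ctl$rho,
                         max_iter = ctl$max_iter, tol = ctl$tol, init = init)
        rk <- numeric_rank(cand$L, ctl$rank_tol)
        gap <- abs(rk - target_rank)
        if (gap < best$gap || (gap == best$gap && mid < best$gamma))
          best <- list(gap = gap, gamma = mid, sol = cand, rank = rk)
        if (rk == target_rank) hi <- mid    # prefer smaller gamma at the target
        else if (rk > target_rank) lo <- mid
        else hi <- mid
        init <- cand
        if (hi - lo < 1e-6 * hi) break
      }
      sol <- best$sol; gamma_used <- best$gamma
    }
  }
  S <- sol$S; L <- sol$L
  Theta <- S - L
  eT <- eigen((Theta + t(Theta)) / 2, symmetric = TRUE, only.values = TRUE)$values
  edge_mask <- abs(S) > ctl$rank_tol & upper.tri(S)
  n_edges <- sum(edge_mask)
  rk <- numeric_rank(L, ctl$rank_tol)
  pc <- -S / sqrt(tcrossprod(diag(S)))
  diag(pc) <- 1
  bic <- n * (-sum(log(pmax(eT, 1e-12))) + sum(sigma * Theta)) +
    log(n) * (n_edges + rk * p - rk * (rk - 1) / 2)
  structure(list(S = S, L = L, Theta = Theta, rank = rk,
                 lambda = lambda, gamma = gamma_used, partial_cor = pc,
                 bic = bic, n_edges = n_edges, eigmin = min(eT),
                 objective = sol$objective, converged = sol$converged,
                 n = n, otu_ids = colnames(sigma)),
            class = "slr_fit")
}

#' @export
print.slr_fit <- function(x, ...) {
  cat(sprintf("SLR fit: p = %d, rank(L) = %d, %d edges, lambda = %.4g, BIC = %.1f%s\n",
              nrow(x$S), x$rank, x$n_edges, x$lambda, x$bic,
              if (x$converged) "" else " (ADMM not converged)"))
  invisible(x)
}

#' Choose the sparsity penalty by an edge-density ceiling
#'
#' Scans a geometric path of `lambda` values from the largest off-diagonal
#' covariance downwards, fitting the rank-0 graphical lasso at each, and
#' returns the smallest `lambda` (densest graph) whose edge density does
#' not exceed `max_density`.
#'
#' @param sigma Covariance/correlation matrix (or `clr_matrix`).
#' @param n Sample count (inferred from a `clr_matrix`).
#' @param max_density Maximum fraction of possible edges (default 0.05).
#' @param path_length Number of `lambda` values scanned.
#' @param control Passed to [slr_fit()].
#' @return A list with `lambda` and the scanned `path` tibble.
#' @export
choose_lambda <- function(sigma, n = NULL, max_density = 0.05,
                          path_length = 20, control = list()) {
  if (inherits(sigma, "clr_matrix")) {
    n <- nrow(sigma)
    sigma <- stats::cor(unclass(sigma))
  }
  p <- nrow(sigma)
  lmax <- max(abs(sigma[upper.tri(sigma)]))
  lams <- exp(seq(log(lmax), log(lmax * 0.01), length.out = path_length))
  dens <- numeric(path_length)
  for (i in seq_along(lams)) {
    f <- slr_fit(sigma, n, lambda = lams[i], target_rank = 0, control = control)
    dens[i] <- f$n_edges / (p * (p - 1) / 2)
  }
  okay <- which(dens <= max_density)
  lambda <- if (length(okay) > 0) lams[max(okay)] else lams[1]
  list(lambda = lambda,
       path = tibble::tibble(lambda = lams, density = dens))
}

#' Select the latent rank by BIC
#'
#' Fits the sparse + low-rank model at every rank in `ranks` (default 0 to
#' 20) for a fixed sparsity penalty and returns the fit with the smallest
#' \deqn{BIC = n[-\log\det\hat\Theta + tr(\hat\Sigma\hat\Theta)] +
#'  \ln(n)[|E(S)| + rp - r(r-1)/2].}
#'
#' @param clr A `clr_matrix` (or covariance matrix with `n` supplied).
#' @param n Sample count when `clr` is a covariance matrix.
#' @param ranks Integer vector of candidate latent ranks.
#' @param lambda Sparsity penalty; chosen by [choose_lambda()] when `NULL`.
#' @param max_density Edge-density ceiling for the lambda choice.
#' @param control Passed to [slr_fit()].
#' @return A list of class `bic_selection`: `best` (an `slr_fit`), `table`
#'   (tibble: rank, achieved_rank, bic, n_edges, fit_term), `lambda`.
#' @export
bic_select <- function(clr, n = NULL, ranks = 0:20, lambda = NULL,
                       max_density = 0.05, control = list()) {
  if (inherits(clr, "clr_matrix")) {
    n <- nrow(clr)
    sigma <- stats::cor(unclass(clr))
  } else sigma <- clr
  if (is.null(lambda))
    lambda <- choose_lambda(sigma, n, max_density, control = control)$lambda
  fits <- lapply(ranks, function(r)
    slr_fit(sigma, n, lambda = lambda, target_rank = r, control = control))
  bics <- vapply(fits, `[[`, numeric(1), "bic")
  fit_term <- vapply(fits, function(f)
    -sum(log(pmax(eigen(f$Theta, symmetric = TRUE, only.values = TRUE)$values,
                  1e-12))) + sum(sigma * f$Theta), numeric(1))
  tab <- tibble::tibble(rank = ranks,
                        achieved_rank = vapply(fits, `[[`, integer(1), "rank"),
                        bic = bics,
                        n_edges = vapply(fits, `[[`, numeric(1), "n_edges"),
                        fit_term = fit_term)
  structure(list(best = fits[[which.min(bics)]], table = tab,
                 lambda = lambda),
            class = "bic_selection")
}

#' @export
print.bic_selection <- function(x, ...) {
  cat(sprintf("BIC rank selection: best rank = %d (lambda = %.4g, BIC = %.1f)\n",
              x$best$rank, x$lambda, x$best$bic))
  invisible(x)
}
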