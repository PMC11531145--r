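#' Control parameters for jSDM fitting
#'
#' @param ridge Gaussian (L2) penalty on non-intercept coefficients and
#'   latent loadings; stabilises fits against separation when design blocks
#'   are wide relative to sample counts.
#' @param maxit Maximum optimiser iterations.
#' @param tol IRLS convergence tolerance on coefficients.
#' @param mc_samples Monte-Carlo draws used while fitting covariance models.
#' @param mc_samples_ll Draws used for the reported log-likelihood.
#' @param prob_clip Probability clipping bound for log-likelihood stability.
#' @return A list of class `jsdm_control`.
#' @export
jsdm_control <- function(ridge = 1, maxit = 300, tol = 1e-8,
                         mc_samples = 100, mc_samples_ll = 1000,
                         prob_clip = 1e-12) {
  structure(list(ridge = ridge, maxit = maxit, tol = tol,
                 mc_samples = mc_samples, mc_samples_ll = mc_samples_ll,
                 prob_clip = prob_clip), class = "jsdm_control")
}

# Ridge-penalised probit regression by iteratively reweighted least squares.
# `penalty` is a per-coefficient vector (0 for the intercept).
probit_irls <- function(X, y, penalty, maxit = 100, tol = 1e-8) {
  p <- ncol(X)
  b <- numeric(p)
  b[1] <- stats::qnorm(min(max(mean(y), 1e-3), 1 - 1e-3))
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% b), -8), 8)
    mu <- stats::pnorm(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    phi <- pmax(stats::dnorm(eta), 1e-10)
    w <- phi^2 / (mu * (1 - mu))
    z <- eta + (y - mu) / phi
    H <- crossprod(X, X * w) + diag(penalty, p)
    bn <- tryCatch(drop(solve(H, crossprod(X, w * z))),
                   error = function(e) b)
    if (max(abs(bn - b)) < tol) { b <- bn; converged <- TRUE; break }
    b <- bn
  }
  list(coef = b, converged = converged, iterations = it)
}

# Exact Bernoulli log-likelihood per OTU for probability matrix P.
bernoulli_ll <- function(P, Y, clip = 1e-12) {
  P <- pmin(pmax(P, clip), 1 - clip)
  colSums(Y * log(P) + (1 - Y) * log1p(-P))
}

# Monte-Carlo marginal log-likelihood of the latent-factor probit model,
# with per-OTU decomposition. Draws are supplied (common random numbers).
# Returns total, per-OTU vector (summing to total), per-cell marginal
# probabilities, and (optionally) gradients for the fitting path.
mc_loglik <- function(B, Lambda, X, Y, U, clip = 1e-12, grad = FALSE,
                      ridge = 0) {
  n <- nrow(Y); S <- ncol(Y); K <- nrow(U) / n; r <- ncol(Lambda)
  idx <- rep(seq_len(n), K)
  eta <- X %*% B
  eta_big <- eta[idx, , drop = FALSE] + U %*% t(Lambda)
  P <- stats::pnorm(eta_big)
  P <- pmin(pmax(P, clip), 1 - clip)
  Yb <- Y[idx, , drop = FALSE]
  l <- Yb * log(P) + (1 - Yb) * log1p(-P)
  A <- matrix(rowSums(l), n, K)            # A[i, k] = sum_s l_isk
  Amax <- apply(A, 1, max)
  lse <- Amax + log(rowMeans(exp(A - Amax)))
  total <- sum(lse)
  W <- exp(A - lse - log(K))               # posterior draw weights, rows sum to 1
  wvec <- as.vector(W)                     # ordered i fastest, matching idx
  out <- list(total = total)
  # per-OTU decomposition: posterior-weighted conditional log-likelihood
  # plus an equal share of the log-mean-exp mixing correction, so the
  # per-OTU vector sums exactly to the total.
  Cs <- colSums(l * wvec)
  out$per_otu <- Cs + (total - sum(Cs)) / S
  names(out$per_otu) <- colnames(Y)
  # fitted cell probabilities: posterior-weighted (empirical-Bayes) over the
  # latent draws, so the covariance factor contributes to in-sample fit
  pm <- rowsum(P * wvec, idx)
  dimnames(pm) <- dimnames(Y)
  out$prob <- pm
  if (grad) {
    score <- (Yb - P) * stats::dnorm(eta_big) / (P * (1 - P))
    Rw <- score * wvec
    M <- rowsum(Rw, idx)
    dB <- crossprod(X, M)
    dL <- t(crossprod(U, Rw))              # S x r
    pen_mask <- matrix(1, nrow(B), ncol(B)); pen_mask[1, ] <- 0
    out$grad_B <- dB - ridge * B * pen_mask
    out$grad_Lambda <- dL - ridge * Lambda
  }
  out
}

# Deterministic latent draws for n samples, K draws, r factors.
latent_draws <- function(n, K, r, seed) {
  with_seed(seed, matrix(stats::rnorm(n * K * r), n * K, r))
}

#' Fit one joint species distribution model
#'
#' Occurrence of each OTU is modelled with a probit link. Without the
#' covariance factor the model factorises into independent (ridge-penalised)
#' probit regressions, fitted exactly by IRLS. With the covariance factor,
#' residual fungus-fungus covariance is represented by `r` standard-normal
#' latent factors per sample with OTU-specific loadings, and the Monte-Carlo
#' marginal likelihood (common random numbers, `mc_samples` draws) is
#' maximised by L-BFGS with analytic gradients. Fits are deterministic for
#' fixed `seed` and control settings.
#'
#' @param design A `jsdm_design` from [prepare_inputs()].
#' @param spec A row of [model_lattice()], a model name such as
#'   `"P + S + Cov"`, or a logical vector with elements `P`, `S`, `Sp`,
#'   `Cov`.
#' @param r Number of latent factors (used only when Cov is included).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @param control A [jsdm_control()] list.
#' @param include_extra Include the extra covariate block (if present in the
#'   design) in every model containing at least one factor.
#' @return An object of class `jsdm_fit`.
#' @export
jsdm_fit <- function(design, spec, r = 8, seed = 1, control = jsdm_control(),
                     include_extra = FALSE) {
  stopifnot(inherits(design, "jsdm_design"))
  spec <- as_model_spec(spec)
  include <- c(P = spec$P, S = spec$S, Sp = spec$Sp, extra = include_extra)
  X <- assemble_design(design, include)
  Y <- design$Y
  n <- nrow(Y); S <- ncol(Y); p <- ncol(X)
  if (spec$Cov && r < 1) stop("covariance models need r >= 1")
  penalty <- c(0, rep(control$ridge, p - 1))

  irls <- lapply(seq_len(S), function(s) probit_irls(X, Y[, s], penalty,
                                                     maxit = 100, tol = control$tol))
  B <- vapply(irls, `[[`, numeric(p), "coef")
  dim(B) <- c(p, S)
  dimnames(B) <- list(colnames(X), colnames(Y))
  converged <- all(vapply(irls, `[[`, logical(1), "converged"))
  trace <- NULL

  if (!spec$Cov) {
    prob <- stats::pnorm(X %*% B)
    dimnames(prob) <- dimnames(Y)
    ll_per_otu <- bernoulli_ll(prob, Y, control$prob_clip)
    fit <- list(Lambda = NULL, r = 0L, prob = prob,
                ll_per_otu = ll_per_otu, ll_total = sum(ll_per_otu))
  } else {
    K <- control$mc_samples
    U <- latent_draws(n, K, r, seed)
    Lambda0 <- with_seed(seed + 1L, matrix(stats::rnorm(S * r, 0, 0.05), S, r))
    par0 <- c(B, Lambda0)
    unpack <- function(par) list(B = matrix(par[seq_len(p * S)], p, S),
                                 Lambda = matrix(par[-seq_len(p * S)], S, r))
    # fn and gr share one evaluation via a small cache (L-BFGS calls both
    # at the same parameter value)
    cache <- new.env(parent = emptyenv())
    evaluate <- function(par) {
      if (!is.null(cache$par) && identical(par, cache$par)) return(cache$val)
      th <- unpack(par)
      ml <- mc_loglik(th$B, th$Lambda, X, Y, U, control$prob_clip,
                      grad = TRUE, ridge = control$ridge)
      pen <- 0.5 * control$ridge * (sum(th$B[-1, ]^2) + sum(th$Lambda^2))
      val <- list(obj = -(ml$total - pen),
                  grad = -c(ml$grad_B, ml$grad_Lambda))
      cache$par <- par; cache$val <- val
      val
    }
    fn <- function(par) evaluate(par)$obj
    gr <- function(par) evaluate(par)$grad
    opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = control$maxit, factr = 1e8))
    th <- unpack(opt$par)
    B <- th$B; dimnames(B) <- list(colnames(X), colnames(Y))
    Lambda <- th$Lambda
    dimnames(Lambda) <- list(colnames(Y), paste0("LF", seq_len(r)))
    K_ll <- control$mc_samples_ll
    U_ll <- latent_draws(n, K_ll, r, seed + 7L)
    ml <- mc_loglik(B, Lambda, X, Y, U_ll, control$prob_clip)
    converged <- converged && opt$convergence == 0
    trace <- list(optim_convergence = opt$convergence,
                  optim_message = opt$message, value = -opt$value,
                  counts = opt$counts)
    fit <- list(Lambda = Lambda, r = as.integer(r), prob = ml$prob,
                ll_per_otu = ml$per_otu, ll_total = ml$total)
  }

  structure(c(list(spec = spec, name = spec$name, B = B, X = X, Y = Y,
                   seed = seed, control = control, converged = converged,
                   trace = trace, otu_ids = colnames(Y)),
              fit),
            class = "jsdm_fit")
}

as_model_spec <- function(spec) {
  lattice <- model_lattice()
  if (is.character(spec) && length(spec) == 1) {
    hit <- lattice[lattice$name == spec, ]
    if (nrow(hit) == 0) stop("unknown model name: ", spec)
    return(as.list(hit))
  }
  if (is.data.frame(spec)) return(as.list(spec[1, ]))
  if (is.logical(spec) && all(c("P", "S", "Sp", "Cov") %in% names(spec))) {
    hit <- lattice[lattice$P == spec[["P"]] & lattice$S == spec[["S"]] &
                     lattice$Sp == spec[["Sp"]] & lattice$Cov == spec[["Cov"]], ]
    return(as.list(hit))
  }
  stop("cannot interpret model spec")
}

#' @export
print.jsdm_fit <- function(x, ...) {
  cat(sprintf("jSDM fit: %s | %d samples x %d OTUs | r = %d | logLik = %.2f%s\n",
              x$name, nrow(x$Y), ncol(x$Y), x$r, x$ll_total,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Log-likelihood of a fitted jSDM
#'
#' For covariance models this is a Monte-Carlo estimate of the marginal
#' likelihood with common random numbers (deterministic for fixed seed);
#' for factor-only models it is the exact Bernoulli log-likelihood. The
#' per-OTU decomposition sums to the total.
#'
#' @param fit A `jsdm_fit`.
#' @param mc_samples Number of Monte-Carlo draws.
#' @param seed Seed for the draws (defaults to the fit's).
#' @return A list with `total` and `per_otu`.
#' @export
jsdm_log_likelihood <- function(fit, mc_samples = NULL, seed = NULL) {
  stopifnot(inherits(fit, "jsdm_fit"))
  if (fit$r == 0) {
    per <- bernoulli_ll(fit$prob, fit$Y, fit$control$prob_clip)
    return(list(total = sum(per), per_otu = per))
  }
  if (is.null(mc_samples)) mc_samples <- fit$control$mc_samples_ll
  if (is.null(seed)) seed <- fit$seed + 7L
  U <- latent_draws(nrow(fit$Y), mc_samples, fit$r, seed)
  ml <- mc_loglik(fit$B, fit$Lambda, fit$X, fit$Y, U, fit$control$prob_clip)
  list(total = ml$total, per_otu = ml$per_otu)
}

#' @export
logLik.jsdm_fit <- function(object, ...) {
  structure(object$ll_total,
            df = length(object$B) + length(object$Lambda),
            class = "logLik")
}

#' Predicted occurrence probabilities from a fitted jSDM
#'
#' Two prediction types are available for covariance models, mirroring the
#' conditional/marginal distinction of mixed models:
#' \describe{
#'   \item{`"conditional"`}{empirical-Bayes fitted values: draw-level probit
#'     probabilities averaged under the posterior weights of the latent
#'     factors given the observed community. These are the in-sample fitted
#'     values through which the covariance factor expresses itself.}
#'   \item{`"marginal"`}{latent factors integrated out (plain Monte-Carlo
#'     average); the calibration-relevant prediction for new samples.}
#' }
#' For factor-only models the two coincide with \eqn{\Phi(X \hat B)}.
#'
#' @param object A `jsdm_fit`.
#' @param type `"conditional"` or `"marginal"`.
#' @param mc_samples,seed Draw settings for the marginal average (defaults
#'   match the fit's reporting settings).
#' @param ... Unused.
#' @return A samples x OTUs probability matrix.
#' @export
predict.jsdm_fit <- function(object, type = c("conditional", "marginal"),
                             mc_samples = NULL, seed = NULL, ...) {
  type <- match.arg(type)
  if (object$r == 0 || type == "conditional") return(object$prob)
  if (is.null(mc_samples)) mc_samples <- object$control$mc_samples_ll
  if (is.null(seed)) seed <- object$seed + 7L
  n <- nrow(object$Y); K <- mc_samples
  U <- latent_draws(n, K, object$r, seed)
  idx <- rep(seq_len(n), K)
  eta <- (object$X %*% object$B)[idx, , drop = FALSE] + U %*% t(object$Lambda)
  pm <- rowsum(stats::pnorm(eta), idx) / K
  dimnames(pm) <- dimnames(object$Y)
  pm
}

#' Pooled ROC AUC of a fitted jSDM
#'
#' Rank-based area under the ROC curve over all (sample, OTU) cells pooled.
#'
#' @param fit A `jsdm_fit`, or a numeric matrix/vector of predicted
#'   probabilities.
#' @param response Binary observations matching `fit` (taken from the fit if
#'   omitted).
#' @param type Prediction type for `jsdm_fit` inputs (see
#'   [predict.jsdm_fit()]).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(fit, response = NULL, type = "conditional") {
  if (inherits(fit, "jsdm_fit")) {
    p <- as.vector(predict(fit, type = type))
    y <- as.vector(if (is.null(response)) fit$Y else response)
  } else {
    p <- as.vector(fit); y <- as.vector(response)
  }
  stopifnot(length(p) == length(y), all(y %in% c(0, 1)))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes present")
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
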