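# Shared fixtures and independent oracles for the test suite.

fast_ctl <- function(...) {
  jsdm_control(ridge = 1, mc_samples = 30, mc_samples_ll = 300, maxit = 60, ...)
}

# Null-calibration preset with light sequencing depths: depth only shapes the
# count layer, not the occurrence draws, so binary-data calibrations are
# unchanged while simulation is much cheaper.
light_null_params <- function() {
  ge <- default_guild_effects()
  ge$n_otus <- c(24L, 21L, 15L)
  ge[, c("plant_effect_sd", "soil_coupling", "spatial_effect_sd",
         "factor_loading_sd")] <- 0
  truth_params(n_positions = 124, mean_samples_per_position = 12,
               guild_effects = ge, n_latent_factors = 2,
               alpha_mean = qnorm(0.3), alpha_sd = 0,
               root_depth_mean = 2000, soil_depth_mean = 2e4,
               fixed_effort = TRUE)
}

# Minimal design wrapper for response-only model toys (intercept +/- Cov).
response_design <- function(Y) {
  n <- nrow(Y)
  structure(list(Y = Y, X_P = matrix(0, n, 0), X_S = matrix(0, n, 0),
                 X_Sp = matrix(0, n, 0), X_extra = NULL, metadata = NULL,
                 otu_ids = colnames(Y)),
            class = "jsdm_design")
}

named_counts <- function(m, prefix_s = "s", prefix_o = "o") {
  dimnames(m) <- list(paste0(prefix_s, seq_len(nrow(m))),
                      paste0(prefix_o, seq_len(ncol(m))))
  storage.mode(m) <- "integer"
  m
}

rank_auc <- function(score, positive) {
  r <- rank(score)
  n1 <- sum(positive); n0 <- sum(!positive)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Graphical lasso by block coordinate descent (Friedman-style), off-diagonal
# penalty only — independent of the package's ADMM path.
glasso_cd_oracle <- function(Sigma, lambda, tol = 1e-10, maxit = 2000) {
  p <- nrow(Sigma)
  W <- Sigma
  B <- matrix(0, p, p)
  for (it in seq_len(maxit)) {
    W_old <- W
    for (j in seq_len(p)) {
      idx <- setdiff(seq_len(p), j)
      W11 <- W[idx, idx]; s12 <- Sigma[idx, j]
      b <- B[idx, j]
      for (k in 1:200) {
        b_old <- b
        for (l in seq_along(idx)) {
          r <- s12[l] - sum(W11[l, -l] * b[-l])
          b[l] <- sign(r) * max(abs(r) - lambda, 0) / W11[l, l]
        }
        if (max(abs(b - b_old)) < tol) break
      }
      B[idx, j] <- b
      W[idx, j] <- W[j, idx] <- W11 %*% b
    }
    if (max(abs(W - W_old)) < tol * 10) break
  }
  Theta <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- setdiff(seq_len(p), j)
    th_jj <- 1 / (W[j, j] - sum(W[idx, j] * B[idx, j]))
    Theta[j, j] <- th_jj
    Theta[idx, j] <- Theta[j, idx] <- -B[idx, j] * th_jj
  }
  Theta
}

# Gauss-Hermite nodes/weights via Golub-Welsch (weight exp(-x^2)).
gauss_hermite <- function(k) {
  i <- seq_len(k - 1)
  J <- matrix(0, k, k)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(x = e$values, w = sqrt(pi) * e$vectors[1, ]^2)
}

# Poisson IRLS with log link and offset — independent of stats::glm.
poisson_irls_oracle <- function(X, y, offset, tol = 1e-12, maxit = 100) {
  b <- rep(0, ncol(X))
  b[1] <- log(sum(y) / sum(exp(offset)))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b) + offset
    mu <- exp(eta)
    z <- eta - offset + (y - mu) / mu
    bn <- drop(solve(crossprod(X, X * mu), crossprod(X, mu * z)))
    if (max(abs(bn - b)) < tol) return(bn)
    b <- bn
  }
  b
}

# Exhaustive d-min/d-max over integer redistributions of a row total across
# columns with fixed availabilities q (for small totals).
exhaustive_d_range <- function(total, q) {
  J <- length(q)
  grid <- as.matrix(expand.grid(rep(list(0:total), J - 1)))
  grid <- grid[rowSums(grid) <= total, , drop = FALSE]
  cnt <- cbind(grid, total - rowSums(grid))
  d <- apply(cnt, 1, function(cc) {
    p <- cc / total; s <- p > 0
    sum(p[s] * log(p[s] / q[s]))
  })
  c(min = min(d), max = max(d))
}

toy_metadata <- function(n_pos = 4, per_pos = 3, hosts = c("A", "B")) {
  pos <- rep(sprintf("p%02d", seq_len(n_pos)), each = per_pos)
  n <- length(pos)
  tibble::tibble(
    sample_id = sprintf("r%03d", seq_len(n)), kind = "root",
    position_id = pos,
    x = rep(seq_len(n_pos) * 10, each = per_pos),
    y = rep(seq_len(n_pos) %% 2 * 10, each = per_pos),
    host_plant = rep_len(hosts, n))
}
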