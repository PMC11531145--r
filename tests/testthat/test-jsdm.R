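test_that("design preparation applies the sampling-design filters", {
  ds <- simulate_dataset("assembly", seed = 3)
  md <- ds$metadata
  # drop the soil sample of one position: its root samples must vanish
  drop_pos <- md$position_id[md$kind == "soil"][1]
  soil_kept <- ds$soil[!rownames(ds$soil) %in%
                         md$sample_id[md$kind == "soil" &
                                        md$position_id == drop_pos], ,
                       drop = FALSE]
  expect_message(
    des <- prepare_inputs(ds$root, soil_kept, md, min_host_samples = 15),
    "without soil data")
  expect_false(any(des$metadata$position_id == drop_pos))
  # host boundary: a host with exactly min_host_samples samples is retained,
  # one below is excluded
  full <- prepare_inputs(ds$root, ds$soil, md, min_host_samples = 15)
  counts <- table(md$host_plant[md$kind == "root"])
  n_min <- min(counts[counts >= 15])
  expect_true(all(table(full$metadata$host_plant) >= 15))
  strict <- prepare_inputs(ds$root, ds$soil, md, min_host_samples = n_min + 1)
  expect_false(names(counts)[counts == n_min][1] %in%
                 unique(strict$metadata$host_plant))
  # supplementary mode: lower host threshold plus an extra covariate column
  ph <- tibble::tibble(position_id = unique(md$position_id), ph = runif(
    length(unique(md$position_id)), 4, 6))
  supp <- prepare_inputs(ds$root, ds$soil, md, min_host_samples = 15,
                         extra_covariates = ph)
  expect_identical(colnames(supp$X_extra), "E_ph")
  # soil axes respect the cumulative-contribution rule
  expect_identical(ncol(full$X_S), full$soil_ordination$n_axes)
})

test_that("intercept-only probit recovers the prevalence quantile", {
  set.seed(31)
  Y <- named_counts(matrix(rbinom(400, 1, 0.25), 400, 1), prefix_o = "OTU")
  des <- response_design(Y)
  f <- jsdm_fit(des, "Null", seed = 1, control = jsdm_control(ridge = 0))
  expect_equal(unname(f$B[1, 1]), qnorm(mean(Y)), tolerance = 1e-6)
})

test_that("factor-only fits match the standard probit-regression oracle", {
  # single binary covariate toy: exact MLE comparison
  set.seed(41)
  n <- 400
  x <- rbinom(n, 1, 0.5)
  Y <- named_counts(matrix(0L, n, 3))
  for (s in 1:3) {
    b <- c(-0.4, 0.9 * s / 3)
    Y[, s] <- rbinom(n, 1, pnorm(b[1] + b[2] * x))
  }
  des <- response_design(Y)
  des$X_P <- cbind(P_x = x)
  f <- jsdm_fit(des, "P", seed = 1, control = jsdm_control(ridge = 0))
  X <- cbind(1, x)
  for (s in 1:3) {
    g <- suppressWarnings(glm.fit(X, Y[, s], family = binomial("probit")))
    expect_equal(unname(f$B[, s]), unname(coef(g)), tolerance = 1e-4)
  }
})

test_that("log-likelihood closed forms hold", {
  Y <- named_counts(matrix(c(1L, 0L, 1L, 1L, 0L, 0L), 3, 2))
  # p = 0.5 everywhere
  ll <- rootfungi:::bernoulli_ll(matrix(0.5, 3, 2), Y)
  expect_equal(sum(ll), 6 * log(0.5))
  # perfect predictions (clipped): LL ~ 0
  llp <- rootfungi:::bernoulli_ll(ifelse(Y == 1, 1, 0), Y)
  expect_equal(sum(llp), 0, tolerance = 1e-9)
  # null-model LL equals the closed-form Bernoulli sum at the prevalences
  set.seed(5)
  Yb <- named_counts(matrix(rbinom(300, 1, 0.4), 100, 3))
  des <- response_design(Yb)
  f <- jsdm_fit(des, "Null", seed = 1, control = jsdm_control(ridge = 0))
  phat <- colMeans(Yb)
  closed <- sum(colSums(Yb) * log(phat) + (100 - colSums(Yb)) * log(1 - phat))
  expect_equal(f$ll_total, closed, tolerance = 1e-6)
})

test_that("Monte-Carlo marginal likelihood matches Gauss-Hermite quadrature", {
  set.seed(12)
  n <- 40; S <- 6
  a <- rnorm(S, 0, 0.5); L <- matrix(rnorm(S, 0, 1), S, 1)
  u <- rnorm(n)
  Y <- named_counts(matrix(rbinom(n * S, 1,
                                  pnorm(outer(rep(1, n), a) + u %*% t(L))),
                           n, S))
  q <- gauss_hermite(60)
  ll_gh <- sum(vapply(seq_len(n), function(i) {
    fu <- vapply(q$x, function(x) {
      p <- pnorm(a + sqrt(2) * x * L[, 1])
      prod(ifelse(Y[i, ] == 1, p, 1 - p))
    }, numeric(1))
    log(sum(q$w / sqrt(pi) * fu))
  }, numeric(1)))
  des <- response_design(Y)
  f <- jsdm_fit(des, "Cov", r = 1, seed = 1,
                control = jsdm_control(ridge = 0.1, mc_samples = 30, maxit = 20))
  f$B <- matrix(a, 1, S, dimnames = list("(Intercept)", colnames(Y)))
  f$Lambda <- matrix(L, S, 1, dimnames = list(colnames(Y), "LF1"))
  ll_mc <- jsdm_log_likelihood(f, mc_samples = 4000, seed = 99)
  expect_equal(ll_mc$total, ll_gh, tolerance = abs(ll_gh) * 0.005)
  expect_equal(sum(ll_mc$per_otu), ll_mc$total, tolerance = 1e-8)
})

test_that("latent-factor fits recover the loading correlation structure", {
  set.seed(11)
  n <- 300; S <- 40; r <- 2
  alpha <- rnorm(S, -0.3, 0.4)
  Lam <- matrix(rnorm(S * r, 0, 0.8), S, r)
  u <- matrix(rnorm(n * r), n, r)
  Y <- named_counts(matrix(rbinom(n * S, 1,
                                  pnorm(matrix(alpha, n, S, byrow = TRUE) +
                                          u %*% t(Lam))), n, S),
                    prefix_o = "OTU")
  des <- response_design(Y)
  fit <- jsdm_fit(des, "Cov", r = 2, seed = 1,
                  control = jsdm_control(ridge = 1, mc_samples = 100,
                                         mc_samples_ll = 500, maxit = 200))
  Ct <- cov2cor(tcrossprod(Lam) + diag(S))
  Ce <- cov2cor(tcrossprod(fit$Lambda) + diag(S))
  mae <- mean(abs(Ct[upper.tri(Ct)] - Ce[upper.tri(Ce)]))
  expect_lt(mae, 0.15)
})

test_that("fits are bit-reproducible for a fixed seed and control", {
  set.seed(77)
  Y <- named_counts(matrix(rbinom(50 * 8, 1, 0.4), 50, 8))
  des <- response_design(Y)
  f1 <- jsdm_fit(des, "Cov", r = 2, seed = 5, control = fast_ctl())
  f2 <- jsdm_fit(des, "Cov", r = 2, seed = 5, control = fast_ctl())
  expect_identical(f1$B, f2$B)
  expect_identical(f1$Lambda, f2$Lambda)
  expect_identical(f1$ll_total, f2$ll_total)
})

test_that("per-OTU log-likelihood ratios decompose the total", {
  ds <- simulate_dataset("assembly", seed = 2)
  des <- prepare_inputs(ds$root, ds$soil, ds$metadata, min_host_samples = 15)
  fa <- jsdm_fit(des, "P + S", seed = 1)
  fb <- jsdm_fit(des, "S", seed = 1)
  expect_equal(per_otu_llr(fa, fa), setNames(rep(0, ncol(des$Y)), des$otu_ids))
  llr <- per_otu_llr(fa, fb)
  expect_equal(sum(llr), fa$ll_total - fb$ll_total, tolerance = 1e-8)
})

test_that("factor attribution wires exactly the four stated comparisons", {
  pairs <- rootfungi:::attribution_pairs()
  expect_identical(pairs$model_a[pairs$factor == "Cov"], "Full (P + S + Sp + Cov)")
  expect_identical(pairs$model_b[pairs$factor == "Cov"], "P + S + Sp")
  expect_identical(pairs$model_a[pairs$factor == "P"], "P + S + Sp")
  expect_identical(pairs$model_b[pairs$factor == "P"], "S + Sp")
  expect_identical(pairs$model_b[pairs$factor == "S"], "P + Sp")
  expect_identical(pairs$model_b[pairs$factor == "Sp"], "P + S")
  # a lattice without the required comparator models is rejected
  ds <- simulate_dataset("assembly", seed = 2)
  des <- prepare_inputs(ds$root, ds$soil, ds$metadata, min_host_samples = 15)
  lat <- fit_lattice(des, r = 2, seed = 1, control = fast_ctl(),
                     models = c("Full (P + S + Sp + Cov)", "P + S + Sp"))
  expect_error(attribute_factors(lat), "lacks model")
})

test_that("pooled AUC matches pair counting and behaves at the extremes", {
  y <- c(1, 0, 1, 0)
  expect_equal(roc_auc(c(0.9, 0.1, 0.8, 0.2), y), 1)
  expect_equal(roc_auc(rep(0.5, 4), y), 0.5)
  # 4-cell toy against exhaustive pair counting
  p <- c(0.7, 0.6, 0.2, 0.4)
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  oracle <- mean(ifelse(p[pairs$i] > p[pairs$j], 1,
                        ifelse(p[pairs$i] == p[pairs$j], 0.5, 0)))
  expect_equal(roc_auc(p, y), oracle)
  set.seed(9)
  pp <- runif(300); yy <- rbinom(300, 1, pp)
  expect_equal(roc_auc(pp, yy),
               as.numeric(suppressMessages(pROC::auc(yy, pp))),
               tolerance = 1e-10)
})
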