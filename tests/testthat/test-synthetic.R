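test_that("landscape respects spacing and is reproducible", {
  p <- truth_params(n_positions = 30, arena = 100)
  l1 <- generate_landscape(p, seed = 4)
  expect_gte(min(dist(l1$positions[, c("x", "y")])), p$min_spacing)
  expect_identical(generate_landscape(p, seed = 4)$positions, l1$positions)
  # degenerate two-position case
  l2 <- generate_landscape(truth_params(n_positions = 2, arena = 40), seed = 1)
  expect_identical(nrow(l2$positions), 2L)
  expect_error(generate_landscape(truth_params(n_positions = 100, arena = 10)),
               "larger arena")
})

test_that("soil latent fields follow the Gaussian-process range", {
  base <- truth_params(n_positions = 60, arena = 120,
                       n_soil_extra_otus = 0)
  land <- generate_landscape(base, seed = 2)
  # near-infinite range: fields almost constant across positions
  geL <- default_guild_effects(); geL$spatial_range <- 1e6
  pL <- truth_params(n_positions = 60, arena = 120, guild_effects = geL,
                     n_soil_extra_otus = 0)
  zL <- simulate_soil(pL, land, seed = 3)$latents
  within_var_L <- mean(apply(zL, 2, var))
  # near-zero range: fields i.i.d. across positions, variance ~ 1
  geS <- default_guild_effects(); geS$spatial_range <- 1e-6
  pS <- truth_params(n_positions = 60, arena = 120, guild_effects = geS,
                     n_soil_extra_otus = 0)
  zS <- simulate_soil(pS, land, seed = 3)$latents
  within_var_S <- mean(apply(zS, 2, var))
  expect_lt(within_var_L, 0.05)
  expect_gt(within_var_S, 0.7)
  # empirical variogram increases with distance up to the range
  ge <- default_guild_effects(); ge$spatial_range <- 30
  pM <- truth_params(n_positions = 60, arena = 120, guild_effects = ge,
                     n_soil_extra_otus = 0)
  zM <- simulate_soil(pM, land, seed = 3)$latents
  d <- as.matrix(dist(land$positions[, c("x", "y")]))
  vario <- function(lo, hi) {
    sel <- d > lo & d <= hi
    mean(vapply(seq_len(ncol(zM)), function(j) {
      dif <- outer(zM[, j], zM[, j], `-`)^2
      mean(dif[sel])
    }, numeric(1)))
  }
  expect_lt(vario(0, 15), vario(15, 45))
  expect_lt(vario(15, 45), vario(45, 120))
})

test_that("root occurrences follow the probit model when effects are zero", {
  ge <- default_guild_effects()
  ge[, c("plant_effect_sd", "soil_coupling", "spatial_effect_sd",
         "factor_loading_sd")] <- 0
  pr <- truth_params(n_positions = 50, arena = 110, guild_effects = ge,
                     mean_samples_per_position = 10,
                     alpha_mean = qnorm(0.3), alpha_sd = 0,
                     root_depth_mean = 5000)
  land <- generate_landscape(pr, seed = 6)
  soil <- simulate_soil(pr, land, seed = 7)
  roots <- simulate_roots(pr, land, soil, seed = 8)
  prev <- mean(roots$truth$eta == qnorm(0.3))  # all linear predictors = alpha
  expect_equal(prev, 1)
  emp <- mean(pnorm(roots$truth$eta))
  y_emp <- mean((roots$table > 0))
  # observed occurrence <= latent presence (reads can drop a present OTU),
  # and latent presence matches Phi(alpha) within binomial error
  n_cells <- prod(dim(roots$table))
  expect_lt(abs(emp - 0.3), 1e-12)
  expect_lt(abs(y_emp - 0.3), 4 * sqrt(0.3 * 0.7 / n_cells) + 0.02)
  # per-plant prevalences equal within sampling error when plant effects are 0
  md <- roots$metadata[roots$metadata$kind == "root", ]
  by_host <- tapply(rowMeans(roots$table[md$sample_id, ] > 0), md$host_plant, mean)
  by_host <- by_host[table(md$host_plant) >= 20]
  expect_lt(max(by_host) - min(by_host), 0.1)
  # reproducibility
  roots2 <- simulate_roots(pr, land, soil, seed = 8)
  expect_identical(roots$table, roots2$table)
  pr_bad <- pr; pr_bad$n_latent_factors <- 1000
  expect_error(simulate_roots(pr_bad, land, soil, seed = 1), "latent dimension")
})

test_that("network dataset exposes a consistent sparse + low-rank truth", {
  nd <- generate_network_dataset(p = 20, n = 150, n_edges = 12, rank = 2,
                                 seed = 13)
  expect_identical(nd$counts, generate_network_dataset(p = 20, n = 150,
                                                       n_edges = 12, rank = 2,
                                                       seed = 13)$counts)
  ev <- eigen(nd$Theta, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  expect_lt(max(ev) / min(ev), 1e6)      # finite condition number
  expect_identical(nrow(nd$edges_true), 12L)
  expect_equal(sum(eigen(nd$L_true, symmetric = TRUE,
                         only.values = TRUE)$values > 1e-8), 2)
  # rank 0, no edges: Theta diagonal; CLR correlations are only the
  # compositional artefact (small off-diagonals)
  nd0 <- generate_network_dataset(p = 25, n = 600, n_edges = 0, rank = 0,
                                  seed = 14)
  expect_true(all(abs(nd0$Theta[upper.tri(nd0$Theta)]) < 1e-12))
  cc <- cor(unclass(clr_transform(nd0$counts)))
  expect_lt(median(abs(cc[upper.tri(cc)])), 0.15)
  # CLR correlation approaches the truth-implied correlation as n grows
  err <- vapply(c(100, 400, 1600), function(nn) {
    ndc <- generate_network_dataset(p = 15, n = nn, n_edges = 8, rank = 0,
                                    seed = 7)
    Ct <- cov2cor(solve(ndc$Theta))
    Ce <- cor(unclass(clr_transform(ndc$counts)))
    sqrt(sum((Ct - Ce)^2))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})
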