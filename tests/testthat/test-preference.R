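test_that("d' extremes match exhaustive integer redistribution", {
  N <- named_counts(matrix(c(10L, 0L, 0L, 10L), 2, 2, byrow = TRUE),
                    prefix_s = "f", prefix_o = "P")
  dp <- dprime(N)
  expect_equal(dp$d_prime, c(1, 1))
  # greedy bounds equal brute force for random small matrices (totals <= 12)
  set.seed(17)
  for (rep in 1:8) {
    J <- sample(2:4, 1)
    M <- matrix(rpois(2 * J, 2) + 1L, 2, J)
    q <- colSums(M) / sum(M)
    dp2 <- dprime(named_counts(M, prefix_s = "f", prefix_o = "P"))
    for (i in 1:2) {
      ex <- exhaustive_d_range(sum(M[i, ]), q)
      expect_equal(dp2$d_min[i], unname(ex["min"]), tolerance = 1e-10)
      expect_equal(dp2$d_max[i], unname(ex["max"]), tolerance = 1e-10)
    }
  }
})

test_that("d' is 0 for availability-proportional rows and scale-invariant", {
  N <- named_counts(matrix(c(4L, 6L, 2L, 3L), 2, 2, byrow = TRUE),
                    prefix_s = "f", prefix_o = "P")
  dp <- dprime(N)
  expect_equal(dp$d[1], 0)
  expect_equal(dp$d_prime[1], 0)
  # scale invariance holds up to the granularity of the integer
  # redistribution bounds (KL and d_max are exactly invariant; d_min falls
  # slightly as the grid refines)
  set.seed(23)
  M <- matrix(rpois(3 * 3, 3) + 1L, 3, 3)
  d1 <- dprime(named_counts(M, prefix_s = "f", prefix_o = "P"))
  d3 <- dprime(named_counts(M * 3L, prefix_s = "f", prefix_o = "P"))
  expect_equal(d1$d, d3$d, tolerance = 1e-10)
  expect_equal(d1$d_max, d3$d_max, tolerance = 1e-10)
  expect_lt(max(abs(d1$d_prime - d3$d_prime)), 0.02)
  # single partner column: flagged undefined
  single <- named_counts(matrix(c(5L, 3L), 2, 1), prefix_s = "f", prefix_o = "P")
  expect_true(all(is.na(dprime(single)$d_prime)))
})

test_that("bipartite construction counts co-observations and applies filters", {
  md <- toy_metadata(n_pos = 6, per_pos = 4)
  set.seed(2)
  occ <- named_counts(matrix(rbinom(24 * 5, 1, 0.5), 24, 5))
  rownames(occ) <- md$sample_id
  bp <- build_bipartite(occ, md, min_otu_occurrence = 5, min_host_samples = 5)
  # cell = number of samples carrying both labels
  for (o in colnames(bp$N)) {
    expect_equal(unname(bp$N[, o]),
                 unname(vapply(rownames(bp$N), function(f)
                   sum(occ[md$host_plant == o, f]), numeric(1))))
  }
  # OTU below the occurrence threshold is discarded (boundary strict <)
  occ2 <- occ; occ2[, 1] <- 0L; occ2[1:4, 1] <- 1L
  bp2 <- build_bipartite(occ2, md, min_otu_occurrence = 5, min_host_samples = 5)
  expect_false("o1" %in% rownames(bp2$N))
  bp3 <- build_bipartite(occ2, md, min_otu_occurrence = 4, min_host_samples = 5)
  expect_true("o1" %in% rownames(bp3$N))
  expect_error(build_bipartite(occ, md, min_otu_occurrence = 1000),
               "pass the occurrence filters")
})

test_that("within-position shuffles preserve per-position label multisets", {
  md <- toy_metadata(n_pos = 5, per_pos = 4, hosts = c("A", "B", "C"))
  md$host_plant[md$position_id == "p01"] <- "A"   # monoculture position
  for (s in 1:5) {
    perm <- shuffle_within_position(md, seed = s)
    expect_identical(perm[md$position_id == "p01"],
                     md$host_plant[md$position_id == "p01"])
    for (p in unique(md$position_id))
      expect_identical(sort(perm[md$position_id == p]),
                       sort(md$host_plant[md$position_id == p]))
  }
  # single-sample position label is fixed
  md1 <- md[c(1, 5:20), ]
  perm1 <- shuffle_within_position(md1, seed = 9)
  expect_identical(perm1[1], md1$host_plant[1])
})

test_that("two-position toy matches exhaustive enumeration of the null", {
  # 2 positions x 2 samples each, hosts A/B at both; OTU present in one
  # sample per position. Exhaustive null of N(otu, A): each position
  # contributes A or B with probability 1/2 -> N_A ~ Binomial(2, 1/2).
  md <- tibble::tibble(
    sample_id = paste0("r", 1:4), kind = "root",
    position_id = rep(c("p1", "p2"), each = 2),
    x = rep(c(0, 50), each = 2), y = 0,
    host_plant = c("A", "B", "A", "B"))
  occ <- named_counts(matrix(c(1L, 0L, 1L, 0L), 4, 1))
  rownames(occ) <- md$sample_id
  tdp <- two_dim_preference(occ, md, n_perm = 4000, seed = 2,
                            min_otu_occurrence = 1, min_host_samples = 1)
  expect_equal(unname(tdp$null_mean["o1", "A"]), 1, tolerance = 0.05)
  expect_equal(unname(tdp$null_sd["o1", "A"]), sqrt(0.5), tolerance = 0.05)
})

test_that("monoculture positions give a degenerate permutation null", {
  md <- toy_metadata(n_pos = 4, per_pos = 3)
  md$host_plant <- ifelse(md$position_id %in% c("p01", "p02"), "A", "B")
  set.seed(6)
  occ <- named_counts(matrix(rbinom(12 * 4, 1, 0.6), 12, 4))
  rownames(occ) <- md$sample_id
  pref <- standardized_preference(occ, md, n_perm = 50, seed = 1,
                                  min_otu_occurrence = 1, min_host_samples = 1)
  expect_true(all(pref$otu$degenerate))
  expect_true(all(pref$otu$z == 0))
})

test_that("the d' and pair statistics share one permutation stream per seed", {
  ds <- simulate_dataset("assembly", seed = 4)
  a <- standardized_preference(ds$root, ds$metadata, n_perm = 40, seed = 7,
                               min_otu_occurrence = 10, min_host_samples = 15)
  b <- two_dim_preference(ds$root, ds$metadata, n_perm = 40, seed = 7,
                          min_otu_occurrence = 10, min_host_samples = 15)
  expect_identical(a$pair$score, b$score)
  expect_identical(a$pair$null_mean, b$null_mean)
})

test_that("Benjamini-Hochberg q-values follow the step-up closed form", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.02, 0.9)
  expect_equal(bh_fdr(p), c(0.003, 0.03, 0.9))
  # monotone in p
  set.seed(1); pv <- runif(20)
  q <- bh_fdr(pv)
  expect_true(all(diff(q[order(pv)]) >= -1e-12))
})
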