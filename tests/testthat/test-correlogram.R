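test_that("identical communities at all positions give a flagged result", {
  md <- toy_metadata(n_pos = 6, per_pos = 1)
  comm <- named_counts(matrix(1L, 6, 5))
  rownames(comm) <- md$sample_id
  res <- suppressWarnings(mantel_correlogram(comm, md, n_perm = 50, seed = 1))
  expect_true(all(is.na(res$r)))
  expect_identical(attr(res, "flag"), "zero community variance")
})

test_that("two spatial blocks with distinct communities give positive within-block r", {
  # 6 positions: two tight blocks 100 m apart, block-specific OTU sets
  md <- tibble::tibble(
    sample_id = paste0("s", 1:6), kind = "root",
    position_id = paste0("p", 1:6),
    x = c(0, 5, 10, 100, 105, 110), y = 0, host_plant = "A")
  comm <- named_counts(rbind(
    matrix(rep(c(1L, 1L, 1L, 0L, 0L, 0L), 3), 3, 6, byrow = TRUE),
    matrix(rep(c(0L, 0L, 0L, 1L, 1L, 1L), 3), 3, 6, byrow = TRUE)))
  rownames(comm) <- md$sample_id
  res <- suppressWarnings(
    mantel_correlogram(comm, md, breaks = c(0, 15, 80, 120),
                       n_perm = 200, seed = 2))
  # direct-formula oracle for the first class
  dgeo <- as.matrix(dist(md[, c("x", "y")]))
  deco <- as.matrix(vegan::vegdist(comm, "jaccard", binary = TRUE))
  low <- lower.tri(dgeo)
  ind <- as.numeric(dgeo[low] <= 15)
  r_direct <- -cor(deco[low], ind)
  expect_equal(res$r[1], r_direct, tolerance = 1e-12)
  expect_gt(res$r[1], 0)              # within-block class: positive
  expect_lt(res$r[res$class_mid_m > 80], 0)  # between-block class: negative
})

test_that("correlogram r values agree with the vegan reference", {
  set.seed(99)
  np <- 40
  md <- tibble::tibble(sample_id = paste0("s", 1:np), kind = "root",
                       position_id = paste0("p", 1:np),
                       x = runif(np, 0, 100), y = runif(np, 0, 100),
                       host_plant = "A")
  comm <- named_counts(matrix(rbinom(np * 30, 1, 0.4), np, 30))
  rownames(comm) <- md$sample_id
  res <- suppressWarnings(mantel_correlogram(comm, md, n_perm = 49, seed = 1))
  D <- vegan::vegdist(comm, "jaccard", binary = TRUE)
  ref <- vegan::mantel.correlog(D, XY = as.matrix(md[, c("x", "y")]),
                                n.class = nrow(res), nperm = 9,
                                cutoff = FALSE)
  # identical class construction from class 2 onwards (vegan treats the
  # lowest boundary inclusively in its own way); compare overlapping classes
  expect_equal(res$r[-1], unname(ref$mantel.res[-1, 3]), tolerance = 1e-10)
})

test_that("guild subsetting restricts the community before pooling", {
  ds <- simulate_dataset("assembly", seed = 5)
  gm <- ds$guilds
  one_guild <- gm[gm$guild == "EcMF", ]
  sub_comm <- ds$root[, intersect(colnames(ds$root), one_guild$otu_id)]
  a <- suppressWarnings(mantel_correlogram(ds$root, ds$metadata, n_perm = 30,
                                           seed = 3, guild_map = gm,
                                           guild = "EcMF"))
  b <- suppressWarnings(mantel_correlogram(sub_comm, ds$metadata, n_perm = 30,
                                           seed = 3))
  expect_equal(a$r, b$r)
  # single-guild data: subset equals the all-guild correlogram
  gm_all <- tibble::tibble(otu_id = colnames(sub_comm), guild = "EcMF")
  c2 <- suppressWarnings(mantel_correlogram(sub_comm, ds$metadata, n_perm = 30,
                                            seed = 3, guild_map = gm_all,
                                            guild = "EcMF"))
  expect_equal(b$r, c2$r)
  expect_error(mantel_correlogram(ds$root, ds$metadata, guild = "EcMF"),
               "guild_map")
})

test_that("position-level pooling is idempotent", {
  ds <- simulate_dataset("assembly", seed = 6)
  md <- ds$metadata[ds$metadata$kind == "root", ]
  pooled <- rowsum((ds$root > 0) + 0L, md$position_id[
    match(rownames(ds$root), md$sample_id)])
  pooled <- (pooled > 0) + 0L
  md_pos <- md[!duplicated(md$position_id), ]
  md_pos$sample_id <- md_pos$position_id
  rownames(pooled) <- rownames(pooled)
  a <- suppressWarnings(mantel_correlogram(ds$root, ds$metadata, n_perm = 30,
                                           seed = 4))
  b <- suppressWarnings(mantel_correlogram(pooled, md_pos, n_perm = 30,
                                           seed = 4))
  expect_equal(a$r, b$r)
})
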