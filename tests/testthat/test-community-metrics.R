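test_that("diversity indices match direct formula evaluation", {
  m <- matrix(c(25, 25, 25, 25), 1, 4)
  tab <- community_table(m, 1)
  d <- rarefy_diversity(tab, depth = 100, reps = 1, seed = 1)
  expect_equal(d$richness, 4)
  expect_equal(d$shannon, log(4), tolerance = 1e-12)
  expect_equal(d$pielou, 1, tolerance = 1e-12)

  tab1 <- community_table(matrix(c(50, 0), 1, 2), 1)
  d1 <- rarefy_diversity(tab1, depth = 50, reps = 1, seed = 1)
  expect_equal(d1$richness, 1)
  expect_equal(d1$shannon, 0)
  expect_equal(d1$pielou, 0)                  # 0/0 convention

  tab2 <- community_table(matrix(c(6, 2), 1, 2), 1)
  d2 <- rarefy_diversity(tab2, depth = 8, reps = 1, seed = 1)
  expect_equal(d2$shannon, -(0.75 * log(0.75) + 0.25 * log(0.25)),
               tolerance = 1e-12)
  expect_equal(d2$shannon, 0.5623351, tolerance = 1e-6)
})

test_that("rarefaction errors name the shallow sample and is unbiased", {
  m <- rbind(d01 = c(100, 100), d02 = c(5, 5))
  tab <- community_table(m, c(1, 2))
  expect_error(rarefy_diversity(tab, depth = 50), "d02")
  # unbiasedness: expected rarefied proportion equals the input proportion
  big <- community_table(matrix(c(600, 200, 200), 1, 3), 1)
  props <- replicate(200, {
    sub <- suppressWarnings(vegan::rrarefy(big$counts, 100))
    sub[1, 1] / 100
  })
  expect_lt(abs(mean(props) - 0.6), 3 * sd(props) / sqrt(200))
})

test_that("Bray-Curtis matches the closed form and its bounds", {
  m <- rbind(a = c(6, 2), b = c(2, 2), c = c(6, 2), d = c(0, 5))
  tab <- community_table(m, 1:4)
  bc <- as.matrix(bray_curtis(tab))
  expect_equal(bc["a", "b"], 1 - 8 / 12, tolerance = 1e-12)
  expect_equal(bc["a", "c"], 0)               # identical samples
  expect_equal(bc["a", "d"], 1 - 2 * 2 / 13, tolerance = 1e-12)
  m2 <- rbind(c(5, 0), c(0, 7))
  expect_equal(as.vector(bray_curtis(community_table(m2, 1:2))), 1)  # disjoint
  set.seed(30)
  tabr <- random_table(8, 12, seed = 30)
  bcr <- as.matrix(bray_curtis(tabr))
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(bcr[i, j],
                 oracle_bray_curtis(tabr$counts[i, ], tabr$counts[j, ]),
                 tolerance = 1e-12)
  expect_true(all(bcr >= 0 & bcr <= 1))
  expect_error(bray_curtis(community_table(rbind(c(1, 1), c(0, 0)), 1:2)),
               "zero total")
})

test_that("NMDS embeds identical samples together and exact geometry at low stress", {
  set.seed(14)
  pts <- matrix(rnorm(20 * 3), 20, 3)
  d <- dist(pts)
  ord <- nmds(d, k = 3, restarts = 5, seed = 2)
  expect_lte(ord$stress, 0.01)                 # exactly embeddable cloud
  expect_equal(colMeans(ord$points), rep(0, 3), tolerance = 1e-8,
               ignore_attr = TRUE)
  # duplicated rows -> coincident embedding
  m <- rbind(c(10, 0, 5), c(10, 0, 5), c(0, 10, 5), c(3, 3, 3), c(8, 1, 1))
  bc <- bray_curtis(community_table(m, 1:5))
  ord2 <- nmds(bc, k = 2, restarts = 10, seed = 3)
  expect_lt(sqrt(sum((ord2$points[1, ] - ord2$points[2, ])^2)), 1e-4)
  expect_error(nmds(bc, k = 5), "smaller than the number of samples")
})

test_that("NMDS axis orientation follows sampling day and seed is reproducible", {
  run <- cached_run(11)
  bc <- bray_curtis(run$community)
  o1 <- nmds(bc, k = 3, restarts = 5, seed = 9,
             sample_days = run$community$sample_days)
  o2 <- nmds(bc, k = 3, restarts = 5, seed = 9,
             sample_days = run$community$sample_days)
  expect_identical(o1$points, o2$points)
  for (j in 1:3)
    expect_gte(cor(o1$points[, j], run$community$sample_days), 0)
})

test_that("Ward + elbow staging recovers three planted blobs exactly", {
  set.seed(77)
  centers <- rbind(c(0, 0), c(8, 0), c(0, 8))
  pts <- do.call(rbind, lapply(1:3, function(i)
    sweep(matrix(rnorm(20, 0, 0.4), 10, 2), 2, centers[i, ], "+")))
  st <- cluster_stages(dist(pts), k_max = 8)
  expect_equal(st$k, 3)
  expect_identical(st$labels, rep(1:3, each = 10))
  st1 <- cluster_stages(dist(pts), k = 1)
  expect_true(all(st1$labels == 1))
  expect_warning(cluster_stages(dist(pts[1:5, ]), k_max = 8), "k_max")
})

test_that("indicator point-biserial equals the Pearson dummy-variable oracle", {
  A <- matrix(c(2, 0, 1, 0), 4, 1, dimnames = list(NULL, "t1"))
  res <- indicator_taxa(A, stages = c(1, 2, 1, 2), permutations = 99,
                        seed = 1)
  r <- res$r_pb[res$stage == 1]
  expect_equal(r, 1.5 / sqrt(2.75), tolerance = 1e-10)
  expect_equal(r, 0.9045340, tolerance = 1e-6)
  # perfect separation
  A2 <- matrix(c(5, 5, 0, 0), 4, 1, dimnames = list(NULL, "t1"))
  res2 <- indicator_taxa(A2, stages = c(1, 1, 2, 2), permutations = 99,
                         seed = 1)
  expect_equal(res2$r_pb[res2$stage == 1], 1)
  # random tables against the brute-force oracle
  set.seed(41)
  for (rep in 1:20) {
    A3 <- matrix(runif(60), 10, 6,
                 dimnames = list(NULL, paste0("t", 1:6)))
    lab <- sample(1:3, 10, replace = TRUE)
    while (length(unique(lab)) < 2) lab <- sample(1:3, 10, replace = TRUE)
    res3 <- indicator_taxa(A3, lab, permutations = 9, seed = rep)
    for (s in sort(unique(lab))) {
      memb <- as.numeric(lab == s)
      for (tx in 1:6) {
        got <- res3$r_pb[res3$stage == s & res3$taxon == paste0("t", tx)]
        expect_equal(got, oracle_point_biserial(A3[, tx], memb),
                     tolerance = 1e-10)
      }
    }
  }
  # constant taxon
  A4 <- matrix(c(1, 1, 1, 1, 0, 2, 0, 2), 4, 2,
               dimnames = list(NULL, c("const", "var")))
  res4 <- indicator_taxa(A4, c(1, 1, 2, 2), permutations = 49, seed = 2)
  expect_equal(res4$r_pb[res4$taxon == "const"], c(0, 0))
  expect_equal(res4$p_value[res4$taxon == "const"], c(1, 1))
})

test_that("dissimilarity structure summarises gaps and stages correctly", {
  m <- matrix(rep(c(5, 5, 5), 4), 4, 3, byrow = TRUE)
  tab <- community_table(m, 1:4)
  ds <- dissimilarity_structure(bray_curtis(tab), 1:4)
  expect_true(all(ds$gap_curve$mean_dissimilarity == 0))
  expect_equal(ds$gap_curve$n_pairs[ds$gap_curve$gap == 1], 3)  # n - 1 pairs
  run <- cached_run(11)
  bc <- bray_curtis(run$community)
  ds2 <- dissimilarity_structure(bc, run$community$sample_days,
                                 run$truth$stages)
  # drifting succession: dissimilarity grows with time gap
  rho <- cor(ds2$gap_curve$gap, ds2$gap_curve$mean_dissimilarity,
             method = "spearman")
  expect_gt(rho, 0.8)
  expect_equal(sort(unique(ds2$stage_dispersion$stage)), 1:3)
})
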