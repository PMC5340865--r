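test_that("rarefaction subsamples to exact depth, deterministically", {
  ft <- random_table(51, n_samples = 5, n_features = 20, max_count = 100)
  depth <- min(rowSums(ft)) - 5
  r1 <- rarefy(ft, depth, seed = 7)
  r2 <- rarefy(ft, depth, seed = 7)
  expect_identical(unclass(r1)[, ], unclass(r2)[, ])
  expect_true(all(rowSums(r1) == depth))
  expect_true(all(unclass(r1) <= unclass(ft)[rownames(r1), ]))
  # a sample already at the target depth is returned unchanged
  exact <- feature_table(matrix(c(3L, 2L), 1, 2,
                                dimnames = list("s", c("AA", "CC"))))
  expect_equal(unclass(rarefy(exact, 5, seed = 1))[, ],
               unclass(exact)[, ])
  expect_error(rarefy(ft, 0, seed = 1), "positive")
  # shallow samples are dropped and recorded
  deep <- rarefy(ft, max(rowSums(ft)), seed = 1)
  expect_true(length(attr(deep, "dropped_samples")) > 0)
})

test_that("observed richness counts detected features", {
  expect_equal(observed_richness(c(3, 0, 1)), 2L)
  expect_equal(observed_richness(c(0, 0)), 0L)
  ft <- random_table(52)
  r <- rarefy(ft, min(rowSums(ft)), seed = 2)
  expect_true(all(observed_richness(r) <=
                    observed_richness(ft)[rownames(r)]))
})

test_that("Bray-Curtis matches its formula and bounds", {
  expect_equal(bray_curtis(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 2)), 1)
  expect_equal(bray_curtis(c(6, 0, 2), c(2, 2, 0)), 8 / 12)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(1, 2), c(1, 2, 3)), "length")
  withr::with_seed(8, {
    for (i in 1:50) {
      u <- runif(10); v <- runif(10)
      expect_equal(bray_curtis(u, v), sum(abs(u - v)) / sum(u + v),
                   tolerance = 1e-12)
      expect_equal(bray_curtis(u, v), bray_curtis(v, u))
      expect_true(bray_curtis(u, v) >= 0 && bray_curtis(u, v) <= 1)
    }
  })
})

test_that("distance_matrix is frequency-based and consistent with pairwise calls", {
  ft <- random_table(53, n_samples = 4, n_features = 8)
  d <- distance_matrix(ft)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  freq <- relative_frequencies(ft)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(d[i, j], bray_curtis(freq[i, ], freq[j, ]))
  }
  # depth scaling of one sample leaves its distances unchanged
  scaled <- unclass(ft); scaled[2, ] <- scaled[2, ] * 10
  expect_equal(distance_matrix(feature_table(scaled)), d)
  # duplicated sample has zero distance to its twin
  dup <- unclass(ft); dup[3, ] <- dup[1, ] * 2
  rownames(dup)[3] <- "twin"
  expect_equal(distance_matrix(feature_table(dup))[1, 3], 0)
})

test_that("PCoA recovers Euclidean configurations", {
  # three collinear points at 0, 1, 2
  d_line <- as.matrix(dist(matrix(c(0, 1, 2), 3, 1)))
  ord <- pcoa(d_line)
  expect_equal(ncol(ord$coordinates), 1)  # second eigenvalue ~ 0
  expect_equal(dist(ord$coordinates)[1:3], dist(matrix(c(0, 1, 2)))[1:3],
               tolerance = 1e-9, ignore_attr = TRUE)
  # random planar points: pairwise distances reproduced within 1e-9
  withr::with_seed(9, pts <- matrix(rnorm(14), 7, 2))
  d2 <- as.matrix(dist(pts))
  ord2 <- pcoa(d2)
  expect_equal(as.matrix(dist(ord2$coordinates)), d2, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_true(all(diff(ord2$eigenvalues) <= 1e-8))
  expect_equal(sum(ord2$proportion_explained), 1)
  # duplicated sample gets identical coordinates
  d3 <- as.matrix(dist(pts[c(1, 1, 2, 3), ]))
  ord3 <- pcoa(d3)
  expect_equal(ord3$coordinates[1, ], ord3$coordinates[2, ],
               tolerance = 1e-9)
  expect_warning(pcoa(d2, n_axes = 10), "truncating")
})

test_that("Kruskal-Wallis matches hand computation and handles degenerate ties", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  expect_equal(kw$statistic, 7.2)  # 12/(9*10) * (36+225+576)/3 - 30
  expect_equal(kw$df, 2)
  same <- kruskal_wallis(list(c(5, 5), c(5, 5, 5)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("Kruskal-Wallis H matches an independent rank-sum oracle with ties", {
  oracle_h <- function(groups) {
    x <- unlist(groups); g <- rep(seq_along(groups), lengths(groups))
    n <- length(x); r <- rank(x)
    h <- 12 / (n * (n + 1)) *
      sum(tapply(r, g, sum)^2 / tabulate(g)) - 3 * (n + 1)
    ties <- table(x)
    h / (1 - sum(ties^3 - ties) / (n^3 - n))
  }
  withr::with_seed(10, {
    for (i in 1:200) {
      k <- sample(2:4, 1)
      groups <- lapply(seq_len(k), function(j)
        sample(1:6, sample(3:8, 1), replace = TRUE))  # heavy ties
      if (diff(range(unlist(groups))) == 0) next
      got <- kruskal_wallis(groups)
      expect_equal(got$statistic, oracle_h(groups), tolerance = 1e-10)
      expect_equal(got$p_value,
                   pchisq(got$statistic, k - 1, lower.tail = FALSE))
    }
  })
})

test_that("permutation p-values are calibrated on exchangeable data", {
  withr::with_seed(11, {
    p <- replicate(60, {
      groups <- list(rnorm(5), rnorm(5))
      kruskal_wallis(groups, method = "permutation", n_perm = 199,
                     seed = sample.int(1e6, 1))$p_value
    })
  })
  expect_gt(mean(p < 0.05), 0)  # occasionally rejects
  expect_lt(mean(p < 0.05), 0.15)  # but near nominal size
})

test_that("class taxonomy summary conserves mass per study", {
  ft <- toy_table(matrix(c(10, 0, 0, 10), 2, 2), c("s1", "s2"),
                  c("AAAA", "CCCC"))
  md <- data.frame(sample_id = c("s1", "s2"), study_id = "st1")
  tax <- data.frame(feature_id = c("AAAA", "CCCC"),
                    lineage = c("k__B; p__X; c__ClassA",
                                "k__B; p__Y; c__ClassB"))
  cs <- class_taxonomy_summary(ft, tax, md)
  expect_equal(sort(unname(cs["st1", ])), c(0.5, 0.5))
  # single class saturates
  tax1 <- data.frame(feature_id = c("AAAA", "CCCC"),
                     lineage = rep("k__B; p__X; c__OnlyOne", 2))
  expect_equal(unname(class_taxonomy_summary(ft, tax1, md)[1, 1]), 1)
  # features missing from the taxonomy land in unclassified, totals still 1
  tax_missing <- tax[1, , drop = FALSE]
  cs2 <- class_taxonomy_summary(ft, tax_missing, md)
  expect_true("unclassified" %in% colnames(cs2))
  expect_equal(sum(cs2["st1", ]), 1)
})

test_that("sweep results are reproducible and consistent at depth zero", {
  cfg <- sim_config(n_features = 80, n_blooms = 2, depth = 800,
                    bloom_growth_rates = c(2, 1.6), n_frozen_studies = 2,
                    samples_per_study = 15, n_subjects = 2,
                    age_masked_features = c(8, 0))
  sim <- simulate_cohort_studies(cfg, 3)
  blooms <- sim$truth$bloom_sequences
  sw1 <- age_diversity_sweep(sim$tables$shipped, sim$metadata, blooms,
                             rarefaction_depth = 100, seed = 5)
  sw2 <- age_diversity_sweep(sim$tables$shipped, sim$metadata, blooms,
                             rarefaction_depth = 100, seed = 5)
  expect_identical(sw1$statistic, sw2$statistic)
  expect_equal(nrow(sw1), length(blooms) + 1)
  expect_true(all(sw1$p_value > 0 & sw1$p_value <= 1))
  # depth-0-only sweep equals the direct unfiltered test
  sw0 <- age_diversity_sweep(sim$tables$shipped, sim$metadata, blooms,
                             rarefaction_depth = 100, seed = 5, depths = 0)
  rar <- rarefy(sim$tables$shipped, 100, seed = 5)
  age <- sim$metadata$age_category[match(rownames(rar),
                                         sim$metadata$sample_id)]
  direct <- kruskal_wallis(split(as.numeric(observed_richness(rar)), age))
  expect_equal(sw0$statistic[1], direct$statistic)
  expect_equal(sw0$p_value[1], direct$p_value)

  merged <- merge_tables(sim$tables)
  d1 <- suppressWarnings(cross_study_distance_sweep(
    merged, sim$metadata, blooms, n_pairs = 50, seed = 5))
  d2 <- suppressWarnings(cross_study_distance_sweep(
    merged, sim$metadata, blooms, n_pairs = 50, seed = 5))
  expect_identical(d1$mean_distance, d2$mean_distance)
  expect_equal(sort(unique(d1$depth)), 0:2)
  expect_equal(nrow(d1), 3 * 3)  # 3 study pairs x 3 depths
})

test_that("exhaustive pair enumeration matches the sweep mean on tiny studies", {
  ft <- random_table(61, n_samples = 6, n_features = 10)
  md <- data.frame(sample_id = rownames(ft),
                   study_id = rep(c("a", "b"), each = 3))
  # with-replacement draws over all 9 cross pairs converge to the
  # exhaustive mean; at large n_pairs the MC error is tiny
  sw <- cross_study_distance_sweep(ft, md, colnames(ft)[1],
                                   depths = 0, n_pairs = 20000, seed = 3)
  freq <- relative_frequencies(ft)
  exhaustive <- mean(outer(1:3, 4:6, Vectorize(function(i, j)
    bray_curtis(freq[i, ], freq[j, ]))))
  expect_equal(sw$mean_distance[1], exhaustive, tolerance = 0.01)
})
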