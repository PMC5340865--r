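test_that("relative_frequencies normalizes rows and drops empty samples", {
  ft <- toy_table(matrix(c(3, 0, 1, 0), 2, 2))
  expect_warning(freq <- relative_frequencies(ft), "zero-total")
  expect_equal(nrow(freq), 1)
  expect_equal(unname(freq[1, ]), c(0.75, 0.25))
  expect_equal(attr(freq, "dropped_samples"), "s2")
  single <- toy_table(matrix(c(4, 0), 1, 2), "s1")
  expect_equal(unname(relative_frequencies(single)[1, ]), c(1, 0))
})

test_that("storage fold changes follow the detection-floor rules", {
  # equal depths; fill feature keeps both samples at the same total
  fix <- paired_storage(c(10, 4, 2, 984), c(80, 7, 40, 873))
  sfc <- storage_fold_changes(fix$table, fix$metadata)
  cmp <- sfc$comparisons
  expect_equal(cmp$log2fc[1], 3)           # log2(80/10)
  expect_true(cmp$excluded[2])             # both 4 and 7 below floor
  expect_true(is.na(cmp$log2fc[2]))
  expect_equal(cmp$log2fc[3], 2)           # clamp 2 -> 10, log2(40/10)
  expect_equal(sfc$max_fold$max_fold[1], 8)
  expect_true(is.na(sfc$max_fold$max_fold[2]))  # absent everywhere
})

test_that("storage fold changes error when a subject lacks a day-0 baseline", {
  fix <- paired_storage(c(10, 10), c(20, 20))
  md <- fix$metadata
  md$day[md$sample_id == "d0"] <- 2
  expect_error(storage_fold_changes(fix$table, md), "subj1")
})

test_that("depth normalization makes fold changes scale-invariant", {
  base <- c(15, 40, 3, 500)
  rt <- c(120, 35, 60, 380)
  fix1 <- paired_storage(base, rt)
  fix2 <- paired_storage(base, rt * 4)  # room-temp sample 4x deeper
  s1 <- storage_fold_changes(fix1$table, fix1$metadata)
  s2 <- storage_fold_changes(fix2$table, fix2$metadata)
  expect_equal(s2$comparisons$log2fc, s1$comparisons$log2fc)
  expect_equal(s2$comparisons$excluded, s1$comparisons$excluded)
})

test_that("fold-change arithmetic matches an independent oracle on random triples", {
  # independent reimplementation of the rule for one (c0, ct) pair
  oracle <- function(c0, ct, d0, dt, thr = 10) {
    m <- min(d0, dt)
    c0 <- c0 * m / d0; ct <- ct * m / dt
    if (c0 < thr && ct < thr) return(NA_real_)
    log2(max(ct, thr) / max(c0, thr))
  }
  withr::with_seed(99, {
    for (rep in 1:60) {
      n <- 5
      c0 <- rpois(n, lambda = sample(c(2, 8, 30, 200), n, replace = TRUE))
      ct <- rpois(n, lambda = sample(c(2, 8, 30, 200), n, replace = TRUE))
      fill0 <- sample(500:2000, 1); fillt <- sample(500:2000, 1)
      fix <- paired_storage(c(c0, fill0), c(ct, fillt))
      got <- storage_fold_changes(fix$table, fix$metadata)$comparisons
      d0 <- sum(c0) + fill0; dt <- sum(ct) + fillt
      want <- vapply(seq_len(n), function(i) oracle(c0[i], ct[i], d0, dt),
                     numeric(1))
      expect_equal(got$log2fc[seq_len(n)], want)
    }
  })
})

test_that("cross-study fold changes take the minimum over frozen studies", {
  # exact compositions: target 6%, frozen studies 2% and 1%
  fix <- freq_tables(c(0.06, 0.94), list(c(0.02, 0.98), c(0.01, 0.99)))
  cs <- cross_study_fold_changes(fix$target, fix$frozen)
  expect_equal(cs$min_fold[1], min(0.06 / 0.02, 0.06 / 0.01))
  expect_equal(cs$min_fold[1], 3)
})

test_that("pseudo-frequency floors zero denominators; absent targets score 0", {
  fix <- freq_tables(c(0.05, 0, 0.95), list(c(0, 0.05, 0.95)))
  cs <- cross_study_fold_changes(fix$target, fix$frozen, pseudo_freq = 1e-6)
  expect_equal(cs$min_fold[1], 0.05 / 1e-6)  # 50000
  expect_equal(cs$min_fold[2], 0)            # absent from target
  expect_error(cross_study_fold_changes(fix$target, list()), "frozen")
})

test_that("the three-way selection criterion fires as specified", {
  mk_storage <- function(folds) data.frame(feature_id = names(folds),
                                           max_fold = unname(folds))
  mk_cross <- function(folds) data.frame(feature_id = names(folds),
                                         min_fold = unname(folds))
  storage <- mk_storage(c(f1 = 4, f2 = 60, f3 = NA, f4 = 1.5))
  cross <- mk_cross(c(f1 = 3, f2 = 1.2, f3 = 2.5, f4 = 10))
  sel <- select_candidates(storage, cross)
  expect_setequal(sel$feature_id, c("f1", "f2", "f3"))
  expect_equal(sel$criterion[sel$feature_id == "f1"], "both_axes")
  expect_equal(sel$criterion[sel$feature_id == "f2"], "storage_extreme")
  expect_equal(sel$criterion[sel$feature_id == "f3"], "cross_only")
  # both_axes is recorded when both both_axes and storage_extreme hold
  sel2 <- select_candidates(mk_storage(c(g = 80)), mk_cross(c(g = 5)))
  expect_equal(sel2$criterion, "both_axes")
})

test_that("selection agrees with a brute-force rule evaluation on a threshold grid", {
  t_cross <- 2; t_storage <- 2; t_extreme <- 50
  storage_vals <- c(NA, 0, 0.5, 1.9, 1.999, 2, 2.001, 10, 49.9, 50, 50.1, 400)
  cross_vals <- c(0, 0.5, 1.9, 1.999, 2, 2.001, 3, 80)
  grid <- expand.grid(storage = storage_vals, cross = cross_vals)
  # >=1000 pairs straddling all thresholds
  withr::with_seed(5, {
    extra <- data.frame(storage = ifelse(runif(950) < 0.2, NA,
                                         2^runif(950, -2, 7)),
                        cross = 2^runif(950, -2, 7))
    grid <- rbind(grid, extra)
  })
  grid$feature_id <- sprintf("f%04d", seq_len(nrow(grid)))
  sel <- select_candidates(
    data.frame(feature_id = grid$feature_id, max_fold = grid$storage),
    data.frame(feature_id = grid$feature_id, min_fold = grid$cross))
  got <- grid$feature_id %in% sel$feature_id
  # brute force, predicate by predicate
  want <- mapply(function(s, x) {
    p1 <- !is.na(s) && s >= t_storage && x >= t_cross
    p2 <- !is.na(s) && s >= t_extreme
    p3 <- is.na(s) && x >= t_cross
    p1 || p2 || p3
  }, grid$storage, grid$cross)
  expect_equal(got, unname(want))
})

test_that("lowering thresholds never removes a selected candidate", {
  withr::with_seed(6, {
    storage <- ifelse(runif(300) < 0.25, NA, 2^runif(300, -2, 7))
    cross <- 2^runif(300, -2, 7)
  })
  ids <- sprintf("f%03d", seq_along(cross))
  sf <- data.frame(feature_id = ids, max_fold = storage)
  cf <- data.frame(feature_id = ids, min_fold = cross)
  tight <- select_candidates(sf, cf, t_cross = 3, t_storage = 3,
                             t_extreme = 60)
  loose <- select_candidates(sf, cf, t_cross = 1.5, t_storage = 1.5,
                             t_extreme = 30)
  expect_true(all(tight$feature_id %in% loose$feature_id))
})

test_that("severity ranking weighs abundance and breaks ties lexicographically", {
  target <- toy_table(matrix(c(10, 1, 89), 1, 3), "s1",
                      c("CCCC", "GGGG", "TTTT"))
  cand <- data.frame(feature_id = c("CCCC", "GGGG"),
                     max_storage_fold = c(4, 4),
                     min_cross_fold = c(3, 3),
                     criterion = "both_axes")
  ranked <- rank_candidates(cand, target)
  expect_equal(ranked$sequence[ranked$rank == 1], "CCCC")  # higher frequency
  one <- rank_candidates(cand[1, ], target)
  expect_equal(one$rank, 1L)
  # identical severities: lexicographically smaller sequence first
  tie_target <- toy_table(matrix(c(10, 10, 80), 1, 3), "s1",
                          c("GGGG", "CCCC", "TTTT"))
  tie <- rank_candidates(cand, tie_target)
  expect_equal(tie$sequence, c("CCCC", "GGGG"))
})
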