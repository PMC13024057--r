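test_that("consensus is a pixelwise majority vote with ties included", {
  m <- matrix(runif(64) > 0.5, 8, 8)
  expect_equal(consensus_mask(list(m, m, m)), m)
  a <- matrix(FALSE, 2, 2); a[1, 1] <- TRUE; a[2, 2] <- TRUE
  b <- matrix(FALSE, 2, 2); b[1, 1] <- TRUE
  cc <- matrix(FALSE, 2, 2); cc[1, 1] <- TRUE; cc[1, 2] <- TRUE
  cons <- consensus_mask(list(a, b, cc))
  expect_true(cons[1, 1])        # covered by 3
  expect_false(cons[2, 2])       # covered by 1
  expect_false(cons[1, 2])       # covered by 1
  # 2-of-4 coverage is exactly the 0.5 rule: ties are included
  expect_true(consensus_mask(list(a, a, b, b))[2, 2])
  expect_true(consensus_mask(list(a, a, b, b))[1, 1])
  set.seed(31)
  masks <- replicate(5, matrix(runif(100) > 0.4, 10, 10), simplify = FALSE)
  cons <- consensus_mask(masks)
  inter <- Reduce(`&`, masks); uni <- Reduce(`|`, masks)
  expect_true(all(cons[inter]))
  expect_true(all(uni[cons]))
  expect_error(consensus_mask(list(a, matrix(FALSE, 3, 3))), "differ")
})

test_that("the group threshold is the interpolated percentile of the pool", {
  expect_equal(as.numeric(group_threshold(list(matrix(0.3, 5, 5)))), 0.3)
  # pooled values 1..100 at q = 75: rank h = (n-1)p + 1 = 75.25
  vals <- matrix(sample(1:100), 10, 10)
  oracle <- {
    s <- sort(as.numeric(vals))
    h <- (100 - 1) * 0.75 + 1
    s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  }
  expect_equal(as.numeric(group_threshold(list(vals))), oracle)
  expect_equal(oracle, 75.25)
  expect_equal(attr(group_threshold(list(vals)), "q"), 75)
  expect_error(group_threshold(list()), "empty")
})

test_that("the regional statistic equals exhaustive enumeration", {
  # constant map at or above threshold: value is the constant
  cmap <- matrix(2.5, 6, 6)
  mask <- matrix(TRUE, 6, 6)
  r <- region_mean_index(cmap, mask, t = 2.5)
  expect_equal(r$value, 2.5)
  expect_equal(r$n_supra, 36)
  # everything below threshold: value 0, N_s 0 by convention
  r0 <- region_mean_index(cmap, mask, t = 3)
  expect_equal(r0$value, 0)
  expect_equal(r0$n_supra, 0)
  expect_error(region_mean_index(cmap, matrix(FALSE, 6, 6), 1), "empty")
  # brute force on random instances
  set.seed(32)
  for (i in 1:100) {
    map <- matrix(runif(256), 16, 16)
    mask <- matrix(runif(256) > 0.6, 16, 16)
    if (!any(mask)) mask[1, 1] <- TRUE
    t <- runif(1)
    got <- region_mean_index(map, mask, t)
    acc <- 0; ns <- 0
    for (ii in 1:16) for (jj in 1:16) {
      if (mask[ii, jj] && map[ii, jj] >= t) {
        acc <- acc + map[ii, jj]; ns <- ns + 1
      }
    }
    expect_equal(got$n_supra, ns)
    expect_equal(got$value, if (ns == 0) 0 else acc / ns, tolerance = 1e-12)
  }
})

test_that("raising the threshold shrinks the supra-threshold set", {
  set.seed(33)
  map <- matrix(runif(400), 20, 20)
  mask <- matrix(runif(400) > 0.5, 20, 20)
  ts <- sort(runif(8))
  ns <- vapply(ts, function(t) region_mean_index(map, mask, t)$n_supra, 0)
  expect_true(all(diff(ns) <= 0))
})

test_that("indices scale linearly with the map (threshold rescaled)", {
  set.seed(34)
  map <- matrix(runif(144), 12, 12)
  mask <- matrix(runif(144) > 0.5, 12, 12)
  t <- as.numeric(group_threshold(list(map)))
  t_scaled <- as.numeric(group_threshold(list(3 * map)))
  expect_equal(t_scaled, 3 * t, tolerance = 1e-12)
  expect_equal(region_mean_index(3 * map, mask, t_scaled)$value,
               3 * region_mean_index(map, mask, t)$value, tolerance = 1e-12)
})

test_that("the ensemble statistic averages the per-mask values", {
  set.seed(35)
  map <- matrix(runif(100), 10, 10)
  m1 <- matrix(runif(100) > 0.5, 10, 10); m1[1, 1] <- TRUE
  m2 <- matrix(runif(100) > 0.5, 10, 10); m2[1, 1] <- TRUE
  t <- 0.4
  e <- ensemble_index(map, list(m1, m2), t)
  v1 <- region_mean_index(map, m1, t); v2 <- region_mean_index(map, m2, t)
  expect_equal(e$value, (v1$value + v2$value) / 2, tolerance = 1e-12)
  # identical masks collapse to the single-mask value
  expect_equal(ensemble_index(map, list(m1, m1, m1), t)$value, v1$value)
})

test_that("zero-jitter annotators make the ensemble equal the truth value", {
  spec <- clean_spec(64)
  ms <- group_mask_set(spec, 10, "male", k = 5,
                       jitter = list(shift_sd = 0, morph_max = 0), seed = 1)
  map <- matrix(runif(64 * 64), 64, 64)
  t <- 0.5
  e <- ensemble_index(map, lapply(ms$annotators, `[[`, "maxilla"), t)
  truth_v <- region_mean_index(map, ms$truth$maxilla, t)
  expect_equal(e$value, truth_v$value, tolerance = 1e-12)
  expect_equal(lapply(ms$consensus, unname), lapply(ms$truth, unname))
})

test_that("the index table reproduces an end-to-end hand computation", {
  spec <- clean_spec(64)
  ms <- build_mask_sets(spec, bins = 10, sexes = "male", k = 3,
                        jitter = list(shift_sd = 0.5, morph_max = 1),
                        seed = 2)
  set.seed(36)
  maps <- replicate(3, matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  groups <- data.frame(age_bin = rep(10L, 3), sex = "male",
                       stringsAsFactors = FALSE)
  tab <- index_table(maps, groups, ms, kind = "ASI")
  t_pool <- as.numeric(group_threshold(maps))
  for (region in names(ms[["10.male"]]$truth)) {
    per_subj <- vapply(maps, function(mp)
      mean(vapply(ms[["10.male"]]$annotators, function(a)
        region_mean_index(mp, a[[region]], t_pool)$value, 0)), 0)
    expect_equal(tab$value[tab$region == region], mean(per_subj),
                 tolerance = 1e-12)
  }
  # a single subject per group: the group value is that subject's value
  tab1 <- index_table(maps[1], groups[1, , drop = FALSE], ms, kind = "ASI")
  expect_equal(tab1$n_subjects, rep(1, 6))
  # all-zero maps give all-zero indices
  zero <- index_table(list(matrix(0, 64, 64)), groups[1, , drop = FALSE],
                      ms, kind = "ASI")
  expect_true(all(zero$value == 0))
})

test_that("ASI and SSI share one implementation bit-for-bit", {
  spec <- clean_spec(64)
  ms <- build_mask_sets(spec, bins = 12, sexes = "female", k = 4, seed = 3)
  set.seed(37)
  maps <- replicate(4, matrix(runif(64 * 64), 64, 64), simplify = FALSE)
  groups <- data.frame(age_bin = rep(12L, 4), sex = "female",
                       stringsAsFactors = FALSE)
  asi <- index_table(maps, groups, ms, kind = "ASI")
  ssi <- index_table(maps, groups, ms, kind = "SSI")
  expect_identical(asi$value, ssi$value)
  expect_identical(asi$n_supra, ssi$n_supra)
  expect_identical(asi$t, ssi$t)
})
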