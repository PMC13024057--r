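test_that("rendering is deterministic given spec, subject and seed", {
  spec <- clean_spec()
  a <- render_phantom(spec, subj(9.5), seed = 7)
  b <- render_phantom(spec, subj(9.5), seed = 7)
  expect_identical(a$image, b$image)
  expect_identical(a$masks, b$masks)
  # also with noise and jitter active
  spec2 <- phantom_spec(canvas_side = 64)
  expect_identical(render_phantom(spec2, subj(12.2, "female"), seed = 3)$image,
                   render_phantom(spec2, subj(12.2, "female"), seed = 3)$image)
})

test_that("canvas side is honoured up to the full-scale 1000 px mode", {
  spec <- phantom_spec(canvas_side = 1000, validate = FALSE)
  img <- render_phantom(spec, subj(10), seed = 1)$image
  expect_equal(dim(img), c(1000, 1000))
})

test_that("age limits are enforced", {
  spec <- clean_spec()
  expect_error(render_phantom(spec, subj(3.5), 1), "\\[4, 19\\)")
  expect_error(render_phantom(spec, subj(19), 1), "\\[4, 19\\)")
  expect_silent(render_phantom(spec, subj(18.99), 1))
})

test_that("overlapping canonical footprints are rejected at validation", {
  bad <- default_regions()
  bad[[4]]$params$center <- c(0.70, 0.56)  # sphenoid onto the maxilla
  expect_error(phantom_spec(canvas_side = 64, regions = bad), "overlap")
})

test_that("a growing region's mask area increases with age as its scaled shape", {
  spec <- clean_spec(128)
  a4 <- sum(render_phantom(spec, subj(4, "male"), 1)$masks$mandible)
  a18 <- sum(render_phantom(spec, subj(18.9, "male"), 1)$masks$mandible)
  expect_gt(a18, a4)
  # oracle: area of a uniformly scaled planar shape grows as scale^2
  rg <- spec$regions[[which(vapply(spec$regions, `[[`, "", "name") ==
                              "mandible")]]
  scale_at <- function(a)   # male: growth plus the dimorphic size offset
    1 + rg$growth_coeff /
      (1 + exp(-rg$growth_rate * (a - rg$growth_midpoint))) +
      rg$dimorphism_coeff * (a - 4) / 15
  s4 <- scale_at(4); s18 <- scale_at(18.9)
  expect_equal(a18 / a4, (s18 / s4)^2, tolerance = 0.05)
  # monotone over a grid
  areas <- vapply(seq(4, 18.5, by = 2), function(a)
    sum(render_phantom(spec, subj(a, "male"), 1)$masks$temporal), 0)
  expect_true(all(diff(areas) >= 0))
})

test_that("truth masks are pairwise disjoint", {
  spec <- phantom_spec(canvas_side = 64, region_scale_sd = 0.025)
  set.seed(42)
  for (i in 1:8) {
    ph <- render_phantom(spec, subj(runif(1, 4, 19),
                                    sample(c("male", "female"), 1),
                                    sample(c("standard", "mirrored"), 1)),
                         seed = i)
    expect_true(all(Reduce(`+`, ph$masks) <= 1))
  }
})

test_that("sexes differ only inside dimorphic regions", {
  spec <- clean_spec(128)
  m <- render_phantom(spec, subj(17, "male"), 5)
  f <- render_phantom(spec, subj(17, "female"), 5)
  diffpix <- m$image != f$image
  halo <- m$masks$mandible | f$masks$mandible
  expect_true(all(diffpix <= halo))
  expect_gt(sum(diffpix), 0)
})

test_that("cohort sampling respects the sex ratio and is reproducible", {
  spec <- clean_spec()
  co <- sample_cohort(spec, 10, sex_ratio = 1, seed = 1, render = FALSE)
  expect_equal(co$metadata$sex, rep("male", 10))
  a <- sample_cohort(spec, 25, seed = 9, render = FALSE)$metadata
  b <- sample_cohort(spec, 25, seed = 9, render = FALSE)$metadata
  expect_identical(a, b)
  expect_equal(a$age, round(a$age, 2))
  expect_error(sample_cohort(spec, 0), ">= 1")
})

test_that("uniform age law fills one-year bins within exact binomial bounds", {
  spec <- clean_spec()
  md <- sample_cohort(spec, 1000, seed = 4, render = FALSE)$metadata
  counts <- table(factor(floor(md$age), levels = 4:18))
  lo <- qbinom(0.005, 1000, 1 / 15)
  hi <- qbinom(0.995, 1000, 1 / 15)
  expect_true(all(counts >= lo & counts <= hi))
})

test_that("planted importance follows the schedule derivative", {
  spec <- clean_spec()
  # a region with zero growth gets zero score at all ages
  zero_growth <- spec
  zero_growth$regions[[1]]$growth_coeff <- 0
  for (a in c(4, 10, 18))
    expect_equal(unname(planted_importance(zero_growth, a)["orbit"]), 0)
  # all-zero coefficients: all-zero vector, no normalization
  flat <- spec
  for (i in seq_along(flat$regions)) flat$regions[[i]]$growth_coeff <- 0
  expect_equal(unname(planted_importance(flat, 10)), rep(0, 6))
  # scores are a normalized simplex when any signal exists
  sc <- planted_importance(spec, 11)
  expect_equal(sum(sc), 1)
  # oracle: closed-form |beta * k * g(1-g)| normalized, evaluated directly
  ages <- seq(4, 18.99, by = 0.01)
  oracle <- sapply(ages, function(a) {
    raw <- vapply(spec$regions, function(rg) {
      g <- 1 / (1 + exp(-rg$growth_rate * (a - rg$growth_midpoint)))
      abs(rg$growth_coeff * rg$growth_rate * g * (1 - g))
    }, 0)
    (raw / sum(raw))[[5]]  # temporal
  })
  got <- vapply(ages, function(a) planted_importance(spec, a)[["temporal"]],
                0)
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("annotation replicas reproduce the truth at zero jitter", {
  spec <- clean_spec(64)
  truth <- render_phantom(spec, subj(10), 1)$masks
  ann <- simulate_annotations(truth, k = 3,
                              jitter = list(shift_sd = 0, morph_max = 0),
                              seed = 1)
  for (a in ann) expect_identical(lapply(a, unname), lapply(truth, unname))
})

test_that("small annotation jitter keeps replicas close to the truth", {
  spec <- clean_spec(128)
  truth <- render_phantom(spec, subj(12), 1)$masks
  ann <- simulate_annotations(truth, k = 20,
                              jitter = list(shift_sd = 0.7, morph_max = 1),
                              seed = 2)
  expect_length(ann, 20)
  dices <- unlist(lapply(ann, function(a)
    mapply(dice, a, truth)))
  expect_true(all(dices >= 0.55))
  expect_gt(mean(dices), 0.75)
})

test_that("annotation jitter that empties masks errors after retries", {
  tiny <- list(dot = matrix(c(rep(FALSE, 40), TRUE, rep(FALSE, 40)), 9, 9))
  expect_error(
    suppressWarnings(simulate_annotations(tiny, k = 2,
                                          jitter = list(shift_sd = 50,
                                                        morph_max = 0),
                                          seed = 1, retry_cap = 2)),
    "emptied")
})
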