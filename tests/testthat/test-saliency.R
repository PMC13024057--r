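toy_model <- function(head = "age_regression", hidden = 5, seed = 1,
                      side = 32, channels = c(3, 4)) {
  m <- build_model(model_config("small_cnn", side, head,
                                channels = channels, hidden = hidden),
                   seed = seed)
  m$fitted <- TRUE
  m$task <- if (head == "age_regression") "age" else "sex"
  m
}

test_that("a zero head yields an identically zero saliency map", {
  m <- toy_model(hidden = 0)
  m$params[[length(m$params) - 1]][] <- 0
  sm <- gradcam_map(m, matrix(runif(32 * 32), 32, 32))
  expect_true(all(sm$rect == 0))
  expect_true(all(sm$raw == 0))
})

test_that("channel weights equal finite-difference gradients through the head", {
  set.seed(21)
  for (trial in 1:5) {
    m <- toy_model(hidden = 5, seed = trial)
    img <- matrix(runif(32 * 32), 32, 32)
    sm <- gradcam_map(m, img)
    # recompute features and differentiate the head numerically
    F <- cephsal:::forward_batched(m, array(img, c(32, 32, 1)),
                                   want_features = TRUE)$features[[1]]
    p <- m$params
    L <- length(m$config$channels)
    W1 <- p[[2 * L + 1]]; b1 <- p[[2 * L + 2]]
    W2 <- p[[2 * L + 3]]; b2 <- p[[2 * L + 4]]
    head_out <- function(Fc) {
      f <- apply(Fc, 3, mean)
      h <- pmax(as.numeric(W1 %*% f + b1), 0)
      as.numeric(W2[1, ] %*% h + b2[1])
    }
    np <- prod(dim(F)[1:2])
    for (r in seq_len(dim(F)[3])) {
      grads <- vapply(list(c(1, 1), c(3, 5), c(8, 8)), function(ij) {
        up <- F; up[ij[1], ij[2], r] <- up[ij[1], ij[2], r] + 1e-3
        dn <- F; dn[ij[1], ij[2], r] <- dn[ij[1], ij[2], r] - 1e-3
        (head_out(up) - head_out(dn)) / 2e-3
      }, 0)
      alpha_fd <- mean(grads)  # gradient is uniform over pixels (GAP)
      denom <- max(abs(alpha_fd), abs(sm$alpha[r]), 1e-8)
      expect_lt(abs(alpha_fd - sm$alpha[r] * np / np) / denom, 1e-3)
    }
    # the rectified map is the positive part of the weighted feature sum
    recon <- Reduce(`+`, lapply(seq_len(dim(F)[3]), function(r)
      sm$alpha[r] * F[, , r]))
    expect_equal(sm$raw, recon, tolerance = 1e-12)
    expect_equal(sm$rect, pmax(recon, 0), tolerance = 1e-12)
  }
})

test_that("rectified maps are non-negative across random networks", {
  set.seed(22)
  for (i in 1:200) {
    m <- toy_model(hidden = sample(c(0L, 4L), 1), seed = i, side = 16,
                   channels = c(2, 3))
    sm <- gradcam_map(m, matrix(runif(16 * 16), 16, 16))
    expect_true(all(sm$rect >= 0))
  }
})

test_that("sex-head Grad-CAM targets an explicit class logit", {
  m <- toy_model("sex_classification")
  img <- matrix(runif(32 * 32), 32, 32)
  a <- gradcam_map(m, img, target = "male")
  b <- gradcam_map(m, img, target = "female")
  expect_false(isTRUE(all.equal(a$raw, b$raw)))
  expect_equal(gradcam_map(m, img, target = "true",
                           true_class = "male")$raw, a$raw)
  expect_error(gradcam_map(m, img, target = "true"), "true_class")
})

test_that("bilinear upsampling matches the hand-computed oracle", {
  m2 <- matrix(c(1, 3, 2, 4), 2, 2)   # [[1,2],[3,4]] row-major
  got <- cephsal:::bilinear_resize(m2, 4, 4)
  alpha <- c(0, 0.25, 0.75, 1)
  expected <- outer(2 * alpha, alpha, function(a, b) 1 + a + b)
  expect_equal(got, expected, tolerance = 1e-6)
  # constant map stays constant at any resolution
  cm <- matrix(0.7, 3, 3)
  expect_true(all(abs(cephsal:::bilinear_resize(cm, 9, 9) - 0.7) < 1e-12))
})

test_that("upsample_align produces image-frame non-negative aligned maps", {
  m <- toy_model()
  sm <- gradcam_map(m, matrix(runif(32 * 32), 32, 32))
  up <- upsample_align(sm, 32, "mirrored")
  expect_equal(dim(up$image), c(32, 32))
  expect_true(all(up$image >= 0))
  # aligning twice equals aligning once: standard input passes through
  again <- align_orientation(up$image, "standard")
  expect_identical(again, up$image)
})

test_that("group averaging is the pixelwise mean", {
  a <- matrix(runif(16), 4, 4)
  b <- matrix(runif(16), 4, 4)
  expect_equal(group_average(list(a, a, a))$mean, a)
  expect_equal(group_average(list(a, b))$mean, (a + b) / 2)
  set.seed(23)
  maps <- replicate(50, matrix(runif(64), 8, 8), simplify = FALSE)
  brute <- matrix(0, 8, 8)
  for (mm in maps) brute <- brute + mm
  brute <- brute / 50
  expect_lt(max(abs(group_average(maps)$mean - brute)), 1e-9)
  expect_error(group_average(list()), "empty")
  expect_error(group_average(list(a, matrix(0, 3, 3))), "mismatch")
})

test_that("overlays colorize blue to red over the image", {
  img <- matrix(runif(100), 10, 10)
  map <- matrix(0, 10, 10); map[4, 7] <- 1
  ov <- colorize_overlay(map, img)
  expect_equal(dim(ov), c(10, 10, 3))
  expect_true(all(ov >= 0 & ov <= 1))
  # maximal-saliency pixel sits at the red end, zero pixels at the blue end
  expect_gt(ov[4, 7, 1], ov[4, 7, 3])
  expect_gt(ov[1, 1, 3], ov[1, 1, 1])
  # constant map renders uniformly blue
  flat <- colorize_overlay(matrix(1, 10, 10), img)
  expect_true(all(flat[, , 3] >= flat[, , 1]))
})
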