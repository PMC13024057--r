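test_that("the L1 loss matches its definition", {
  expect_equal(l1_loss(c(4, 6), c(5, 5)), 1.0)
  expect_equal(l1_loss(c(7.3, 12.1), c(7.3, 12.1)), 0)
  set.seed(1)
  for (i in 1:20) {
    a <- runif(8, 4, 19); b <- runif(8, 4, 19)
    expect_gte(l1_loss(a, b), 0)
    expect_equal(l1_loss(a, b), sum(abs(a - b)) / 8, tolerance = 1e-12)
  }
  expect_error(l1_loss(numeric(0), numeric(0)), "positive length")
})

test_that("softmax cross-entropy matches direct evaluation", {
  # equal logits: p = 0.5/0.5, single-sample loss = ln 2
  expect_equal(softmax_xent(matrix(c(1.3, 1.3), 1), 1), log(2),
               tolerance = 1e-12)
  # z = (2, 0), male: p_m = 1/(1+e^-2) ~ 0.8808, loss ~ 0.1269
  expect_equal(softmax_xent(matrix(c(2, 0), 1), 1), 0.126928011,
               tolerance = 1e-6)
  set.seed(2)
  for (i in 1:20) {
    z <- matrix(rnorm(12, sd = 2), 6, 2)
    g <- rbinom(6, 1, 0.5)
    expect_equal(softmax_xent(z, g), ref_xent(z, g), tolerance = 1e-12)
    p <- exp(z) / rowSums(exp(z))
    expect_equal(rowSums(p), rep(1, 6), tolerance = 1e-12)
  }
  expect_error(softmax_xent(matrix(c(Inf, 0), 1), 1), "non-finite")
})

test_that("the learning-rate schedule decays by 0.8 every 5 epochs", {
  ctl <- train_control(lr0 = 1e-3)
  expect_equal(lr_at_epoch(ctl, 1), 1e-3)
  expect_equal(lr_at_epoch(ctl, 5), 1e-3)
  expect_equal(lr_at_epoch(ctl, 6), 8e-4)
  expect_equal(lr_at_epoch(ctl, 11), 6.4e-4)  # 1e-3 * 0.8^2
})

test_that("model construction exposes the feature stack and head shapes", {
  eff <- build_model(model_config("efficientnet_b0", input_side = 1000))
  expect_equal(eff$config$last_feature_channels, 320L)
  expect_equal(eff$stages$channels[8], 320)
  expect_error(fit_cnn(eff, array(0, c(8, 8, 2)), 1:2), "not trainable")

  age <- build_model(model_config("small_cnn", 32, channels = c(3, 4)),
                     seed = 1)
  x <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_length(predict(age, x), 3)

  sex <- build_model(model_config("small_cnn", 32, "sex_classification",
                                  channels = c(3, 4)), seed = 1)
  p <- predict(sex, x, type = "prob")
  expect_equal(dim(p), c(3, 2))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))
  cls <- predict(sex, x, type = "class")
  expect_equal(levels(cls), c("male", "female"))
  expect_error(build_model(list()), "model_config")
  expect_error(predict(age, array(0, c(16, 16, 1))), "input side")
})

test_that("engine gradients match central differences, mixed strides included", {
  cfg <- model_config("small_cnn", 12, channels = c(3, 4),
                      strides = c(1, 2), hidden = 5)
  model <- build_model(cfg, seed = 3)
  arch <- cephsal:::cnn_arch(cfg)
  set.seed(4)
  imgs <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  labels <- c(6.5, 14.2)
  p <- model$params
  r <- cephsal:::cpp_cnn_batch_grad(imgs, labels, p, arch, 0L)
  lossfn <- function(pp) cephsal:::cpp_cnn_batch_grad(imgs, labels, pp,
                                                      arch, 0L)$loss
  for (l in seq_along(p)) {
    for (k in sample(length(p[[l]]), min(4, length(p[[l]])))) {
      eps <- 1e-6
      up <- p; up[[l]][k] <- up[[l]][k] + eps
      dn <- p; dn[[l]][k] <- dn[[l]][k] - eps
      fd <- (lossfn(up) - lossfn(dn)) / (2 * eps)
      expect_equal(r$grads[[l]][k], fd, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss on a linearly signalled toy set", {
  set.seed(5)
  n <- 80
  ages <- runif(n, 4, 19)
  x <- array(0, c(16, 16, n))
  for (i in 1:n) x[, , i] <- matrix(ages[i] / 19 + rnorm(256, 0, 0.05), 16)
  cfg <- model_config("small_cnn", 16, channels = c(4, 8), hidden = 8)
  m <- ceph_cnn(x[, , 1:60], ages[1:60], "age", x[, , 61:80], ages[61:80],
                config = cfg,
                control = train_control(max_epochs = 15), seed = 6)
  expect_lt(m$history$train_loss[nrow(m$history)], m$history$train_loss[1])
  # the restored parameters achieve the best validation loss seen
  expect_equal(m$best_val_loss, min(m$history$val_loss), tolerance = 1e-12)
  expect_lte(cephsal:::eval_loss(m, x[, , 61:80], ages[61:80]),
             min(m$history$val_loss) + 1e-9)
  # residuals for the regression head
  expect_length(residuals(m, x[, , 61:80], ages[61:80]), 20)
})

test_that("training halts after `patience` epochs without improvement", {
  set.seed(7)
  x <- array(runif(16 * 16 * 30), c(16, 16, 30))
  ages <- runif(30, 4, 19)
  cfg <- model_config("small_cnn", 16, channels = c(3, 4), hidden = 4)
  # a vanishing learning rate freezes the model: epoch 1 sets the reference,
  # then three non-improving epochs trigger the stop
  m <- ceph_cnn(x[, , 1:20], ages[1:20], "age", x[, , 21:30], ages[21:30],
                config = cfg,
                control = train_control(lr0 = 1e-12, max_epochs = 50,
                                        patience = 3), seed = 8)
  expect_equal(nrow(m$history), 4)
  expect_equal(m$best_epoch, 1)
})

test_that("prediction is deterministic and two runs with one seed coincide", {
  set.seed(9)
  x <- array(runif(16 * 16 * 40), c(16, 16, 40))
  y <- runif(40, 4, 19)
  cfg <- model_config("small_cnn", 16, channels = c(3, 4), hidden = 4)
  ctl <- train_control(max_epochs = 3)
  m1 <- ceph_cnn(x[, , 1:30], y[1:30], "age", x[, , 31:40], y[31:40],
                 config = cfg, control = ctl, seed = 10)
  m2 <- ceph_cnn(x[, , 1:30], y[1:30], "age", x[, , 31:40], y[31:40],
                 config = cfg, control = ctl, seed = 10)
  expect_identical(m1$history, m2$history)
  expect_identical(predict(m1, x), predict(m1, x))
  expect_identical(predict(m1, x), predict(m2, x))
})
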