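#' Model configuration
#'
#' Describes a backbone for the age-regression or sex-classification proxy
#' task. The trainable backbone is \code{small_cnn}: stride-2 3x3
#' convolution blocks with ReLU, a global average pool and a linear head, so
#' the last convolutional feature stack is uniformly exposed for
#' gradient-weighted class activation mapping. The \code{efficientnet_b0}
#' backbone is accepted for configuration at the 1000-px scale (its last
#' feature stack has 320 channels) but is not trainable in this CPU
#' implementation.
#'
#' @param backbone "small_cnn" or "efficientnet_b0".
#' @param input_side input image side in pixels.
#' @param head "age_regression" (1 output) or "sex_classification"
#'   (2 outputs: male and female logits).
#' @param channels output channels of the successive small_cnn blocks.
#' @param strides per-block stride (recycled if scalar); a stride-1 stem
#'   preserves sub-pixel edge information at modest extra cost.
#' @param hidden width of the ReLU hidden layer between the global average
#'   pool and the output (mirroring the reference architecture's pooled
#'   fully-connected head); 0 gives a purely linear head.
#' @return object of class \code{model_config}.
#' @export
model_config <- function(backbone = c("small_cnn", "efficientnet_b0"),
                         input_side = 128,
                         head = c("age_regression", "sex_classification"),
                         channels = c(8, 16, 32, 64), hidden = 64,
                         strides = 2) {
  backbone <- match.arg(backbone)
  head <- match.arg(head)
  last <- if (backbone == "efficientnet_b0") 320L else
    as.integer(channels[length(channels)])
  structure(list(backbone = backbone, input_side = as.integer(input_side),
                 head = head, channels = as.integer(channels),
                 strides = as.integer(rep(strides,
                                          length.out = length(channels))),
                 hidden = as.integer(hidden),
                 n_out = if (head == "age_regression") 1L else 2L,
                 last_feature_channels = last),
            class = "model_config")
}

#' Training control parameters
#'
#' Adam with weight decay 1e-4, learning rate multiplied by 0.8 every 5
#' epochs, early stopping after 3 epochs without validation improvement,
#' at most 100 epochs.
#'
#' @param lr0 initial learning rate (default 3e-3, chosen for stable
#'   convergence at desk scale; the reference work does not state one).
#' @param lr_decay multiplicative decay factor.
#' @param decay_every epochs between decays.
#' @param weight_decay L2 penalty on convolution/head weights.
#' @param patience consecutive non-improving validation epochs tolerated.
#' @param max_epochs epoch cap.
#' @param batch_size mini-batch size.
#' @param min_delta minimum validation-loss decrease that counts as
#'   improvement.
#' @return object of class \code{train_control}.
#' @export
train_control <- function(lr0 = 3e-3, lr_decay = 0.8, decay_every = 5,
                          weight_decay = 1e-4, patience = 3, max_epochs = 100,
                          batch_size = 32, min_delta = 1e-4) {
  stopifnot(patience >= 1, max_epochs >= 1, batch_size >= 1, lr0 > 0)
  structure(list(lr0 = lr0, lr_decay = lr_decay, decay_every = decay_every,
                 weight_decay = weight_decay, patience = patience,
                 max_epochs = max_epochs, batch_size = batch_size,
                 min_delta = min_delta),
            class = "train_control")
}

#' Learning rate at a given epoch
#' @param control a \code{train_control}.
#' @param epoch 1-based epoch index.
#' @return the scheduled learning rate.
#' @export
lr_at_epoch <- function(control, epoch) {
  control$lr0 * control$lr_decay^((epoch - 1) %/% control$decay_every)
}

efficientnet_b0_stages <- function() {
  data.frame(stage = 1:9,
             operator = c("Conv3x3", "MBConv1 k3x3", "MBConv6 k3x3",
                          "MBConv6 k5x5", "MBConv6 k3x3", "MBConv6 k5x5",
                          "MBConv6 k5x5", "MBConv6 k3x3",
                          "Conv1x1 & Pooling & FC"),
             resolution = c(1000, 500, 500, 250, 125, 62, 62, 31, 31),
             channels = c(32, 16, 24, 24, 80, 112, 192, 320, 1280),
             layers = c(1, 1, 2, 2, 3, 3, 4, 1, 1))
}

cnn_arch <- function(config) {
  list(channels = config$channels, ksize = 3L,
       stride = config$strides %||% 2L, pad = 1L,
       n_out = config$n_out, hidden = config$hidden %||% 0L)
}

init_params <- function(config, seed) {
  with_seed(seed, {
    p <- list()
    cin <- 1L
    for (co in config$channels) {
      p[[length(p) + 1]] <- matrix(rnorm(co * cin * 9,
                                         sd = sqrt(2 / (cin * 9))),
                                   co, cin * 9)
      p[[length(p) + 1]] <- rep(0, co)
      cin <- co
    }
    if (config$hidden > 0) {
      p[[length(p) + 1]] <- matrix(rnorm(config$hidden * cin,
                                         sd = sqrt(2 / cin)),
                                   config$hidden, cin)
      p[[length(p) + 1]] <- rep(0, config$hidden)
      cin <- config$hidden
    }
    p[[length(p) + 1]] <- matrix(rnorm(config$n_out * cin,
                                       sd = sqrt(1 / cin)),
                                 config$n_out, cin)
    p[[length(p) + 1]] <- rep(0, config$n_out)
    p
  })
}

#' Build an untrained model
#'
#' @param config a \code{model_config}.
#' @param seed seed for weight initialization (He-scaled Gaussian).
#' @return object of class \code{ceph_cnn} (untrained).
#' @export
build_model <- function(config, seed = 1) {
  if (!inherits(config, "model_config")) stop("config must be a model_config")
  params <- if (config$backbone == "small_cnn") init_params(config, seed)
            else NULL
  structure(list(config = config, params = params,
                 stages = if (config$backbone == "efficientnet_b0")
                   efficientnet_b0_stages() else NULL,
                 fitted = FALSE, history = NULL, task = NULL),
            class = "ceph_cnn")
}

check_trainable <- function(model) {
  if (model$config$backbone != "small_cnn")
    stop("backbone '", model$config$backbone,
         "' is not trainable in this CPU implementation; use small_cnn")
}

encode_labels <- function(y, head) {
  if (head == "age_regression") {
    y <- as.numeric(y)
    if (any(!is.finite(y))) stop("non-finite age labels")
    y
  } else {
    if (is.numeric(y)) {
      if (!all(y %in% 0:1)) stop("numeric sex labels must be 0 (male)/1 (female)")
      as.numeric(y)
    } else {
      y <- match.arg(as.character(y), c("male", "female"), several.ok = TRUE)
      as.numeric(y == "female")   # class index: male = 0, female = 1
    }
  }
}

#' Mean absolute (L1) loss
#'
#' \code{(1/B) * sum |A_n - Ahat_n|} over a batch of age labels and
#' predictions.
#'
#' @param actual,predicted numeric vectors of equal positive length.
#' @return scalar loss in years.
#' @export
l1_loss <- function(actual, predicted) {
  if (!length(actual) || length(actual) != length(predicted))
    stop("actual and predicted must have equal positive length")
  mean(abs(actual - predicted))
}

#' Softmax cross-entropy for the sex task
#'
#' Softmax over the (male, female) logits followed by the negative
#' log-likelihood \code{-(1/B) * sum[g log p_m + (1-g) log p_f]} with
#' g = 1 for male.
#'
#' @param logits n x 2 matrix, columns (male, female).
#' @param g numeric vector, 1 = male, 0 = female.
#' @return scalar loss.
#' @export
softmax_xent <- function(logits, g) {
  logits <- rbind(logits)
  if (any(!is.finite(logits))) stop("non-finite logits")
  stopifnot(ncol(logits) == 2, nrow(logits) == length(g))
  z <- logits - apply(logits, 1, max)
  p <- exp(z) / rowSums(exp(z))
  -mean(g * log(p[, 1]) + (1 - g) * log(p[, 2]))
}

softmax_probs <- function(logits) {
  z <- logits - apply(logits, 1, max)
  exp(z) / rowSums(exp(z))
}

eval_loss <- function(model, x, y_enc) {
  pred <- forward_batched(model, x)
  if (model$config$head == "age_regression") l1_loss(y_enc, pred[1, ])
  else softmax_xent(t(pred), 1 - y_enc)   # g = 1 male; y_enc 1 = female
}

forward_batched <- function(model, x, want_features = FALSE, chunk = 256) {
  n <- dim(x)[3]
  preds <- matrix(0, model$config$n_out, n)
  feats <- if (want_features) vector("list", n)
  arch <- cnn_arch(model$config)
  for (s in seq(1, n, by = chunk)) {
    e <- min(s + chunk - 1, n)
    r <- cpp_cnn_forward(x[, , s:e, drop = FALSE], model$params, arch,
                         want_features)
    preds[, s:e] <- r$pred
    if (want_features) feats[s:e] <- r$features
  }
  if (want_features) list(pred = preds, features = feats) else preds
}

#' Fit a model by mini-batch Adam
#'
#' Trains with the L1 loss (age) or softmax cross-entropy (sex), Adam with
#' weight decay, exponential learning-rate decay (x lr_decay every
#' decay_every epochs) and early stopping on the validation loss; the
#' parameters from the best validation epoch are restored. Fully
#' deterministic given the seed.
#'
#' @param model an untrained or trained \code{ceph_cnn} (small_cnn backbone).
#' @param x training images, side x side x n array.
#' @param y training labels (years, or "male"/"female").
#' @param x_val,y_val validation set (required).
#' @param control a \code{train_control}.
#' @param augment optional \code{augment_params} applied on the fly to
#'   training images.
#' @param seed seed driving batch shuffling and augmentation.
#' @param verbose print per-epoch losses.
#' @return the fitted \code{ceph_cnn} with \code{history} and
#'   \code{best_epoch}.
#' @export
fit_cnn <- function(model, x, y, x_val, y_val, control = train_control(),
                    augment = NULL, seed = 1, verbose = FALSE) {
  check_trainable(model)
  if (is.null(dim(x)) || length(dim(x)) != 3 || dim(x)[3] < 1)
    stop("x must be a side x side x n array with n >= 1")
  if (dim(x)[1] != model$config$input_side)
    stop("image side ", dim(x)[1], " does not match config input_side ",
         model$config$input_side)
  if (missing(x_val) || is.null(x_val) || dim(x_val)[3] < 1)
    stop("a non-empty validation set is required for early stopping")
  head <- model$config$head
  y_enc <- encode_labels(y, head)
  yv_enc <- encode_labels(y_val, head)
  task <- if (head == "age_regression") 0L else 1L
  arch <- cnn_arch(model$config)
  params <- model$params
  mstate <- lapply(params, function(p) p * 0)
  vstate <- lapply(params, function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  tstep <- 0
  n <- dim(x)[3]
  is_weight <- rep(c(TRUE, FALSE), length(params) / 2)
  best <- list(loss = Inf, acc = -Inf, params = params, epoch = 0)
  best_stop <- Inf
  bad <- 0
  hist <- data.frame(epoch = integer(), lr = numeric(),
                     train_loss = numeric(), val_loss = numeric())
  with_seed(seed, {
    for (epoch in seq_len(control$max_epochs)) {
      lr <- lr_at_epoch(control, epoch)
      ord <- sample.int(n)
      tr_loss <- 0
      for (s in seq(1, n, by = control$batch_size)) {
        idx <- ord[s:min(s + control$batch_size - 1, n)]
        xb <- x[, , idx, drop = FALSE]
        if (!is.null(augment)) {
          for (j in seq_along(idx))
            xb[, , j] <- apply_augmentation(xb[, , j], augment)
        }
        yb <- if (task == 0L) y_enc[idx] else y_enc[idx]
        r <- cpp_cnn_batch_grad(xb, yb, params, arch, task)
        tr_loss <- tr_loss + r$loss * length(idx)
        tstep <- tstep + 1
        for (l in seq_along(params)) {
          g <- r$grads[[l]]
          if (is_weight[l] && control$weight_decay > 0)
            g <- g + control$weight_decay * params[[l]]
          mstate[[l]] <- beta1 * mstate[[l]] + (1 - beta1) * g
          vstate[[l]] <- beta2 * vstate[[l]] + (1 - beta2) * g^2
          mhat <- mstate[[l]] / (1 - beta1^tstep)
          vhat <- vstate[[l]] / (1 - beta2^tstep)
          params[[l]] <- params[[l]] - lr * mhat / (sqrt(vhat) + eps)
        }
      }
      model$params <- params
      val_loss <- eval_loss(model, x_val, yv_enc)
      val_acc <- if (head == "sex_classification") {
        pv <- softmax_probs(t(forward_batched(model, x_val)))
        mean((pv[, 2] >= 0.5) == (yv_enc == 1))
      } else NA_real_
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_loss = tr_loss / n,
                                     val_loss = val_loss,
                                     val_acc = val_acc))
      if (verbose)
        message(sprintf("epoch %3d lr %.2e train %.4f val %.4f", epoch, lr,
                        tr_loss / n, val_loss))
      # checkpoint selection: best validation performance (accuracy for the
      # sex head, loss tie-break; loss for the age head)
      better <- if (head == "sex_classification") {
        val_acc > best$acc || (val_acc == best$acc && val_loss < best$loss)
      } else val_loss < best$loss - control$min_delta
      if (better)
        best <- list(loss = val_loss, acc = val_acc, params = params,
                     epoch = epoch)
      # stopping: no validation-loss improvement for `patience` epochs
      if (val_loss < best_stop - control$min_delta) {
        best_stop <- val_loss
        bad <- 0
      } else {
        bad <- bad + 1
        if (bad >= control$patience) break
      }
    }
  })
  model$params <- best$params
  model$fitted <- TRUE
  model$history <- hist
  model$best_epoch <- best$epoch
  model$best_val_loss <- best$loss
  model$control <- control
  model$task <- if (head == "age_regression") "age" else "sex"
  model$train_labels <- y_enc
  model
}

#' Fit a craniofacial proxy-task CNN
#'
#' One-shot constructor: builds a \code{small_cnn} for the requested task and
#' fits it. This is the package's central fitting function; the returned
#' object supports \code{predict}, \code{print}, \code{summary},
#' \code{coef}, \code{plot} and \code{residuals}.
#'
#' @param x training images (side x side x n array, intensities in [0, 1]).
#' @param y labels: ages in years, or sex ("male"/"female").
#' @param task "age" (regression) or "sex" (classification).
#' @param x_val,y_val validation set used for early stopping.
#' @param config a \code{model_config}; defaults to a small_cnn matched to
#'   the input side.
#' @param control a \code{train_control}.
#' @param augment optional \code{augment_params}.
#' @param seed seed for initialization, shuffling and augmentation.
#' @param verbose print training progress.
#' @return a fitted \code{ceph_cnn}.
#' @export
ceph_cnn <- function(x, y, task = c("age", "sex"), x_val, y_val,
                     config = NULL, control = train_control(),
                     augment = NULL, seed = 1, verbose = FALSE) {
  task <- match.arg(task)
  if (is.null(config))
    config <- model_config("small_cnn", input_side = dim(x)[1],
                           head = if (task == "age") "age_regression"
                                  else "sex_classification")
  seeds <- derive_seeds(seed, 2)
  model <- build_model(config, seed = seeds[1])
  fit_cnn(model, x, y, x_val, y_val, control = control, augment = augment,
          seed = seeds[2], verbose = verbose)
}

#' Predict from a fitted model
#'
#' @param object a fitted \code{ceph_cnn}.
#' @param newdata images array (side x side x n) or a single matrix.
#' @param type "response" (ages, or female probability), "prob"
#'   (n x 2 matrix of male/female probabilities) or "class" (sex labels at
#'   the 0.5 threshold).
#' @param threshold decision threshold on the female probability.
#' @param ... unused.
#' @return predictions as described under \code{type}.
#' @export
predict.ceph_cnn <- function(object, newdata, type = c("response", "prob",
                                                       "class"),
                             threshold = 0.5, ...) {
  type <- match.arg(type)
  check_trainable(object)
  if (is.matrix(newdata)) newdata <- array(newdata, c(dim(newdata), 1))
  if (dim(newdata)[1] != object$config$input_side ||
      dim(newdata)[2] != object$config$input_side)
    stop("newdata dimensions do not match the model input side")
  pred <- forward_batched(object, newdata)
  if (object$config$head == "age_regression") {
    if (type != "response") stop("type '", type, "' applies to the sex head")
    return(as.numeric(pred[1, ]))
  }
  p <- softmax_probs(t(pred))
  colnames(p) <- c("male", "female")
  switch(type,
         prob = p,
         response = as.numeric(p[, "female"]),
         class = factor(ifelse(p[, "female"] >= threshold, "female", "male"),
                        levels = c("male", "female")))
}

#' @export
print.ceph_cnn <- function(x, ...) {
  cat("Craniofacial proxy-task CNN (", x$config$backbone, ")\n", sep = "")
  cat("  head:", x$config$head, " input:", x$config$input_side, "px\n")
  cat("  feature stack:", x$config$last_feature_channels, "channels\n")
  if (isTRUE(x$fitted))
    cat(sprintf("  fitted: best epoch %d, validation loss %.4f\n",
                x$best_epoch, x$best_val_loss))
  else cat("  not fitted\n")
  invisible(x)
}

#' @export
summary.ceph_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("  epochs run:", nrow(object$history), "\n")
    print(utils::tail(object$history, 3), row.names = FALSE)
  }
  invisible(object)
}

#' @export
coef.ceph_cnn <- function(object, ...) {
  L <- length(object$config$channels)
  p <- object$params
  nm <- c(t(outer(paste0("conv", seq_len(L)), c("W", "b"), paste, sep = "_")))
  head_nm <- if (object$config$hidden > 0)
    c("head_hidden_W", "head_hidden_b", "head_W", "head_b")
  else c("head_W", "head_b")
  names(p) <- c(nm, head_nm)
  p
}

#' @export
plot.ceph_cnn <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  invisible(x)
}

#' @export
residuals.ceph_cnn <- function(object, x, y, ...) {
  if (object$config$head != "age_regression")
    stop("residuals are defined for the age-regression head")
  y - predict(object, x)
}
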