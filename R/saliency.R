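#' Grad-CAM saliency map for one image
#'
#' Gradient-weighted class activation mapping on the last convolutional
#' feature stack: each channel weight is the global average of the gradient
#' of the target with respect to that feature map,
#' \code{alpha_r = (1/N_p) * sum_ij d target / d F_ij^r}; the map is the
#' weighted sum \code{M = sum_r alpha_r F_r}, rectified to
#' \code{M* = ReLU(M)}. For the architecture used here (features -> global
#' average pool -> linear head) the gradient with respect to each feature
#' pixel is the head weight divided by the pixel count, which the
#' implementation exploits; it agrees with finite-difference gradients (see
#' the test suite).
#'
#' @param model a fitted \code{ceph_cnn}.
#' @param image single image matrix at the model's input side.
#' @param target for the age head, "prediction" (the scalar age output); for
#'   the sex head, "true" requires \code{true_class}, or give "male"/
#'   "female" to target that class logit.
#' @param true_class optional "male"/"female" when \code{target = "true"}.
#' @return object of class \code{saliency_map}: list with \code{raw} (M),
#'   \code{rect} (M*, feature resolution), \code{alpha}, and bookkeeping
#'   fields.
#' @export
gradcam_map <- function(model, image, target = "prediction",
                        true_class = NULL) {
  check_trainable(model)
  if (!isTRUE(model$fitted)) stop("model must be fitted")
  x <- array(image, c(dim(image), 1))
  r <- forward_batched(model, x, want_features = TRUE)
  F <- r$features[[1]]
  row <- target_row(model, target, true_class)
  m <- gradcam_from_features(F, model, row)
  structure(list(raw = m$raw, rect = m$rect, alpha = m$alpha,
                 task = model$task, target = target,
                 feature_dims = dim(F)[1:2]),
            class = "saliency_map")
}

target_row <- function(model, target, true_class = NULL) {
  if (model$config$head == "age_regression") return(1L)
  if (identical(target, "true")) {
    if (is.null(true_class)) stop("target 'true' needs true_class")
    target <- true_class
  }
  switch(match.arg(target, c("male", "female", "prediction")),
         male = 1L, female = 2L,
         prediction = stop("sex-head Grad-CAM needs an explicit class target"))
}

# alpha_r = (1/N_p) sum_ij d target / d F_ij^r, computed through the head
# analytically: every feature pixel reaches the target only via the global
# average pool, so d target / d F_ij^r = (d target / d f_r) / N_p, with the
# hidden ReLU layer (if any) contributing its active-unit gating for this
# sample. M = sum_r alpha_r F_r, M* = ReLU(M).
gradcam_from_features <- function(F, model, row) {
  np <- prod(dim(F)[1:2])
  p <- model$params
  L <- length(model$config$channels)
  g <- if ((model$config$hidden %||% 0L) > 0) {
    f <- apply(F, 3, mean)
    W1 <- p[[2 * L + 1]]; b1 <- p[[2 * L + 2]]; W2 <- p[[2 * L + 3]]
    active <- as.numeric(W1 %*% f + b1) > 0
    as.numeric(W2[row, , drop = FALSE] %*% (W1 * active))
  } else {
    p[[2 * L + 1]][row, ]
  }
  alpha <- g / np
  raw <- matrix(0, dim(F)[1], dim(F)[2])
  for (r in seq_len(dim(F)[3])) raw <- raw + alpha[r] * F[, , r]
  list(raw = raw, rect = pmax(raw, 0), alpha = alpha)
}

#' Batched Grad-CAM maps for a set of subjects
#'
#' @param model a fitted \code{ceph_cnn}.
#' @param images side x side x n array.
#' @param targets for the sex head, a vector of class targets per subject
#'   (typically the true class); ignored for the age head.
#' @return list of \code{saliency_map}s.
#' @export
gradcam_maps <- function(model, images, targets = NULL) {
  check_trainable(model)
  n <- dim(images)[3]
  r <- forward_batched(model, images, want_features = TRUE)
  lapply(seq_len(n), function(i) {
    row <- if (model$config$head == "age_regression") 1L else
      target_row(model, targets[[i]])
    m <- gradcam_from_features(r$features[[i]], model, row)
    structure(list(raw = m$raw, rect = m$rect, alpha = m$alpha,
                   task = model$task, target = if (row == 1L &&
                     model$config$head == "age_regression") "prediction"
                   else c("male", "female")[row],
                   feature_dims = dim(r$features[[i]])[1:2]),
              class = "saliency_map")
  })
}

#' Upsample a saliency map to image resolution and align its orientation
#'
#' Bilinear upsampling of the rectified map to the preprocessed-image frame,
#' then a horizontal flip for mirrored subjects so all maps share the
#' standard lateral orientation. Values stay non-negative.
#'
#' @param map a \code{saliency_map} (feature resolution).
#' @param target_side side of the preprocessed image.
#' @param orientation "standard" or "mirrored" (subject metadata).
#' @return the map with an added \code{image} field (target_side square
#'   matrix, standard orientation).
#' @export
upsample_align <- function(map, target_side, orientation = "standard") {
  stopifnot(inherits(map, "saliency_map"))
  up <- bilinear_resize(map$rect, target_side, target_side)
  map$image <- align_orientation(up, orientation)
  map$image_dims <- c(target_side, target_side)
  map
}

#' Population-average saliency map
#'
#' Pixelwise arithmetic mean of aligned image-resolution maps belonging to
#' one group (age bin, or age bin x sex).
#'
#' @param maps list of upsampled \code{saliency_map}s of identical
#'   dimensions.
#' @param group_key identifier stored with the average.
#' @return object of class \code{avg_saliency_map} with fields \code{mean},
#'   \code{n}, \code{group_key}.
#' @export
group_average <- function(maps, group_key = NULL) {
  if (!length(maps)) stop("empty map list")
  mats <- lapply(maps, function(m) if (inherits(m, "saliency_map"))
    m$image %||% stop("map lacks image resolution; run upsample_align")
    else m)
  d <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == d), TRUE)))
    stop("maps have mismatched dimensions")
  structure(list(mean = Reduce(`+`, mats) / length(mats), n = length(mats),
                 group_key = group_key),
            class = "avg_saliency_map")
}

#' Render a saliency overlay
#'
#' Min-max normalizes the map, colors it on a blue-to-red ramp and
#' alpha-blends it over the grayscale image. Visualization only: indices are
#' always computed from raw saliency values. A constant map renders
#' uniformly blue.
#'
#' @param map numeric matrix (saliency, image resolution).
#' @param image grayscale matrix of the same dimensions, values in [0, 1].
#' @param alpha blend weight of the color layer.
#' @return H x W x 3 RGB array in [0, 1].
#' @export
colorize_overlay <- function(map, image, alpha = 0.45) {
  if (inherits(map, "saliency_map")) map <- map$image
  if (inherits(map, "avg_saliency_map")) map <- map$mean
  stopifnot(all(dim(map) == dim(image)))
  rng <- range(map)
  z <- if (rng[2] - rng[1] < .Machine$double.eps) map * 0 else
    (map - rng[1]) / (rng[2] - rng[1])
  col <- array(0, c(dim(map), 3))
  col[, , 1] <- z          # red rises with saliency
  col[, , 3] <- 1 - z      # blue falls
  out <- array(rep(clamp01(image), 3), c(dim(map), 3))
  (1 - alpha) * out + alpha * col
}
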