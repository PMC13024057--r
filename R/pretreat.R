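#' Contrast-limited adaptive histogram equalization
#'
#' Thin wrapper around EBImage's CLAHE with the defaults used throughout the
#' pipeline (clip limit 2, 8x8 tiles). Dimensions are preserved and output
#' intensities stay in [0, 1]. A constant image is returned unchanged.
#'
#' @param image numeric matrix in [0, 1].
#' @param clip_limit contrast clip limit.
#' @param tile_grid number of tiles per side.
#' @return equalized matrix of the same dimensions.
#' @export
equalize_contrast <- function(image, clip_limit = 2, tile_grid = 8) {
  if (length(image) == 0) stop("empty image")
  stopifnot(all(is.finite(image)))
  if (max(image) - min(image) < .Machine$double.eps) return(image)
  out <- EBImage::clahe(EBImage::Image(image), nx = tile_grid, ny = tile_grid,
                        limit = clip_limit)
  clamp01(matrix(EBImage::imageData(out), nrow(image), ncol(image)))
}

#' Rescale to a square canvas with aspect-preserving zero padding
#'
#' The longer side is scaled to \code{target_side} (bilinear); the short side
#' is rounded half-up and the image zero-padded to a square, content
#' centered, with any odd pixel of padding going to the bottom/right.
#'
#' @param image numeric matrix.
#' @param target_side side of the square output canvas (>= 2).
#' @return list(image, record) where record is a \code{geometry_record}
#'   holding scale, the four pads and the source/target dims.
#' @export
resize_and_pad <- function(image, target_side) {
  if (target_side < 2) stop("target_side must be >= 2")
  h <- nrow(image); w <- ncol(image)
  if (h == 0 || w == 0) stop("degenerate image")
  scale <- target_side / max(h, w)
  nh <- if (h >= w) target_side else floor(h * scale + 0.5)
  nw <- if (w > h) target_side else floor(w * scale + 0.5)
  resized <- if (nh == h && nw == w) image else
    matrix(EBImage::imageData(EBImage::resize(EBImage::Image(image),
                                              w = nh, h = nw)), nh, nw)
  pad_v <- target_side - nh
  pad_h <- target_side - nw
  top <- pad_v %/% 2; bottom <- pad_v - top
  left <- pad_h %/% 2; right <- pad_h - left
  out <- matrix(0, target_side, target_side)
  out[top + seq_len(nh), left + seq_len(nw)] <- resized
  rec <- structure(list(scale = scale, pad_top = top, pad_left = left,
                        pad_bottom = bottom, pad_right = right,
                        source_dims = c(h, w),
                        target_dims = c(target_side, target_side),
                        flip_applied = FALSE),
                   class = "geometry_record")
  list(image = out, record = rec)
}

#' Augmentation parameters
#'
#' @param rotation_range max absolute rotation (degrees).
#' @param translation_range max absolute translation (fraction of side).
#' @param scale_range two-element multiplicative scale range.
#' @param flip_prob horizontal flip probability.
#' @return object of class \code{augment_params}.
#' @export
augment_params <- function(rotation_range = 5, translation_range = 0.03,
                           scale_range = c(0.95, 1.05), flip_prob = 0.5) {
  stopifnot(rotation_range >= 0, translation_range >= 0,
            flip_prob >= 0, flip_prob <= 1, length(scale_range) == 2)
  structure(list(rotation_range = rotation_range,
                 translation_range = translation_range,
                 scale_range = scale_range, flip_prob = flip_prob),
            class = "augment_params")
}

#' Apply one random affine + flip augmentation
#'
#' Draws a rotation, translation and scale uniformly within the configured
#' ranges plus a Bernoulli horizontal flip, and applies them about the image
#' center (bilinear). Deterministic given the seed; identity ranges return
#' the input unchanged.
#'
#' @param image numeric matrix.
#' @param params an \code{augment_params}.
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return augmented matrix, same dimensions.
#' @export
apply_augmentation <- function(image, params = augment_params(), seed = NULL) {
  draw <- function() {
    list(rot = runif(1, -params$rotation_range, params$rotation_range),
         tr = runif(2, -params$translation_range, params$translation_range) *
           dim(image),
         sc = runif(1, params$scale_range[1], params$scale_range[2]),
         flip = runif(1) < params$flip_prob)
  }
  d <- if (is.null(seed)) draw() else with_seed(seed, draw())
  out <- image
  if (d$flip) out <- flip_horizontal(out)
  identity_affine <- abs(d$rot) < 1e-12 && all(abs(d$tr) < 1e-12) &&
    abs(d$sc - 1) < 1e-12
  if (!identity_affine) {
    th <- d$rot * pi / 180
    cy <- nrow(out) / 2; cx <- ncol(out) / 2
    # EBImage affine maps output px through m; rows/cols are dims 1/2
    a <- d$sc * cos(th); b <- d$sc * sin(th)
    # rotation+scale about center followed by translation (rows, cols)
    off <- c(cy - a * cy + b * cx + d$tr[1],
             cx - b * cy - a * cx + d$tr[2])
    m <- rbind(c(a, -b), c(b, a), off)
    out <- matrix(EBImage::imageData(
      EBImage::affine(EBImage::Image(out), m, filter = "bilinear",
                      antialias = FALSE)), nrow(out), ncol(out))
  }
  out
}

#' Map a mask through a geometry record
#'
#' Applies the same scale / pad / flip as \code{resize_and_pad} (nearest
#' neighbor, so the mask stays binary).
#'
#' @param mask logical or 0/1 matrix in the source frame.
#' @param record a \code{geometry_record}.
#' @return logical matrix in the target frame.
#' @export
transform_mask <- function(mask, record) {
  if (!all(dim(mask) == record$source_dims))
    stop("mask dimensions do not match the geometry record's source frame")
  nh <- record$target_dims[1] - record$pad_top - record$pad_bottom
  nw <- record$target_dims[2] - record$pad_left - record$pad_right
  m <- nearest_resize(mask > 0, nh, nw)
  out <- matrix(FALSE, record$target_dims[1], record$target_dims[2])
  out[record$pad_top + seq_len(nh), record$pad_left + seq_len(nw)] <- m
  if (isTRUE(record$flip_applied)) out <- flip_horizontal(out)
  out
}

#' Invert a geometry record on a mask
#'
#' Undoes flip, padding and scaling, returning the mask to the source frame
#' (nearest neighbor).
#'
#' @param mask logical matrix in the target frame.
#' @param record a \code{geometry_record}.
#' @return logical matrix in the source frame.
#' @export
invert_geometry <- function(mask, record) {
  if (!all(dim(mask) == record$target_dims))
    stop("mask dimensions do not match the geometry record's target frame")
  m <- mask > 0
  if (isTRUE(record$flip_applied)) m <- flip_horizontal(m)
  nh <- record$target_dims[1] - record$pad_top - record$pad_bottom
  nw <- record$target_dims[2] - record$pad_left - record$pad_right
  core <- m[record$pad_top + seq_len(nh), record$pad_left + seq_len(nw),
            drop = FALSE]
  nearest_resize(core, record$source_dims[1], record$source_dims[2])
}

nearest_resize <- function(m, out_rows, out_cols) {
  if (all(dim(m) == c(out_rows, out_cols))) return(m)
  ri <- pmin(pmax(ceiling((seq_len(out_rows) - 0.5) * nrow(m) / out_rows), 1),
             nrow(m))
  ci <- pmin(pmax(ceiling((seq_len(out_cols) - 0.5) * ncol(m) / out_cols), 1),
             ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Align an image or saliency map to the standard lateral orientation
#'
#' Mirrored inputs are flipped horizontally; standard inputs pass through.
#' Orientation comes from cohort metadata (pixel-based detection is out of
#' scope).
#'
#' @param x numeric matrix.
#' @param orientation "standard" or "mirrored".
#' @return matrix in standard orientation.
#' @export
align_orientation <- function(x, orientation) {
  if (!orientation %in% c("standard", "mirrored"))
    stop("unknown orientation: ", orientation)
  if (orientation == "mirrored") flip_horizontal(x) else x
}

#' Equalize a whole image stack
#'
#' Applies \code{\link{equalize_contrast}} to each image of a cohort array;
#' the standard preprocessing applied before training and saliency
#' extraction.
#'
#' @param images side x side x n array.
#' @param clip_limit,tile_grid passed to \code{equalize_contrast}.
#' @return array of the same shape.
#' @export
preprocess_images <- function(images, clip_limit = 2, tile_grid = 8) {
  for (i in seq_len(dim(images)[3]))
    images[, , i] <- equalize_contrast(images[, , i], clip_limit, tile_grid)
  images
}
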