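#' @useDynLib cephsal, .registration = TRUE
#' @importFrom graphics legend matplot par
#' @importFrom grDevices dev.off png
#' @importFrom Rcpp evalCpp
#' @importFrom stats quantile rbinom rnorm runif sd cor predict coef residuals
#' @importFrom utils head write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr under a private RNG stream, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Dice similarity between two binary masks
#'
#' @param a,b logical or 0/1 matrices of equal dimension.
#' @return Dice coefficient in [0, 1]; 1 when both masks are empty.
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  a <- a > 0; b <- b > 0
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

# Bilinear resampling with pixel-center alignment (source pixel i covers
# [i-1, i) in 0-based continuous coordinates, sampled at i - 0.5).
bilinear_resize <- function(m, out_rows, out_cols) {
  sr <- nrow(m) / out_rows
  sc <- ncol(m) / out_cols
  ry <- (seq_len(out_rows) - 0.5) * sr - 0.5
  rx <- (seq_len(out_cols) - 0.5) * sc - 0.5
  y0 <- pmin(pmax(floor(ry), 0), nrow(m) - 1)
  x0 <- pmin(pmax(floor(rx), 0), ncol(m) - 1)
  y1 <- pmin(y0 + 1, nrow(m) - 1)
  x1 <- pmin(x0 + 1, ncol(m) - 1)
  wy <- pmin(pmax(ry - y0, 0), 1)
  wx <- pmin(pmax(rx - x0, 0), 1)
  a <- m[y0 + 1, x0 + 1, drop = FALSE]
  b <- m[y0 + 1, x1 + 1, drop = FALSE]
  cc <- m[y1 + 1, x0 + 1, drop = FALSE]
  d <- m[y1 + 1, x1 + 1, drop = FALSE]
  WX <- matrix(wx, out_rows, out_cols, byrow = TRUE)
  WY <- matrix(wy, out_rows, out_cols)
  (a * (1 - WX) + b * WX) * (1 - WY) + (cc * (1 - WX) + d * WX) * WY
}

flip_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

# Derive independent child seeds from one parent seed (all < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}
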