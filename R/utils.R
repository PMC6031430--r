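#' @useDynLib optomap, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm rnorm runif fft mvfft quantile sd var pnorm
#'   complete.cases lm coef setNames median wilcox.test
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Separable Gaussian smoothing of a matrix
#'
#' Convolves a matrix with an isotropic Gaussian kernel (zero padding at the
#' boundary). Used for behavior-space density maps; callers renormalize.
#'
#' @param m numeric matrix.
#' @param sigma kernel width in matrix cells; `0` returns `m` unchanged.
#' @return smoothed matrix, same dimensions.
#' @keywords internal
smooth2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  nr <- nrow(m); nc <- ncol(m)
  # pad, convolve rows then columns
  conv1 <- function(x) {
    # x: matrix, convolve along first dimension
    np <- nrow(x) + 2 * r
    xp <- matrix(0, np, ncol(x))
    xp[(r + 1):(r + nrow(x)), ] <- x
    out <- matrix(0, nrow(x), ncol(x))
    for (j in seq_along(k)) {
      out <- out + k[j] * xp[j:(j + nrow(x) - 1L), , drop = FALSE]
    }
    out
  }
  m1 <- conv1(m)
  t(conv1(t(m1)))
}

#' Rotate an image about its center
#'
#' Bilinear inverse-mapped rotation; samples outside the source are zero.
#' Positive angles rotate the image content counter-clockwise in the
#' (column, -row) frame used throughout the package.
#'
#' @param img numeric matrix.
#' @param angle_deg rotation angle in degrees.
#' @return rotated matrix of identical size.
#' @export
rotate_image <- function(img, angle_deg) {
  th <- angle_deg * pi / 180
  if (abs(th) < 1e-12) return(img)
  h <- nrow(img); w <- ncol(img)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  # inverse rotation of target coords into source coords
  sx <- cos(th) * xx + sin(th) * yy + cx
  sy <- -sin(th) * xx + cos(th) * yy + cy
  bilinear_sample(img, sy, sx)
}

# Bilinear lookup of img at (row=sy, col=sx) matrices; out-of-range -> 0.
bilinear_sample <- function(img, sy, sx) {
  h <- nrow(img); w <- ncol(img)
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  val <- function(yi, xi) {
    ok <- yi >= 1 & yi <= h & xi >= 1 & xi <= w
    out <- numeric(length(yi))
    out[ok] <- img[cbind(yi[ok], xi[ok])]
    out
  }
  v <- (1 - fy) * (1 - fx) * val(y0, x0) +
    (1 - fy) * fx * val(y0, x0 + 1) +
    fy * (1 - fx) * val(y0 + 1, x0) +
    fy * fx * val(y0 + 1, x0 + 1)
  matrix(v, nrow(sy), ncol(sy))
}

#' Shift an image by whole pixels
#'
#' @param img numeric matrix.
#' @param dy,dx shift in rows / columns; vacated cells are zero-filled.
#' @return shifted matrix.
#' @export
shift_image <- function(img, dy, dx) {
  h <- nrow(img); w <- ncol(img)
  out <- matrix(0, h, w)
  ys <- seq_len(h) - dy
  xs <- seq_len(w) - dx
  oky <- ys >= 1 & ys <= h
  okx <- xs >= 1 & xs <= w
  out[oky, okx] <- img[ys[oky], xs[okx]]
  out
}

# Smallest power of two >= n (FFT padding).
next_pow2 <- function(n) 2^ceiling(log2(n))

# Shannon entropy in bits of a non-negative vector summing to 1.
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
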