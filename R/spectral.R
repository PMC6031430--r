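#' Dyadically spaced wavelet channel grid
#'
#' Center frequencies log2-equally spaced from `f_min` to `f_max`:
#' `f_i = f_min * 2^((i-1) * log2(f_max/f_min) / (n-1))`. The default is 25
#' channels between 1 and 50 Hz (the Nyquist frequency of a 100 fps
#' recording).
#'
#' @param f_min,f_max lowest / highest center frequency, Hz.
#' @param n number of channels (>= 2).
#' @return `channel_grid` object with `frequencies`, `f_min`, `f_max`, `n`.
#' @export
channel_grid <- function(f_min = 1, f_max = 50, n = 25) {
  stop_if_not(f_min > 0 && f_max > f_min, "need 0 < f_min < f_max")
  stop_if_not(n >= 2, "need at least 2 channels")
  f <- f_min * 2^((seq_len(n) - 1) * log2(f_max / f_min) / (n - 1))
  structure(list(frequencies = f, f_min = f_min, f_max = f_max, n = as.integer(n)),
            class = "channel_grid")
}

# Morlet scale for center frequency f (exact scale-frequency relation for
# nondimensional frequency omega0).
morlet_scale <- function(f, omega0) {
  (omega0 + sqrt(2 + omega0^2)) / (4 * pi * f)
}

#' Morlet continuous wavelet transform of postural modes
#'
#' Transforms each mode separately via FFT and retains only the amplitudes
#' of the complex coefficients. Channels are normalized so a
#' unit-amplitude sinusoid at a channel's center frequency yields peak
#' amplitude 1 at every channel. Invalid frames are zero-filled for the
#' transform and masked afterwards.
#'
#' @param modes a `postural_modes` object (or plain T x n_modes matrix).
#' @param grid a [channel_grid()]; `f_max` must not exceed `fps / 2`.
#' @param fps frames per second (taken from `modes` when available).
#' @param omega0 Morlet nondimensional frequency (default 5).
#' @param stride keep every `stride`-th output frame (the transform always
#'   runs at full rate).
#' @return `wavelet_spectrogram`: `amplitudes` array
#'   `(T_out, n_modes, n_channels)`, `frames` (0-based source frame
#'   indices), `valid`, `fps`, `omega0`, `grid`.
#' @export
morlet_cwt <- function(modes, grid, fps = NULL, omega0 = 5, stride = 1L) {
  if (inherits(modes, "postural_modes")) {
    fps <- fps %||% modes$fps
    valid <- modes$valid
    X <- modes$modes
  } else {
    X <- as.matrix(modes)
    valid <- rep(TRUE, nrow(X))
  }
  stop_if_not(!is.null(fps), "fps must be supplied")
  if (grid$f_max > fps / 2 + 1e-9)
    stop("channel grid exceeds the Nyquist frequency of the system (fps/2 = ",
         fps / 2, " Hz)", call. = FALSE)
  T_len <- nrow(X)
  if (T_len < fps / grid$f_min)
    stop("series shorter than one period of the lowest channel (",
         grid$f_min, " Hz)", call. = FALSE)
  X[!valid | is.na(X)] <- 0
  stride <- as.integer(stride)
  # mixed-radix FFT padding; a stride-divisible length enables exact
  # spectral decimation (the analytic band-passed signal is evaluated only
  # at the strided output frames via a folded short inverse FFT)
  N <- stats::nextn(T_len, c(2, 3, 5))
  fold <- stride > 1L && N %% stride == 0L
  dt <- 1 / fps
  omega <- 2 * pi * c(seq(0, N / 2), seq(-N / 2 + 1, -1)) / (N * dt)
  keep <- seq(1L, T_len, by = stride)
  n_modes <- ncol(X)
  n_ch <- grid$n
  amps <- array(0, c(length(keep), n_modes, n_ch))
  Xp <- rbind(X, matrix(0, N - T_len, n_modes))
  XF <- mvfft(Xp)
  M <- N %/% max(stride, 1L)
  for (c_i in seq_len(n_ch)) {
    f <- grid$frequencies[c_i]
    s <- morlet_scale(f, omega0)
    resp <- 0.5 * pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(2 * pi * f * s - omega0)^2 / 2)
    # the Morlet window is a Gaussian of sd 1/s rad/s around omega0/s on
    # the positive axis; restrict work to bins within 9 sd
    dw <- 2 * pi / (N * dt)
    k_lo <- max(2L, floor((omega0 / s - 9 / s) / dw) + 1L)
    k_hi <- min(N %/% 2 + 1L, ceiling((omega0 / s + 9 / s) / dw) + 1L)
    band <- k_lo:k_hi
    psi_b <- pi^(-1 / 4) * sqrt(2 * pi * s / dt) *
      exp(-(s * omega[band] - omega0)^2 / 2)
    Yb <- XF[band, , drop = FALSE] * psi_b
    if (fold) {
      # decimation identity: the strided samples' DFT is the folded spectrum
      idx <- (band - 1L) %% M
      fr <- rowsum(Re(Yb), idx)
      fi <- rowsum(Im(Yb), idx)
      folded <- matrix(0 + 0i, M, n_modes)
      rows <- as.integer(rownames(fr)) + 1L
      folded[rows, ] <- complex(real = fr, imaginary = fi)
      W <- mvfft(folded, inverse = TRUE) / N
      amps[, , c_i] <- Mod(W[seq_along(keep), , drop = FALSE]) / resp
    } else {
      YF <- matrix(0 + 0i, N, n_modes)
      YF[band, ] <- Yb
      W <- mvfft(YF, inverse = TRUE) / N
      amps[, , c_i] <- Mod(W[keep, , drop = FALSE]) / resp
    }
  }
  structure(list(
    amplitudes = amps, frames = keep - 1L, valid = valid[keep], fps = fps,
    omega0 = omega0, grid = grid
  ), class = "wavelet_spectrogram")
}

#' Normalize wavelet spectrograms into feature vectors
#'
#' Flattens the mode x channel amplitudes of each frame, applies a small
#' floor `eps` (keeping later Kullback-Leibler divergences finite) and
#' normalizes each row to sum to 1. Frames whose amplitudes are all zero
#' become uniform rows and are flagged low-power.
#'
#' @param spectrogram a [morlet_cwt()] result.
#' @param eps additive floor before normalization.
#' @return `feature_vectors`: `features` (T x n_modes*n_channels matrix,
#'   rows summing to 1), `frames`, `valid`, `low_power`, `n_modes`,
#'   `n_channels`.
#' @export
normalize_spectra <- function(spectrogram, eps = 1e-12) {
  a <- spectrogram$amplitudes
  d <- dim(a)
  X <- matrix(a, d[1], d[2] * d[3])
  rs <- rowSums(X)
  low <- rs <= 0
  X <- X + eps
  F <- X / rowSums(X)
  structure(list(
    features = F, frames = spectrogram$frames, valid = spectrogram$valid,
    low_power = low, n_modes = d[2], n_channels = d[3],
    fps = spectrogram$fps
  ), class = "feature_vectors")
}
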