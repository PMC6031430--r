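#' Segment the fly in a single frame
#'
#' Edge-based segmentation: Canny edge detection (Gaussian blur, Sobel
#' gradients, non-maximum suppression, hysteresis thresholds set from the
#' frame's maximum gradient), morphological dilation to close the outline,
#' hole filling, and retention of the largest closed contour; the filled
#' region is eroded back by the dilation radius. All pixels inside the
#' closed curve count as fly. An empty result, or a fly touching the image
#' border (partially out of frame), flags the frame invalid.
#'
#' @param frame grayscale matrix, intensities in `[0, 1]`.
#' @param low_frac,high_frac hysteresis thresholds as fractions of the
#'   maximum gradient magnitude.
#' @param dilation_radius structuring-element radius in pixels.
#' @return list: `mask` (logical matrix), `valid` (logical).
#' @export
segment_fly <- function(frame, low_frac = 0.1, high_frac = 0.3,
                        dilation_radius = 4) {
  edges <- canny_edges(frame, low_frac, high_frac)
  if (!any(edges)) {
    return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)), valid = FALSE))
  }
  brush <- EBImage::makeBrush(2 * dilation_radius + 1, "disc")
  dil <- EBImage::dilate(edges * 1, brush)
  filled <- EBImage::fillHull(dil > 0)
  lab <- EBImage::bwlabel(filled)
  sizes <- tabulate(lab[lab > 0])
  if (!length(sizes)) {
    return(list(mask = matrix(FALSE, nrow(frame), ncol(frame)), valid = FALSE))
  }
  if (length(sizes) > 1 && sort(sizes, decreasing = TRUE)[2] > 0.5 * max(sizes))
    warning("multiple similar-size components; keeping the largest")
  keep <- which.max(sizes)
  # erode back by the dilation radius plus a sub-pixel step (diamond): the
  # detected edge band straddles the outer boundary, leaving a thin halo
  mask <- EBImage::erode(EBImage::erode((lab == keep) * 1, brush),
                         EBImage::makeBrush(3, "diamond")) > 0
  mask <- matrix(as.logical(mask), nrow(frame), ncol(frame))
  h <- nrow(mask); w <- ncol(mask)
  touches <- any(mask[1, ]) || any(mask[h, ]) || any(mask[, 1]) || any(mask[, w])
  list(mask = mask, valid = any(mask) && !touches)
}

# Canny edge map (logical matrix). Thresholds relative to max gradient.
canny_edges <- function(frame, low_frac, high_frac) {
  f <- smooth2d(frame, 1)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # gradient along rows
  gx <- conv3(f, sx)
  gy <- conv3(f, t(sx))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax <= 0) return(matrix(FALSE, nrow(f), ncol(f)))
  ang <- atan2(gy, gx)  # direction of the gradient
  # quantize to 4 directions and suppress non-maxima along the gradient
  sector <- (round(ang / (pi / 4)) %% 4)
  off <- list(c(1, 0), c(1, 1), c(0, 1), c(-1, 1))
  nms <- matrix(FALSE, nrow(f), ncol(f))
  for (s in 0:3) {
    d <- off[[s + 1]]
    n1 <- shift_image(mag, d[1], d[2])
    n2 <- shift_image(mag, -d[1], -d[2])
    nms <- nms | (sector == s & mag >= n1 & mag >= n2)
  }
  weak <- nms & mag >= low_frac * mmax
  strong <- nms & mag >= high_frac * mmax
  if (!any(strong)) return(matrix(FALSE, nrow(f), ncol(f)))
  lab <- EBImage::bwlabel(weak * 1)
  keep <- unique(lab[strong])
  keep <- keep[keep > 0]
  matrix(lab %in% keep, nrow(f), ncol(f))
}

# 3x3 convolution via shifts (zero boundary).
conv3 <- function(img, k) {
  out <- matrix(0, nrow(img), ncol(img))
  for (i in -1:1) for (j in -1:1) {
    w <- k[i + 2, j + 2]
    if (w != 0) out <- out + w * shift_image(img, i, j)
  }
  out
}

#' Estimate the fly's body area from segmented frames
#'
#' Fits a two-component Gaussian mixture to the foreground pixel
#' intensities of each sampled frame; body pixels (head, thorax, abdomen)
#' belong to the brighter component, wings/legs to the dimmer one. Returns
#' the mean body-pixel count over the sample. When the mixture is
#' degenerate the split falls back to Otsu's threshold, and a frame of
#' uniform intensity contributes its full foreground area.
#'
#' @param frames list of grayscale matrices (or a `frame_stack`).
#' @param masks list of logical masks matching `frames`.
#' @param n_sample number of frames to sample (the standard procedure uses
#'   100 randomly selected images; fewer triggers a warning).
#' @param seed RNG seed for the frame sample.
#' @return mean body area in pixels.
#' @export
estimate_body_area <- function(frames, masks, n_sample = 100, seed = 1) {
  n <- length(frames)
  if (min(n, n_sample) < 100)
    warning("body-area estimate based on fewer than 100 segmented frames")
  set.seed(seed)
  idx <- if (n > n_sample) sort(sample.int(n, n_sample)) else seq_len(n)
  areas <- vapply(idx, function(i) {
    v <- frames[[i]][masks[[i]]]
    if (!length(v)) return(NA_real_)
    body_pixel_count(v)
  }, numeric(1))
  mean(areas, na.rm = TRUE)
}

# Body-pixel count among foreground intensities v (two-component GMM with
# Otsu fallback).
body_pixel_count <- function(v) {
  if (sd(v) < 1e-6) return(length(v))  # uniform blob: nothing to split
  fit <- tryCatch(
    suppressWarnings(mclust::Mclust(v, G = 2, modelNames = "V",
                                    verbose = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit) &&
      abs(diff(fit$parameters$mean)) >
      0.25 * sqrt(max(fit$parameters$variance$sigmasq))) {
    body <- which.max(fit$parameters$mean)
    return(sum(fit$classification == body))
  }
  thr <- otsu_threshold(v)
  n_hi <- sum(v > thr)
  if (n_hi == 0) length(v) else n_hi
}

# Otsu threshold on a numeric vector (256-bin histogram).
otsu_threshold <- function(v) {
  r <- range(v)
  if (diff(r) <= 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = 257)
  h <- tabulate(findInterval(v, breaks, all.inside = TRUE), nbins = 256)
  w1 <- cumsum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  m1 <- cumsum(h * mids)
  total_m <- m1[256]; total_w <- w1[256]
  mu1 <- m1 / pmax(w1, 1e-12)
  mu2 <- (total_m - m1) / pmax(total_w - w1, 1e-12)
  between <- w1 * (total_w - w1) * (mu1 - mu2)^2
  mids[which.max(between[-256])]
}

#' Rescale a frame so its fly matches a reference body area
#'
#' Applies the uniform linear scale `sqrt(reference_area / body_area)`
#' about the image center with intensity-preserving bilinear interpolation;
#' the canvas size is unchanged.
#'
#' @param frame grayscale matrix.
#' @param body_area estimated body area of this session's fly, pixels.
#' @param reference_area body area of the reference fly, pixels.
#' @return list: `frame` (rescaled matrix), `factor` (linear scale).
#' @export
rescale_frame <- function(frame, body_area, reference_area) {
  stop_if_not(body_area > 0 && reference_area > 0, "areas must be positive")
  f <- sqrt(reference_area / body_area)
  if (abs(f - 1) < 1e-12) return(list(frame = frame, factor = 1))
  h <- nrow(frame); w <- ncol(frame)
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(rep(seq_len(w), each = h), h, w)
  out <- bilinear_sample(frame, (yy - cy) / f + cy, (xx - cx) / f + cx)
  list(frame = out, factor = f)
}

#' Rotationally align a frame to a reference
#'
#' Finds the angle maximizing the angular cross-correlation of the
#' magnitudes of the two images' 2D polar Fourier transforms (translation-
#' invariant), resolves the 180-degree head/tail ambiguity of the magnitude
#' spectrum by preferring the orientation with more mass on the head side
#' of the canvas (synthetic flies are rendered head-up), and refines the
#' peak to sub-bin precision by parabolic interpolation.
#'
#' @param frame,reference same-shape grayscale matrices (segmented).
#' @param n_angles angular bins of the polar grid (default 360, i.e. 1
#'   degree resolution).
#' @return list: `angle` (degrees; rotating `frame` by `-angle` aligns it
#'   to the reference), `rotated` (the aligned frame), `valid` (`FALSE`
#'   for a flat spectrum).
#' @export
align_rotation <- function(frame, reference, n_angles = 360) {
  stop_if_not(all(dim(frame) == dim(reference)), "shape mismatch")
  pf <- polar_spectrum(frame, n_angles)
  pr <- polar_spectrum(reference, n_angles)
  if (sd(pf) < 1e-12 || sd(pr) < 1e-12) {
    return(list(angle = 0, rotated = frame, valid = FALSE))
  }
  pf <- sweep(pf, 2, colMeans(pf))
  pr <- sweep(pr, 2, colMeans(pr))
  cc <- Re(mvfft(mvfft(pf) * Conj(mvfft(pr)), inverse = TRUE))
  corr <- rowSums(cc)
  step <- 360 / n_angles
  peak <- which.max(corr)
  cand <- c(peak, ((peak - 1 + n_angles / 2) %% n_angles) + 1)
  # resolve the 180-degree ambiguity: the head side (low y, relative to the
  # fly's own centroid) carries more mass when the fly is upright
  score <- vapply(cand, function(p) {
    r <- rotate_image(frame, -(p - 1) * step)
    tot <- sum(r)
    if (tot <= 0) return(0)
    cy <- sum(t(r) * seq_len(ncol(r))) / tot
    sum(r[, seq_len(floor(cy))])
  }, numeric(1))
  best <- cand[which.max(score)]
  # parabolic refinement around the chosen peak
  cm <- corr[((best - 2) %% n_angles) + 1]
  c0 <- corr[best]
  cp <- corr[(best %% n_angles) + 1]
  denom <- cm - 2 * c0 + cp
  frac <- if (abs(denom) > 1e-12) 0.5 * (cm - cp) / denom else 0
  ang <- ((best - 1 + frac) * step) %% 360
  list(angle = ang, rotated = rotate_image(frame, -ang), valid = TRUE)
}

# Radius x angle resampling of the log-magnitude 2D Fourier spectrum.
polar_spectrum <- function(img, n_angles) {
  h <- nrow(img); w <- ncol(img)
  win <- hann2d(h, w)
  F <- fft(img * win)
  mag <- log1p(Mod(fftshift2(F)))
  cy <- floor(h / 2) + 1; cx <- floor(w / 2) + 1
  rmax <- floor(min(h, w) / 2) - 1
  radii <- seq(2, rmax, length.out = floor(min(h, w) / 2))
  angs <- 2 * pi * (seq_len(n_angles) - 1) / n_angles
  sy <- cy + outer(sin(angs), radii)
  sx <- cx + outer(cos(angs), radii)
  bilinear_sample(mag, sy, sx)  # n_angles x n_radii
}

hann2d <- function(h, w) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  yy <- matrix(seq_len(h) - cy, h, w)
  xx <- matrix(rep(seq_len(w) - cx, each = h), h, w)
  r <- sqrt((yy / (h / 2))^2 + (xx / (w / 2))^2)
  wnd <- 0.5 * (1 + cos(pi * pmin(r, 1)))
  wnd
}

fftshift2 <- function(m) {
  h <- nrow(m); w <- ncol(m)
  m[c((floor(h / 2) + 1):h, 1:floor(h / 2)),
    c((floor(w / 2) + 1):w, 1:floor(w / 2))]
}

#' Translationally align a frame to a reference
#'
#' Integer-pixel shift maximizing the circular spatial cross-correlation,
#' computed by FFT. Input should already be rotationally aligned.
#'
#' @param frame,reference same-shape grayscale matrices.
#' @return list: `dx`, `dy` (displacement of `frame` relative to the
#'   reference, first/second index), `shifted` (frame moved by
#'   `(-dx, -dy)`, i.e. aligned).
#' @export
align_translation <- function(frame, reference) {
  stop_if_not(all(dim(frame) == dim(reference)), "shape mismatch")
  h <- nrow(frame); w <- ncol(frame)
  C <- Re(fft(fft(frame) * Conj(fft(reference)), inverse = TRUE))
  peak <- which.max(C)
  iy <- ((peak - 1) %% h)
  ix <- ((peak - 1) %/% h)
  dx <- if (iy > h / 2) iy - h else iy
  dy <- if (ix > w / 2) ix - w else ix
  list(dx = dx, dy = dy, shifted = shift_image(frame, -dx, -dy))
}

#' Prepare a raw frame stack for postural decomposition
#'
#' Runs the full canonicalization chain per frame: segmentation, masking,
#' session-level size normalization, rotational alignment to a common
#' reference and translational registration. Invalid frames (failed
#' segmentation, border contact, flat spectra) are carried through as gaps.
#'
#' @param stack a `frame_stack` (e.g. from [render_movie()]).
#' @param reference_area target body area, pixels; defaults to this
#'   session's own estimate (scale factor 1).
#' @param reference optional reference frame; defaults to the first valid
#'   prepared frame.
#' @param n_area_sample frames sampled for the body-area estimate.
#' @return a `frame_stack` with aligned `frames`, updated `valid`,
#'   `scale_factor`, per-frame `angles_deg`, `shifts`, and
#'   `fraction_valid`.
#' @export
prepare_frames <- function(stack, reference_area = NULL, reference = NULL,
                           n_area_sample = 100) {
  T_len <- dim(stack$frames)[3]
  frames <- lapply(seq_len(T_len), function(t) stack$frames[, , t])
  segs <- lapply(frames, segment_fly)
  valid <- vapply(segs, `[[`, logical(1), "valid") &
    (stack$valid %||% rep(TRUE, T_len))
  masked <- lapply(seq_len(T_len), function(t) frames[[t]] * segs[[t]]$mask)
  ok <- which(valid)
  stop_if_not(length(ok) > 0, "no valid frames to prepare")
  area <- suppressWarnings(estimate_body_area(masked[ok],
                                              lapply(segs[ok], `[[`, "mask"),
                                              n_sample = n_area_sample))
  reference_area <- reference_area %||% area
  factor <- sqrt(reference_area / area)
  out <- array(0, dim(stack$frames))
  angles <- numeric(T_len); sx <- integer(T_len); sy <- integer(T_len)
  for (t in ok) {
    fr <- rescale_frame(masked[[t]], area, reference_area)$frame
    if (is.null(reference)) reference <- fr
    ra <- align_rotation(fr, reference)
    if (!ra$valid) { valid[t] <- FALSE; next }
    tr <- align_translation(ra$rotated, reference)
    out[, , t] <- tr$shifted
    angles[t] <- ra$angle; sx[t] <- tr$dx; sy[t] <- tr$dy
  }
  structure(list(
    frames = out, valid = valid, fps = stack$fps, scale_factor = factor,
    angles_deg = angles, shifts = cbind(dx = sx, dy = sy),
    fraction_valid = mean(valid), reference = reference
  ), class = "frame_stack")
}
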