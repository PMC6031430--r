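#' Radon transform of one aligned frame
#'
#' Pixel-driven line-integral projections over angles
#' `{0, angle_spacing, ..., 180 - angle_spacing}` degrees: each pixel's
#' intensity is distributed linearly between the two offset bins adjacent
#' to its projection, so the total image mass is conserved exactly at
#' every angle.
#'
#' @param image square numeric matrix (aligned frame).
#' @param angle_spacing projection angle spacing, degrees (default 2,
#'   giving 90 projection angles).
#' @return matrix `n_offsets x n_angles` (the sinogram); attributes
#'   `angles` (degrees) and `offsets` (pixels from center).
#' @export
radon_frame <- function(image, angle_spacing = 2) {
  stop_if_not(nrow(image) == ncol(image), "image must be square and aligned")
  n <- nrow(image)
  angles <- seq(0, 180 - angle_spacing, by = angle_spacing)
  cy <- (n + 1) / 2
  yy <- as.vector(matrix(seq_len(n), n, n)) - cy
  xx <- as.vector(matrix(rep(seq_len(n), each = n), n, n)) - cy
  v <- as.vector(image)
  dmax <- ceiling(sqrt(2) * n / 2) + 1
  offsets <- seq(-dmax, dmax)
  nb <- length(offsets)
  sino <- matrix(0, nb, length(angles))
  for (a in seq_along(angles)) {
    th <- angles[a] * pi / 180
    t0 <- xx * cos(th) + yy * sin(th) + dmax + 1  # 1-based bin coordinate
    i0 <- floor(t0)
    wf <- t0 - i0
    acc <- numeric(nb + 1)
    s1 <- rowsum(v * (1 - wf), i0)
    s2 <- rowsum(v * wf, i0 + 1)
    acc[as.integer(rownames(s1))] <- acc[as.integer(rownames(s1))] + s1
    acc[as.integer(rownames(s2))] <- acc[as.integer(rownames(s2))] + s2
    sino[, a] <- acc[seq_len(nb)]
  }
  attr(sino, "angles") <- angles
  attr(sino, "offsets") <- offsets
  sino
}

#' Radon-transform a prepared frame stack
#'
#' @param stack a prepared `frame_stack`.
#' @param angle_spacing projection angle spacing, degrees.
#' @return `radon_stack` object: `pixels` (T x P matrix of flattened
#'   sinograms; invalid frames are `NA` rows), `valid`, `fps`, `geometry`
#'   (image size, angle spacing, sinogram dimensions).
#' @export
radon_stack <- function(stack, angle_spacing = 2) {
  T_len <- dim(stack$frames)[3]
  first <- radon_frame(stack$frames[, , 1], angle_spacing)
  P <- length(first)
  X <- matrix(NA_real_, T_len, P)
  for (t in seq_len(T_len)) {
    if (!stack$valid[t]) next
    X[t, ] <- as.vector(radon_frame(stack$frames[, , t], angle_spacing))
  }
  structure(list(
    pixels = X, valid = stack$valid, fps = stack$fps,
    geometry = list(img_size = nrow(stack$frames),
                    angle_spacing = angle_spacing,
                    n_offsets = nrow(first), n_angles = ncol(first))
  ), class = "radon_stack")
}

#' Select high-variance Radon pixels
#'
#' Keeps the smallest set of highest-variance Radon-space pixels whose
#' summed variance reaches the target fraction of the total variance
#' (default 95%). The retained count is data-dependent and recorded.
#'
#' @param rstack a [radon_stack()] (or plain T x P matrix).
#' @param target_variance fraction of total variance to capture, in (0, 1].
#' @return `pixel_selection` object: `indices` (sorted), `variance_fraction_captured`,
#'   `n_total`, `geometry`.
#' @export
select_pixels <- function(rstack, target_variance = 0.95) {
  X <- if (inherits(rstack, "radon_stack")) rstack$pixels else rstack
  X <- X[complete.cases(X), , drop = FALSE]
  stop_if_not(nrow(X) >= 2, "need at least 2 valid frames")
  stop_if_not(target_variance > 0 && target_variance <= 1,
              "target_variance must lie in (0, 1]")
  v <- apply(X, 2, var)
  tot <- sum(v)
  stop_if_not(tot > 0, "zero total variance in Radon stack")
  ord <- order(v, decreasing = TRUE)
  cs <- cumsum(v[ord]) / tot
  k <- which(cs >= target_variance - 1e-12)[1]
  idx <- sort(ord[seq_len(k)])
  structure(list(
    indices = idx, variance_fraction_captured = cs[k], n_total = length(v),
    geometry = if (inherits(rstack, "radon_stack")) rstack$geometry else NULL
  ), class = "pixel_selection")
}

#' Principal components of the selected Radon pixels
#'
#' Plain PCA (mean-centered, no per-pixel standardization) of the retained
#' Radon-space pixels, keeping the `n_modes` top-variance modes (default
#' 50).
#'
#' @param rstack a [radon_stack()].
#' @param selection a [select_pixels()] result.
#' @param n_modes number of postural modes to keep.
#' @return `pca_basis` object: `mean`, `rotation` (pixels x modes,
#'   orthonormal columns), `eigenvalues` (non-increasing),
#'   `variance_fraction`, `n_modes`, `geometry`.
#' @export
fit_postural_pca <- function(rstack, selection, n_modes = 50) {
  X <- if (inherits(rstack, "radon_stack")) rstack$pixels else rstack
  X <- X[complete.cases(X), selection$indices, drop = FALSE]
  stop_if_not(nrow(X) >= 2, "need at least 2 valid frames")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc, nu = 0, nv = min(n_modes, ncol(X)))
  rank_num <- sum(sv$d > sv$d[1] * 1e-9)
  if (n_modes > rank_num) {
    warning(sprintf("n_modes = %d exceeds numerical rank %d; truncating",
                    n_modes, rank_num))
    n_modes <- rank_num
  }
  sv$v <- sv$v[, seq_len(n_modes), drop = FALSE]
  eig_all <- sv$d^2 / (nrow(X) - 1)
  total <- sum(apply(X, 2, var))
  structure(list(
    mean = mu, rotation = sv$v, eigenvalues = eig_all[seq_len(n_modes)],
    all_eigenvalues = eig_all, total_variance = total,
    variance_fraction = sum(eig_all[seq_len(n_modes)]) / total,
    n_modes = n_modes, selection = selection$indices,
    geometry = selection$geometry
  ), class = "pca_basis")
}

#' Project frames onto the postural modes
#'
#' Centers the selected Radon pixels with the training mean and projects
#' onto the PCA basis; invalid frames give masked (NA) rows. Refuses
#' geometry mismatches between the stack and the fitted basis.
#'
#' @param rstack a [radon_stack()].
#' @param basis a [fit_postural_pca()] result.
#' @return `postural_modes` object: `modes` (T x n_modes), `valid`, `fps`.
#' @export
project_frames <- function(rstack, basis) {
  if (!is.null(basis$geometry) && !is.null(rstack$geometry) &&
      !identical(rstack$geometry, basis$geometry))
    stop("geometry mismatch between Radon stack and PCA basis", call. = FALSE)
  X <- rstack$pixels[, basis$selection, drop = FALSE]
  ok <- complete.cases(X)
  scores <- matrix(NA_real_, nrow(X), basis$n_modes)
  scores[ok, ] <- sweep(X[ok, , drop = FALSE], 2, basis$mean) %*% basis$rotation
  structure(list(modes = scores, valid = ok & rstack$valid, fps = rstack$fps),
            class = "postural_modes")
}
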