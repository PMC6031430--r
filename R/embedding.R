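#' Kullback-Leibler divergence between two spectra
#'
#' `KL(p, q) = sum_i p_i log2(p_i / q_i)` in bits. Inputs must be floored,
#' normalized feature rows (each summing to 1); unnormalized input is an
#' error. Non-negative, zero iff `p == q`, and asymmetric in general.
#'
#' @param p,q numeric vectors summing to 1.
#' @return divergence in bits.
#' @export
kl_distance <- function(p, q) {
  stop_if_not(length(p) == length(q), "length mismatch")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6)
    stop("kl_distance expects normalized probability vectors", call. = FALSE)
  ok <- p > 0
  sum(p[ok] * log2(p[ok] / q[ok]))
}

# All-pairs KL divergences (bits): rows of A against rows of B.
# D[i, j] = sum_d A[i,d] log2 A[i,d] - sum_d A[i,d] log2 B[j,d].
kl_cross_matrix <- function(A, B) {
  hA <- rowSums(A * log2(A))
  D <- hA - A %*% t(log2(B))
  D[D < 0] <- 0  # clip numerical negatives
  D
}

# Perplexity-calibrated conditional affinities from a distance matrix.
# Rows are points, columns neighbors; diag (or self) excluded by `self`.
# Returns row-stochastic P.
perplexity_affinities <- function(D, perplexity, self = TRUE, tol = 1e-5,
                                  max_iter = 50) {
  n <- nrow(D)
  logU <- log(perplexity)
  P <- matrix(0, n, ncol(D))
  for (i in seq_len(n)) {
    di <- D[i, ]
    if (self) di[i] <- Inf
    beta <- 1; bmin <- -Inf; bmax <- Inf
    for (it in seq_len(max_iter)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw <= 0) { beta <- beta / 2; next }
      p <- w / sw
      H <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(H - logU) < tol) break
      if (H > logU) { bmin <- beta; beta <- if (is.finite(bmax)) (beta + bmax) / 2 else beta * 2 }
      else { bmax <- beta; beta <- if (is.finite(bmin)) (beta + bmin) / 2 else beta / 2 }
    }
    P[i, ] <- w / sum(w)
  }
  P
}

#' Importance subsampling of one session's feature vectors
#'
#' Selects `quota` exemplar frames covering the session's occupied
#' behavior space approximately uniformly: frames are drawn with
#' probability inversely proportional to their local density, so rare
#' behaviors are strongly over-represented relative to uniform sampling.
#' Local density is a Gaussian kernel sum over the session's pairwise
#' KL divergences, with the bandwidth set from the mean divergence so
#' that distinct behaviors separate regardless of the absolute distance
#' scale.
#'
#' @param features a `feature_vectors` object (or plain row-stochastic
#'   matrix).
#' @param quota exemplars to draw (default 600 per session).
#' @param seed RNG seed.
#' @param max_rows cap on rows entering the draw.
#' @param n_ref reference rows the kernel density is evaluated against
#'   (a random subset; keeps the cost linear in the session length).
#' @param bandwidth_frac kernel bandwidth as a fraction of the mean
#'   divergence to the reference rows.
#' @param ... ignored (historical arguments).
#' @return integer indices of the exemplar rows (into the session's valid
#'   rows as supplied).
#' @export
importance_subsample <- function(features, quota = 600, seed = 1,
                                 max_rows = 5000, n_ref = 500,
                                 bandwidth_frac = 0.25, ...) {
  X <- if (inherits(features, "feature_vectors")) features$features else features
  n <- nrow(X)
  if (quota >= n) {
    if (quota > n) warning("quota exceeds available rows; taking all rows")
    return(seq_len(n))
  }
  set.seed(seed)
  sub <- if (n > max_rows) sort(sample.int(n, max_rows)) else seq_len(n)
  Xs <- X[sub, , drop = FALSE]
  ref <- if (length(sub) > n_ref) sample(seq_along(sub), n_ref)
         else seq_along(sub)
  D <- kl_cross_matrix(Xs, Xs[ref, , drop = FALSE])
  h <- max(mean(D) * bandwidth_frac, 1e-12)
  dens <- rowSums(exp(-D / h))
  w <- 1 / pmax(dens, 1e-12)
  picked <- sample(seq_along(sub), quota, prob = w / sum(w))
  sort(sub[picked])
}

#' Hierarchical training-set construction across sessions
#'
#' Round 1 draws `quota` importance-sampled exemplars from every session.
#' While more than `final` exemplars remain, they are randomly partitioned
#' into groups of about `group_size` rows and each group is importance-
#' subsampled again, keeping twice as many points per group as in the
#' previous round, until one pool of at most `final` rows remains. The
#' defaults reproduce the standard 600-per-session / 36,000-point
#' construction.
#'
#' @param sessions list of `feature_vectors` (one per recording session).
#' @param quota per-session exemplar count (round 1).
#' @param group_size rows per group in later rounds.
#' @param final target training-set size.
#' @param seed RNG seed.
#' @return `training_set`: `features` (matrix), `provenance` (data.frame
#'   `session`, `row`), `params`.
#' @export
hierarchical_training_set <- function(sessions, quota = 600,
                                      group_size = 36000, final = 36000,
                                      seed = 1) {
  stop_if_not(length(sessions) >= 1, "need at least one session")
  pool <- NULL
  prov <- NULL
  for (s in seq_along(sessions)) {
    fv <- sessions[[s]]
    X <- fv$features[fv$valid, , drop = FALSE]
    rows <- which(fv$valid)
    idx <- importance_subsample(X, quota = min(quota, nrow(X)),
                                seed = seed + s)
    pool <- rbind(pool, X[idx, , drop = FALSE])
    prov <- rbind(prov, data.frame(session = s, row = rows[idx]))
  }
  keep_per_group <- quota
  round <- 1L
  set.seed(seed)
  while (nrow(pool) > final) {
    round <- round + 1L
    keep_per_group <- keep_per_group * 2L
    n <- nrow(pool)
    n_groups <- max(1L, ceiling(n / group_size))
    grp <- sample(rep(seq_len(n_groups), length.out = n))
    keep_idx <- integer(0)
    for (g in seq_len(n_groups)) {
      rows_g <- which(grp == g)
      idx <- importance_subsample(pool[rows_g, , drop = FALSE],
                                  quota = min(keep_per_group, length(rows_g)),
                                  seed = seed + 1000L * round + g)
      keep_idx <- c(keep_idx, rows_g[idx])
    }
    if (length(keep_idx) >= nrow(pool)) break  # cannot shrink further
    pool <- pool[keep_idx, , drop = FALSE]
    prov <- prov[keep_idx, , drop = FALSE]
  }
  if (nrow(pool) > final) {
    sel <- sort(sample.int(nrow(pool), final))
    pool <- pool[sel, , drop = FALSE]
    prov <- prov[sel, , drop = FALSE]
  }
  structure(list(features = pool, provenance = prov,
                 params = list(quota = quota, group_size = group_size,
                               final = final, seed = seed)),
            class = "training_set")
}

#' Train the 2D behavior-space embedding
#'
#' Minimizes the t-SNE objective over affinities derived from pairwise
#' KL divergences between the training feature vectors (perplexity-
#' calibrated Gaussian kernels on the KL distances, symmetrized as
#' `(p_ij + p_ji) / 2`). Fully seeded; the converged cost is recorded.
#'
#' @param training_set a [hierarchical_training_set()] result (or plain
#'   feature matrix).
#' @param perplexity t-SNE perplexity (default 32).
#' @param n_iter gradient-descent iterations (default 1000).
#' @param seed RNG seed for the initial layout.
#' @param eta learning rate.
#' @return `training_embedding`: `Y` (n x 2), `cost`, `features`,
#'   hyperparameter provenance.
#' @export
tsne_embed <- function(training_set, perplexity = 32, n_iter = 1000,
                       seed = 1, eta = 200) {
  X <- if (inherits(training_set, "training_set")) training_set$features
       else training_set
  bad <- which(!apply(is.finite(X), 1, all))
  if (length(bad))
    stop("non-finite feature rows: ", paste(head(bad, 5), collapse = ", "),
         call. = FALSE)
  D <- kl_cross_matrix(X, X)
  if (!all(is.finite(D))) {
    bad <- which(!apply(is.finite(D), 1, all))
    stop("non-finite KL distances for rows: ",
         paste(head(bad, 5), collapse = ", "), call. = FALSE)
  }
  P <- perplexity_affinities(D, min(perplexity, (nrow(X) - 1) / 3))
  P <- (P + t(P)) / (2 * nrow(P))
  set.seed(seed)
  Y0 <- matrix(rnorm(2 * nrow(X), sd = 1e-4), ncol = 2)
  fit <- tsne_cpp(P, Y0, n_iter, eta = eta, exaggeration = 12,
                  exag_iter = min(250, n_iter %/% 4))
  structure(list(
    Y = fit$Y, cost = fit$cost, features = X,
    params = list(perplexity = perplexity, n_iter = n_iter, seed = seed,
                  eta = eta)
  ), class = "training_embedding")
}

#' Re-embed feature vectors into a trained behavior space
#'
#' Places each new frame at the 2D position minimizing its t-SNE-style
#' cost against the training points (seeded gradient descent from the
#' best-matching training position). Points failing the convergence test
#' (final gradient norm below `grad_tol` and non-increasing cost over the
#' last 10 steps) fall back to the median position of their `k` nearest
#' training rows.
#'
#' @param features a `feature_vectors` object (or plain matrix).
#' @param embedding a [tsne_embed()] result.
#' @param perplexity affinity perplexity for placement (default 5: each
#'   frame is placed against its handful of nearest training exemplars,
#'   which puts training rows back onto their own trained positions).
#' @param n_iter maximum gradient steps per point (points stop early once
#'   the gradient norm falls below `grad_tol`).
#' @param k fallback neighbor count.
#' @param grad_tol convergence threshold on the gradient norm.
#' @param chunk rows processed per block (bounds memory).
#' @param k_aff training neighbors entering the affinity calibration
#'   (weights farther out are negligible at small perplexity).
#' @return `embedded_points`: data.frame `frame` (0-based), `x`, `y`,
#'   `valid`, `converged`; invalid input rows keep `NA` coordinates.
#' @export
reembed <- function(features, embedding, perplexity = 5, n_iter = 80, k = 10,
                    grad_tol = 1e-5, chunk = 4000, k_aff = 64) {
  fv <- inherits(features, "feature_vectors")
  X <- if (fv) features$features else features
  valid <- if (fv) features$valid else rep(TRUE, nrow(X))
  frames <- if (fv) features$frames else seq_len(nrow(X)) - 1L
  perp <- min(perplexity, (nrow(embedding$features) - 1) / 3)
  n <- nrow(X)
  xy <- matrix(NA_real_, n, 2)
  conv <- rep(NA, n)
  idx_valid <- which(valid)
  for (start in seq(1, length(idx_valid), by = chunk)) {
    rows <- idx_valid[start:min(start + chunk - 1, length(idx_valid))]
    D <- kl_cross_matrix(X[rows, , drop = FALSE], embedding$features)
    fit <- reembed_chunk_cpp(t(D), embedding$Y, perp, n_iter, eta = 0.5,
                             grad_tol = grad_tol, k_aff = k_aff)
    ok <- fit$grad_norm < grad_tol & fit$monotone
    if (any(!ok)) {
      for (i in which(!ok)) {
        nb <- order(D[i, ])[seq_len(k)]
        fit$Y[i, ] <- apply(embedding$Y[nb, , drop = FALSE], 2, median)
      }
    }
    xy[rows, ] <- fit$Y
    conv[rows] <- ok
  }
  structure(data.frame(frame = frames, x = xy[, 1], y = xy[, 2],
                       valid = valid, converged = conv),
            class = c("embedded_points", "data.frame"))
}
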