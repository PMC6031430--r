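#' Assign a trial's post-stimulus region
#'
#' Finds the mode of the trial's behavior-space density during the first
#' second after stimulus onset (smoothed, argmax cell; ties broken
#' row-major and logged). The trial is assigned to the nearest region
#' whose edge lies within `tol` grid cells of the mode (ties by smaller
#' distance, then smaller region id); trials farther than `tol` from every
#' region receive the 'zero' label.
#'
#' @param points the trial's embedded points during the post window
#'   (data.frame `x`, `y`).
#' @param regions a `region_set` (typically the significant regions).
#' @param grid a [map_grid()].
#' @param tol assignment tolerance in grid cells (default 5).
#' @param sigma mode-density smoothing in grid cells.
#' @param distance_maps optional precomputed [region_distance_maps()].
#' @return list: `label` (0 = zero label), `mode` (cell `c(ix, iy)`),
#'   `distance` (to the assigned region; 0 inside).
#' @export
assign_post_region <- function(points, regions, grid, tol = 5, sigma = 1.5,
                               distance_maps = NULL) {
  d <- density_map(points, grid, sigma)
  if (isTRUE(attr(d, "empty")))
    stop("no valid frames in the post-stimulus window", call. = FALSE)
  peak <- which(d == max(d))
  if (length(peak) > 1)
    message("degenerate density mode; first cell in row-major order used")
  peak <- peak[1]
  cell <- c(((peak - 1) %% grid$n) + 1, ((peak - 1) %/% grid$n) + 1)
  if (regions$n_regions == 0)
    return(list(label = 0L, mode = cell, distance = Inf))
  dm <- distance_maps %||% region_distance_maps(regions)
  dists <- vapply(dm, function(m) m[cell[1], cell[2]], numeric(1))
  k <- which.min(dists)  # ties: smaller id wins (which.min is first)
  if (dists[k] <= tol) list(label = as.integer(k), mode = cell,
                            distance = dists[k])
  else list(label = 0L, mode = cell, distance = dists[k])
}

#' Build pre-density / post-region assignments for all trials
#'
#' For every fly and cycle: the pre-stimulus density over
#' `pre_window_s` (default `[-1.5, -0.5)` s relative to onset) and the
#' post-stimulus region label from [assign_post_region()] over
#' `post_window_s` (default `[0, 1)` s). Trials without valid frames in
#' either window are dropped (logged).
#'
#' @param embedded list of `embedded_points` data frames (one per fly).
#' @param schedule an [make_led_schedule()] object.
#' @param regions a `region_set`.
#' @param grid a [map_grid()].
#' @param pre_window_s,post_window_s windows in seconds relative to onset.
#' @param tol assignment tolerance in grid cells.
#' @param sigma density smoothing in grid cells.
#' @return `trial_assignments`: `pre` (n_cells x n_trials matrix of
#'   normalized pre densities), `label` (integer vector), `info`
#'   (data.frame `fly`, `cycle`), `grid`, `regions`, `n_dropped`.
#' @export
trial_assignments <- function(embedded, schedule, regions, grid,
                              pre_window_s = c(-1.5, -0.5),
                              post_window_s = c(0, 1), tol = 5,
                              sigma = 1.5) {
  dm <- region_distance_maps(regions)
  pre_list <- list(); labels <- integer(0); info <- NULL; dropped <- 0L
  for (i in seq_along(embedded)) {
    pts <- embedded[[i]]
    pts <- pts[pts$valid & !is.na(pts$x), , drop = FALSE]
    for (n in seq_len(schedule$n_cycles)) {
      onset <- schedule$onset_frames[n]
      pre_sel <- pts$frame >= onset + pre_window_s[1] * schedule$fps &
        pts$frame < onset + pre_window_s[2] * schedule$fps
      post_sel <- pts$frame >= onset + post_window_s[1] * schedule$fps &
        pts$frame < onset + post_window_s[2] * schedule$fps
      if (!any(pre_sel) || !any(post_sel)) { dropped <- dropped + 1L; next }
      pre_d <- density_map(pts[pre_sel, , drop = FALSE], grid, sigma)
      if (isTRUE(attr(pre_d, "empty"))) { dropped <- dropped + 1L; next }
      asg <- assign_post_region(pts[post_sel, , drop = FALSE], regions, grid,
                                tol = tol, sigma = sigma, distance_maps = dm)
      pre_list[[length(pre_list) + 1L]] <- as.vector(pre_d)
      labels <- c(labels, asg$label)
      info <- rbind(info, data.frame(fly = i, cycle = n))
    }
  }
  if (dropped > 0)
    message(dropped, " trial(s) without valid frames dropped")
  stop_if_not(length(labels) > 0, "no usable trials")
  structure(list(pre = do.call(cbind, pre_list), label = labels,
                 info = info, grid = grid, regions = regions,
                 n_dropped = dropped),
            class = "trial_assignments")
}

#' Plug-in mutual information between pre-stimulus density and
#' post-stimulus region
#'
#' `MI = sum_k p(R_k) sum_x p_pre(x | R_k) log2[ p_pre(x | R_k) /
#' sum_l p_pre(x | R_l) p(R_l) ]`, discretized on the grid. Conditional
#' densities are the normalized mean pre-window densities of the trials
#' carrying each label (the zero label included). Bounded above by
#' `log2(N + 1)` for `N` regions plus the zero label.
#'
#' @param assignments a [trial_assignments()] result, or a list with
#'   fields `pre` (cells x trials matrix) and `label`.
#' @param trial_subset optional indices of trials to use (resampling).
#' @return `mi_estimate`: `mi` (bits), `p_label`, `labels`, `cond`
#'   (cells x labels matrix), `marginal`, `n_trials`.
#' @export
mutual_information <- function(assignments, trial_subset = NULL) {
  lab <- assignments$label
  pre <- assignments$pre
  if (!is.null(trial_subset)) {
    lab <- lab[trial_subset]
    pre <- pre[, trial_subset, drop = FALSE]
  }
  cs <- colSums(pre)
  if (any(abs(cs - 1) > 1e-6))
    stop("pre-window conditional densities must be normalized", call. = FALSE)
  labs <- sort(unique(lab))
  n <- length(lab)
  if (length(labs) < 2) {
    return(structure(list(mi = 0, p_label = setNames(1, labs[1]),
                          labels = labs, cond = NULL, marginal = NULL,
                          n_trials = n), class = "mi_estimate"))
  }
  p_label <- vapply(labs, function(l) mean(lab == l), numeric(1))
  cond <- vapply(labs, function(l) {
    m <- rowMeans(pre[, lab == l, drop = FALSE])
    m / sum(m)
  }, numeric(nrow(pre)))
  marginal <- as.vector(cond %*% p_label)
  mi <- 0
  for (k in seq_along(labs)) {
    ok <- cond[, k] > 0 & marginal > 0
    mi <- mi + p_label[k] *
      sum(cond[ok, k] * log2(cond[ok, k] / marginal[ok]))
  }
  structure(list(mi = max(mi, 0), p_label = setNames(p_label, labs),
                 labels = labs, cond = cond, marginal = marginal,
                 n_trials = n), class = "mi_estimate")
}

#' Partial mutual-information map for one region
#'
#' Cellwise contribution of region `k` to the mutual information:
#' `p(R_k) p_pre(x | R_k) log2[ p_pre(x | R_k) / marginal(x) ]`. Summed
#' over cells and regions these maps reconstruct the total MI exactly.
#'
#' @param mi_fit a [mutual_information()] result.
#' @param k region label (an element of `mi_fit$labels`; 0 = zero label).
#' @param grid optional [map_grid()] to shape the output as a matrix.
#' @return vector (or matrix) over grid cells.
#' @export
partial_mi_map <- function(mi_fit, k, grid = NULL) {
  j <- match(k, mi_fit$labels)
  stop_if_not(!is.na(j), "label %s not present", as.character(k))
  v <- numeric(length(mi_fit$marginal))
  ok <- mi_fit$cond[, j] > 0 & mi_fit$marginal > 0
  v[ok] <- mi_fit$p_label[j] * mi_fit$cond[ok, j] *
    log2(mi_fit$cond[ok, j] / mi_fit$marginal[ok])
  if (!is.null(grid)) matrix(v, grid$n, grid$n) else v
}

#' Finite-size bias-corrected mutual information
#'
#' The plug-in MI estimator is biased upward at finite trial counts.
#' Following the standard subsampling correction, the plug-in MI is
#' recomputed on bootstrap subsets drawn with replacement at several
#' fractions of the data and the mean MI is extrapolated linearly in the
#' reciprocal of the effective sample size to an infinite number of
#' trials; the variance is extrapolated the same way. Because draws are
#' with replacement, a subset of nominal size `f * n` contains
#' `n * (1 - exp(-f))` distinct trials in expectation, and that effective
#' count is what the small-sample bias scales with, so it is used as the
#' extrapolation abscissa.
#'
#' @param assignments a [trial_assignments()] result.
#' @param fractions subsample fractions.
#' @param n_boot bootstrap resamples (with replacement) per fraction.
#' @param seed RNG seed.
#' @return `mi_estimate` with fields `mi` (raw plug-in), `mi_corrected`,
#'   `sd` (extrapolated), `fractions`, `curve` (per-fraction mean/var),
#'   `n_trials`.
#' @export
bias_correct <- function(assignments, fractions = c(0.5, 0.625, 0.75, 0.875, 1),
                         n_boot = 100, seed = 1) {
  n <- length(assignments$label)
  if (n < 20) warning("fewer than 20 trials; extrapolation unstable")
  set.seed(seed)
  raw <- mutual_information(assignments)$mi
  means <- vars <- numeric(length(fractions))
  ns <- pmax(2L, round(fractions * n))
  for (f in seq_along(fractions)) {
    mis <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, ns[f], replace = TRUE)
      mutual_information(assignments, trial_subset = idx)$mi
    }, numeric(1))
    means[f] <- mean(mis)
    vars[f] <- var(mis)
  }
  x <- 1 / (n * (1 - exp(-ns / n)))  # expected distinct trials per subset
  fit <- tryCatch(lm(means ~ x), error = function(e) NULL)
  if (is.null(fit) || anyNA(coef(fit))) {
    warning("extrapolation ill-conditioned; returning raw MI")
    corrected <- raw; sd_out <- sd(means)
  } else {
    corrected <- unname(coef(fit)[1])
    vfit <- lm(vars ~ x)
    sd_out <- sqrt(max(unname(coef(vfit)[1]), 0))
    if (sd_out == 0) sd_out <- sqrt(max(vars[length(vars)], 0))
  }
  structure(list(mi = raw, mi_corrected = corrected, sd = sd_out,
                 fractions = fractions,
                 curve = data.frame(n = ns, mean = means, var = vars),
                 n_trials = n), class = "mi_estimate")
}

#' @export
print.mi_estimate <- function(x, ...) {
  if (!is.null(x$mi_corrected))
    cat(sprintf("MI: %.4f bits (raw %.4f, sd %.4f, %d trials)\n",
                x$mi_corrected, x$mi, x$sd, x$n_trials))
  else cat(sprintf("MI: %.4f bits (%d trials)\n", x$mi, x$n_trials))
  invisible(x)
}

#' Context dependence of experimental versus control flies
#'
#' Computes the bias-corrected mutual information between pre-stimulus
#' density and post-stimulus region separately for the experimental and
#' control arms, using the experimental arm's significant regions for
#' both (the control arm is scored against the same map geometry).
#'
#' @param embedded list of `embedded_points` data frames (all flies).
#' @param roles character vector, `"experimental"` / `"control"`.
#' @param schedule an [make_led_schedule()] object.
#' @param regions the experimental arm's significant `region_set`.
#' @param grid a [map_grid()].
#' @param ... passed to [trial_assignments()] and [bias_correct()].
#' @param n_boot,seed bias-correction parameters.
#' @return list: `experimental`, `control` (both `mi_estimate`).
#' @export
experimental_vs_control_mi <- function(embedded, roles, schedule, regions,
                                       grid, n_boot = 100, seed = 1, ...) {
  arm <- function(role, s) {
    asg <- trial_assignments(embedded[roles == role], schedule, regions,
                             grid, ...)
    bias_correct(asg, n_boot = n_boot, seed = s)
  }
  list(experimental = arm("experimental", seed),
       control = arm("control", seed + 1L))
}
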