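#' Stimulation and reference windows of a trial
#'
#' The stimulation window is the first 3 s of LED on (`t = 0` to `3` s
#' after onset) and the reference window the 15 s furthest from
#' stimulation (`t = 30` to `45` s), following the standard analysis. Both
#' are expressed as 0-based frame offsets from the cycle onset.
#'
#' @param schedule an [make_led_schedule()] object.
#' @param on_window,off_window window bounds in seconds from onset.
#' @return list: `on` and `off` integer frame-offset vectors, plus the
#'   window definitions in seconds.
#' @export
trial_windows <- function(schedule, on_window = c(0, 3),
                          off_window = c(30, 45)) {
  cyc_s <- schedule$cycle_frames / schedule$fps
  if (off_window[2] > cyc_s)
    stop("cycle (", cyc_s, " s) shorter than the reference window end (",
         off_window[2], " s)", call. = FALSE)
  fr <- function(w) seq.int(w[1] * schedule$fps, w[2] * schedule$fps - 1)
  list(on = fr(on_window), off = fr(off_window),
       on_window_s = on_window, off_window_s = off_window)
}

#' Per-fly, per-cycle on/off densities
#'
#' Builds, for every fly and stimulation cycle, the mean behavior-space
#' density during the stimulation window (rho^on) and the reference
#' window (rho^off). Cells are grid-indexed; windows with no valid
#' embedded frame are flagged missing.
#'
#' @param embedded list of `embedded_points` data frames (one per fly,
#'   column `frame` 0-based).
#' @param roles character vector, `"experimental"` or `"control"` per fly.
#' @param schedule an [make_led_schedule()] object.
#' @param grid a [map_grid()].
#' @param sigma density smoothing in grid cells.
#' @param windows a [trial_windows()] result.
#' @return `trial_tensor`: `on`, `off` (arrays `n_cells x n_cycles x
#'   n_flies`), `missing` (logical matrix cycles x flies), `roles`,
#'   `grid`, `sigma`, `windows`, `schedule`.
#' @export
trial_densities <- function(embedded, roles, schedule, grid, sigma = 1.5,
                            windows = trial_windows(schedule)) {
  n_fly <- length(embedded)
  stop_if_not(length(roles) == n_fly, "one role per fly required")
  nc <- schedule$n_cycles
  ncell <- grid$n^2
  on_arr <- array(NA_real_, c(ncell, nc, n_fly))
  off_arr <- array(NA_real_, c(ncell, nc, n_fly))
  miss <- matrix(FALSE, nc, n_fly)
  for (i in seq_len(n_fly)) {
    pts <- embedded[[i]]
    pts <- pts[pts$valid & !is.na(pts$x), , drop = FALSE]
    cyc <- cycle_index(pts$frame, schedule)
    ph <- cycle_phase(pts$frame, schedule)
    for (n in seq_len(nc)) {
      sel_on <- !is.na(cyc) & cyc == n & ph %in% windows$on
      sel_off <- !is.na(cyc) & cyc == n & ph %in% windows$off
      don <- density_map(pts[sel_on, , drop = FALSE], grid, sigma)
      doff <- density_map(pts[sel_off, , drop = FALSE], grid, sigma)
      if (isTRUE(attr(don, "empty")) || isTRUE(attr(doff, "empty"))) {
        miss[n, i] <- TRUE
      } else {
        on_arr[, n, i] <- don
        off_arr[, n, i] <- doff
      }
    }
  }
  structure(list(on = on_arr, off = off_arr, missing = miss, roles = roles,
                 grid = grid, sigma = sigma, windows = windows,
                 schedule = schedule),
            class = "trial_tensor")
}

#' Density-shift statistic chi for one trial
#'
#' `chi_{i,n} = rho^on_{i,n} - (rho^off_{i,n-1} + rho^off_{i,n}) / 2`:
#' the stimulation-window density compared to the average of the two
#' flanking reference windows. Undefined for cycle 1 (no preceding
#' reference window).
#'
#' @param tensor a [trial_densities()] result.
#' @param i fly index.
#' @param n cycle index (>= 2).
#' @return `grid$n x grid$n` matrix (cells sum to 0).
#' @export
chi_map <- function(tensor, i, n) {
  stop_if_not(n >= 2, "chi is undefined for cycle 1 (needs cycle n-1)")
  v <- tensor$on[, n, i] - (tensor$off[, n - 1, i] + tensor$off[, n, i]) / 2
  matrix(v, tensor$grid$n, tensor$grid$n)
}

# All chi maps as an n_cells x n_trials matrix for the given flies; trials
# with any missing constituent density are dropped.
chi_matrix <- function(tensor, flies) {
  nc <- dim(tensor$on)[2]
  out <- NULL
  for (i in flies) {
    for (n in 2:nc) {
      if (tensor$missing[n, i] || tensor$missing[n - 1, i]) next
      out <- cbind(out, tensor$on[, n, i] -
                     (tensor$off[, n - 1, i] + tensor$off[, n, i]) / 2)
    }
  }
  out
}

#' Sidak-corrected per-comparison threshold
#'
#' `alpha' = 1 - (1 - alpha)^(1/m)`.
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons.
#' @return per-comparison threshold.
#' @export
sidak_threshold <- function(alpha, m) {
  stop_if_not(alpha > 0 && alpha < 1, "alpha must lie in (0,1)")
  stop_if_not(all(m >= 1), "m must be at least 1")
  1 - (1 - alpha)^(1 / m)
}

#' Shannon entropy of a density map
#'
#' `H = -sum p log2 p` over cells with positive density, in bits.
#'
#' @param density normalized density (matrix or vector summing to 1).
#' @return entropy in bits.
#' @export
entropy <- function(density) {
  stop_if_not(abs(sum(density) - 1) < 1e-6,
              "entropy expects a normalized density")
  entropy_bits(as.vector(density))
}

# Vectorized two-sided Wilcoxon rank-sum p-values per cell.
# X: a x cells, Y: b x cells. Small untied samples use the exact
# distribution (delegated to wilcox.test); larger ones the normal
# approximation with tie and continuity correction. Constant cells give
# p = 1.
rank_sum_p <- function(X, Y, exact_max = 10) {
  a <- nrow(X); b <- nrow(Y); N <- a + b
  M <- rbind(X, Y)
  small <- max(a, b) <= exact_max
  p <- vapply(seq_len(ncol(M)), function(j) {
    v <- M[, j]
    if (max(v) == min(v)) return(1)
    if (small && !anyDuplicated(v)) {
      return(suppressWarnings(
        wilcox.test(v[seq_len(a)], v[a + seq_len(b)], exact = TRUE)$p.value))
    }
    r <- rank(v)
    W <- sum(r[seq_len(a)]) - a * (a + 1) / 2  # Mann-Whitney U
    mu <- a * b / 2
    tt <- table(v)
    tie <- sum(tt^3 - tt)
    s2 <- a * b / 12 * ((N + 1) - tie / (N * (N - 1)))
    if (s2 <= 0) return(1)
    z <- (abs(W - mu) - 0.5) / sqrt(s2)
    min(1, 2 * pnorm(-z))
  }, numeric(1))
  p
}

#' Significance maps for one line
#'
#' Tests every grid cell with two Wilcoxon rank-sum tests pooled over
#' flies and cycles: (1) within experimental flies, stimulation-window
#' densities rho^on against reference-window densities rho^off; (2) the
#' chi statistic of experimental flies against that of control flies. The
#' Sidak-corrected threshold uses `m = ceiling(2^H)` comparisons, with `H`
#' the entropy in bits of the mean experimental density (an upper bound on
#' the number of distinguishable map locations). A cell is significant
#' only if both tests pass.
#'
#' @param tensor a [trial_densities()] result containing both arms.
#' @param alpha family-wise error rate.
#' @return `significance_map`: `p_on_off`, `p_chi` (matrices), `mask`
#'   (logical matrix), `H`, `m`, `alpha_prime`, `mean_density`.
#' @export
significance_maps <- function(tensor, alpha = 0.05) {
  exp_f <- which(tensor$roles == "experimental")
  ctl_f <- which(tensor$roles == "control")
  stop_if_not(length(exp_f) >= 2 && length(ctl_f) >= 2,
              "need at least 2 flies per arm")
  nc <- dim(tensor$on)[2]
  stop_if_not(nc >= 2, "need at least 2 cycles")
  gn <- tensor$grid$n
  keep <- function(i) which(!tensor$missing[, i])
  on_mat <- do.call(cbind, lapply(exp_f, function(i)
    tensor$on[, keep(i), i, drop = FALSE]))
  off_mat <- do.call(cbind, lapply(exp_f, function(i)
    tensor$off[, keep(i), i, drop = FALSE]))
  on_mat <- matrix(on_mat, gn^2); off_mat <- matrix(off_mat, gn^2)
  mean_density <- rowMeans(cbind(on_mat, off_mat))
  mean_density <- mean_density / sum(mean_density)
  H <- entropy_bits(mean_density)
  m <- ceiling(2^H)
  a_prime <- sidak_threshold(alpha, m)
  p1 <- rank_sum_p(t(on_mat), t(off_mat))
  chi_e <- chi_matrix(tensor, exp_f)
  chi_c <- chi_matrix(tensor, ctl_f)
  p2 <- rank_sum_p(t(chi_e), t(chi_c))
  mask <- matrix(p1 < a_prime & p2 < a_prime, gn, gn)
  structure(list(
    p_on_off = matrix(p1, gn, gn), p_chi = matrix(p2, gn, gn), mask = mask,
    H = H, m = m, alpha_prime = a_prime, alpha = alpha,
    mean_density = matrix(mean_density, gn, gn),
    mean_chi = matrix(rowMeans(chi_e), gn, gn)
  ), class = "significance_map")
}

#' Significantly activated regions
#'
#' Connected components of the significant-cell mask, each associated with
#' the watershed regions it overlaps. When a full [significance_maps()]
#' result is supplied, only cells whose mean chi is positive enter the
#' mask: significance is two-sided (a stimulated fly also vacates its
#' other behaviors, so depleted cells can test significant), but activated
#' regions are density increases. An empty mask yields `N = 0`, a valid
#' outcome (lines without a detectable phenotype).
#'
#' @param signif a [significance_maps()] result (or logical mask matrix,
#'   used as-is).
#' @param regions optional watershed `region_set` on the same grid.
#' @return list: `regions` (a `region_set` of the mask components),
#'   `N` (component count), `overlaps` (list of overlapping watershed
#'   region ids per component).
#' @export
significant_regions <- function(signif, regions = NULL) {
  mask <- if (inherits(signif, "significance_map"))
    signif$mask & signif$mean_chi > 0 else signif
  if (!any(mask)) {
    empty <- structure(list(labels = matrix(0L, nrow(mask), ncol(mask)),
                            n_regions = 0L, sizes = integer(0),
                            names = character(0), threshold = NA),
                       class = "region_set")
    return(list(regions = empty, N = 0L, overlaps = list()))
  }
  lab <- matrix(as.integer(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(mask * 1)))), nrow(mask))
  N <- max(lab)
  overlaps <- lapply(seq_len(N), function(k) {
    if (is.null(regions)) return(integer(0))
    ov <- unique(regions$labels[lab == k])
    sort(ov[ov > 0])
  })
  rs <- structure(list(labels = lab, n_regions = N,
                       sizes = tabulate(lab[lab > 0], N),
                       names = paste0("A", seq_len(N)), threshold = NA),
                  class = "region_set")
  list(regions = rs, N = N, overlaps = overlaps)
}

#' Stimulus-locked entropy curve
#'
#' For each phase of the stimulation cycle, pools embedded points from all
#' flies and cycles detected within `halfwidth_s` of that phase (periodic
#' boundary conditions), forms the phase density `p_t(x, y)` with Gaussian
#' smoothing `sigma`, and records its Shannon entropy `H(t)` in bits.
#' The baseline-subtracted variant subtracts the mean entropy over the
#' reference-window phases.
#'
#' @param embedded list of `embedded_points` data frames (pooled; e.g. all
#'   experimental flies of a line).
#' @param schedule an [make_led_schedule()] object.
#' @param grid a [map_grid()].
#' @param sigma smoothing width in grid cells (default 2).
#' @param halfwidth_s pooling half-window, seconds (default 0.2).
#' @param step_s phase step, seconds.
#' @param baseline subtract the mean over the reference-window phases.
#' @param off_window_s reference window for the baseline, seconds.
#' @return data.frame `phase_s`, `H_bits`, `n_points` (`H_bits` is `NA`
#'   for empty phase windows); baseline value in attribute `baseline`.
#' @export
entropy_curve <- function(embedded, schedule, grid, sigma = 2,
                          halfwidth_s = 0.2, step_s = 0.1, baseline = FALSE,
                          off_window_s = c(30, 45)) {
  if (is.data.frame(embedded)) embedded <- list(embedded)
  pts <- do.call(rbind, lapply(embedded, function(p)
    p[p$valid & !is.na(p$x), c("frame", "x", "y"), drop = FALSE]))
  ph <- cycle_phase(pts$frame, schedule)
  pts <- pts[!is.na(ph), , drop = FALSE]
  ph <- ph[!is.na(ph)] / schedule$fps
  cyc_s <- schedule$cycle_frames / schedule$fps
  ord <- order(ph)
  pts <- pts[ord, , drop = FALSE]; ph <- ph[ord]
  cells <- point_to_cell(pts, grid)
  phases <- seq(0, cyc_s - step_s / 2, by = step_s)
  n <- grid$n
  H <- rep(NA_real_, length(phases)); np <- integer(length(phases))
  for (j in seq_along(phases)) {
    lo <- phases[j] - halfwidth_s; hi <- phases[j] + halfwidth_s
    sel <- if (lo < 0) ph >= lo + cyc_s | ph <= hi
           else if (hi > cyc_s) ph >= lo | ph <= hi - cyc_s
           else ph >= lo & ph <= hi
    cc <- cells[sel, , drop = FALSE]
    cc <- cc[complete.cases(cc), , drop = FALSE]
    np[j] <- nrow(cc)
    if (!nrow(cc)) next
    counts <- tabulate((cc[, 2] - 1L) * n + cc[, 1], nbins = n * n)
    d <- smooth2d(matrix(counts, n, n), sigma)
    d <- d / sum(d)
    H[j] <- entropy_bits(d)
  }
  base <- mean(H[phases >= off_window_s[1] & phases < off_window_s[2]],
               na.rm = TRUE)
  out <- data.frame(phase_s = phases,
                    H_bits = if (baseline) H - base else H,
                    n_points = np)
  attr(out, "baseline") <- base
  out
}

#' Region occupancy time course
#'
#' Mean density in a map region over a series of sliding windows across
#' the stimulation cycle: for each phase, the fraction of each fly's
#' embedded points inside the region during `[t, t + window_s)`, averaged
#' with its standard deviation across flies and cycles.
#'
#' @param embedded list of `embedded_points` data frames (one per fly).
#' @param regions a `region_set`.
#' @param region region id within `regions`.
#' @param schedule an [make_led_schedule()] object.
#' @param grid a [map_grid()].
#' @param window_s sliding-window length, seconds (default 3).
#' @param step_s phase step, seconds.
#' @return data.frame `phase_s`, `mean`, `sd`, `n` (fly-cycle samples).
#' @export
region_timecourse <- function(embedded, regions, region, schedule, grid,
                              window_s = 3, step_s = 0.5) {
  mask <- regions$labels == region
  cyc_s <- schedule$cycle_frames / schedule$fps
  phases <- seq(0, cyc_s - step_s / 2, by = step_s)
  samples <- vector("list", length(phases))
  for (i in seq_along(embedded)) {
    pts <- embedded[[i]]
    pts <- pts[pts$valid & !is.na(pts$x), , drop = FALSE]
    ph <- cycle_phase(pts$frame, schedule) / schedule$fps
    cyc <- cycle_index(pts$frame, schedule)
    ok <- !is.na(ph)
    pts <- pts[ok, , drop = FALSE]; ph <- ph[ok]; cyc <- cyc[ok]
    cells <- point_to_cell(pts, grid)
    ongrid <- complete.cases(cells)
    inreg <- rep(FALSE, nrow(pts))
    inreg[ongrid] <- mask[cells[ongrid, , drop = FALSE]]
    for (j in seq_along(phases)) {
      lo <- phases[j]; hi <- phases[j] + window_s
      sel <- if (hi <= cyc_s) ph >= lo & ph < hi
             else ph >= lo | ph < hi - cyc_s
      sel <- sel & ongrid
      if (!any(sel)) next
      occ <- tapply(inreg[sel], cyc[sel], mean)
      samples[[j]] <- c(samples[[j]], occ)
    }
  }
  data.frame(
    phase_s = phases,
    mean = vapply(samples, function(s) if (length(s)) mean(s) else NA_real_,
                  numeric(1)),
    sd = vapply(samples, function(s) if (length(s) > 1) sd(s) else NA_real_,
                numeric(1)),
    n = vapply(samples, length, integer(1))
  )
}

#' Average activation map across lines targeting one neuron
#'
#' For each line, the mean chi map over flies and cycles with
#' non-significant cells and negative means zeroed
#' (`E[chi_{i,n}(x,y)] > 0` on significant cells only); the per-neuron
#' map is the cellwise average of these across lines.
#'
#' @param line_results list; each element has `mean_chi` (matrix) and
#'   `mask` (logical matrix), e.g. a [significance_maps()] result.
#' @return averaged activation map (matrix).
#' @export
neuron_average <- function(line_results) {
  stop_if_not(length(line_results) >= 1, "need at least one line result")
  d <- dim(line_results[[1]]$mean_chi)
  maps <- lapply(line_results, function(lr) {
    stop_if_not(all(dim(lr$mean_chi) == d), "grid mismatch across lines")
    m <- lr$mean_chi
    m[!lr$mask | m < 0] <- 0
    m
  })
  Reduce(`+`, maps) / length(maps)
}
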