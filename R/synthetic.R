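#' Sticky uniform transition matrix
#'
#' Row-stochastic matrix whose self-transition probability gives a mean
#' state dwell time of `dwell_s` seconds at `fps`; the remaining mass is
#' uniform over the other states. The frame-resolution chain with this
#' matrix approximates bout-level dwell times through self-transitions.
#'
#' @param n_states number of latent behavior states.
#' @param dwell_s mean dwell time per bout, seconds.
#' @param fps frames per second.
#' @return `n_states x n_states` row-stochastic matrix.
#' @export
sticky_transition_matrix <- function(n_states, dwell_s = 2, fps = 100) {
  stop_if_not(n_states >= 2, "need at least 2 states")
  p_stay <- 1 - 1 / (dwell_s * fps)
  M <- matrix((1 - p_stay) / (n_states - 1), n_states, n_states)
  diag(M) <- p_stay
  M
}

#' LED-on transition matrix pulling toward a target state
#'
#' Mixes a per-frame evoked transition into a baseline matrix:
#' `T_on = (1 - strength) * T_off + strength * e_target`. With the default
#' strength the evoked state is reached with ~0.2 s latency and held for
#' the rest of the stimulation window.
#'
#' @param T_off baseline (LED-off) transition matrix.
#' @param target index of the LED-activated state.
#' @param strength per-frame evoked transition probability.
#' @return row-stochastic matrix.
#' @export
activation_transition_matrix <- function(T_off, target, strength = 0.05) {
  n <- nrow(T_off)
  stop_if_not(target >= 1 && target <= n, "target state out of range")
  M <- (1 - strength) * T_off
  M[, target] <- M[, target] + strength
  M
}

check_stochastic <- function(M, name) {
  if (!is.matrix(M) || nrow(M) != ncol(M) || any(M < -1e-12) ||
      any(abs(rowSums(M) - 1) > 1e-8))
    stop(sprintf("%s is not a row-stochastic square matrix", name),
         call. = FALSE)
  invisible(M)
}

default_state_spectra <- function(n_states, n_modes, fps) {
  # distinct base frequencies, log-spaced over 2-32 Hz, two harmonically
  # unrelated lines per state on a dedicated mode pair
  f <- 2 * 2^((seq_len(n_states) - 1) * log2(16) / max(1, n_states - 1))
  lapply(seq_len(n_states), function(k) {
    m1 <- ((2 * k - 2) %% n_modes) + 1
    m2 <- ((2 * k - 1) %% n_modes) + 1
    data.frame(mode = c(m1, m2), freq = c(f[k], min(1.45 * f[k], 0.48 * fps)),
               amp = c(1, 0.5))
  })
}

#' Configuration for synthetic sessions
#'
#' Describes the hidden behavior-state process and its postural signature:
#' a frame-resolution Markov chain with separate LED-off and LED-on
#' transition matrices, an optional context map making the evoked state
#' depend on the pre-stimulus state (coupling `delta`), and per-state sets
#' of (mode, frequency, amplitude) oscillation triples that generate the
#' posture-mode time series.
#'
#' @param n_states number of latent behavior states.
#' @param n_modes number of posture modes to synthesize.
#' @param fps frames per second.
#' @param T_off,T_on row-stochastic transition matrices for LED-off /
#'   LED-on frames; defaults: sticky uniform baseline and, for `T_on`, an
#'   activation matrix pulling to `target_state`.
#' @param target_state LED-activated state used for the default `T_on`.
#'   `NULL` makes `T_on = T_off` (a control line; the LED has no effect).
#' @param on_strength per-frame evoked transition probability for the
#'   default `T_on`.
#' @param context_map integer vector mapping pre-stimulus state to intended
#'   evoked state; default the identity-shift permutation.
#' @param delta context coupling in `[0, 1]`: 0 = evoked state independent
#'   of the pre-stimulus state, 1 = fully context-determined.
#' @param state_spectra list (one element per state) of data frames with
#'   columns `mode`, `freq` (Hz), `amp`; default gives each state a
#'   separable two-line signature. All frequencies must stay below the
#'   Nyquist frequency `fps / 2`.
#' @param noise_sd additive Gaussian noise on the synthesized modes.
#' @param dwell_s mean bout dwell time for the default `T_off`, seconds.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_states = 5, n_modes = 10, fps = 100,
                             T_off = NULL, T_on = NULL, target_state = NULL,
                             on_strength = 0.05, context_map = NULL,
                             delta = 0, state_spectra = NULL,
                             noise_sd = 0.1, dwell_s = 2) {
  T_off <- T_off %||% sticky_transition_matrix(n_states, dwell_s, fps)
  if (is.null(T_on)) {
    T_on <- if (is.null(target_state)) T_off else
      activation_transition_matrix(T_off, target_state, on_strength)
  }
  check_stochastic(T_off, "T_off")
  check_stochastic(T_on, "T_on")
  stop_if_not(delta >= 0 && delta <= 1, "delta must lie in [0, 1]")
  context_map <- context_map %||% (seq_len(n_states) %% n_states + 1L)
  stop_if_not(length(context_map) == n_states &&
                all(context_map %in% seq_len(n_states)),
              "context_map must map each state to a state")
  state_spectra <- state_spectra %||%
    default_state_spectra(n_states, n_modes, fps)
  stop_if_not(length(state_spectra) == n_states,
              "state_spectra must have one entry per state")
  for (sp in state_spectra) {
    if (nrow(sp) && any(sp$freq >= fps / 2))
      stop("state_spectra frequency at or above the Nyquist frequency of ",
           "the system (fps/2 = ", fps / 2, " Hz)", call. = FALSE)
  }
  structure(list(
    n_states = as.integer(n_states), n_modes = as.integer(n_modes), fps = fps,
    T_off = T_off, T_on = T_on, target_state = target_state,
    on_strength = on_strength, context_map = as.integer(context_map),
    delta = delta, state_spectra = state_spectra, noise_sd = noise_sd,
    dwell_s = dwell_s
  ), class = "synthetic_config")
}

#' Control-fly variant of a configuration
#'
#' Returns the same configuration with `T_on = T_off` and `delta = 0`, so
#' the LED has no effect (the non-retinal-fed control arm).
#'
#' @param config a [synthetic_config()].
#' @export
control_config <- function(config) {
  config$T_on <- config$T_off
  config$delta <- 0
  config$target_state <- NULL
  config
}

#' Simulate the latent behavior-state sequence of one fly
#'
#' Runs the frame-resolution Markov chain against an LED schedule: `T_off`
#' rows during LED-off frames and the `delta`-mixed evoked dynamics during
#' LED-on frames. Reproducible given `seed`.
#'
#' @param config a [synthetic_config()].
#' @param schedule an [make_led_schedule()] object (same `fps`).
#' @param seed integer RNG seed.
#' @return object of class `ground_truth`: `state_sequence` (length
#'   `total_frames`, 1-based state labels), `pre_states` and
#'   `evoked_states` per cycle, plus the config's `context_map`.
#' @export
simulate_states <- function(config, schedule, seed = 1) {
  stop_if_not(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  stop_if_not(abs(config$fps - schedule$fps) < 1e-9,
              "config and schedule fps disagree")
  set.seed(seed)
  init <- sample.int(config$n_states, 1)
  res <- simulate_chain_cpp(config$T_off, config$T_on, config$context_map,
                            config$delta, config$on_strength,
                            led_mask(schedule), schedule$onset_frames, init)
  structure(list(
    state_sequence = res$states, pre_states = res$pre_states,
    evoked_states = res$evoked, context_map = config$context_map,
    n_states = config$n_states, fps = config$fps, seed = seed
  ), class = "ground_truth")
}

#' Synthesize posture-mode time series from a state sequence
#'
#' Each latent state drives its configured oscillation triples: mode `m` at
#' frame `t` is the sum of `amp * sin(2*pi*f*t/fps + phase)` over the active
#' state's triples on mode `m`, plus Gaussian noise. Phases are drawn once
#' per bout (run of constant state) so wavelet amplitudes are stable within
#' bouts.
#'
#' @param ground_truth a [simulate_states()] result.
#' @param config the matching [synthetic_config()].
#' @param seed integer RNG seed.
#' @return `postural_modes` object: `modes` (T x n_modes matrix), `fps`,
#'   `valid` (all `TRUE` for synthetic data).
#' @export
synthesize_posture <- function(ground_truth, config, seed = 1) {
  set.seed(seed)
  st <- ground_truth$state_sequence
  T_len <- length(st)
  M <- matrix(0, T_len, config$n_modes)
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tt <- seq_len(T_len) - 1L
  for (b in seq_along(r$values)) {
    sp <- config$state_spectra[[r$values[b]]]
    if (!nrow(sp)) next
    idx <- starts[b]:ends[b]
    for (j in seq_len(nrow(sp))) {
      ph <- runif(1, 0, 2 * pi)
      M[idx, sp$mode[j]] <- M[idx, sp$mode[j]] +
        sp$amp[j] * sin(2 * pi * sp$freq[j] * tt[idx] / config$fps + ph)
    }
  }
  if (config$noise_sd > 0)
    M <- M + matrix(rnorm(length(M), sd = config$noise_sd), nrow(M))
  structure(list(modes = M, fps = config$fps, valid = rep(TRUE, T_len)),
            class = "postural_modes")
}

#' Simulate a session directly in behavior-space coordinates
#'
#' State-level shortcut for testing the map, trial-statistics and mutual-
#' information stages in isolation: each latent state owns a territory in
#' the 2D map (Gaussian scatter around a state center) and every frame is
#' emitted at a draw from the active state's territory, bypassing the
#' rendering / wavelet / embedding stages entirely. Synthetic by
#' construction; the full inference path is exercised separately.
#'
#' @param config a [synthetic_config()].
#' @param schedule an [make_led_schedule()] object.
#' @param seed integer RNG seed.
#' @param centers `n_states x 2` matrix of state centers; default on the
#'   unit circle.
#' @param scatter_sd isotropic within-state scatter, map units.
#' @param stride emit every `stride`-th frame (1 = all frames).
#' @return list: `points` (data.frame `frame` (0-based), `x`, `y`, `state`,
#'   `valid`), `ground_truth`, `centers`, `scatter_sd`.
#' @export
simulate_embedded_fly <- function(config, schedule, seed = 1, centers = NULL,
                                  scatter_sd = 0.05, stride = 1L) {
  centers <- centers %||% state_centers(config$n_states)
  gt <- simulate_states(config, schedule, seed)
  keep <- seq(1L, length(gt$state_sequence), by = stride)
  st <- gt$state_sequence[keep]
  n <- length(st)
  pts <- data.frame(
    frame = keep - 1L,
    x = centers[st, 1] + rnorm(n, sd = scatter_sd),
    y = centers[st, 2] + rnorm(n, sd = scatter_sd),
    state = st, valid = TRUE
  )
  list(points = pts, ground_truth = gt, centers = centers,
       scatter_sd = scatter_sd)
}

#' Default state-center layout (unit circle)
#'
#' @param n_states number of states.
#' @return `n_states x 2` matrix.
#' @export
state_centers <- function(n_states) {
  a <- 2 * pi * (seq_len(n_states) - 1) / n_states
  cbind(cos(a), sin(a))
}

#' Simulate a 6+6 cohort in behavior-space coordinates
#'
#' Experimental flies follow `config`; control flies follow
#' [control_config()] of it (LED has no effect). One session per fly.
#'
#' @inheritParams simulate_embedded_fly
#' @param n_exp,n_ctrl number of experimental / control flies.
#' @return list with `flies` (list of [simulate_embedded_fly()] results),
#'   `roles` (character vector), `schedule`, `centers`.
#' @export
simulate_embedded_cohort <- function(config, schedule, seed = 1,
                                     n_exp = 6, n_ctrl = 6, centers = NULL,
                                     scatter_sd = 0.05, stride = 1L) {
  centers <- centers %||% state_centers(config$n_states)
  ctrl <- control_config(config)
  roles <- c(rep("experimental", n_exp), rep("control", n_ctrl))
  flies <- lapply(seq_along(roles), function(i) {
    cfg <- if (roles[i] == "experimental") config else ctrl
    simulate_embedded_fly(cfg, schedule, seed = seed * 1000L + i,
                          centers = centers, scatter_sd = scatter_sd,
                          stride = stride)
  })
  list(flies = flies, roles = roles, schedule = schedule, centers = centers)
}

#' Exact context mutual information of the generator
#'
#' Analytic value of the mutual information between the pre-stimulus
#' behavior-space location and the evoked region for a fully
#' context-coupled configuration (`delta = 1`, deterministic context map),
#' computed by exact enumeration over the known chain. Pre-onset states
#' are weighted by the stationary distribution of `T_off`; because the
#' chain keeps moving during the pre-stimulus window, the location density
#' conditional on a pre-onset state is the mixture of territory Gaussians
#' obtained by propagating `T_off` backwards over the window gap (the
#' sticky uniform chain is reversible, so backward transition
#' probabilities are the matrix powers of `T_off`). The evoked region of
#' pre-onset state `s` is `context_map[s]`'s territory.
#'
#' @param config a [synthetic_config()].
#' @param grid a [map_grid()] covering the territories.
#' @param centers state-center matrix (default unit circle).
#' @param scatter_sd territory scatter, map units.
#' @param pre_window_s pre-stimulus window in seconds relative to onset
#'   (matching the estimator's window).
#' @return mutual information in bits.
#' @export
generator_context_mi <- function(config, grid, centers = NULL,
                                 scatter_sd = 0.05,
                                 pre_window_s = c(-1.5, -0.5)) {
  centers <- centers %||% state_centers(config$n_states)
  pi_off <- stationary_distribution(config$T_off)
  n <- config$n_states
  # mean backward transition kernel over the pre-window lags
  lags <- seq(round(-pre_window_s[2] * config$fps),
              round(-pre_window_s[1] * config$fps) - 1)
  Tpow <- diag(n)
  for (t in seq_len(min(lags) - 1)) Tpow <- Tpow %*% config$T_off
  W <- matrix(0, n, n)
  for (t in lags) {
    Tpow <- Tpow %*% config$T_off
    W <- W + Tpow
  }
  W <- W / length(lags)
  # territory densities per state
  G <- lapply(seq_len(n), function(s)
    gaussian_on_grid(grid, centers[s, ], scatter_sd))
  labels <- config$context_map
  lab_ids <- sort(unique(labels))
  p_label <- vapply(lab_ids, function(l) sum(pi_off[labels == l]), numeric(1))
  cond <- lapply(lab_ids, function(l) {
    pre_states <- which(labels == l)
    w0 <- pi_off[pre_states] / sum(pi_off[pre_states])
    d <- 0
    for (j in seq_along(pre_states)) {
      mix <- W[pre_states[j], ]  # P(window state | pre-onset state)
      for (s in seq_len(n)) d <- d + w0[j] * mix[s] * G[[s]]
    }
    d / sum(d)
  })
  marg <- Reduce(`+`, Map(function(d, p) d * p, cond, p_label))
  mi <- 0
  for (k in seq_along(cond)) {
    ok <- cond[[k]] > 0 & marg > 0
    mi <- mi + p_label[k] * sum(cond[[k]][ok] * log2(cond[[k]][ok] / marg[ok]))
  }
  mi
}

#' Trial-resolution context cohort
#'
#' Synthetic sessions realizing the deterministic context joint exactly:
#' in every cycle the fly's pre-stimulus state is drawn independently and
#' uniformly, it holds that state's territory until onset, and during
#' stimulation it occupies the territory of `context_map[pre]` with
#' probability `delta` (otherwise the LED `target_state`). After the
#' stimulation window a fresh recovery state is drawn. Unlike the
#' frame-resolution chain of [simulate_embedded_fly()], trials are
#' independent and the pre-window state never mixes, so the injected
#' mutual information equals the analytic value of [context_trial_mi()]
#' up to territory overlap.
#'
#' @param config a [synthetic_config()] (uses `n_states`, `context_map`,
#'   `delta`, `target_state`).
#' @param schedule an [make_led_schedule()] object with a lead-in or more
#'   than one cycle (so pre-windows exist).
#' @param seed RNG seed.
#' @param n_flies sessions to generate.
#' @param centers state-center matrix (default unit circle).
#' @param scatter_sd within-territory scatter, map units.
#' @param stride emit every `stride`-th frame.
#' @param latency_s seconds after onset before the evoked territory is
#'   reached (frames in between stay in the pre territory).
#' @return list: `flies` (list of point data frames), `pre_states`,
#'   `evoked_states` (matrices fly x cycle), `centers`, `scatter_sd`.
#' @export
simulate_context_cohort <- function(config, schedule, seed = 1, n_flies = 6,
                                    centers = NULL, scatter_sd = 0.05,
                                    stride = 1L, latency_s = 0.1) {
  centers <- centers %||% state_centers(config$n_states)
  set.seed(seed)
  n <- config$n_states
  tgt <- config$target_state %||% config$context_map[1]
  lat <- round(latency_s * schedule$fps)
  pre_m <- matrix(0L, n_flies, schedule$n_cycles)
  evo_m <- matrix(0L, n_flies, schedule$n_cycles)
  flies <- vector("list", n_flies)
  for (i in seq_len(n_flies)) {
    st <- integer(schedule$total_frames)
    st[seq_len(schedule$onset_frames[1])] <- sample.int(n, 1)
    for (cy in seq_len(schedule$n_cycles)) {
      onset <- schedule$onset_frames[cy]
      pre <- if (onset == 0) sample.int(n, 1) else st[onset]
      pre_m[i, cy] <- pre
      evoked <- if (runif(1) < config$delta) config$context_map[pre] else tgt
      evo_m[i, cy] <- evoked
      on_end <- onset + schedule$on_frames
      st[(onset + 1):min(onset + lat, on_end)] <- pre
      if (onset + lat < on_end) st[(onset + lat + 1):on_end] <- evoked
      cyc_end <- min(onset + schedule$cycle_frames, schedule$total_frames)
      if (on_end < cyc_end) {
        recov <- sample.int(n, 1)
        st[(on_end + 1):cyc_end] <- recov
      }
    }
    keep <- seq(1L, schedule$total_frames, by = stride)
    sk <- st[keep]
    flies[[i]] <- data.frame(
      frame = keep - 1L,
      x = centers[sk, 1] + rnorm(length(sk), sd = scatter_sd),
      y = centers[sk, 2] + rnorm(length(sk), sd = scatter_sd),
      state = sk, valid = TRUE)
  }
  list(flies = flies, pre_states = pre_m, evoked_states = evo_m,
       centers = centers, scatter_sd = scatter_sd)
}

#' Analytic mutual information of the trial-resolution context joint
#'
#' Exact MI between the pre-stimulus location density and the evoked
#' region for [simulate_context_cohort()]: pre-states are uniform, the
#' evoked label is `context_map[pre]` with probability `delta` and the
#' LED target otherwise, and each state's location density is its
#' territory Gaussian discretized on the grid.
#'
#' @inheritParams generator_context_mi
#' @return mutual information in bits.
#' @export
context_trial_mi <- function(config, grid, centers = NULL,
                             scatter_sd = 0.05) {
  centers <- centers %||% state_centers(config$n_states)
  n <- config$n_states
  tgt <- config$target_state %||% config$context_map[1]
  # joint over (pre-state, label)
  J <- matrix(0, n, n)
  for (s in seq_len(n)) {
    J[s, config$context_map[s]] <- J[s, config$context_map[s]] +
      config$delta / n
    J[s, tgt] <- J[s, tgt] + (1 - config$delta) / n
  }
  p_label <- colSums(J)
  keep <- which(p_label > 0)
  G <- lapply(seq_len(n), function(s)
    gaussian_on_grid(grid, centers[s, ], scatter_sd))
  cond <- lapply(keep, function(l) {
    w <- J[, l] / p_label[l]
    d <- 0
    for (s in seq_len(n)) if (w[s] > 0) d <- d + w[s] * G[[s]]
    d / sum(d)
  })
  marg <- Reduce(`+`, Map(function(d, p) d * p, cond, p_label[keep]))
  mi <- 0
  for (k in seq_along(cond)) {
    ok <- cond[[k]] > 0 & marg > 0
    mi <- mi + p_label[keep[k]] *
      sum(cond[[k]][ok] * log2(cond[[k]][ok] / marg[ok]))
  }
  mi
}

# Stationary distribution of a row-stochastic matrix (left eigenvector).
stationary_distribution <- function(M) {
  e <- eigen(t(M))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  v / sum(v)
}

# Isotropic Gaussian density discretized on a map grid (cell centers).
gaussian_on_grid <- function(grid, center, sd) {
  cx <- grid_cell_centers(grid)
  d <- outer(dnorm(cx$x, center[1], sd), dnorm(cx$y, center[2], sd))
  d / sum(d)
}
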