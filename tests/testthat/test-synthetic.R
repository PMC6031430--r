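test_that("LED schedule arithmetic matches the stimulation protocol", {
  sch <- make_led_schedule(100, 30, 15, 45)
  expect_equal(sch$total_frames, 180000L)
  expect_equal(sch$onset_frames[1:4], c(0L, 6000L, 12000L, 18000L))
  expect_true(all(diff(sch$onset_frames) == 6000L))
  m <- led_mask(sch)
  expect_equal(sum(m), 30 * 15 * 100)
  expect_equal(sum(m[1:1500]), 1500)  # first on window fully on

  one <- make_led_schedule(100, 1, 15, 45)
  expect_equal(one$onset_frames, 0L)
  tiny <- make_led_schedule(100, 2, 0.01, 0.01)
  expect_equal(tiny$onset_frames, c(0L, 2L))

  expect_error(make_led_schedule(3, 1, 0.1, 0.9), "whole number")
  expect_error(make_led_schedule(-1, 1, 1, 1), "positive")
})

test_that("cycle phase and index are consistent with the schedule", {
  sch <- make_led_schedule(100, 3, 15, 45, lead_in_s = 2)
  expect_equal(sch$onset_frames, c(200L, 6200L, 12200L))
  expect_equal(cycle_phase(c(200, 250, 6200), sch), c(0, 50, 0))
  expect_true(is.na(cycle_phase(0, sch)))
  expect_equal(cycle_index(c(200, 6199, 6200), sch), c(1L, 1L, 2L))
})

test_that("control chains are stationary across LED phase", {
  cfg <- synthetic_config(n_states = 4, n_modes = 4)  # T_on = T_off
  sch <- make_led_schedule(100, 30, 15, 45)
  gt <- simulate_states(cfg, sch, seed = 11)
  expect_gte(length(gt$state_sequence), 1e4)
  led <- led_mask(sch)
  # stride far beyond the 2 s dwell so samples are near-independent
  keep <- seq(1, length(led), by = 500)
  tab <- table(gt$state_sequence[keep], led[keep])
  # G-test of independence between occupancy and LED phase
  g <- 2 * sum(tab * log(tab / outer(rowSums(tab), colSums(tab)) * sum(tab)))
  p <- pchisq(g, df = (nrow(tab) - 1) * (ncol(tab) - 1), lower.tail = FALSE)
  expect_gt(p, 0.05)
})

test_that("an LED-activated state is enriched during stimulation", {
  cfg <- synthetic_config(n_states = 4, n_modes = 4, target_state = 3,
                          on_strength = 0.05)
  sch <- make_led_schedule(100, 30, 15, 45)
  gt <- simulate_states(cfg, sch, seed = 5)
  led <- led_mask(sch)
  occ_on <- mean(gt$state_sequence[led] == 3)
  occ_off <- mean(gt$state_sequence[!led] == 3)
  expect_gt(occ_on, occ_off + 0.3)
})

test_that("full context coupling makes the evoked state a function of the pre-onset state", {
  ctx <- c(2L, 3L, 4L, 5L, 1L)
  cfg <- synthetic_config(n_states = 5, n_modes = 4, target_state = 1,
                          delta = 1, context_map = ctx, on_strength = 0.2)
  sch <- make_led_schedule(100, 20, 15, 45, lead_in_s = 2)
  gt <- simulate_states(cfg, sch, seed = 9)
  expect_equal(gt$evoked_states, ctx[gt$pre_states])
  # dominant on-window occupancy matches the intended evoked state
  led <- which(led_mask(sch))
  for (cy in seq_len(sch$n_cycles)) {
    onset <- sch$onset_frames[cy]
    win <- (onset + 101):(onset + sch$on_frames)  # after evoked latency
    dom <- as.integer(names(which.max(table(gt$state_sequence[win]))))
    expect_equal(dom, gt$evoked_states[cy])
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_states = 3, n_modes = 4, target_state = 2)
  sch <- make_led_schedule(100, 2, 15, 45)
  a <- simulate_states(cfg, sch, seed = 42)
  b <- simulate_states(cfg, sch, seed = 42)
  expect_identical(a, b)
  expect_identical(synthesize_posture(a, cfg, 7), synthesize_posture(b, cfg, 7))
  c1 <- simulate_embedded_fly(cfg, sch, seed = 42)
  c2 <- simulate_embedded_fly(cfg, sch, seed = 42)
  expect_identical(c1$points, c2$points)
})

test_that("non-stochastic transition matrices are rejected", {
  M <- matrix(c(0.5, 0.6, 0.5, 0.5), 2, 2)
  expect_error(synthetic_config(n_states = 2, n_modes = 2, T_off = M),
               "stochastic")
})

test_that("posture synthesis produces the configured oscillations", {
  # single state, one triple on mode 1 at 10 Hz, no noise
  sp <- list(data.frame(mode = 1, freq = 10, amp = 1))
  cfg <- synthetic_config(n_states = 1, n_modes = 3, state_spectra = sp,
                          noise_sd = 0, T_off = matrix(1, 1, 1),
                          context_map = 1L)
  gt <- list(state_sequence = rep(1L, 1000))
  pm <- synthesize_posture(gt, cfg, seed = 1)
  expect_equal(dim(pm$modes), c(1000L, 3L))
  expect_equal(pm$modes[, 2], rep(0, 1000))
  expect_equal(pm$modes[, 3], rep(0, 1000))
  # pure 10 Hz sinusoid: spectral peak at 10 Hz, unit amplitude
  sp_hat <- Mod(fft(pm$modes[, 1]))[2:500]
  expect_equal(which.max(sp_hat), 100)  # 10 Hz bin of a 10 s record
  expect_equal(max(abs(pm$modes[, 1])), 1, tolerance = 0.01)

  # zero amplitudes, zero noise: all-zero series
  sp0 <- list(data.frame(mode = 1, freq = 10, amp = 0)[0, ])
  cfg0 <- synthetic_config(n_states = 1, n_modes = 2, state_spectra = sp0,
                           noise_sd = 0, T_off = matrix(1, 1, 1),
                           context_map = 1L)
  pm0 <- synthesize_posture(gt, cfg0, seed = 1)
  expect_true(all(pm0$modes == 0))
})

test_that("frequencies at or above Nyquist are rejected", {
  sp <- list(data.frame(mode = 1, freq = 50, amp = 1))
  expect_error(
    synthetic_config(n_states = 1, n_modes = 2, state_spectra = sp,
                     T_off = matrix(1, 1, 1), context_map = 1L),
    "Nyquist")
})

test_that("wavelet channel decoding recovers states with disjoint spectra", {
  # two states on different modes/frequencies; one transition, no noise
  sp <- list(data.frame(mode = 1, freq = 5, amp = 1),
             data.frame(mode = 2, freq = 20, amp = 1))
  cfg <- synthetic_config(n_states = 2, n_modes = 2, state_spectra = sp,
                          noise_sd = 0)
  gt <- list(state_sequence = rep(c(1L, 2L), each = 6000))
  pm <- synthesize_posture(gt, cfg, seed = 2)
  w <- morlet_cwt(pm, channel_grid(), fps = 100)
  flat <- matrix(w$amplitudes, dim(w$amplitudes)[1], 2 * 25)
  # flattened columns interleave modes (mode index fastest); the winning
  # mode owns the state
  decoded <- ((max.col(flat) - 1L) %% 2L) + 1L
  expect_gte(mean(decoded == gt$state_sequence), 0.99)
})

test_that("injected context information is analytic and monotone in delta", {
  grid <- unit_grid()
  mis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(d) {
    cfg <- synthetic_config(n_states = 5, n_modes = 4, target_state = 2,
                            delta = d)
    context_trial_mi(cfg, grid)
  }, numeric(1))
  expect_true(all(diff(mis) > -1e-12))
  expect_equal(mis[1], 0, tolerance = 1e-12)
  # deterministic permutation map with disjoint territories: MI = log2(5)
  expect_equal(mis[5], log2(5), tolerance = 1e-3)
})

test_that("rendered movies are rigid when amplitudes are zero", {
  sp0 <- list(data.frame(mode = 1, freq = 10, amp = 0),
              data.frame(mode = 1, freq = 10, amp = 0))
  cfg <- synthetic_config(n_states = 2, n_modes = 2, state_spectra = sp0,
                          noise_sd = 0)
  sch <- make_led_schedule(100, 1, 1, 1)
  gt <- simulate_states(cfg, sch, 1)
  mv <- render_movie(gt, cfg, seed = 1, n_frames = 5, rot_step = 0,
                     trans_step = 0)
  for (t in 2:5) expect_equal(mv$frames[, , t], mv$frames[, , 1])
})

test_that("rendered LED logs round-trip through the log reader", {
  cfg <- synthetic_config(n_states = 2, n_modes = 4)
  sch <- make_led_schedule(100, 2, 0.2, 0.3)
  gt <- simulate_states(cfg, sch, 1)
  mv <- render_movie(gt, cfg, seed = 1, n_frames = 100, schedule = sch)
  path <- withr::local_tempfile(fileext = ".txt")
  write_led_log(mv$led_log, path)
  back <- read_led_log(path)
  expect_equal(back, mv$led_log)
})
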