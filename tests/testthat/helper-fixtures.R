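# Shared small fixtures, built in code at test time.

# A tiny rendered movie (no global motion unless asked).
tiny_movie <- function(n_frames = 4, seed = 1, noise_sd = 0, rot_step = 0,
                       trans_step = 0, ...) {
  cfg <- synthetic_config(n_states = 2, n_modes = 4, noise_sd = noise_sd)
  sch <- make_led_schedule(100, 1, 1, 1)
  gt <- simulate_states(cfg, sch, seed)
  render_movie(gt, cfg, seed = seed, n_frames = n_frames,
               rot_step = rot_step, trans_step = trans_step, ...)
}

# Short single-fly posture-mode session with k separable states.
tiny_modes <- function(n_states = 3, seed = 1, noise_sd = 0.1,
                       n_cycles = 1, on_s = 15, off_s = 45) {
  cfg <- synthetic_config(n_states = n_states, n_modes = 2 * n_states,
                          noise_sd = noise_sd)
  sch <- make_led_schedule(100, n_cycles, on_s, off_s)
  gt <- simulate_states(cfg, sch, seed)
  list(config = cfg, schedule = sch, gt = gt,
       modes = synthesize_posture(gt, cfg, seed))
}

# Map grid covering the unit-circle territories.
unit_grid <- function(resolution = 64) {
  map_grid(cbind(c(-1.5, 1.5), c(-1.5, 1.5)), resolution = resolution,
           pad = 0)
}

# Circular angular difference in degrees.
angle_diff <- function(a, b) {
  d <- abs((a - b) %% 360)
  min(d, 360 - d)
}

# Body-pixel count of a single frame via the package's mixture split,
# taking the visible silhouette as the mask.
body_area_of_frame <- function(frame, floor = 0.05) {
  optomap:::body_pixel_count(frame[frame > floor])
}

# Random probability vectors (floored + normalized like feature rows).
random_prob_rows <- function(n, d, eps = 1e-12) {
  X <- matrix(stats::rexp(n * d), n, d) + eps
  X / rowSums(X)
}
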