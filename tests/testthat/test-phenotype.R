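test_that("trial windows cover 0-3 s on and 30-45 s off", {
  sch <- make_led_schedule(100, 30, 15, 45)
  w <- trial_windows(sch)
  expect_length(w$on, 300)
  expect_length(w$off, 1500)
  expect_equal(w$on[1], 0)
  expect_equal(w$off[1], 3000)
  expect_length(intersect(w$on, w$off), 0)
  # onset at frame 6000: absolute on frames are [6000, 6300)
  expect_equal(sch$onset_frames[2] + range(w$on), c(6000, 6299))
  expect_error(trial_windows(make_led_schedule(100, 2, 5, 10)), "shorter")
})

test_that("trial densities are normalized and track the stimulus", {
  sch <- make_led_schedule(100, 6, 15, 45)
  grid <- unit_grid()
  # pinned fly: a single state throughout, on- and off-densities agree
  cfg1 <- synthetic_config(n_states = 2, n_modes = 4,
                           T_off = matrix(c(1, 1, 0, 0), 2), context_map = c(1L, 1L))
  pin <- simulate_embedded_fly(cfg1, sch, seed = 1)
  tens1 <- trial_densities(list(pin$points), "experimental", sch, grid)
  expect_equal(sum(tens1$on[, 2, 1]), 1, tolerance = 1e-9)
  tv <- 0.5 * sum(abs(tens1$on[, 2, 1] - tens1$off[, 2, 1]))
  expect_lt(tv, 0.05)
  # LED-activated state: on-window mass in its territory exceeds off
  cfg2 <- synthetic_config(n_states = 3, n_modes = 4, target_state = 2,
                           on_strength = 0.1)
  act <- simulate_embedded_fly(cfg2, sch, seed = 2, stride = 5L)
  tens2 <- trial_densities(list(act$points), "experimental", sch, grid)
  terr <- territory_regions(act$centers, act$scatter_sd, grid)$labels == 2
  mass_on <- mean(apply(tens2$on[, , 1], 2, function(d) sum(d[terr])))
  mass_off <- mean(apply(tens2$off[, , 1], 2, function(d) sum(d[terr])))
  expect_gt(mass_on, mass_off + 0.2)
  # windows without embedded frames are flagged missing
  gap <- act$points[!(act$points$frame %in% (sch$onset_frames[3] + 0:299)), ]
  tens3 <- trial_densities(list(gap), "experimental", sch, grid)
  expect_true(tens3$missing[3, 1])
  expect_false(tens3$missing[2, 1])
})

test_that("the chi statistic follows its defining arithmetic", {
  sch <- make_led_schedule(100, 3, 15, 45)
  grid <- map_grid(data.frame(x = 0:1, y = 0:1), resolution = 2, pad = 0)
  tens <- list(on = array(0, c(4, 3, 1)), off = array(0, c(4, 3, 1)),
               missing = matrix(FALSE, 3, 1), grid = grid)
  class(tens) <- "trial_tensor"
  tens$on[, 2, 1] <- c(0.5, 0.5, 0, 0)
  tens$off[, 1, 1] <- c(0.2, 0.4, 0.4, 0)
  tens$off[, 2, 1] <- c(0.4, 0.2, 0.2, 0.2)
  chi <- chi_map(tens, 1, 2)
  expect_equal(chi[1, 1], 0.5 - (0.2 + 0.4) / 2)  # 0.2 on the printed formula
  expect_equal(sum(chi), 0, tolerance = 1e-9)     # densities all sum to 1
  # identical on/off densities give a zero map
  tens$on[, 2, 1] <- tens$off[, 2, 1] <- tens$off[, 1, 1]
  expect_true(all(chi_map(tens, 1, 2) == 0))
  expect_error(chi_map(tens, 1, 1), "cycle 1")
})

test_that("the Sidak threshold matches its closed form", {
  expect_equal(sidak_threshold(0.05, 1), 0.05)
  expect_equal(sidak_threshold(0.05, 20), 1 - 0.95^(1 / 20), tolerance = 1e-15)
  expect_equal(sidak_threshold(0.05, 20), 0.00256, tolerance = 1e-3)
  m <- c(1, 2, 5, 20, 2^10)
  expect_true(all(diff(sidak_threshold(0.05, m)) < 0))
})

test_that("entropy obeys bounds, identities and additivity", {
  expect_equal(entropy(rep(1 / 1024, 1024)), 10)
  pm <- c(1, rep(0, 63))
  expect_equal(entropy(pm), 0)
  set.seed(3)
  px <- as.vector(random_prob_rows(1, 32))
  py <- as.vector(random_prob_rows(1, 16))
  joint <- outer(px, py)
  expect_equal(entropy(joint), entropy(px) + entropy(py), tolerance = 1e-9)
  expect_equal(entropy(joint), oracle_entropy(as.vector(joint)),
               tolerance = 1e-12)
  expect_error(entropy(c(0.4, 0.4)), "normalized")
})

test_that("the rank-sum test matches exact enumeration and wilcox.test", {
  p_or <- oracle_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(p_or, 0.1)
  expect_equal(wilcox.test(c(1, 2, 3), c(4, 5, 6))$p.value, 0.1)
  # the vectorized normal approximation agrees with wilcox.test's
  # corrected approximation on moderate samples
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(30); y <- rnorm(30, 0.4)
    p_pkg <- optomap:::rank_sum_p(matrix(x), matrix(y))
    p_ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(p_pkg, p_ref, tolerance = 1e-9)
  }
  # constant cells are never significant
  expect_equal(optomap:::rank_sum_p(matrix(1, 5), matrix(1, 5)), 1)
})

test_that("significance maps find the activated territory and report 2^H comparisons", {
  sch <- make_led_schedule(100, 8, 15, 45)
  grid <- unit_grid()
  cfg <- synthetic_config(n_states = 4, n_modes = 4, target_state = 3,
                          on_strength = 0.1)
  coh <- simulate_embedded_cohort(cfg, sch, seed = 5, n_exp = 6, n_ctrl = 6,
                                  stride = 5L)
  emb <- lapply(coh$flies, function(f) f$points)
  tens <- trial_densities(emb, coh$roles, sch, grid)
  sig <- significance_maps(tens)
  expect_equal(sig$m, ceiling(2^sig$H))
  expect_equal(sig$alpha_prime, 1 - 0.95^(1 / sig$m))
  terr <- territory_regions(coh$centers, coh$flies[[1]]$scatter_sd,
                            grid, radius_mult = 5)$labels == 3
  act <- sig$mask & sig$mean_chi > 0
  expect_gt(sum(act & terr) / sum(act | terr), 0.3)
  sr <- significant_regions(sig)
  expect_gte(sr$N, 1)
})

test_that("significant region extraction counts mask components", {
  empty <- matrix(FALSE, 16, 16)
  expect_equal(significant_regions(empty)$N, 0L)
  one <- empty; one[4:6, 4:6] <- TRUE
  s1 <- significant_regions(one)
  expect_equal(s1$N, 1L)
  lab <- matrix(0L, 16, 16); lab[4:6, 4:6] <- 1L
  ws <- structure(list(labels = lab, n_regions = 1L, sizes = 9L,
                       names = "R1", threshold = 0), class = "region_set")
  expect_equal(significant_regions(one, ws)$overlaps[[1]], 1L)
  two <- one; two[12:14, 12:14] <- TRUE
  expect_equal(significant_regions(two)$N, 2L)
})

test_that("entropy curves pool 41 frames per cycle and track stimulation", {
  sch <- make_led_schedule(100, 2, 15, 45)
  grid <- unit_grid()
  pts <- data.frame(frame = 0:(sch$total_frames - 1), x = 0.3, y = -0.2,
                    valid = TRUE)
  ec <- entropy_curve(list(pts), sch, grid, step_s = 1)
  # +-200 ms at 100 fps: 41 frames per cycle, two cycles pooled
  expect_equal(ec$n_points[ec$phase_s == 30], 82L)
  # a fixed location gives the same (kernel) entropy at every phase
  expect_lt(diff(range(ec$H_bits)), 1e-9)
  # a stationary (single-state) fly's curve is flat
  cfgS <- synthetic_config(n_states = 1, n_modes = 2,
                           T_off = matrix(1, 1, 1), context_map = 1L,
                           state_spectra = list(data.frame(mode = 1,
                                                           freq = 5,
                                                           amp = 1)))
  sch30 <- make_led_schedule(100, 30, 15, 45)
  fly <- simulate_embedded_fly(cfgS, sch30, seed = 6)
  ecS <- entropy_curve(list(fly$points), sch30, grid, step_s = 1)
  expect_lt(max(ecS$H_bits) - min(ecS$H_bits), 0.1)
  # LED pinning the fly: the minimum falls inside the stimulation window
  cfgA <- synthetic_config(n_states = 3, n_modes = 4, target_state = 1,
                           on_strength = 0.1)
  flies <- lapply(1:4, function(i)
    simulate_embedded_fly(cfgA, sch30, seed = 10 + i, stride = 5L)$points)
  ecA <- entropy_curve(flies, sch30, grid, step_s = 0.5)
  tmin <- ecA$phase_s[which.min(ecA$H_bits)]
  expect_lt(tmin, 15)
  # recovery after offset: late-cycle entropy is back near baseline
  late <- mean(ecA$H_bits[ecA$phase_s >= 30 & ecA$phase_s < 45])
  expect_gt(late, min(ecA$H_bits, na.rm = TRUE) + 0.5)
})

test_that("region time courses report occupancy with spread", {
  sch <- make_led_schedule(100, 6, 15, 45)
  grid <- unit_grid()
  cfg <- synthetic_config(n_states = 3, n_modes = 4)
  flies <- lapply(1:3, function(i)
    simulate_embedded_fly(cfg, sch, seed = i, stride = 10L)$points)
  whole <- structure(list(labels = matrix(1L, grid$n, grid$n),
                          n_regions = 1L, sizes = grid$n^2, names = "R1",
                          threshold = 0), class = "region_set")
  tc <- region_timecourse(flies, whole, 1, sch, grid, step_s = 5)
  expect_true(all(abs(tc$mean - 1) < 1e-12))
  none <- structure(list(labels = matrix(0L, grid$n, grid$n),
                         n_regions = 1L, sizes = 0L, names = "R1",
                         threshold = 0), class = "region_set")
  # an empty region is never occupied
  tc0 <- region_timecourse(flies, none, 1, sch, grid, step_s = 5)
  expect_true(all(tc0$mean == 0))
  expect_true(all(tc$n > 0))
})

test_that("per-neuron averaging keeps positive significant activation only", {
  m <- matrix(0, 8, 8)
  a <- m; a[2:3, 2:3] <- 0.4; a[6, 6] <- -0.5
  mask_a <- m > -Inf  # everything significant
  line_a <- list(mean_chi = a, mask = mask_a)
  avg1 <- neuron_average(list(line_a))
  expect_equal(avg1[2, 2], 0.4)
  expect_equal(avg1[6, 6], 0)  # negative means are zeroed
  expect_equal(neuron_average(list(line_a, line_a)), avg1)
  b <- m; b[6:7, 6:7] <- 0.8
  line_b <- list(mean_chi = b, mask = mask_a)
  avg <- neuron_average(list(line_a, line_b))
  expect_equal(avg[2, 2], 0.2)   # half weight per line
  expect_equal(avg[6, 6], 0.4)
  bad <- list(mean_chi = matrix(0, 4, 4), mask = matrix(TRUE, 4, 4))
  expect_error(neuron_average(list(line_a, bad)), "grid mismatch")
})
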