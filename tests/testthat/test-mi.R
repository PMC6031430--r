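# A small hand-built region set on a 20x20 grid: region 1 is a left block,
# region 2 a right block.
two_block_regions <- function() {
  lab <- matrix(0L, 20, 20)
  lab[3:6, 3:6] <- 1L
  lab[15:18, 15:18] <- 2L
  structure(list(labels = lab, n_regions = 2L,
                 sizes = c(16L, 16L), names = c("R1", "R2"), threshold = 0),
            class = "region_set")
}

block_grid <- function() {
  map_grid(data.frame(x = c(0, 1), y = c(0, 1)), resolution = 20, pad = 0)
}

# Points whose density mode lands exactly on the given cell.
points_at_cell <- function(cell, grid, n = 30) {
  cc <- grid_cell_centers(grid)
  data.frame(x = rep(cc$x[cell[1]], n), y = rep(cc$y[cell[2]], n),
             valid = TRUE)
}

test_that("post-stimulus trials are assigned by mode location and the 5-cell rule", {
  g <- block_grid()
  r <- two_block_regions()
  # mode inside region 2
  a <- assign_post_region(points_at_cell(c(16, 16), g), r, g)
  expect_equal(a$label, 2L)
  expect_equal(a$distance, 0)
  # mode 4 cells from region 1 and far from region 2: assigned to region 1
  b <- assign_post_region(points_at_cell(c(10, 4), g), r, g)
  expect_equal(b$label, 1L)
  expect_equal(b$distance, 4)
  # mode farther than 5 cells from every region: the zero label
  cc <- assign_post_region(points_at_cell(c(12, 10), g), r, g)
  expect_equal(cc$label, 0L)
  # no regions at all: the zero label
  empty <- structure(list(labels = matrix(0L, 20, 20), n_regions = 0L,
                          sizes = integer(0), names = character(0),
                          threshold = 0), class = "region_set")
  expect_equal(assign_post_region(points_at_cell(c(10, 10), g), empty,
                                  g)$label, 0L)
})

test_that("mutual information vanishes when pre-densities carry no label information", {
  set.seed(1)
  pre <- matrix(rep(as.vector(random_prob_rows(1, 100)), 40), ncol = 40)
  asg <- list(pre = pre, label = rep(c(0L, 1L, 2L), length.out = 40))
  expect_equal(mutual_information(asg)$mi, 0, tolerance = 1e-9)
  # a single label also gives zero
  asg1 <- list(pre = pre, label = rep(1L, 40))
  expect_equal(mutual_information(asg1)$mi, 0)
})

test_that("disjoint equiprobable conditionals saturate the log2(N+1) bound", {
  # N = 3 regions plus the zero label, each on its own 25-cell support
  n_per <- 10
  pre <- matrix(0, 100, 4 * n_per)
  lab <- rep(0:3, each = n_per)
  for (t in seq_len(4 * n_per)) {
    block <- lab[t] * 25 + 1:25
    pre[block, t] <- 1 / 25
  }
  asg <- list(pre = pre, label = lab)
  expect_equal(mutual_information(asg)$mi, 2, tolerance = 1e-12)
})

test_that("the plug-in MI matches the brute-force double loop", {
  set.seed(2)
  for (rep_i in 1:20) {
    n_tr <- sample(10:40, 1)
    pre <- t(random_prob_rows(n_tr, 50))
    lab <- sample(0:3, n_tr, replace = TRUE)
    asg <- list(pre = pre, label = lab)
    expect_equal(mutual_information(asg)$mi,
                 oracle_mi_assignments(pre, lab), tolerance = 1e-12)
  }
  bad <- list(pre = matrix(2, 10, 4), label = rep(0:1, 2))
  expect_error(mutual_information(bad), "normalized")
})

test_that("MI is invariant to relabeling and to empty regions", {
  set.seed(3)
  pre <- t(random_prob_rows(30, 40))
  lab <- sample(1:3, 30, replace = TRUE)
  mi0 <- mutual_information(list(pre = pre, label = lab))$mi
  perm <- c(7L, 5L, 9L)
  mi_perm <- mutual_information(list(pre = pre, label = perm[lab]))$mi
  expect_equal(mi0, mi_perm, tolerance = 1e-12)
  # the bound: MI <= log2(number of labels)
  expect_lte(mi0, log2(3) + 1e-9)
})

test_that("partial MI maps decompose the total exactly", {
  set.seed(4)
  pre <- t(random_prob_rows(36, 60))
  lab <- sample(0:2, 36, replace = TRUE)
  fit <- mutual_information(list(pre = pre, label = lab))
  total <- sum(vapply(fit$labels, function(k) sum(partial_mi_map(fit, k)),
                      numeric(1)))
  expect_equal(total, fit$mi, tolerance = 1e-9)
  # a label whose conditional equals the marginal contributes ~nothing
  pre2 <- cbind(pre, fit$marginal, fit$marginal, fit$marginal)
  lab2 <- c(lab, 9L, 9L, 9L)
  fit2 <- mutual_information(list(pre = pre2, label = lab2))
  expect_lt(sum(abs(partial_mi_map(fit2, 9L))), 0.02)
  expect_error(partial_mi_map(fit, 42L), "not present")
})

test_that("partial maps localize the context that predicts a region", {
  g <- unit_grid()
  sch <- make_led_schedule(100, 30, 15, 45, lead_in_s = 2)
  cfg <- synthetic_config(n_states = 4, n_modes = 4, target_state = 2,
                          delta = 1)
  coh <- simulate_context_cohort(cfg, sch, seed = 5, n_flies = 4,
                                 stride = 5L)
  regions <- territory_regions(coh$centers, coh$scatter_sd, g)
  asg <- suppressMessages(trial_assignments(coh$flies, sch, regions, g))
  fit <- mutual_information(asg)
  # region ctx[a] is predicted by pre-state a: its partial map concentrates
  # on state a's territory
  a <- 3L
  target_lab <- cfg$context_map[a]
  pm <- partial_mi_map(fit, target_lab, g)
  terr_a <- territory_regions(coh$centers, coh$scatter_sd, g,
                              radius_mult = 5)$labels == a
  pos <- pmax(pm, 0)
  expect_gte(sum(pos[terr_a]) / sum(pos), 0.6)
})

test_that("bias correction tightens with more trials and stays near truth", {
  g <- unit_grid()
  cfg <- synthetic_config(n_states = 4, n_modes = 4, target_state = 2,
                          delta = 1)
  truth <- context_trial_mi(cfg, g)
  gaps <- vapply(c(10, 30), function(nc) {
    sch <- make_led_schedule(100, nc, 15, 45, lead_in_s = 2)
    diffs <- vapply(1:3, function(s) {
      coh <- simulate_context_cohort(cfg, sch, seed = s, n_flies = 6,
                                     stride = 5L)
      regions <- territory_regions(coh$centers, coh$scatter_sd, g)
      asg <- suppressMessages(trial_assignments(coh$flies, sch, regions, g))
      bc <- bias_correct(asg, n_boot = 40, seed = s)
      abs(bc$mi - bc$mi_corrected)
    }, numeric(1))
    mean(diffs)
  }, numeric(1))
  # tripling the trial count shrinks the raw-vs-corrected gap
  expect_lt(gaps[2], gaps[1])
})

test_that("few trials trigger the instability warning", {
  set.seed(6)
  pre <- t(random_prob_rows(10, 20))
  asg <- list(pre = pre, label = sample(0:1, 10, replace = TRUE))
  expect_warning(bias_correct(asg, n_boot = 10, seed = 1), "fewer than 20")
})
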