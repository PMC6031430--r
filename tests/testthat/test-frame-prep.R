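test_that("blank frames are flagged invalid with an empty mask", {
  seg <- segment_fly(matrix(0, 96, 96))
  expect_false(seg$valid)
  expect_false(any(seg$mask))
})

test_that("segmentation recovers the rendered silhouette across fly sizes", {
  for (bs in c(1, 1.5, 2)) {
    mv <- tiny_movie(n_frames = 1, body_scale = bs)
    fr <- mv$frames[, , 1]
    seg <- segment_fly(fr)
    expect_true(seg$valid)
    expect_equal(sum(seg$mask) / sum(fr > 0), 1, tolerance = 0.1)
  }
})

test_that("a fly touching the border invalidates the frame", {
  mv <- tiny_movie(n_frames = 1)
  fr <- shift_image(mv$frames[, , 1], 40, 0)  # push the fly into the border
  seg <- segment_fly(fr)
  expect_false(seg$valid)
})

test_that("body area from the intensity mixture matches the rendered body", {
  mv <- tiny_movie(n_frames = 30)
  frames <- lapply(1:30, function(t) mv$frames[, , t])
  masks <- lapply(frames, function(f) f > 0)  # exact silhouettes
  est <- suppressWarnings(estimate_body_area(frames, masks, n_sample = 30))
  expect_equal(est, mv$body_area_px, tolerance = 0.05)
})

test_that("a uniform-intensity blob falls back to its full area", {
  blob <- matrix(0, 64, 64)
  blob[20:40, 20:40] <- 0.5
  est <- suppressWarnings(estimate_body_area(list(blob), list(blob > 0),
                                             n_sample = 1))
  expect_equal(est, 21^2)
})

test_that("doubling the fly's linear size quadruples the estimated area", {
  areas <- vapply(c(1, 2), function(bs) {
    mv <- tiny_movie(n_frames = 10, body_scale = bs)
    frames <- lapply(1:10, function(t) mv$frames[, , t])
    suppressWarnings(estimate_body_area(frames,
                                        lapply(frames, function(f) f > 0),
                                        n_sample = 10))
  }, numeric(1))
  expect_equal(areas[2] / areas[1], 4, tolerance = 0.1)
})

test_that("rescaling applies the square-root area factor", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  expect_equal(rescale_frame(fr, 300, 300)$factor, 1)
  expect_identical(rescale_frame(fr, 300, 300)$frame, fr)
  expect_equal(rescale_frame(fr, 400, 100)$factor, 0.5)
  expect_error(rescale_frame(fr, 0, 100), "positive")
})

test_that("rescaled flies reach the reference body area (fixed point)", {
  big <- tiny_movie(n_frames = 5, body_scale = 2)
  ref <- tiny_movie(n_frames = 5, body_scale = 1)
  area_big <- big$body_area_px
  area_ref <- ref$body_area_px
  rs <- rescale_frame(big$frames[, , 1], area_big, area_ref)
  est <- body_area_of_frame(rs$frame)
  expect_equal(est, area_ref, tolerance = 0.05)
})

test_that("rotational alignment recovers injected angles within one bin", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  expect_equal(align_rotation(fr, fr)$angle, 0, tolerance = 1e-6)
  for (th in c(10, 34, 127, 218, 305)) {
    rec <- align_rotation(rotate_image(fr, th), fr)$angle
    expect_lt(angle_diff(rec, th), 1)
  }
})

test_that("the head/tail ambiguity is resolved toward the head-up pose", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  rec <- align_rotation(rotate_image(fr, 180), fr)$angle
  expect_lt(angle_diff(rec, 180), 1)  # not folded back to 0
})

test_that("a flat frame cannot be rotationally aligned", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  out <- align_rotation(matrix(0, 96, 96), fr)
  expect_false(out$valid)
})

test_that("translational alignment recovers integer shifts", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  expect_equal(align_translation(fr, fr)[c("dx", "dy")],
               list(dx = 0, dy = 0))
  tr <- align_translation(shift_image(fr, 7, -3), fr)
  expect_equal(tr$dx, 7)
  expect_equal(tr$dy, -3)
  expect_equal(tr$shifted, fr)
  # pure noise stays well-defined
  set.seed(1)
  noise <- matrix(runif(96^2), 96)
  out <- align_translation(noise, fr)
  expect_true(is.finite(out$dx) && is.finite(out$dy))
})

test_that("alignment is idempotent to one grid step", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  moved <- shift_image(rotate_image(fr, 50), 4, -2)
  r1 <- align_rotation(moved, fr)
  t1 <- align_translation(r1$rotated, fr)
  r2 <- align_rotation(t1$shifted, fr)
  t2 <- align_translation(r2$rotated, fr)
  expect_lt(angle_diff(r2$angle, 0), 1)
  expect_lte(abs(t2$dx), 1)
  expect_lte(abs(t2$dy), 1)
})

test_that("compose-and-recover holds for random rigid transforms", {
  fr <- tiny_movie(n_frames = 1)$frames[, , 1]
  set.seed(3)
  for (i in 1:10) {
    th <- runif(1, 0, 360)
    d <- sample(-6:6, 2)
    moved <- rotate_image(shift_image(fr, d[1], d[2]), th)
    ra <- align_rotation(moved, fr)
    tr <- align_translation(ra$rotated, fr)
    expect_lt(angle_diff(ra$angle, th), 1)
    expect_lte(abs(tr$dx - d[1]), 1)
    expect_lte(abs(tr$dy - d[2]), 1)
  }
})

test_that("prepare_frames aligns a jittered movie and reports validity", {
  mv <- tiny_movie(n_frames = 12, seed = 4, rot_step = 2, trans_step = 0.8)
  prep <- suppressWarnings(prepare_frames(mv, n_area_sample = 12))
  expect_gte(prep$fraction_valid, 0.8)
  expect_equal(dim(prep$frames), dim(mv$frames))
  # aligned frames correlate strongly with the reference
  ok <- which(prep$valid)[-1]
  for (t in head(ok, 3)) {
    a <- prep$frames[, , t]; r <- prep$reference
    expect_gt(cor(as.vector(a), as.vector(r)), 0.8)
  }
})
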