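#' Render a synthetic fly movie from a ground-truth state sequence
#'
#' Draws a head-up fly (bright elliptical body with a head lobe, dimmer
#' appendage blobs whose angles follow the first two synthetic posture
#' modes) on a square canvas, then applies a global rigid rotation and
#' translation random walk. Emulates the fly-centered crops a tracking rig
#' saves; intended for testing the frame-preparation stage, not for
#' photorealism. Frames where the fly touches the border are flagged
#' invalid rather than raising an error.
#'
#' @param ground_truth a [simulate_states()] result (only the first
#'   `n_frames` frames are rendered).
#' @param config the matching [synthetic_config()].
#' @param seed integer RNG seed.
#' @param n_frames number of frames to render.
#' @param img_size canvas side in pixels (>= 64).
#' @param body_scale linear size multiplier of the fly.
#' @param rot_step sd of the per-frame global rotation increment, degrees
#'   (0 = no global rotation).
#' @param trans_step sd of the per-frame global translation increment,
#'   pixels.
#' @param appendage_gain degrees of appendage deflection per unit of mode
#'   amplitude.
#' @param modes optional `postural_modes` from [synthesize_posture()];
#'   synthesized on the fly when missing.
#' @return a `frame_stack`: `frames` (img_size x img_size x n_frames
#'   array), `valid`, `fps`, `scale_factor`, plus `centroids` (data.frame
#'   `frame`, `x`, `y`), `led_log` (data.frame `frame`, `led`),
#'   `angles_deg` (injected global rotation per frame) and `body_area_px`
#'   (rendered body-pixel count of the canonical pose).
#' @export
render_movie <- function(ground_truth, config, seed = 1, n_frames = 200,
                         img_size = 96, body_scale = 1, rot_step = 1,
                         trans_step = 0.5, appendage_gain = 20,
                         modes = NULL, schedule = NULL) {
  stop_if_not(img_size >= 64, "image size must be at least 64 x 64")
  if (is.null(modes)) modes <- synthesize_posture(ground_truth, config, seed)
  n_frames <- min(n_frames, nrow(modes$modes))
  set.seed(seed + 7L)
  ang <- cumsum(rnorm(n_frames, sd = rot_step))
  cx <- img_size / 2 + cumsum(rnorm(n_frames, sd = trans_step))
  cy <- img_size / 2 + cumsum(rnorm(n_frames, sd = trans_step))
  # keep the random walk loosely centered
  cx <- img_size / 2 + pmin(pmax(cx - img_size / 2, -8), 8)
  cy <- img_size / 2 + pmin(pmax(cy - img_size / 2, -8), 8)

  frames <- array(0, c(img_size, img_size, n_frames))
  valid <- logical(n_frames)
  for (t in seq_len(n_frames)) {
    defl <- appendage_gain * modes$modes[t, 1:2]
    fr <- draw_fly(img_size, cx[t], cy[t], ang[t], body_scale, defl)
    frames[, , t] <- fr$img
    valid[t] <- !fr$touches_border
  }
  led <- if (is.null(schedule)) rep(0L, n_frames) else
    as.integer(led_mask(schedule)[seq_len(n_frames)])
  canonical <- draw_fly(img_size, img_size / 2, img_size / 2, 0, body_scale,
                        c(0, 0))
  structure(list(
    frames = frames, valid = valid, fps = config$fps, scale_factor = 1,
    centroids = data.frame(frame = seq_len(n_frames) - 1L, x = cx, y = cy),
    led_log = data.frame(frame = seq_len(n_frames) - 1L, led = led),
    angles_deg = ang, body_area_px = canonical$body_area
  ), class = "frame_stack")
}

# Draw one fly. Canvas indexed [x, y]; the head points toward -y ("up")
# at zero rotation. Returns the image, border flag and body pixel count.
draw_fly <- function(img_size, cx, cy, angle_deg, scale, appendage_defl,
                     body_intensity = 200 / 255, leg_intensity = 80 / 255) {
  th <- angle_deg * pi / 180
  xs <- matrix(seq_len(img_size), img_size, img_size) - cx
  ys <- matrix(rep(seq_len(img_size), each = img_size), img_size, img_size) - cy
  # body frame: rotate world coords by -theta
  bx <- cos(th) * xs + sin(th) * ys
  by <- -sin(th) * xs + cos(th) * ys
  a <- 7 * scale; b <- 13 * scale          # ellipse semi-axes (narrow, long)
  body <- (bx / a)^2 + (by / b)^2 <= 1
  head <- (bx / (4.5 * scale))^2 + ((by + 14 * scale) / (4.5 * scale))^2 <= 1
  img <- matrix(0, img_size, img_size)
  img[body | head] <- body_intensity
  # two appendages at +-55 deg from the head axis, deflected by the modes
  for (side in c(-1, 1)) {
    base <- side * 55 + appendage_defl[if (side < 0) 1 else 2]
    ar <- 11 * scale  # adjacent to the body so the closed contour is tight
    aa <- (base) * pi / 180
    ax <- ar * sin(aa); ay <- -ar * cos(aa)
    leg <- ((bx - ax) / (3 * scale))^2 + ((by - ay) / (3 * scale))^2 <= 1
    img[leg & img == 0] <- leg_intensity
  }
  fg <- img > 0
  touches <- any(fg[1, ]) || any(fg[img_size, ]) ||
    any(fg[, 1]) || any(fg[, img_size])
  list(img = img, touches_border = touches,
       body_area = sum(body | head))
}
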