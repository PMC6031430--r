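#' Read an LED stimulus log
#'
#' Two-column whitespace- or comma-separated text: frame index and LED
#' state (0/1), one row per frame as written by the acquisition rig.
#' Frame indices must be strictly increasing; a single missing frame
#' between two rows of equal state is interpolated with a warning.
#'
#' @param path text file path.
#' @return data.frame `frame` (0-based), `led` (integer 0/1).
#' @export
read_led_log <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  parts <- strsplit(trimws(raw), "[,[:space:]]+")
  bad_cols <- which(lengths(parts) != 2)
  if (length(bad_cols))
    stop("malformed LED log at line ", bad_cols[1], call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric LED log entry at line ",
                     which(apply(is.na(m), 1, any))[1], call. = FALSE)
  if (!all(m[, 2] %in% c(0, 1))) {
    bad <- which(!(m[, 2] %in% c(0, 1)))[1]
    stop("LED state outside {0,1} at line ", bad, call. = FALSE)
  }
  d <- diff(m[, 1])
  if (any(d <= 0))
    stop("non-monotone frame numbers at line ", which(d <= 0)[1] + 1,
         call. = FALSE)
  gaps <- which(d == 2)
  if (length(gaps)) {
    fill <- do.call(rbind, lapply(gaps, function(g) {
      if (m[g, 2] == m[g + 1, 2]) c(m[g, 1] + 1, m[g, 2]) else NULL
    }))
    if (!is.null(fill)) {
      warning(nrow(fill), " missing LED sample(s) interpolated")
      m <- rbind(m, fill)
      m <- m[order(m[, 1]), ]
    }
  }
  data.frame(frame = as.integer(m[, 1]), led = as.integer(m[, 2]))
}

#' Write an LED stimulus log
#'
#' @param led_log data.frame `frame`, `led` (or a schedule via
#'   [led_mask()]).
#' @param path output text file.
#' @export
write_led_log <- function(led_log, path) {
  writeLines(paste(led_log$frame, led_log$led), path)
}

#' Infer the stimulation schedule from an LED log
#'
#' Onsets are rising edges of the LED state. The inferred cycle spacing
#' and on-duration must be uniform within `tol_frames`; the result is a
#' [make_led_schedule()] object (including any leading off period).
#'
#' @param led_log data.frame from [read_led_log()].
#' @param fps frames per second.
#' @param tol_frames allowed jitter in frames.
#' @return an `led_schedule`.
#' @export
infer_schedule <- function(led_log, fps, tol_frames = 1) {
  s <- led_log$led
  rises <- which(diff(c(0L, s)) == 1)
  if (!length(rises)) stop("LED log contains no stimulation onset",
                           call. = FALSE)
  falls <- which(diff(c(s, 0L)) == -1)
  on_len <- falls - rises + 1
  if (diff(range(on_len)) > tol_frames)
    stop("inconsistent LED-on durations", call. = FALSE)
  onsets <- led_log$frame[rises]
  if (length(onsets) > 1) {
    spacing <- diff(onsets)
    if (diff(range(spacing)) > tol_frames)
      stop("inconsistent cycle spacing", call. = FALSE)
    cyc <- round(mean(spacing))
  } else {
    cyc <- nrow(led_log) - onsets[1]
  }
  on_f <- round(mean(on_len))
  make_led_schedule(fps, length(onsets), on_f / fps, (cyc - on_f) / fps,
                    lead_in_s = onsets[1] / fps)
}

#' Write / read a centroid track
#'
#' @param centroids data.frame `frame`, `x`, `y`.
#' @param path CSV path.
#' @export
write_centroids <- function(centroids, path) {
  utils::write.csv(centroids, path, row.names = FALSE)
}

#' @rdname write_centroids
#' @export
read_centroids <- function(path) {
  utils::read.csv(path)
}

#' Write a frame stack as an image directory
#'
#' One grayscale PNG per frame, zero-padded filenames (the on-disk format
#' the pipeline reads back in place of uncompressed video).
#'
#' @param stack a `frame_stack`.
#' @param dir output directory (created).
#' @export
write_image_dir <- function(stack, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  T_len <- dim(stack$frames)[3]
  for (t in seq_len(T_len)) {
    EBImage::writeImage(EBImage::Image(stack$frames[, , t]),
                        file.path(dir, sprintf("frame_%06d.png", t - 1L)))
  }
  invisible(dir)
}

#' Read a frame stack from an image directory
#'
#' Frames are ordered by their zero-padded filenames. 150 x 150 crops (or
#' any other fixed size) are accepted as-is.
#'
#' @param dir directory of grayscale PNG/TIFF frames.
#' @param fps frames per second to record on the stack.
#' @return a `frame_stack`.
#' @export
read_image_dir <- function(dir, fps = 100) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE))
  stop_if_not(length(files) > 0, "no image frames found in %s", dir)
  first <- EBImage::imageData(EBImage::readImage(files[1]))
  if (length(dim(first)) > 2) first <- first[, , 1]
  frames <- array(0, c(nrow(first), ncol(first), length(files)))
  frames[, , 1] <- first
  for (t in seq_along(files)[-1]) {
    img <- EBImage::imageData(EBImage::readImage(files[t]))
    if (length(dim(img)) > 2) img <- img[, , 1]
    frames[, , t] <- img
  }
  structure(list(frames = frames, valid = rep(TRUE, length(files)),
                 fps = fps, scale_factor = 1), class = "frame_stack")
}
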