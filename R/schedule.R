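#' Build an LED stimulation schedule
#'
#' Defines the periodic red-light protocol: `n_cycles` repetitions of
#' `on_s` seconds of LED on followed by `off_s` seconds off, sampled at
#' `fps` frames per second. The default reproduces the standard protocol of
#' 30 cycles of 15 s on / 45 s off at 100 fps. Frame indices are 0-based
#' offsets from the start of the recording, matching the LED log format.
#'
#' @param fps frames per second.
#' @param n_cycles number of stimulation cycles.
#' @param on_s LED-on duration per cycle, seconds.
#' @param off_s LED-off (recovery) duration per cycle, seconds.
#' @param lead_in_s optional LED-off time before the first onset, seconds
#'   (default 0). A non-zero lead-in gives cycle 1 a pre-stimulus window.
#' @return an object of class `led_schedule` with fields `fps`, `n_cycles`,
#'   `on_s`, `off_s`, `lead_in_s`, `onset_frames` (0-based), `cycle_frames`,
#'   `on_frames`, `total_frames`.
#' @examples
#' sch <- make_led_schedule(100, 30, 15, 45)
#' sch$total_frames   # 180000
#' head(sch$onset_frames)
#' @export
make_led_schedule <- function(fps = 100, n_cycles = 30, on_s = 15, off_s = 45,
                              lead_in_s = 0) {
  stop_if_not(fps > 0 && n_cycles > 0 && on_s > 0 && off_s > 0 && lead_in_s >= 0,
              "all schedule arguments must be positive (lead_in_s >= 0)")
  chk <- function(x, label) {
    v <- x * fps
    if (abs(v - round(v)) > 1e-9)
      stop(sprintf("%s * fps = %g is not a whole number of frames", label, v),
           call. = FALSE)
    as.integer(round(v))
  }
  on_f <- chk(on_s, "on_duration")
  cyc_f <- chk(on_s + off_s, "on_duration+off_duration")
  lead_f <- chk(lead_in_s, "lead_in")
  onsets <- lead_f + (seq_len(n_cycles) - 1L) * cyc_f
  structure(list(
    fps = fps, n_cycles = as.integer(n_cycles), on_s = on_s, off_s = off_s,
    lead_in_s = lead_in_s, onset_frames = onsets, cycle_frames = cyc_f,
    on_frames = on_f, total_frames = lead_f + as.integer(n_cycles) * cyc_f
  ), class = "led_schedule")
}

#' @export
print.led_schedule <- function(x, ...) {
  cat(sprintf(
    "LED schedule: %d cycles of %gs on / %gs off at %g fps (%d frames)\n",
    x$n_cycles, x$on_s, x$off_s, x$fps, x$total_frames))
  invisible(x)
}

#' Per-frame LED state for a schedule
#'
#' @param schedule an [make_led_schedule()] object.
#' @return logical vector of length `total_frames`; element `t` is the LED
#'   state of 0-based frame `t - 1`.
#' @export
led_mask <- function(schedule) {
  m <- logical(schedule$total_frames)
  for (on in schedule$onset_frames) {
    m[(on + 1L):(on + schedule$on_frames)] <- TRUE
  }
  m
}

#' Frame phase within the stimulation cycle
#'
#' @param frames 0-based frame indices.
#' @param schedule an [make_led_schedule()] object.
#' @return 0-based frame offsets from the most recent cycle onset (periodic);
#'   `NA` for frames during the lead-in.
#' @export
cycle_phase <- function(frames, schedule) {
  lead <- schedule$onset_frames[1]
  ph <- (frames - lead) %% schedule$cycle_frames
  ph[frames < lead] <- NA_integer_
  ph
}

# Cycle number (1-based) of each 0-based frame; NA during lead-in/overrun.
cycle_index <- function(frames, schedule) {
  lead <- schedule$onset_frames[1]
  idx <- (frames - lead) %/% schedule$cycle_frames + 1L
  idx[frames < lead | idx > schedule$n_cycles] <- NA_integer_
  idx
}
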