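#' Acquisition frame schedule
#'
#' A frame schedule describes the rebinning of a dynamic PET acquisition into
#' contiguous frames. Frames are stored in seconds post-injection; mid-frame
#' times in minutes are derived on construction and used throughout the
#' graphical analyses.
#'
#' @param start_s Numeric vector of frame start times (seconds), strictly
#'   increasing.
#' @param end_s Numeric vector of frame end times (seconds), `end_s > start_s`
#'   framewise; frames must not overlap.
#' @return A `frame_schedule` data frame with columns `start_s`, `end_s`,
#'   `mid_min` and `dur_min`.
#' @examples
#' sched <- default_frame_schedule()
#' sum(sched$end_s - sched$start_s) # 3600 s
#' @export
frame_schedule <- function(start_s, end_s) {
  if (length(start_s) != length(end_s) || length(start_s) == 0L)
    stop("start_s and end_s must be non-empty vectors of equal length")
  if (any(diff(start_s) <= 0)) stop("frame start times must be strictly increasing")
  if (any(end_s <= start_s)) stop("each frame must end after it starts")
  if (any(start_s[-1] < end_s[-length(end_s)] - 1e-9))
    stop("frames must not overlap")
  out <- data.frame(
    start_s = as.numeric(start_s),
    end_s = as.numeric(end_s),
    mid_min = (as.numeric(start_s) + as.numeric(end_s)) / 2 / 60,
    dur_min = (as.numeric(end_s) - as.numeric(start_s)) / 60
  )
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' Default 20-frame, 60-minute acquisition schedule
#'
#' Nine 20 s frames, four 60 s, four 120 s and three 900 s frames, covering
#' 60 min from injection.
#'
#' @return A [frame_schedule()].
#' @export
default_frame_schedule <- function() {
  dur <- c(rep(20, 9), rep(60, 4), rep(120, 4), rep(900, 3))
  end <- cumsum(dur)
  frame_schedule(start_s = end - dur, end_s = end)
}

#' Default arterial and metabolite sampling times
#'
#' Thirteen arterial samples (3, 10, 20, 30, 40, 50 s then 1, 2, 5, 10, 25,
#' 40, 50 min post-injection), of which four (5, 25, 40, 50 min) carry a
#' measured parent fraction.
#'
#' @return `default_arterial_times()` and `default_metabolite_times()` return
#'   sample times in minutes; `default_schedules()` bundles the frame schedule
#'   and both sampling schedules in a list.
#' @export
default_arterial_times <- function() {
  early_s <- c(3, 10, 20, 30, 40, 50)
  c(early_s / 60, 1, 2, 5, 10, 25, 40, 50)
}

#' @rdname default_arterial_times
#' @export
default_metabolite_times <- function() c(5, 25, 40, 50)

#' @rdname default_arterial_times
#' @export
default_schedules <- function() {
  list(
    frames = default_frame_schedule(),
    arterial_times_min = default_arterial_times(),
    metabolite_times_min = default_metabolite_times()
  )
}

#' Default fine time grid for input functions
#'
#' One-second spacing over 0--60 min, fine enough to resolve the 20 s early
#' frames.
#'
#' @param t_max_min Upper end of the grid, minutes.
#' @param dt_s Grid spacing, seconds.
#' @return Numeric vector of times in minutes.
#' @export
default_grid <- function(t_max_min = 60, dt_s = 1) {
  seq(0, t_max_min, by = dt_s / 60)
}
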