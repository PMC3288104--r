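#' PET acquisition frame schedule
#'
#' Construct the 19-frame, 90-minute dynamic acquisition schedule used for
#' [11C]flumazenil scanning: 4 x 15 s, 3 x 1 min, 3 x 2 min, 2 x 5 min,
#' 7 x 10 min, contiguous from injection at t = 0.
#'
#' @param durations Frame durations in minutes. The default is the study
#'   schedule; any positive vector is accepted for non-conformant data.
#' @return A data.frame of class `frame_schedule` with columns `start`,
#'   `duration`, `mid` and `end` (all minutes).
#' @examples
#' sched <- make_frame_schedule()
#' nrow(sched)        # 19
#' sum(sched$duration)  # 90 min
#' @export
make_frame_schedule <- function(durations = c(rep(0.25, 4), rep(1, 3), rep(2, 3),
                                              rep(5, 2), rep(10, 7))) {
  if (!is.numeric(durations) || any(durations <= 0)) {
    stop("frame durations must all be positive")
  }
  start <- cumsum(c(0, durations[-length(durations)]))
  out <- data.frame(start = start,
                    duration = durations,
                    mid = start + durations / 2,
                    end = start + durations)
  class(out) <- c("frame_schedule", "data.frame")
  out
}

#' @keywords internal
assert_schedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("start", "duration") %in% names(schedule)))
  if (schedule$start[1] < 0) stop("schedule cannot start before injection")
  if (any(schedule$duration <= 0)) stop("frame durations must be positive")
  n <- nrow(schedule)
  if (n > 1) {
    gap <- schedule$start[-1] - (schedule$start[-n] + schedule$duration[-n])
    if (any(abs(gap) > 1e-9)) stop("frames must be contiguous")
  }
  invisible(schedule)
}
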