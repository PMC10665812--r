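# Piecewise-constant daily energy intake schedules.

#' Intervention schedule
#'
#' A piecewise-constant daily energy intake protocol. Each segment holds
#' `DE_i` at `level` (fraction of baseline intake) from its start time
#' until the next segment; the first segment must start at t = 0.
#'
#' @param times numeric vector of segment start times (months), strictly
#'   increasing, starting at 0.
#' @param levels intake levels as fractions of baseline (> 0), same length.
#' @param horizon total simulated months.
#' @return object of class `t2d_schedule`.
#' @export
#' @examples
#' # 175% of baseline from month 5, back to baseline at month 64
#' sch <- intervention_schedule(c(0, 5, 64), c(1, 1.75, 1), horizon = 144)
intervention_schedule <- function(times, levels, horizon) {
  stopifnot(length(times) == length(levels), length(times) >= 1)
  if (times[1] != 0) stop("first segment must start at t = 0")
  if (any(diff(times) <= 0)) stop("segment times must be strictly increasing")
  if (any(levels <= 0)) stop("intake levels must be positive")
  if (horizon <= max(times)) stop("horizon must exceed the last switch time")
  structure(list(times = as.numeric(times), levels = as.numeric(levels),
                 horizon = as.numeric(horizon)), class = "t2d_schedule")
}

#' @rdname intervention_schedule
#' @param schedule a `t2d_schedule`.
#' @param t time in months.
#' @return `schedule_level`: the intake fraction active at `t`.
#' @export
schedule_level <- function(schedule, t) {
  if (any(t < 0) || any(t > schedule$horizon))
    stop("time ", t[which(t < 0 | t > schedule$horizon)[1]],
         " outside schedule domain [0, ", schedule$horizon, "]")
  idx <- findInterval(t, schedule$times)
  schedule$levels[idx]
}

#' @export
print.t2d_schedule <- function(x, ...) {
  seg <- paste0(sprintf("%g mo: %g%%", x$times, 100 * x$levels), collapse = "; ")
  cat("<t2d_schedule> ", seg, " (horizon ", x$horizon, " mo)\n", sep = "")
  invisible(x)
}
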