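# Clinically meaningful events along a trajectory.

#' Detect events along a trajectory
#'
#' Locates prediabetes onset, T2D onset, remission, interior extrema of
#' beta-cell mass, and (when a threshold curve is supplied) separatrix
#' crossings. Crossing times are bracketed by sign changes on the output
#' grid and refined by bisection on a spline interpolant to 0.01-month
#' precision; beta extrema are located from sign changes of the exact
#' d(beta)/dt evaluated along the trajectory.
#'
#' Remission is the first time after an intake reduction at which glucose
#' falls below the T2D cutoff (125 mg/dL) and remains below it for the
#' rest of the horizon.
#'
#' @param traj a `t2d_trajectory`.
#' @param params a `t2d_parameters` object.
#' @param threshold optional `t2d_threshold` enabling separatrix-crossing
#'   events.
#' @return data frame (class `t2d_events`): `kind`, `time` (months), and
#'   the interpolated state at the event (`G`, `beta`, `BMI`).
#' @export
detect_events <- function(traj, params, threshold = NULL) {
  t <- traj$time
  G <- traj$state[, "G"]
  beta <- traj$state[, "beta"]
  ev <- list()
  add <- function(kind, time) {
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, time = time,
      G = .traj_interp(traj, "G", time),
      beta = .traj_interp(traj, "beta", time),
      BMI = .traj_interp(traj, "BMI", time))
  }
  gf <- stats::splinefun(t, G, method = "natural")
  up_cross <- function(level) {
    i <- which(G[-length(G)] < level & G[-1] >= level)
    if (!length(i)) return(NULL)
    i <- i[1]
    uniroot(function(x) gf(x) - level, c(t[i], t[i + 1]), tol = 1e-3)$root
  }
  tp <- up_cross(100)
  if (!is.null(tp)) add("prediabetes-onset", tp)
  td <- up_cross(125)
  if (!is.null(td)) add("t2d-onset", td)

  # remission: sustained drop below 125 after an intake reduction
  sch <- traj$schedule
  drops <- which(diff(sch$levels) < 0)
  if (length(drops) && any(G > 125)) {
    t_int <- sch$times[drops[1] + 1]
    after <- which(t >= t_int)
    below <- G[after] < 125
    if (length(below) && below[length(below)]) {
      run_start <- max(which(!below)) + 1
      if (run_start <= length(below)) {
        if (run_start == 1) {
          add("remission", t_int)
        } else {
          i <- after[run_start - 1]
          add("remission",
              uniroot(function(x) gf(x) - 125, c(t[i], t[i + 1]), tol = 1e-3)$root)
        }
      }
    }
  }

  # beta extrema from the exact derivative along the trajectory
  dbeta <- vapply(seq_along(t), function(i) {
    lev <- schedule_level(sch, min(t[i], sch$horizon))
    unname(rhs(t[i], traj$state[i, ], params, lev)[["beta"]])
  }, numeric(1))
  df <- stats::splinefun(t, dbeta, method = "natural")
  sgn <- sign(dbeta)
  flips <- which(sgn[-length(sgn)] * sgn[-1] < 0)
  sw <- sch$times[-1]
  for (i in flips) {
    # ignore flips driven by schedule discontinuities (not true extrema)
    if (length(sw) && any(abs(t[i] - sw) < 1e-6)) next
    # ignore numerical sign wiggle while beta is essentially stationary
    if (max(abs(dbeta[i]), abs(dbeta[i + 1])) < 1e-3) next
    tt <- tryCatch(uniroot(df, c(t[i], t[i + 1]), tol = 1e-3)$root,
                   error = function(e) NA_real_)
    if (is.na(tt)) next
    add(if (df(tt - 0.05) > 0) "beta-maximum" else "beta-minimum", tt)
  }

  # separatrix crossings
  if (!is.null(threshold)) {
    bmi <- traj$obs$BMI
    gsep <- beta - threshold_eval(threshold, bmi)
    sf <- stats::splinefun(t, gsep, method = "natural")
    sg <- sign(gsep)
    for (i in which(sg[-length(sg)] * sg[-1] < 0)) {
      tt <- tryCatch(uniroot(sf, c(t[i], t[i + 1]), tol = 1e-3)$root,
                     error = function(e) NA_real_)
      if (!is.na(tt)) add("separatrix-crossing", tt)
    }
  }

  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(kind = character(), time = numeric(), G = numeric(),
               beta = numeric(), BMI = numeric())
  out <- out[order(out$time), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("t2d_events", "data.frame")
  out
}
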