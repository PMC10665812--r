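# Stiff integration of the model under piecewise-constant intake schedules.

.t2d_state_scale <- c(W = 1e2, G = 1e2, I = 1e1, FFA = 1e2, theta = 1e-2,
                      S_i = 1e0, beta = 1e3, sigma = 1e0)

#' Simulate the model
#'
#' Integrates the eight-variable system with LSODA (via \pkg{deSolve}),
#' restarting the integrator at every schedule switch time so that the
#' discontinuities in daily energy intake are handled exactly. Absolute
#' tolerances are scaled per state variable by its characteristic
#' magnitude.
#'
#' @param params a `t2d_parameters` object.
#' @param schedule an [intervention_schedule()].
#' @param initial initial state; defaults to the healthy baseline
#'   equilibrium [baseline_state()].
#' @param dt output grid spacing, months.
#' @param rtol,atol relative and (scaled) absolute solver tolerances.
#' @param engine `"compiled"` (default) for the C right-hand side or
#'   `"r"` for the pure-R reference implementation [rhs()].
#' @return object of class `t2d_trajectory`: list with `time`, `state`
#'   (matrix, 8 columns), `obs` (data frame of observables), `schedule`,
#'   and `solver` metadata.
#' @export
#' @examples
#' p <- t2d_parameters()
#' tr <- simulate(p, intervention_schedule(c(0, 5), c(1, 1.3), 60))
#' tail(tr$obs$BMI, 1)   # steady-state BMI approaches 1.3 * 25
simulate <- function(params, schedule, initial = NULL, dt = 0.1,
                     rtol = 1e-8, atol = 1e-10,
                     engine = c("compiled", "r")) {
  engine <- match.arg(engine)
  p <- params
  if (is.null(initial)) initial <- baseline_state(p)
  y <- validate_state(initial)
  breaks <- c(schedule$times, schedule$horizon)
  out <- NULL
  atol_vec <- atol * .t2d_state_scale
  for (i in seq_along(schedule$levels)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    times <- unique(c(seq(t0, t1, by = dt), t1))
    seg <- .integrate_segment(p, y, times, schedule$levels[i],
                              rtol, atol_vec, engine)
    y <- seg[nrow(seg), -1]
    names(y) <- .t2d_state_order
    out <- rbind(out, if (i < length(schedule$levels)) seg[-nrow(seg), , drop = FALSE] else seg)
  }
  state <- as.matrix(out[, -1, drop = FALSE])
  colnames(state) <- .t2d_state_order
  lvl <- schedule_level(schedule, pmin(out[, 1], schedule$horizon))
  traj <- structure(list(
    time = out[, 1],
    state = state,
    obs = .observables_frame(state, p, lvl),
    schedule = schedule,
    params = p,
    solver = list(method = "lsoda", rtol = rtol, atol = atol,
                  engine = engine, dt = dt)),
    class = "t2d_trajectory")
  traj
}

.integrate_segment <- function(p, y, times, level, rtol, atol_vec, engine) {
  if (engine == "compiled") {
    res <- deSolve::lsoda(y = y, times = times, func = "t2d_derivs",
                          parms = .param_vector(p, level),
                          dllname = "t2dsim", initfunc = "t2d_initparms",
                          rtol = rtol, atol = atol_vec, maxsteps = 50000)
  } else {
    fr <- function(t, y, parms) list(rhs(t, y, p, level))
    res <- deSolve::lsoda(y = y, times = times, func = fr, parms = NULL,
                          rtol = rtol, atol = atol_vec, maxsteps = 50000)
  }
  d <- diagnostics_ok(res, times)
  if (!d$ok)
    stop("solver failure at t = ", d$last_t, " months (state: ",
         paste(sprintf("%s=%.4g", .t2d_state_order, d$last_y), collapse = ", "), ")")
  unclass(res)
}

diagnostics_ok <- function(res, times) {
  n <- nrow(res)
  if (n < length(times) || any(!is.finite(res[n, ])))
    return(list(ok = FALSE, last_t = res[n, 1], last_y = res[n, -1]))
  list(ok = TRUE)
}

# vectorized observables over the rows of a state matrix
.observables_frame <- function(state, p, DE_frac) {
  W <- state[, "W"]; G <- state[, "G"]; I <- state[, "I"]
  FFA <- state[, "FFA"]; theta <- state[, "theta"]; S_i <- state[, "S_i"]
  beta <- state[, "beta"]; sigma <- state[, "sigma"]
  BMI <- W / p$h^2
  act <- S_i * I
  M <- .hill(G, p$alpha_M, p$K_M)
  ISR <- sigma * .hill(M, p$alpha_ISR, p$K_ISR)
  data.frame(
    BMI = BMI,
    FM = (p$FMR_a * BMI + p$FMR_b) * W,
    HGP = p$HGP_b + p$HGP_max * p$alpha_HGP / (p$alpha_HGP + act),
    M = M, ISR = ISR,
    DE_i = DE_frac * p$DE_i_b,
    DPI = 1 - (S_i * sigma * beta) / (p$S_i_0 * p$sigma_0 * p$beta_0),
    glycemic = classify_glycemic(G),
    row.names = NULL)
}

#' @export
print.t2d_trajectory <- function(x, ...) {
  n <- length(x$time)
  cat("<t2d_trajectory> ", n, " points over ", max(x$time), " months; terminal G = ",
      round(x$state[n, "G"], 1), " mg/dL (", x$obs$glycemic[n], "), BMI = ",
      round(x$obs$BMI[n], 1), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.t2d_trajectory <- function(x, ...) {
  cbind(data.frame(time = x$time), as.data.frame(x$state), x$obs)
}

# cubic-spline interpolant of one trajectory column at arbitrary times
.traj_interp <- function(traj, column, t) {
  v <- if (column %in% colnames(traj$state)) traj$state[, column] else traj$obs[[column]]
  stats::spline(traj$time, v, xout = t, method = "natural")$y
}
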