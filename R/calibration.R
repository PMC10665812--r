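# Weighted-least-squares parameter estimation (Gaussian MLE), multi-start
# search, Fisher-information confidence intervals, and the synthetic-data
# generator used for recovery studies.

.obs_streams <- c("G", "I", "FFA", "theta", "S_i", "beta", "sigma", "BMI")

#' Observation set
#'
#' Sparse time-series observations of model observables: one row per
#' measurement with its stream name, time (months), value and
#' measurement SD.
#'
#' @param stream character; one of `r paste(.obs_streams, collapse=", ")`.
#' @param time months.
#' @param value measured value.
#' @param sd measurement SD (> 0).
#' @return data frame of class `t2d_observations`.
#' @export
observation_set <- function(stream, time, value, sd) {
  stopifnot(length(stream) == length(time), length(time) == length(value),
            length(value) == length(sd))
  bad <- setdiff(unique(stream), .obs_streams)
  if (length(bad)) stop("unknown observation stream(s): ",
                        paste(bad, collapse = ", "))
  if (any(sd <= 0)) stop("measurement SDs must be positive")
  structure(data.frame(stream = stream, time = time, value = value, sd = sd),
            class = c("t2d_observations", "data.frame"))
}

# model prediction for each observation row
.predict_obs <- function(data, params, schedule, dt = 0.5) {
  tr <- simulate(params, schedule, dt = dt, rtol = 1e-7, atol = 1e-9)
  vapply(seq_len(nrow(data)), function(i) {
    v <- data$stream[i]
    .traj_interp(tr, v, data$time[i])
  }, numeric(1))
}

# apply free-parameter values (possibly including schedule levels named
# "level<k>") onto (params, schedule)
.apply_free <- function(free, params, schedule) {
  p <- unclass(params); sch <- schedule
  for (nm in names(free)) {
    if (grepl("^level[0-9]+$", nm)) {
      k <- as.integer(sub("^level", "", nm))
      if (k > length(sch$levels)) stop("schedule has no segment ", k)
      sch$levels[k] <- free[[nm]]
    } else if (nm %in% .t2d_param_order) {
      p[[nm]] <- free[[nm]]
      if (nm %in% c("k_w", "DE_i_b", "DE_e", "h"))
        stop("energy-balance parameter '", nm, "' cannot be freed")
    } else stop("unknown free parameter: ", nm)
  }
  list(params = validate_parameters(p), schedule = sch)
}

#' Weighted least-squares cost
#'
#' Simulates at the trial parameters and returns the weighted sum of
#' squared residuals. With `weighting = "variance"` (the default, the
#' Gaussian maximum-likelihood form) each squared residual is divided by
#' `sd^2`; `weighting = "sd"` reproduces a literal sum of squared
#' differences divided by the SD itself.
#'
#' A solver failure at the trial parameters yields a large finite
#' penalty (1e8) rather than an error, so optimizers continue.
#'
#' @param free named numeric vector of free-parameter values; schedule
#'   levels can be freed as `level1`, `level2`, ...
#' @param params fixed parameter set.
#' @param data a [observation_set()].
#' @param schedule the intake schedule of the experiment.
#' @param weighting `"variance"` or `"sd"`.
#' @return scalar cost.
#' @export
cost <- function(free, params, data, schedule,
                 weighting = c("variance", "sd")) {
  r <- .residuals(free, params, data, schedule, match.arg(weighting))
  sum(r^2)
}

.residuals <- function(free, params, data, schedule, weighting = "variance") {
  tryCatch({
    ap <- .apply_free(as.list(free), params, schedule)
    pred <- .predict_obs(data, ap$params, ap$schedule)
    w <- if (weighting == "variance") data$sd else sqrt(data$sd)
    (data$value - pred) / w
  }, error = function(e) rep(sqrt(1e8 / nrow(data)), nrow(data)))
}

#' Fit free parameters by multi-start bounded least squares
#'
#' Levenberg-Marquardt (via \pkg{minpack.lm}) from `n_starts` random
#' initializations drawn uniformly within the bounds; the best converged
#' solution is returned together with the full start log.
#'
#' @param data a [observation_set()].
#' @param params fixed parameter set.
#' @param schedule intake schedule.
#' @param free character vector of free-parameter names.
#' @param lower,upper named bounds for the free parameters.
#' @param n_starts number of random starts.
#' @param seed integer seed for the start draws.
#' @param weighting see [cost()].
#' @return object of class `t2d_fit`: `par` (estimates), `cost`,
#'   `starts` (log), plus the inputs needed by
#'   [confidence_intervals()].
#' @export
fit <- function(data, params, schedule, free, lower, upper,
                n_starts = 5, seed = 1, weighting = "variance") {
  stopifnot(length(free) >= 1, all(free %in% names(lower)),
            all(free %in% names(upper)),
            all(is.finite(unlist(lower[free]))),
            all(is.finite(unlist(upper[free]))))
  lo <- unlist(lower[free]); hi <- unlist(upper[free])
  set.seed(seed)
  starts <- replicate(n_starts, stats::runif(length(free), lo, hi))
  starts <- matrix(starts, nrow = length(free))
  rownames(starts) <- free
  log_rows <- list(); best <- NULL
  for (k in seq_len(n_starts)) {
    st <- setNames(starts[, k], free)
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lo, upper = hi,
                         fn = .residuals, params = params, data = data,
                         schedule = schedule, weighting = weighting,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(res)) {
      log_rows[[k]] <- data.frame(start = k, converged = FALSE,
                                  cost = NA_real_)
      next
    }
    cst <- sum(res$fvec^2)
    log_rows[[k]] <- data.frame(start = k, converged = TRUE, cost = cst)
    if (is.null(best) || cst < best$cost)
      best <- list(par = setNames(coef(res), free), cost = cst, fit = res)
  }
  if (is.null(best)) stop("all ", n_starts, " starts failed; see log")
  structure(list(par = best$par, cost = best$cost,
                 starts = do.call(rbind, log_rows),
                 data = data, params = params, schedule = schedule,
                 free = free, weighting = weighting, seed = seed),
            class = "t2d_fit")
}

#' @export
print.t2d_fit <- function(x, ...) {
  cat("<t2d_fit> J =", format(x$cost, digits = 6), "\n")
  print(round(x$par, 5))
  invisible(x)
}

#' Asymptotic confidence intervals
#'
#' The Fisher information is approximated by `F = J^T J` with `J` the
#' Jacobian of the weighted residuals at the optimum; `C = F^-1` and the
#' half-width of the interval for parameter i is
#' `t(1 - alpha/2, df) * sqrt(C[i, i])`, `df` = observations minus free
#' parameters. A singular `F` is pseudo-inverted and every parameter
#' with no sensitivity is flagged unidentifiable.
#'
#' @param fit a `t2d_fit`.
#' @param alpha significance level (0.05 for 95% intervals).
#' @return data frame: parameter, estimate, half_width, lower, upper,
#'   identifiable.
#' @export
confidence_intervals <- function(fit, alpha = 0.05) {
  J <- pracma::jacobian(function(th)
    .residuals(setNames(th, fit$free), fit$params, fit$data, fit$schedule,
               fit$weighting), unname(fit$par))
  Fi <- crossprod(J)
  unident <- apply(J, 2, function(cl) all(abs(cl) < 1e-12))
  Ci <- tryCatch(solve(Fi), error = function(e) NULL)
  if (is.null(Ci)) {
    warning("singular Fisher information; using pseudo-inverse",
            if (any(unident)) paste0(" (unidentifiable: ",
              paste(fit$free[unident], collapse = ", "), ")"))
    Ci <- MASS::ginv(Fi)
  }
  df <- nrow(fit$data) - length(fit$free)
  hw <- stats::qt(1 - alpha / 2, df) * sqrt(pmax(diag(Ci), 0))
  data.frame(parameter = fit$free, estimate = unname(fit$par),
             half_width = hw, lower = unname(fit$par) - hw,
             upper = unname(fit$par) + hw, identifiable = !unident)
}

#' Generate synthetic observations
#'
#' Simulates the model and samples the requested streams at the design
#' time points, adding independent Gaussian noise with the given SDs
#' (zero SD in `noise_sd` gives noiseless values while keeping the
#' stated measurement SD for weighting). Emulates sparse trial designs:
#' group means at baseline and a few follow-ups.
#'
#' @param params parameter set (the "truth").
#' @param schedule intake schedule.
#' @param design data frame with columns `stream`, `time`, `sd`, and
#'   optionally `noise_sd` (defaults to `sd`).
#' @param seed integer seed.
#' @return a [observation_set()].
#' @export
generate_synthetic <- function(params, schedule, design, seed = 1) {
  stopifnot(all(c("stream", "time", "sd") %in% names(design)))
  if (is.null(design$noise_sd)) design$noise_sd <- design$sd
  ok <- design$time <= schedule$horizon
  if (!all(ok)) stop("design time beyond schedule horizon")
  base <- observation_set(design$stream, design$time,
                          value = rep(0, nrow(design)), sd = design$sd)
  truth <- .predict_obs(base, params, schedule)
  set.seed(seed)
  base$value <- truth + stats::rnorm(nrow(base), 0, design$noise_sd)
  base
}

#' Sparse trial-like observation design
#'
#' Glucose, insulin, inflammation and BMI at baseline and at 5, 12 and
#' 24 months after an intervention at `t_int` — the measurement pattern
#' of a remission trial follow-up.
#'
#' @param t_int intervention time, months.
#' @param sds named SDs per stream.
#' @return design data frame for [generate_synthetic()].
#' @export
direct_design <- function(t_int = 60,
                          sds = c(G = 8, I = 1, theta = 0.03, BMI = 0.8)) {
  times <- c(0, t_int, t_int + 5, t_int + 12, t_int + 24)
  do.call(rbind, lapply(names(sds), function(sname)
    data.frame(stream = sname, time = times, sd = unname(sds[sname]))))
}

#' Seeded parameter-recovery study
#'
#' Repeatedly generates sparse trial-like synthetic data at the true
#' parameters with proportional Gaussian noise, refits the free
#' parameters from random multi-starts, and checks whether each true
#' value falls inside its asymptotic confidence interval. This is the
#' calibration module's self-validation oracle: bias, RMSE and CI
#' coverage over replicates.
#'
#' @param params true parameter set.
#' @param free free-parameter names (default inflammation half-max and
#'   beta-cell function scale).
#' @param noise_frac measurement SD as a fraction of the true value.
#' @param n_rep number of replicates.
#' @param n_starts multi-starts per replicate.
#' @param seed base seed; replicate r uses `seed + r` for its noise and
#'   `seed + 1000 + r` for its starts.
#' @param alpha CI significance level.
#' @return list with `results` (one row per replicate x parameter:
#'   estimate, half_width, covered), `coverage` (per parameter),
#'   `bias`, `rmse`.
#' @export
recovery_study <- function(params, free = c("K_theta", "sigma_b"),
                           noise_frac = 0.05, n_rep = 50, n_starts = 2,
                           seed = 1, alpha = 0.05) {
  sch <- intervention_schedule(c(0, 5, 60, 65), c(1, 1.4, 0.7, 1.25), 85)
  des <- direct_design(60)
  base <- observation_set(des$stream, des$time, rep(0, nrow(des)), des$sd)
  truth_pred <- .predict_obs(base, params, sch)
  des$sd <- pmax(noise_frac * abs(truth_pred), 1e-3)
  truth <- unlist(unclass(params)[free])
  lower <- as.list(truth * 0.7); upper <- as.list(truth * 1.3)
  rows <- list()
  for (r in seq_len(n_rep)) {
    dat <- generate_synthetic(params, sch, des, seed = seed + r)
    f <- tryCatch(
      fit(dat, params, sch, free = free, lower = lower, upper = upper,
          n_starts = n_starts, seed = seed + 1000 + r),
      error = function(e) NULL)
    if (is.null(f)) next
    ci <- confidence_intervals(f, alpha = alpha)
    rows[[r]] <- data.frame(rep = r, parameter = ci$parameter,
                            truth = unname(truth[ci$parameter]),
                            estimate = ci$estimate,
                            half_width = ci$half_width,
                            covered = ci$lower <= unname(truth[ci$parameter]) &
                                      unname(truth[ci$parameter]) <= ci$upper)
  }
  res <- do.call(rbind, rows)
  agg <- function(fn) vapply(split(res, res$parameter), fn, numeric(1))
  list(results = res,
       coverage = agg(function(d) mean(d$covered)),
       bias = agg(function(d) mean(d$estimate - d$truth)),
       rmse = agg(function(d) sqrt(mean((d$estimate - d$truth)^2))))
}
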