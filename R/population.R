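# Virtual-patient cohorts: parameter sampling, protocol randomization,
# individual classification, and group summaries.

#' Cohort sampling specification
#'
#' Defines which parameters vary across virtual individuals (independent
#' uniform perturbations about the nominal value), the intake-protocol
#' randomization, cohort size and seed. Two shipped presets:
#'
#' * `"fig6"`: intake raised at month 10 by U(150, 180)% of baseline,
#'   restored to baseline at month 80, horizon 120 months.
#' * `"fig9"`: intake raised at month 5 to U(125, 155)%, restricted to
#'   U(60, 80)% at month 60, reintroduced at U(110, 140)% from month 72
#'   (weight-management-trial protocol), horizon 85 months.
#'
#' @param preset `"fig6"` or `"fig9"`.
#' @param n cohort size.
#' @param seed integer seed; fully determines the cohort.
#' @param spread data frame with columns `name`, `lower`, `upper`
#'   (multiplicative bounds relative to nominal); default varies the
#'   inflammation, insulin-sensitivity, beta-cell and turnover parameters
#'   that differ across individuals.
#' @return object of class `t2d_sampling_spec`.
#' @export
sampling_spec <- function(preset = c("fig6", "fig9"), n = 200, seed = 1,
                          spread = default_spread()) {
  preset <- match.arg(preset)
  stopifnot(is.data.frame(spread),
            all(c("name", "lower", "upper") %in% names(spread)),
            all(spread$lower <= spread$upper), all(spread$lower > 0))
  bad <- setdiff(spread$name, .t2d_param_order)
  if (length(bad)) stop("unknown parameter(s) in spread: ",
                        paste(bad, collapse = ", "))
  structure(list(preset = preset, n = as.integer(n), seed = as.integer(seed),
                 spread = spread), class = "t2d_sampling_spec")
}

#' @rdname sampling_spec
#' @export
default_spread <- function() {
  data.frame(
    name  = c("K_theta", "S_i_b", "M_FFA", "tau_beta", "P_max", "A_max",
              "K_sf", "s_th_max", "tau_sigma", "F_Ra1"),
    lower = c(0.90, 0.88, 0.95, 0.80, 0.88, 0.88, 0.92, 0.85, 0.80, 0.85),
    upper = c(1.10, 1.12, 1.00, 1.20, 1.12, 1.12, 1.08, 1.15, 1.20, 1.15))
}

#' Sample a virtual cohort
#'
#' Draws parameter sets and intake schedules for every individual; the
#' seed fully determines the draw. Perturbing the baseline-balance
#' parameters is not allowed, so every sampled set remains admissible and
#' each individual starts from their own healthy baseline at BMI 25.
#'
#' For the `fig9` preset, sampling is centred on a diabetes-prone
#' variant of the nominal set (stronger inflammatory response,
#' `K_theta` scaled by 0.75) so that, as in the trial cohort it
#' emulates, virtually all individuals are diabetic at the intervention.
#'
#' @param spec a [sampling_spec()].
#' @param nominal nominal parameters (default [t2d_parameters()]).
#' @return list of individuals: each has `id`, `params`, `schedule`,
#'   and `intervention` (the time of the intake reduction, months).
#' @export
sample_cohort <- function(spec, nominal = t2d_parameters()) {
  set.seed(spec$seed)
  centre <- unclass(nominal)
  if (spec$preset == "fig9") centre$K_theta <- centre$K_theta * 0.75
  lapply(seq_len(spec$n), function(i) {
    p <- centre
    for (j in seq_len(nrow(spec$spread))) {
      nm <- spec$spread$name[j]
      p[[nm]] <- p[[nm]] * runif(1, spec$spread$lower[j], spec$spread$upper[j])
    }
    # each individual later starts from their own root-solved healthy baseline
    p <- validate_parameters(p)
    if (spec$preset == "fig6") {
      gain <- runif(1, 1.50, 1.80)
      sch <- intervention_schedule(c(0, 10, 80), c(1, gain, 1), horizon = 120)
      t_int <- 80
    } else {
      gain <- runif(1, 1.25, 1.55)
      restrict <- runif(1, 0.60, 0.80)
      reintro <- runif(1, 1.10, 1.40)
      sch <- intervention_schedule(c(0, 5, 60, 72),
                                   c(1, gain, restrict, reintro), horizon = 85)
      t_int <- 60
    }
    list(id = i, params = p, schedule = sch, intervention = t_int)
  })
}

#' Classify one simulated individual
#'
#' `non-diabetic` if glucose never exceeds the T2D cutoff (125 mg/dL);
#' `diabetic` if it enters the T2D range and remains there to the
#' horizon; `remission` if it enters the T2D range and falls back below
#' the cutoff after the intervention and stays below.
#'
#' @param traj a `t2d_trajectory`.
#' @param intervention intervention time, months.
#' @return character label.
#' @export
classify_individual <- function(traj, intervention) {
  if (max(traj$time) < intervention)
    stop("trajectory ends before the intervention at ", intervention, " months")
  G <- traj$state[, "G"]
  if (max(G) <= 125) return("non-diabetic")
  # entered the T2D range; remission iff it ends (and stays) below the cutoff
  if (G[length(G)] <= 125) "remission" else "diabetic"
}

#' Run a virtual cohort
#'
#' Simulates every sampled individual, classifies them, and extracts the
#' per-individual event log (T2D onset time in particular).
#'
#' @param cohort result of [sample_cohort()].
#' @param dt output step, months (coarser than single simulations; the
#'   classification only needs the glucose envelope).
#' @param progress print a dot every 25 individuals.
#' @return object of class `t2d_cohort`: list of individuals, each with
#'   added `trajectory`, `label`, `t2d_onset` (NA if never diabetic).
#' @export
run_cohort <- function(cohort, dt = 0.25, progress = FALSE) {
  out <- lapply(cohort, function(ind) {
    tr <- simulate(ind$params, ind$schedule, dt = dt,
                   rtol = 1e-7, atol = 1e-9)
    lab <- classify_individual(tr, ind$intervention)
    G <- tr$state[, "G"]
    onset <- NA_real_
    if (any(G > 125)) {
      i <- which(G[-length(G)] <= 125 & G[-1] > 125)[1]
      if (!is.na(i)) {
        gf <- stats::splinefun(tr$time, G, method = "natural")
        onset <- tryCatch(uniroot(function(x) gf(x) - 125,
                                  c(tr$time[i], tr$time[i + 1]),
                                  tol = 1e-3)$root,
                          error = function(e) tr$time[i + 1])
      }
    }
    if (progress && ind$id %% 25 == 0) cat(".")
    c(ind, list(trajectory = tr, label = lab, t2d_onset = onset))
  })
  if (progress) cat("\n")
  structure(out, class = "t2d_cohort")
}

#' @export
print.t2d_cohort <- function(x, ...) {
  tab <- table(vapply(x, `[[`, character(1), "label"))
  cat("<t2d_cohort> n = ", length(x), ": ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Group summaries and tests for a cohort
#'
#' Mean, SD and n per group and model variable at the requested times;
#' T2D-duration statistics (intervention time minus onset time); paired
#' t-tests within groups across time and Welch t-tests between groups at
#' each time.
#'
#' @param cohort a `t2d_cohort`.
#' @param times time points, months; default baseline, intervention and
#'   horizon.
#' @param variables state/observable columns to summarize.
#' @return list with `stats` (long data frame: group, variable, time,
#'   mean, sd, n), `duration` (per-group T2D duration mean/sd/n),
#'   `tests` (data frame of t-test results).
#' @export
summarize_cohort <- function(cohort, times = NULL,
                             variables = c("G", "I", "FFA", "S_i", "beta",
                                           "sigma", "theta", "BMI")) {
  labels <- vapply(cohort, `[[`, character(1), "label")
  t_int <- cohort[[1]]$intervention
  horizon <- cohort[[1]]$schedule$horizon
  if (is.null(times)) times <- c(0, t_int, horizon)

  value_at <- function(ind, var, tt) {
    tr <- ind$trajectory
    if (var == "BMI") .traj_interp(tr, "BMI", tt) else .traj_interp(tr, var, tt)
  }
  grid <- expand.grid(group = unique(labels), variable = variables,
                      time = times, stringsAsFactors = FALSE)
  vals <- lapply(seq_len(nrow(grid)), function(k) {
    idx <- which(labels == grid$group[k])
    v <- vapply(cohort[idx], value_at, numeric(1), grid$variable[k], grid$time[k])
    data.frame(grid[k, ], mean = mean(v), sd = stats::sd(v), n = length(v))
  })
  stats_df <- do.call(rbind, vals)

  onsets <- vapply(cohort, function(ind)
    if (is.na(ind$t2d_onset)) NA_real_ else ind$intervention - ind$t2d_onset,
    numeric(1))
  dur <- do.call(rbind, lapply(unique(labels), function(g) {
    d <- onsets[labels == g & !is.na(onsets) & onsets > 0]
    data.frame(group = g, mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) > 1) stats::sd(d) else NA_real_,
               n = length(d))
  }))

  tests <- .cohort_tests(cohort, labels, variables, times)
  list(stats = stats_df, duration = dur, tests = tests,
       labels = labels)
}

.cohort_tests <- function(cohort, labels, variables, times) {
  value_at <- function(ind, var, tt) .traj_interp(ind$trajectory, var, tt)
  rows <- list()
  groups <- unique(labels)
  for (v in variables) {
    # between groups at each time (Welch; unequal group sizes)
    for (tt in times) {
      if (length(groups) >= 2) {
        for (a in seq_along(groups)) for (b in seq_along(groups)) {
          if (a >= b) next
          xa <- vapply(cohort[labels == groups[a]], value_at, numeric(1), v, tt)
          xb <- vapply(cohort[labels == groups[b]], value_at, numeric(1), v, tt)
          if (length(xa) > 1 && length(xb) > 1 &&
              (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
            ht <- stats::t.test(xa, xb)
            rows[[length(rows) + 1L]] <- data.frame(
              comparison = "between-groups", variable = v, time = tt,
              group1 = groups[a], group2 = groups[b],
              statistic = unname(ht$statistic), p = ht$p.value)
          }
        }
      }
    }
    # within group across the last two times (paired)
    if (length(times) >= 2) {
      t1 <- times[length(times) - 1]; t2 <- times[length(times)]
      for (g in groups) {
        x1 <- vapply(cohort[labels == g], value_at, numeric(1), v, t1)
        x2 <- vapply(cohort[labels == g], value_at, numeric(1), v, t2)
        if (length(x1) > 1 && stats::sd(x2 - x1) > 0) {
          ht <- stats::t.test(x1, x2, paired = TRUE)
          rows[[length(rows) + 1L]] <- data.frame(
            comparison = "within-group", variable = v, time = t2,
            group1 = g, group2 = g,
            statistic = unname(ht$statistic), p = ht$p.value)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(comparison = character(), variable = character(),
               time = numeric(), group1 = character(), group2 = character(),
               statistic = numeric(), p = numeric())
}
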