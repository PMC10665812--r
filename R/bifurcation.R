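# Equilibria of the BMI-clamped subsystem, branch continuation, saddle-node
# detection, separatrix threshold, and the remission-restriction map.

# right-hand side of the 7 non-weight equations with W clamped
.clamped_rhs <- function(x7, p, W) {
  st <- c(W, x7)
  names(st) <- .t2d_state_order
  unname(rhs(0, st, p, schedule = 1))[-1]   # DE level irrelevant once W clamped
}

# deterministic multi-start lattice scaled by baseline magnitudes
.eq_starts <- function() {
  grid <- expand.grid(G = c(70, 90, 120, 170, 240, 320),
                      beta = c(30, 100, 300, 600, 1000, 1500))
  lapply(seq_len(nrow(grid)), function(i)
    c(G = grid$G[i], I = pmax(grid$beta[i] / 100, 0.5), FFA = 450,
      beta = grid$beta[i]))
}

#' Equilibria of the BMI-clamped subsystem
#'
#' Clamps body weight at `W = BMI * h^2`, removing the weight equation,
#' and root-solves the remaining seven equations from a fixed lattice of
#' starting points. Solutions are deduplicated and classified as stable
#' or unstable from the eigenvalues of a finite-difference Jacobian;
#' eigenvalues within `marginal_tol` of zero flag the point "marginal".
#'
#' @param BMI clamp value, kg/m2.
#' @param params a `t2d_parameters` object.
#' @param tol residual norm required of a root (scaled units).
#' @param marginal_tol half-width of the eigenvalue band treated as
#'   numerically marginal near folds.
#' @return data frame, one row per equilibrium, ordered by decreasing
#'   beta: BMI, the 7 states, `stable`, `marginal`, `eig` (leading real
#'   part), `resid`.
#' @export
#' @examples
#' eq <- equilibria_at_bmi(35, t2d_parameters())
#' nrow(eq)   # three equilibria in the bistable interval
equilibria_at_bmi <- function(BMI, params, tol = 1e-9, marginal_tol = 1e-6) {
  p <- params
  W <- BMI * p$h^2
  roots <- list()
  for (st in .eq_starts()) {
    eq <- .solve_equilibrium(p, W, start = st)
    if (is.null(eq) || eq$resid > tol) next
    key <- c(eq$state[["G"]], eq$state[["beta"]])
    dup <- any(vapply(roots, function(r)
      all(abs(c(r$state[["G"]], r$state[["beta"]]) - key) /
            pmax(abs(key), 1) < 1e-4), logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- eq
  }
  if (!length(roots)) {
    warning("no equilibrium found at BMI = ", BMI)
    return(.eq_frame(NULL))
  }
  rows <- lapply(roots, function(eq) {
    x7 <- unname(eq$state[-1])
    J <- pracma::jacobian(function(z) .clamped_rhs(z, p, W), x7)
    ev <- max(Re(eigen(J, only.values = TRUE)$values))
    data.frame(BMI = BMI, t(eq$state[-1]), stable = ev < 0,
               marginal = abs(ev) < marginal_tol, eig = ev, resid = eq$resid)
  })
  out <- do.call(rbind, rows)
  out[order(-out$beta), , drop = FALSE]
}

.eq_frame <- function(x) {
  if (is.null(x))
    return(data.frame(BMI = numeric(), G = numeric(), I = numeric(),
                      FFA = numeric(), theta = numeric(), S_i = numeric(),
                      beta = numeric(), sigma = numeric(), stable = logical(),
                      marginal = logical(), eig = numeric(), resid = numeric()))
  x
}

#' Continue equilibrium branches over BMI
#'
#' Scans the BMI range on an adaptive grid (refined near fold points by
#' bisection on branch existence, to `fold_tol` in BMI), labelling each
#' equilibrium as upper-stable, unstable, or lower-stable by stability
#' and beta ordering.
#'
#' @param params a `t2d_parameters` object.
#' @param bmi_range range of the continuation, kg/m2.
#' @param step base grid step, kg/m2.
#' @param fold_tol localization tolerance for saddle-node points, kg/m2.
#' @return object of class `t2d_bifurcation`: list with `branches` (data
#'   frame with a `branch` label column) and `folds` (data frame of
#'   saddle-node (BMI, beta) points).
#' @export
continue_branches <- function(params, bmi_range = c(20, 50), step = 0.25,
                              fold_tol = 0.05) {
  bmis <- seq(bmi_range[1], bmi_range[2], by = step)
  eqs <- lapply(bmis, function(b)
    suppressWarnings(equilibria_at_bmi(b, params)))
  counts <- vapply(eqs, nrow, integer(1))
  pts <- do.call(rbind, eqs)

  # refine every interval over which the number of equilibria changes
  folds <- NULL
  for (i in seq_len(length(bmis) - 1)) {
    if (counts[i] == counts[i + 1]) next
    lo <- bmis[i]; hi <- bmis[i + 1]
    n_lo <- counts[i]
    while (hi - lo > fold_tol) {
      mid <- (lo + hi) / 2
      eq_mid <- suppressWarnings(equilibria_at_bmi(mid, params))
      pts <- rbind(pts, eq_mid)
      if (nrow(eq_mid) == n_lo) lo <- mid else hi <- mid
    }
    eq_lo <- suppressWarnings(equilibria_at_bmi(lo, params))
    # the colliding pair is the upper-stable/unstable pair; record their mean
    if (nrow(eq_lo) >= 2) {
      two <- eq_lo[order(-eq_lo$beta), ][1:2, ]
      folds <- rbind(folds, data.frame(BMI = (lo + hi) / 2,
                                       beta = mean(two$beta)))
    }
  }
  pts <- pts[order(pts$BMI, -pts$beta), ]
  pts$branch <- .label_branches(pts)
  structure(list(branches = pts, folds = folds,
                 params = params, bmi_range = bmi_range),
            class = "t2d_bifurcation")
}

.label_branches <- function(pts) {
  lab <- character(nrow(pts))
  for (b in unique(pts$BMI)) {
    i <- which(pts$BMI == b)
    sub <- pts[i, ]
    l <- character(length(i))
    stable <- sub$stable & !sub$marginal
    unst <- which(!stable)
    stb <- which(stable)
    if (length(stb)) {
      l[stb[which.max(sub$beta[stb])]] <- "upper-stable"
      if (length(stb) > 1) l[stb[which.min(sub$beta[stb])]] <- "lower-stable"
    }
    if (length(unst)) l[unst] <- "unstable"
    # a single stable point is upper or lower depending on beta magnitude
    if (length(i) == 1 && stable[1])
      l[1] <- if (sub$beta[1] > 500) "upper-stable" else "lower-stable"
    lab[i] <- l
  }
  lab
}

#' @export
print.t2d_bifurcation <- function(x, ...) {
  cat("<t2d_bifurcation> ", nrow(x$branches), " equilibria over BMI [",
      x$bmi_range[1], ", ", x$bmi_range[2], "]; ",
      if (is.null(x$folds)) 0 else nrow(x$folds), " fold(s)", sep = "")
  if (!is.null(x$folds))
    cat(" at BMI ", paste(round(x$folds$BMI, 2), collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}

#' Separatrix threshold curve
#'
#' Extracts the unstable-branch beta-cell mass as a monotone-interpolated
#' function of BMI. Inside the bistable interval the curve separates the
#' basins of the healthy (high-beta) and diabetic (low-beta) attractors.
#'
#' @param diagram a `t2d_bifurcation` object.
#' @return object of class `t2d_threshold`: callable data with fields
#'   `fun(BMI)`, `range`, and the supporting points.
#' @export
threshold_curve <- function(diagram) {
  un <- diagram$branches[diagram$branches$branch == "unstable", ]
  if (!nrow(un)) stop("diagram contains no unstable branch")
  un <- un[order(un$BMI), ]
  un <- un[!duplicated(un$BMI), ]
  fn <- stats::splinefun(un$BMI, un$beta, method = "monoH.FC")
  structure(list(fun = fn, range = range(un$BMI),
                 BMI = un$BMI, beta = un$beta),
            class = "t2d_threshold")
}

#' @rdname threshold_curve
#' @param threshold a `t2d_threshold`.
#' @param BMI evaluation points; values outside the bistable interval are
#'   clamped to its ends (the curve is extended constantly).
#' @export
threshold_eval <- function(threshold, BMI) {
  threshold$fun(pmin(pmax(BMI, threshold$range[1]), threshold$range[2]))
}

#' Classify the attractor reached from an initial state
#'
#' Simulates under constant intake and labels the outcome by comparing
#' terminal beta-cell mass against the separatrix threshold at terminal
#' BMI. A terminal point within `band` (relative) of the threshold is
#' reported "undetermined" rather than guessed.
#'
#' @param initial initial state vector.
#' @param DE_frac constant intake, fraction of baseline.
#' @param params a `t2d_parameters` object.
#' @param threshold a `t2d_threshold` (see [threshold_curve()]).
#' @param horizon months simulated (beta is the slowest variable; decades
#'   are required).
#' @param band relative half-width of the undetermined band.
#' @param dt output step, months.
#' @return `"high-beta"`, `"low-beta"`, or `"undetermined"`.
#' @export
classify_attractor <- function(initial, DE_frac, params, threshold,
                               horizon = 600, band = 0.02, dt = 1) {
  sch <- intervention_schedule(0, DE_frac, horizon)
  tr <- simulate(params, sch, initial = initial, dt = dt,
                 rtol = 1e-7, atol = 1e-9)
  n <- length(tr$time)
  beta_T <- tr$state[n, "beta"]
  bmi_T <- tr$obs$BMI[n]
  thr <- threshold_eval(threshold, bmi_T)
  if (bmi_T > threshold$range[2] + 0.5) return("low-beta")
  if (abs(beta_T - thr) < band * thr) return("undetermined")
  if (beta_T > thr) "high-beta" else "low-beta"
}

# quasi-steady reconstruction of the fast subsystem at clamped (BMI, beta):
# theta, S_i, sigma at asymptotic values; (G, I, FFA) root-solved
.quasi_steady_state <- function(params, BMI, beta) {
  p <- params
  W <- BMI * p$h^2
  theta <- .hill(BMI, p$K_theta, p$n_theta)
  resid_fn <- function(z) {
    z <- exp(z)
    G <- z[1]; I <- z[2]; FFA <- z[3]
    S_i <- p$S_i_b * (1 - p$M_FFA * .hill(FFA, p$K_Si_FFA, p$n_Si)) *
      (1 - .hill(theta, p$K_Si_theta, p$n_theta))
    sigma <- max(0, p$sigma_b * (p$s_gu_max * .hill(G, p$K_gu, p$n_gu) -
      .hill(G, p$K_gd, p$n_gd) * p$s_ffa_max * .hill(FFA, p$K_sf, p$n_sf) -
      p$s_th_max * .hill(theta, p$K_st, p$n_st)))
    act <- S_i * I
    HGP <- p$HGP_b + p$HGP_max * p$alpha_HGP / (p$alpha_HGP + act)
    M <- .hill(G, p$alpha_M, p$K_M)
    ISR <- sigma * .hill(M, p$alpha_ISR, p$K_ISR)
    Ra <- (p$F_Ra0 + p$F_Ra1 * (p$FMR_a * BMI + p$FMR_b) * W) /
      (1 + (act / p$K_siF)^p$alpha_SiF)
    c((HGP - (p$E_G0 + act) * G) / 1000,
      (beta * ISR / p$V - p$k_I * I) / 100,
      (Ra - p$c_f * W * FFA) / 1000)
  }
  best <- NULL
  for (st in list(c(90, 10, 400), c(180, 5, 600), c(130, 20, 500))) {
    sol <- .newton_solve(resid_fn, log(st), maxit = 200)
    if (is.null(sol)) next
    if (sol$resid < 1e-9) { best <- list(z = exp(sol$x), r = sol$resid); break }
    if (is.null(best) || sol$resid < best$r)
      best <- list(z = exp(sol$x), r = sol$resid)
  }
  if (is.null(best) || best$r > 1e-7)
    stop("quasi-steady reconstruction failed at BMI = ", BMI,
         ", beta = ", beta)
  G <- best$z[1]; I <- best$z[2]; FFA <- best$z[3]
  S_i <- p$S_i_b * (1 - p$M_FFA * .hill(FFA, p$K_Si_FFA, p$n_Si)) *
    (1 - .hill(theta, p$K_Si_theta, p$n_theta))
  sigma <- max(0, p$sigma_b * (p$s_gu_max * .hill(G, p$K_gu, p$n_gu) -
    .hill(G, p$K_gd, p$n_gd) * p$s_ffa_max * .hill(FFA, p$K_sf, p$n_sf) -
    p$s_th_max * .hill(theta, p$K_st, p$n_st)))
  st <- c(W, G, I, FFA, theta, S_i, beta, sigma)
  names(st) <- .t2d_state_order
  st
}

#' Remission-restriction map
#'
#' For each cell of a (BMI, beta-cell mass) grid, reconstructs the full
#' state by quasi-steady conditioning of the fast variables on the
#' clamped pair, then bisects over constant daily energy intake for the
#' largest level (fraction of baseline) from which the trajectory still
#' converges to the healthy high-beta attractor. Cells that converge
#' even at the upper search bound are coded `"NR"` (no restriction
#' needed); cells that fail even at baseline intake are coded `"F"`.
#'
#' @param params a `t2d_parameters` object.
#' @param bmi,beta grid coordinates.
#' @param de_range search bounds for the intake fraction
#'   (`c(baseline, max)`). The default upper bound 1.55 is close to the
#'   largest constant intake whose steady-state BMI stays inside the
#'   bistable interval; above it every cell eventually loses the healthy
#'   attractor.
#' @param precision bisection precision, fraction of baseline intake.
#' @param diagram optional precomputed [continue_branches()] result.
#' @param horizon classification horizon, months.
#' @return object of class `t2d_remission_map`: list with `grid` (data
#'   frame BMI, beta, max_de (percent of baseline; NA for sentinels),
#'   code in `{"value", "NR", "F", "undetermined"}`) and the threshold
#'   used.
#' @export
remission_map <- function(params, bmi = seq(26, 44, by = 2),
                          beta = seq(200, 900, by = 100),
                          de_range = c(1, 1.55), precision = 0.01,
                          diagram = NULL, horizon = 600) {
  if (is.null(diagram)) diagram <- continue_branches(params)
  thr <- threshold_curve(diagram)
  cls <- function(state, f) classify_attractor(state, f, params, thr,
                                               horizon = horizon, dt = 2)
  rows <- lapply(seq_along(bmi), function(i) {
    do.call(rbind, lapply(seq_along(beta), function(j) {
      st <- .quasi_steady_state(params, bmi[i], beta[j])
      at_base <- cls(st, de_range[1])
      if (at_base == "undetermined")
        return(data.frame(BMI = bmi[i], beta = beta[j], max_de = NA_real_,
                          code = "undetermined"))
      if (at_base == "low-beta")
        return(data.frame(BMI = bmi[i], beta = beta[j], max_de = NA_real_,
                          code = "F"))
      at_top <- cls(st, de_range[2])
      if (at_top == "high-beta")
        return(data.frame(BMI = bmi[i], beta = beta[j], max_de = NA_real_,
                          code = "NR"))
      lo <- de_range[1]; hi <- de_range[2]
      while (hi - lo > precision) {
        mid <- (lo + hi) / 2
        lab <- cls(st, mid)
        if (lab == "high-beta") lo <- mid else hi <- mid
      }
      data.frame(BMI = bmi[i], beta = beta[j], max_de = 100 * lo,
                 code = "value")
    }))
  })
  structure(list(grid = do.call(rbind, rows), threshold = thr,
                 de_range = de_range, params = params),
            class = "t2d_remission_map")
}

#' @export
print.t2d_remission_map <- function(x, ...) {
  tab <- table(x$grid$code)
  cat("<t2d_remission_map> ", nrow(x$grid), " cells: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}
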