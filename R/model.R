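# Model equations: algebraic observables, right-hand side, metabolic-state
# classification, disease progression index, baseline equilibrium.

.t2d_state_order <- c("W", "G", "I", "FFA", "theta", "S_i", "beta", "sigma")

#' Construct a model state vector
#'
#' State ordering is fixed as W (kg), G (mg/dL), I (microU/mL),
#' FFA (micromol/L), theta (unitless, 0-1), S_i, beta (mg), sigma
#' (unitless secretory-capacity multiplier).
#'
#' @param W,G,I,FFA,theta,S_i,beta,sigma state components.
#' @return named numeric vector of length 8.
#' @export
t2d_state <- function(W, G, I, FFA, theta, S_i, beta, sigma) {
  x <- c(W = W, G = G, I = I, FFA = FFA, theta = theta,
         S_i = S_i, beta = beta, sigma = sigma)
  validate_state(x)
}

#' @rdname t2d_state
#' @param x a numeric state vector.
#' @export
validate_state <- function(x) {
  if (length(x) != 8L) stop("state must have 8 components")
  names(x) <- .t2d_state_order
  bad <- names(x)[!is.finite(x)]
  if (length(bad)) stop("non-finite state component(s): ", paste(bad, collapse = ", "))
  # clamp numerically tiny negatives from the integrator; reject real ones
  tiny <- x < 0 & x > -1e-4 * .t2d_state_scale
  x[tiny] <- 0
  neg <- names(x)[x < 0]
  if (length(neg)) stop("negative state component(s): ", paste(neg, collapse = ", "))
  if (x[["theta"]] > 1 + 1e-9) stop("state component 'theta' must not exceed 1")
  x
}

.hill <- function(x, K, n) {
  xn <- x^n
  xn / (xn + K^n)
}

#' Algebraic observables of the model
#'
#' Computes every algebraic quantity of the model at a given state:
#' BMI, fat-mass ratio and fat mass, hepatic glucose production, beta-cell
#' metabolic rate M and insulin secretion rate ISR, FFA appearance and
#' disappearance rates, asymptotic targets of the relaxation equations
#' (theta_inf, S_i_inf, sigma_inf with its four components), beta-cell
#' replication and apoptosis rates, and the disease progression index.
#'
#' @param state numeric state vector (see [t2d_state()]).
#' @param params a `t2d_parameters` object.
#' @param DE_frac active daily energy intake as a fraction of baseline.
#' @return named list of observables.
#' @export
#' @examples
#' p <- t2d_parameters()
#' ob <- observables(baseline_state(p), p)
#' ob$BMI; ob$DPI
observables <- function(state, params, DE_frac = 1) {
  x <- validate_state(state)
  p <- params
  W <- x[["W"]]; G <- x[["G"]]; I <- x[["I"]]; FFA <- x[["FFA"]]
  theta <- x[["theta"]]; S_i <- x[["S_i"]]; beta <- x[["beta"]]; sigma <- x[["sigma"]]

  BMI <- W / p$h^2
  FMR <- p$FMR_a * BMI + p$FMR_b
  FM  <- FMR * W
  act <- S_i * I                         # insulin action
  HGP <- p$HGP_b + p$HGP_max * p$alpha_HGP / (p$alpha_HGP + act)
  M   <- .hill(G, p$alpha_M, p$K_M)
  ISR <- sigma * .hill(M, p$alpha_ISR, p$K_ISR)
  FFA_Ra_max <- p$F_Ra0 + p$F_Ra1 * FM
  FFA_Ra <- FFA_Ra_max / (1 + (act / p$K_siF)^p$alpha_SiF)
  FFA_Rd <- p$c_f * W * FFA
  theta_inf <- .hill(BMI, p$K_theta, p$n_theta)
  S_i_inf <- p$S_i_b * (1 - p$M_FFA * .hill(FFA, p$K_Si_FFA, p$n_Si)) *
    (1 - .hill(theta, p$K_Si_theta, p$n_theta))
  P <- p$P_max * .hill(ISR, p$alpha_P, p$n_P)
  A <- p$A_b + p$A_max * .hill(M, p$alpha_A, p$n_A)
  sigma_gu  <- p$s_gu_max * .hill(G, p$K_gu, p$n_gu)
  sigma_gd  <- .hill(G, p$K_gd, p$n_gd)
  sigma_FFA <- p$s_ffa_max * .hill(FFA, p$K_sf, p$n_sf)
  sigma_th  <- p$s_th_max * .hill(theta, p$K_st, p$n_st)
  sigma_inf <- max(0, p$sigma_b * (sigma_gu - sigma_gd * sigma_FFA - sigma_th))

  list(BMI = BMI, FMR = FMR, FM = FM, HGP = HGP, HEPA_si = S_i,
       M = M, ISR = ISR, FFA_Ra = FFA_Ra, FFA_Rd = FFA_Rd,
       FFA_Ra_max = FFA_Ra_max, theta_inf = theta_inf, S_i_inf = S_i_inf,
       sigma_inf = sigma_inf, sigma_gu = sigma_gu, sigma_gd = sigma_gd,
       sigma_FFA = sigma_FFA, sigma_theta = sigma_th, P = P, A = A,
       DE_i = DE_frac * p$DE_i_b,
       DPI = dpi(S_i, sigma, beta, p))
}

#' Disease progression index
#'
#' `DPI = 1 - (S_i * sigma * beta) / (S_i_0 * sigma_0 * beta_0)`: zero at
#' the healthy baseline, increasing as insulin sensitivity, beta-cell
#' function or beta-cell mass decline below baseline.
#'
#' @param S_i,sigma,beta current values.
#' @param params a `t2d_parameters` object (supplies the baseline refs).
#' @return numeric scalar.
#' @export
dpi <- function(S_i, sigma, beta, params) {
  1 - (S_i * sigma * beta) / (params$S_i_0 * params$sigma_0 * params$beta_0)
}

#' Model right-hand side
#'
#' Time derivative of the eight state variables, in months. The daily
#' energy intake active at `t` is looked up in `schedule`; every
#' relaxation equation has the form `(x_inf - x) / tau`.
#'
#' This is the reference (pure R) implementation; [simulate()] uses an
#' equivalent compiled version by default.
#'
#' @param t time in months.
#' @param state numeric state vector.
#' @param params a `t2d_parameters` object.
#' @param schedule an [intervention_schedule()]; alternatively a single
#'   numeric intake fraction for autonomous use.
#' @return named numeric vector of derivatives.
#' @export
rhs <- function(t, state, params, schedule = 1) {
  DE_frac <- if (is.numeric(schedule) && is.null(attr(schedule, "class")))
    schedule[[1]] else schedule_level(schedule, t)
  x <- state; names(x) <- .t2d_state_order
  p <- params
  ob <- observables(x, p, DE_frac)
  dW <- p$k_w * DE_frac * p$DE_i_b - p$DE_e * x[["W"]]
  dG <- ob$HGP - (p$E_G0 + x[["S_i"]] * x[["I"]]) * x[["G"]]
  dI <- x[["beta"]] * ob$ISR / p$V - p$k_I * x[["I"]]
  dFFA <- ob$FFA_Ra - ob$FFA_Rd
  dtheta <- (ob$theta_inf - x[["theta"]]) / p$tau_theta
  dS_i <- (ob$S_i_inf - x[["S_i"]]) / p$tau_Si
  dbeta <- (p$P_ng + (ob$P - ob$A) * x[["beta"]] - p$s * x[["beta"]]^2) / p$tau_beta
  dsigma <- (ob$sigma_inf - x[["sigma"]]) / p$tau_sigma
  c(W = unname(dW), G = unname(dG), I = unname(dI), FFA = unname(dFFA),
    theta = unname(dtheta), S_i = unname(dS_i), beta = unname(dbeta),
    sigma = unname(dsigma))
}

#' Glycemic state classification
#'
#' Fasting plasma glucose below 100 mg/dL is healthy, 100-125 mg/dL
#' (inclusive at both ends) is prediabetes, above 125 mg/dL is T2D.
#'
#' @param G fasting plasma glucose, mg/dL (vectorized).
#' @return character vector in `{"healthy", "prediabetes", "T2D"}`.
#' @export
#' @examples
#' classify_glycemic(c(95, 110, 130))
classify_glycemic <- function(G) {
  stopifnot(all(G >= 0))
  ifelse(G < 100, "healthy", ifelse(G <= 125, "prediabetes", "T2D"))
}

#' BMI classification
#'
#' BMI below 25 kg/m2 is normal, 25-30 (inclusive) overweight, above 30
#' obese.
#'
#' @param BMI body mass index, kg/m2 (vectorized).
#' @return character vector in `{"normal", "overweight", "obese"}`.
#' @export
classify_bmi <- function(BMI) {
  stopifnot(all(BMI > 0))
  ifelse(BMI < 25, "normal", ifelse(BMI <= 30, "overweight", "obese"))
}

#' Baseline (healthy) equilibrium
#'
#' Root-solves the full system at baseline intake for the metabolically
#' healthy equilibrium: BMI 25 kg/m2 exactly (by the energy-balance
#' invariant), fasting glucose below 100 mg/dL, DPI approximately 0.
#'
#' @param params a `t2d_parameters` object.
#' @param tol residual tolerance (scaled units).
#' @return a state vector (see [t2d_state()]).
#' @export
baseline_state <- function(params, tol = 1e-8) {
  p <- params
  W_b <- 25 * p$h^2
  eq <- .solve_equilibrium(p, W = W_b,
                           start = c(G = 90, I = 10, FFA = 400, beta = 1000))
  if (is.null(eq) || eq$resid > tol)
    stop("baseline equilibrium root-solve did not converge (residual ",
         if (is.null(eq)) "NA" else format(eq$resid, digits = 3), ")")
  eq$state
}

# Solve the clamped-W equilibrium of the 7 remaining equations by reducing
# to the 4 unknowns (G, I, FFA, beta); theta, S_i, sigma sit at their
# asymptotic values. Returns state + scaled residual, or NULL.
.solve_equilibrium <- function(p, W, start, maxit = 200) {
  BMI <- W / p$h^2
  theta <- .hill(BMI, p$K_theta, p$n_theta)
  resid_fn <- function(z) {
    z <- exp(z)    # positivity via log transform
    G <- z[1]; I <- z[2]; FFA <- z[3]; beta <- z[4]
    S_i <- p$S_i_b * (1 - p$M_FFA * .hill(FFA, p$K_Si_FFA, p$n_Si)) *
      (1 - .hill(theta, p$K_Si_theta, p$n_theta))
    sigma_gu  <- p$s_gu_max * .hill(G, p$K_gu, p$n_gu)
    sigma_gd  <- .hill(G, p$K_gd, p$n_gd)
    sigma_FFA <- p$s_ffa_max * .hill(FFA, p$K_sf, p$n_sf)
    sigma_th  <- p$s_th_max * .hill(theta, p$K_st, p$n_st)
    sigma <- max(0, p$sigma_b * (sigma_gu - sigma_gd * sigma_FFA - sigma_th))
    act <- S_i * I
    HGP <- p$HGP_b + p$HGP_max * p$alpha_HGP / (p$alpha_HGP + act)
    M <- .hill(G, p$alpha_M, p$K_M)
    ISR <- sigma * .hill(M, p$alpha_ISR, p$K_ISR)
    P <- p$P_max * .hill(ISR, p$alpha_P, p$n_P)
    A <- p$A_b + p$A_max * .hill(M, p$alpha_A, p$n_A)
    Ra <- (p$F_Ra0 + p$F_Ra1 * (p$FMR_a * BMI + p$FMR_b) * W) /
      (1 + (act / p$K_siF)^p$alpha_SiF)
    c((HGP - (p$E_G0 + act) * G) / 1000,
      (beta * ISR / p$V - p$k_I * I) / 100,
      (Ra - p$c_f * W * FFA) / 1000,
      (p$P_ng + (P - A) * beta - p$s * beta^2) / 10)
  }
  sol <- .newton_solve(resid_fn, log(start), maxit = maxit)
  if (is.null(sol)) return(NULL)
  z <- exp(sol$x)
  resid <- sol$resid
  G <- z[[1]]; FFA <- z[[3]]
  S_i <- p$S_i_b * (1 - p$M_FFA * .hill(FFA, p$K_Si_FFA, p$n_Si)) *
    (1 - .hill(theta, p$K_Si_theta, p$n_theta))
  sigma <- max(0, p$sigma_b * (p$s_gu_max * .hill(G, p$K_gu, p$n_gu) -
    .hill(G, p$K_gd, p$n_gd) * p$s_ffa_max * .hill(FFA, p$K_sf, p$n_sf) -
    p$s_th_max * .hill(theta, p$K_st, p$n_st)))
  st <- c(W = W, G = G, I = z[[2]], FFA = FFA, theta = theta,
          S_i = S_i, beta = z[[4]], sigma = sigma)
  names(st) <- .t2d_state_order
  list(state = st, resid = resid)
}


# damped Newton with finite-difference Jacobian; returns NULL on failure.
# Solvers above work in log coordinates so positivity is automatic.
.newton_solve <- function(fn, x0, maxit = 100, tol = 1e-12) {
  x <- x0
  r <- fn(x)
  nr <- sqrt(sum(r^2))
  if (!is.finite(nr)) return(NULL)
  for (it in seq_len(maxit)) {
    if (nr < tol) break
    J <- tryCatch(pracma::jacobian(fn, x), error = function(e) NULL)
    if (is.null(J) || any(!is.finite(J))) return(NULL)
    dx <- tryCatch(solve(J, -r), error = function(e)
      tryCatch(-MASS::ginv(J) %*% r, error = function(e2) NULL))
    if (is.null(dx) || any(!is.finite(dx))) return(NULL)
    dx <- as.numeric(dx)
    lam <- 1
    improved <- FALSE
    for (h in 1:10) {
      xn <- x + lam * dx
      rn <- fn(xn)
      nn <- sqrt(sum(rn^2))
      if (is.finite(nn) && nn < nr) {
        x <- xn; r <- rn; nr <- nn; improved <- TRUE; break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  if (nr > 1e-6) return(NULL)
  list(x = x, resid = nr)
}
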