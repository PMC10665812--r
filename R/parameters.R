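# Parameter container, validation, and flat-file (YAML) round-trip.

# Fixed field order; the compiled right-hand side indexes into this order,
# with the active intake fraction appended as the last slot.
.t2d_param_order <- c(
  "k_w", "DE_i_b", "DE_e", "h",
  "E_G0", "HGP_b", "HGP_max", "alpha_HGP",
  "k_I", "V", "alpha_ISR", "K_ISR", "alpha_M", "K_M",
  "K_siF", "alpha_SiF", "c_f", "F_Ra0", "F_Ra1", "FMR_a", "FMR_b",
  "tau_theta", "n_theta", "K_theta",
  "tau_Si", "S_i_b", "M_FFA", "n_Si", "K_Si_FFA", "K_Si_theta",
  "P_ng", "P_max", "n_P", "alpha_P", "A_b", "A_max", "n_A", "alpha_A",
  "s", "tau_beta",
  "tau_sigma", "sigma_b",
  "s_gu_max", "K_gu", "n_gu", "K_gd", "n_gd",
  "s_ffa_max", "K_sf", "n_sf", "s_th_max", "K_st", "n_st",
  "S_i_0", "sigma_0", "beta_0"
)

# fields that must be strictly positive (rates, time constants, Hill
# exponents, half-max constants, volumes, baselines)
.t2d_param_positive <- setdiff(.t2d_param_order, "FMR_b")

#' Nominal model parameters
#'
#' Returns the packaged nominal parameter set, optionally with overrides.
#' Time unit is months throughout; glucose is mg/dL, insulin microU/mL,
#' free fatty acids micromol/L, body weight kg, beta-cell mass mg. Daily
#' energy intake `DE_i_b` is in kcal/day and the weight-gain coefficient
#' `k_w` carries the day-to-month conversion, so `k_w * DE_i` is kg/month.
#'
#' The set satisfies the baseline energy balance
#' `k_w * DE_i_b = DE_e * 25 * h^2`, which makes BMI = 25 kg/m2 an exact
#' equilibrium of the weight equation at baseline intake.
#'
#' @param ... named overrides for individual fields.
#' @return An object of class `t2d_parameters` (a named list of scalars).
#' @export
#' @examples
#' p <- t2d_parameters()
#' p$K_theta
t2d_parameters <- function(...) {
  p <- .t2d_nominal()
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), .t2d_param_order)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
    p[names(ov)] <- lapply(ov, as.numeric)
  }
  validate_parameters(p)
}

.t2d_nominal <- function() {
  p <- list(
    # -- body weight / energy balance (Eq. of weight change) --
    k_w    = 0.0813 * 81 / 2500,  # kg per (kcal/day) per month
    DE_i_b = 2500,          # baseline daily energy intake, kcal/day
    DE_e   = 0.0813,        # /month; balance at W = 81 kg (BMI 25, h 1.8)
    h      = 1.8,           # height, m
    # -- fasting glucose --
    E_G0     = 40,          # insulin-independent uptake, /month
    HGP_b    = 4200,        # basal hepatic glucose production, mg/dL/month
    HGP_max  = 9000,        # suppressible HGP, mg/dL/month
    alpha_HGP = 220,        # half-suppression constant for S_i * I
    # -- insulin --
    k_I = 100,              # insulin clearance, /month
    V   = 0.236,            # distribution volume (absorbs secretion scale)
    alpha_ISR = 0.25, K_ISR = 2,   # ISR sigmoid in M: half-max, Hill exponent
    alpha_M = 140, K_M = 4,        # M sigmoid in G: half-max (mg/dL), exponent
    # -- free fatty acids --
    K_siF = 120, alpha_SiF = 2,    # lipolysis suppression vs S_i * I
    c_f = 0.206,                  # FFA turnover per kg body weight, /kg/month
    F_Ra0 = 3000, F_Ra1 = 300,     # max lipolysis intercept/slope vs fat mass
    FMR_a = 0.012, FMR_b = -0.03,  # fat-mass ratio = FMR_a*BMI + FMR_b
    # -- systemic inflammation --
    tau_theta = 4, n_theta = 10, K_theta = 40,   # months; -; kg/m2
    # -- insulin sensitivity --
    tau_Si = 2, S_i_b = 10, M_FFA = 0.9,
    n_Si = 3, K_Si_FFA = 500, K_Si_theta = 0.75,
    # -- beta-cell mass --
    P_ng = 20,              # neogenesis, mg/month (before tau_beta scaling)
    P_max = 0.3, n_P = 3, alpha_P = 0.4,        # replication sigmoid in ISR
    A_b = 0.03, A_max = 0.2, n_A = 6, alpha_A = 0.42,  # apoptosis sigmoid in M
    s = 5.891959967e-05,    # pairwise (logistic) interaction, /mg/month
    tau_beta = 15,          # months
    # -- beta-cell function --
    tau_sigma = 3, sigma_b = 1,
    s_gu_max = 4.619003386, K_gu = 300, n_gu = 1,      # glucose-driven up-regulation
    K_gd = 130, n_gd = 6,                       # glucotoxic component
    s_ffa_max = 2.45, K_sf = 500, n_sf = 4,      # lipotoxic component
    s_th_max = 0.7, K_st = 0.55, n_st = 4,         # inflammation component
    # -- baseline references for the disease progression index --
    S_i_0 = 6.955178531, sigma_0 = 1, beta_0 = 1000
  )
  p[.t2d_param_order]
}

#' Validate a parameter set
#'
#' Checks completeness, finiteness, strict positivity of every rate, time
#' constant, Hill exponent and half-max constant, `M_FFA` in \[0, 1\], and
#' the baseline energy balance `k_w * DE_i_b = DE_e * 25 * h^2`.
#'
#' @param p named list of parameter values.
#' @return `p`, classed as `t2d_parameters`, invisibly usable downstream.
#' @export
validate_parameters <- function(p) {
  p <- unclass(p)
  missing <- setdiff(.t2d_param_order, names(p))
  if (length(missing)) stop("missing parameter(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(p), .t2d_param_order)
  if (length(extra)) stop("unknown parameter(s): ", paste(extra, collapse = ", "))
  p <- p[.t2d_param_order]
  for (nm in .t2d_param_order) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  neg <- .t2d_param_positive[vapply(.t2d_param_positive,
                                    function(nm) p[[nm]] <= 0, logical(1))]
  if (length(neg)) stop("parameter(s) must be strictly positive: ",
                        paste(neg, collapse = ", "))
  if (p$M_FFA > 1) stop("parameter 'M_FFA' must lie in [0, 1]")
  W_b <- 25 * p$h^2
  bal <- abs(p$k_w * p$DE_i_b - p$DE_e * W_b) / (p$DE_e * W_b)
  if (bal > 1e-6)
    stop("baseline energy balance violated: k_w * DE_i_b must equal DE_e * 25 * h^2 ",
         "(relative error ", format(bal, digits = 3), ")")
  structure(p, class = "t2d_parameters")
}

#' @export
print.t2d_parameters <- function(x, ...) {
  cat("<t2d_parameters> ", length(.t2d_param_order), " fields; ",
      "K_theta = ", x$K_theta, " kg/m2, DE_i_b = ", x$DE_i_b, " kcal/day\n", sep = "")
  invisible(x)
}

# numeric vector in compiled-code order, with the active intake fraction
# appended (slot 57)
.param_vector <- function(p, DE_frac = 1) {
  c(unlist(p[.t2d_param_order], use.names = FALSE), DE_frac)
}

#' Read a parameter file
#'
#' The parameter file is a flat YAML mapping with one scalar entry per
#' field (units and provenance carried as `#` comments). Unknown or
#' missing keys are rejected by name and all invariants are re-checked.
#'
#' @param path file path.
#' @return a `t2d_parameters` object.
#' @export
#' @examples
#' nominal <- system.file("extdata", "parameters_nominal.yaml", package = "t2dsim")
#' p <- load_parameters(nominal)
load_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  validate_parameters(lapply(raw, as.numeric))
}

#' Write a parameter file
#'
#' Writes a flat YAML mapping that [load_parameters()] reads back with
#' bit-identical values (values are serialized at full double precision).
#'
#' @param p a `t2d_parameters` object.
#' @param path destination path.
#' @export
write_parameters <- function(p, path) {
  p <- validate_parameters(p)
  lines <- vapply(.t2d_param_order, function(nm)
    paste0(nm, ": ", formatC(p[[nm]], format = "g", digits = 17)), character(1))
  writeLines(lines, path)
  invisible(path)
}
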