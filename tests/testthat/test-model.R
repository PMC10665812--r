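test_that("half-maximal sigmoids evaluate at their construction points", {
  p <- fix_params()
  b <- fix_baseline()
  # BMI equal to K_theta gives half-maximal asymptotic inflammation
  st <- b; st[["W"]] <- p$K_theta * p$h^2
  expect_equal(observables(st, p)$theta_inf, 0.5)
  # G equal to alpha_M gives half-maximal metabolic rate
  st <- b; st[["G"]] <- p$alpha_M
  expect_equal(observables(st, p)$M, 0.5)
  # M equal to alpha_ISR gives ISR = sigma / 2
  G_half <- p$alpha_M * (p$alpha_ISR / (1 - p$alpha_ISR))^(1 / p$K_M)
  st <- b; st[["G"]] <- G_half; st[["sigma"]] <- 0.8
  expect_equal(observables(st, p)$ISR, 0.8 / 2, tolerance = 1e-10)
})

test_that("the disease progression index is anchored at the healthy baseline", {
  p <- fix_params()
  b <- fix_baseline()
  expect_equal(observables(b, p)$DPI, 0, tolerance = 1e-8)
  expect_equal(dpi(p$S_i_0, p$sigma_0, p$beta_0, p), 0)
  # decreasing any one factor below baseline increases the index
  expect_gt(dpi(p$S_i_0 * 0.9, p$sigma_0, p$beta_0, p), 0)
  expect_gt(dpi(p$S_i_0, p$sigma_0 * 0.5, p$beta_0, p), 0)
  expect_gt(dpi(p$S_i_0, p$sigma_0, p$beta_0 * 0.7, p), 0)
})

test_that("non-finite and inadmissible states are rejected by name", {
  p <- fix_params()
  b <- fix_baseline()
  st <- b; st[["FFA"]] <- NaN
  expect_error(observables(st, p), "FFA")
  st <- b; st[["I"]] <- -5
  expect_error(observables(st, p), "I")
  st <- b; st[["theta"]] <- 1.2
  expect_error(observables(st, p), "theta")
})

test_that("glycemic and BMI classifications follow the stated cutoffs", {
  expect_equal(classify_glycemic(c(95, 99.9, 100, 110, 125, 125.1, 130)),
               c("healthy", "healthy", "prediabetes", "prediabetes",
                 "prediabetes", "T2D", "T2D"))
  expect_equal(classify_bmi(c(24, 25, 27, 30, 32)),
               c("normal", "overweight", "overweight", "overweight", "obese"))
  expect_error(classify_glycemic(-1))
})

test_that("the right-hand side has the stated structure", {
  p <- fix_params()
  b <- fix_baseline()
  # weight balance: DE_i = DE_e * W / k_w implies dW/dt = 0
  d <- rhs(0, b, p, schedule = 1)
  expect_equal(unname(d[["W"]]), 0, tolerance = 1e-10)
  # relaxation form: theta below its asymptote rises
  st <- b; st[["W"]] <- 35 * p$h^2   # theta_inf jumps up, theta still low
  expect_gt(rhs(0, st, p, schedule = 1)[["theta"]], 0)
  # at the root-solved baseline the whole field vanishes (scaled)
  scaled <- d / t2dsim:::.t2d_state_scale
  expect_lt(sqrt(sum(scaled^2)), 1e-8)
  # time outside the schedule domain is an error naming the gap
  sch <- intervention_schedule(c(0, 5), c(1, 1.3), 60)
  expect_error(rhs(70, b, p, sch), "outside schedule domain")
})

test_that("response-function monotonicity holds over a state grid", {
  p <- fix_params()
  b <- fix_baseline()
  bmi_grid <- seq(20, 50, by = 2)
  th <- vapply(bmi_grid, function(bmi) {
    st <- b; st[["W"]] <- bmi * p$h^2; observables(st, p)$theta_inf
  }, numeric(1))
  expect_true(all(diff(th) >= 0))
  expect_true(all(th >= 0 & th <= 1))

  ffa_grid <- seq(100, 1200, by = 100)
  si <- vapply(ffa_grid, function(f) {
    st <- b; st[["FFA"]] <- f; observables(st, p)$S_i_inf
  }, numeric(1))
  expect_true(all(diff(si) <= 0))
  th_grid <- seq(0, 1, by = 0.1)
  si2 <- vapply(th_grid, function(t) {
    st <- b; st[["theta"]] <- t; observables(st, p)$S_i_inf
  }, numeric(1))
  expect_true(all(diff(si2) <= 0))

  # HGP non-increasing in insulin action; FFA_Ra too; both via I
  i_grid <- seq(1, 60, by = 5)
  hgp <- vapply(i_grid, function(i) {
    st <- b; st[["I"]] <- i; observables(st, p)$HGP
  }, numeric(1))
  ra <- vapply(i_grid, function(i) {
    st <- b; st[["I"]] <- i; observables(st, p)$FFA_Ra
  }, numeric(1))
  expect_true(all(diff(hgp) <= 0))
  expect_true(all(diff(ra) <= 0))

  # ISR non-decreasing in M (via G), M non-decreasing in G, bounds hold
  g_grid <- seq(60, 300, by = 20)
  ob <- lapply(g_grid, function(g) {
    st <- b; st[["G"]] <- g; observables(st, p)
  })
  M <- vapply(ob, `[[`, numeric(1), "M")
  ISR <- vapply(ob, `[[`, numeric(1), "ISR")
  expect_true(all(diff(M) >= 0) && all(diff(ISR) >= 0))
  expect_true(all(M >= 0 & M <= 1))
  expect_true(all(ISR <= b[["sigma"]] + 1e-12))
  A <- vapply(ob, `[[`, numeric(1), "A")
  expect_true(all(A >= p$A_b))
  # FFA_Ra non-decreasing in fat mass (via W at fixed insulin action)
  ra_fm <- vapply(seq(70, 140, by = 10), function(w) {
    st <- b; st[["W"]] <- w; observables(st, p)$FFA_Ra
  }, numeric(1))
  expect_true(all(diff(ra_fm) >= 0))
})

test_that("baseline equilibrium sits at the healthy anchor point", {
  p <- fix_params()
  b <- fix_baseline()
  expect_equal(unname(b[["W"]]) / p$h^2, 25, tolerance = 1e-9)
  expect_equal(unname(b[["beta"]]), 1000, tolerance = 1e-6)
  expect_lt(b[["G"]], 100)
  expect_equal(unname(b[["sigma"]]), 1, tolerance = 1e-6)
})
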