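test_that("the cost vanishes at truth on noiseless data and detects perturbation", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5, 60, 65), c(1, 1.4, 0.7, 1.25), 85)
  des <- direct_design(60); des$noise_sd <- 0
  dat <- generate_synthetic(p, sch, des, seed = 1)
  expect_lt(cost(c(K_theta = p$K_theta), p, dat, sch), 1e-4)
  expect_gt(cost(c(K_theta = p$K_theta * 1.1), p, dat, sch), 1)
})

test_that("the cost at truth on noisy data matches the chi-square expectation", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5, 60, 65), c(1, 1.4, 0.7, 1.25), 85)
  des <- direct_design(60)
  # accumulate over several replicates to stabilize the comparison
  total <- 0; count <- 0
  for (s in 1:5) {
    dat <- generate_synthetic(p, sch, des, seed = s)
    total <- total + cost(c(K_theta = p$K_theta), p, dat, sch)
    count <- count + nrow(dat)
  }
  expect_lt(abs(total - count), 3 * sqrt(2 * count))
})

test_that("the cost is invariant to observation order and stream splitting", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5), c(1, 1.4), 85)
  des <- direct_design(60)
  dat <- generate_synthetic(p, sch, des, seed = 2)
  free <- c(K_theta = 38)
  j1 <- cost(free, p, dat, sch)
  shuf <- dat[rev(seq_len(nrow(dat))), ]
  class(shuf) <- class(dat)
  expect_equal(cost(free, p, shuf, sch), j1, tolerance = 1e-10)
})

test_that("zero-noise recovery returns the true parameters", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5, 60, 65), c(1, 1.4, 0.7, 1.25), 85)
  truth <- t2d_parameters(K_theta = 36, sigma_b = 1.05)
  des <- direct_design(60); des$noise_sd <- 0
  dat <- generate_synthetic(truth, sch, des, seed = 3)
  f <- fit(dat, p, sch, free = c("K_theta", "sigma_b"),
           lower = list(K_theta = 30, sigma_b = 0.8),
           upper = list(K_theta = 45, sigma_b = 1.2), n_starts = 3, seed = 2)
  expect_equal(unname(f$par[["K_theta"]]), 36, tolerance = 1e-3)
  expect_equal(unname(f$par[["sigma_b"]]), 1.05, tolerance = 1e-3)
  expect_true(all(f$starts$cost[f$starts$converged] >= f$cost - 1e-9))
})

test_that("information adds: duplicated observations shrink intervals by ~1/sqrt(2)", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5, 60, 65), c(1, 1.4, 0.7, 1.25), 85)
  des <- direct_design(60)
  dat <- generate_synthetic(p, sch, des, seed = 4)
  f1 <- fit(dat, p, sch, free = "K_theta",
            lower = list(K_theta = 34), upper = list(K_theta = 46),
            n_starts = 2, seed = 1)
  ci1 <- confidence_intervals(f1)
  dat2 <- rbind(dat, dat); class(dat2) <- class(dat)
  f2 <- fit(dat2, p, sch, free = "K_theta",
            lower = list(K_theta = 34), upper = list(K_theta = 46),
            n_starts = 2, seed = 1)
  ci2 <- confidence_intervals(f2)
  ratio <- ci2$half_width / ci1$half_width
  # 1/sqrt(2) up to the change in the t quantile with df
  expect_lt(abs(ratio - 1 / sqrt(2)), 0.08)
})

test_that("a parameter with no sensitivity is flagged unidentifiable", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5), c(1, 1.3), 40)
  # observations only up to month 30; a level of a segment that never
  # starts cannot influence them
  des <- data.frame(stream = "G", time = c(0, 10, 20, 30), sd = 5)
  dat <- generate_synthetic(p, sch, des, seed = 5)
  sch2 <- intervention_schedule(c(0, 5, 35), c(1, 1.3, 1.3), 40)
  f <- fit(dat, p, sch2, free = c("K_theta", "level3"),
           lower = list(K_theta = 35, level3 = 1), 
           upper = list(K_theta = 45, level3 = 1.6), n_starts = 2, seed = 3)
  ci <- suppressWarnings(confidence_intervals(f))
  expect_false(ci$identifiable[ci$parameter == "level3"])
  expect_true(ci$identifiable[ci$parameter == "K_theta"])
})

test_that("the synthetic generator is seed-reproducible and honest about noise", {
  p <- fix_params()
  sch <- intervention_schedule(c(0, 5), c(1, 1.4), 85)
  des <- direct_design(60)
  d1 <- generate_synthetic(p, sch, des, seed = 11)
  d2 <- generate_synthetic(p, sch, des, seed = 11)
  expect_identical(d1, d2)
  d3 <- generate_synthetic(p, sch, des, seed = 12)
  expect_false(identical(d1$value, d3$value))
  # zero noise returns the noiseless model output
  des0 <- des; des0$noise_sd <- 0
  d0a <- generate_synthetic(p, sch, des0, seed = 1)
  d0b <- generate_synthetic(p, sch, des0, seed = 99)
  expect_identical(d0a$value, d0b$value)
  # replicated-noise sample SD matches the design SD within 10%
  des_rep <- data.frame(stream = "G", time = rep(60, 1000), sd = 8)
  dr <- generate_synthetic(p, sch, des_rep, seed = 21)
  expect_lt(abs(sd(dr$value) - 8) / 8, 0.1)
})
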