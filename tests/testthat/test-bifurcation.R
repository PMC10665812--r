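test_that("equilibrium counts match the bistable structure", {
  p <- fix_params()
  eq25 <- equilibria_at_bmi(25, p)
  expect_equal(nrow(eq25), 3)
  expect_equal(sum(eq25$stable), 2)
  expect_equal(eq25$beta[which.max(eq25$beta)], 1000, tolerance = 1e-3)
  expect_true(all(eq25$resid < 1e-9))
  # beyond the fold only the diabetic attractor persists
  eq45 <- suppressWarnings(equilibria_at_bmi(45, p))
  expect_equal(nrow(eq45), 1)
  expect_true(eq45$stable)
  expect_gt(eq45$G, 125)
})

test_that("every diagram point re-verifies by direct root-solving", {
  p <- fix_params()
  bd <- fix_diagram()
  expect_true(all(bd$branches$resid < 1e-9))
  pick <- bd$branches[bd$branches$BMI %in% c(27, 33, 38), ]
  for (b in unique(pick$BMI)) {
    direct <- equilibria_at_bmi(b, p)
    sub <- pick[pick$BMI == b, ]
    expect_equal(nrow(sub), nrow(direct))
    expect_rel_equal(sort(sub$beta), sort(direct$beta), 1e-6)
  }
})

test_that("the saddle-node fold is localized and flanked correctly", {
  p <- fix_params()
  bd <- fix_diagram()
  expect_false(is.null(bd$folds))
  fold <- max(bd$folds$BMI)
  expect_equal(nrow(suppressWarnings(equilibria_at_bmi(fold - 0.3, p))), 3)
  expect_equal(nrow(suppressWarnings(equilibria_at_bmi(fold + 0.3, p))), 1)
  lab <- bd$branches$branch
  expect_setequal(unique(lab), c("upper-stable", "unstable", "lower-stable"))
  # labels consistent with stability
  expect_true(all(bd$branches$stable[lab != "unstable"] | bd$branches$marginal[lab != "unstable"]))
  expect_true(all(!bd$branches$stable[lab == "unstable"]))
})

test_that("the threshold curve interpolates the unstable branch", {
  bd <- fix_diagram()
  thr <- fix_threshold()
  un <- bd$branches[bd$branches$branch == "unstable", ]
  expect_rel_equal(threshold_eval(thr, un$BMI), un$beta, 1e-9)
  # monotone in BMI over the bistable interval
  grid <- seq(thr$range[1], thr$range[2], length.out = 40)
  expect_true(all(diff(threshold_eval(thr, grid)) >= 0))
  # diagram without an unstable branch is rejected
  bd2 <- bd; bd2$branches <- bd$branches[bd$branches$branch != "unstable", ]
  expect_error(threshold_curve(bd2), "unstable")
})

test_that("initial conditions straddling the threshold diverge to different attractors", {
  p <- fix_params()
  thr <- fix_threshold()
  bmi0 <- 30
  b_thr <- threshold_eval(thr, bmi0)
  up <- t2dsim:::.quasi_steady_state(p, bmi0, b_thr * 1.25)
  dn <- t2dsim:::.quasi_steady_state(p, bmi0, b_thr * 0.75)
  expect_equal(classify_attractor(up, 1, p, thr, horizon = 400), "high-beta")
  expect_equal(classify_attractor(dn, 1, p, thr, horizon = 400), "low-beta")
  # label stable under horizon doubling
  expect_equal(classify_attractor(up, 1, p, thr, horizon = 800), "high-beta")
  expect_equal(classify_attractor(dn, 1, p, thr, horizon = 800), "low-beta")
})

test_that("stronger inflammatory response shifts the fold to lower BMI", {
  folds <- vapply(c(36, 40, 44), function(kt) {
    pk <- t2d_parameters(K_theta = kt)
    lo <- 28; hi <- 46
    for (i in 1:7) {
      mid <- (lo + hi) / 2
      n <- nrow(suppressWarnings(equilibria_at_bmi(mid, pk)))
      if (n >= 3) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  expect_true(all(diff(folds) > 0))
  # and the unstable branch sits lower for stronger inflammation
  p_low <- t2d_parameters(K_theta = 36)
  p_high <- t2d_parameters(K_theta = 44)
  un_low <- equilibria_at_bmi(32, p_low)
  un_high <- equilibria_at_bmi(32, p_high)
  mid_beta <- function(eq) sort(eq$beta)[2]
  expect_lt(mid_beta(un_high), mid_beta(un_low))
})

test_that("the remission map has the documented sentinels and monotonicity", {
  p <- fix_params()
  mp <- remission_map(p, bmi = c(28, 36), beta = c(250, 500, 800),
                      de_range = c(1, 1.55), precision = 0.02,
                      diagram = fix_diagram(), horizon = 400)
  g <- mp$grid
  # deep beta depletion cannot be rescued even at baseline intake
  expect_true(all(g$code[g$beta == 250] == "F"))
  # at fixed BMI the admissible intake is non-decreasing in beta
  for (b in unique(g$BMI)) {
    sub <- g[g$BMI == b, ]
    sub <- sub[order(sub$beta), ]
    vals <- ifelse(sub$code == "F", 0,
                   ifelse(sub$code == "NR", Inf, sub$max_de))
    expect_true(all(diff(vals) >= -2))   # bisection precision slack
  }
  # high beta-cell mass at moderate BMI needs no restriction at all
  expect_true(g$code[g$BMI == 28 & g$beta == 800] == "NR")
})
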