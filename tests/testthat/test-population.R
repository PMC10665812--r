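test_that("cohorts are reproducible and sampled within the declared ranges", {
  spec <- sampling_spec("fig9", n = 8, seed = 42)
  c1 <- sample_cohort(spec)
  c2 <- sample_cohort(spec)
  expect_identical(c1, c2)
  lv <- t(vapply(c1, function(ind) ind$schedule$levels, numeric(4)))
  expect_true(all(lv[, 2] >= 1.25 & lv[, 2] <= 1.55))
  expect_true(all(lv[, 3] >= 0.60 & lv[, 3] <= 0.80))
  expect_true(all(lv[, 4] >= 1.10 & lv[, 4] <= 1.40))
  # all sampled parameter sets remain admissible
  for (ind in c1) expect_s3_class(validate_parameters(ind$params), "t2d_parameters")
})

test_that("a zero-spread cohort collapses to the deterministic scenario", {
  spread0 <- default_spread()
  spread0$lower <- spread0$upper <- rep(1, nrow(spread0))
  spec <- sampling_spec("fig6", n = 3, seed = 5, spread = spread0)
  co <- sample_cohort(spec)
  # identical parameters across individuals
  expect_identical(co[[1]]$params[t2dsim:::.t2d_param_order],
                   co[[2]]$params[t2dsim:::.t2d_param_order])
  # fixing the protocol as well makes every trajectory identical
  for (i in seq_along(co))
    co[[i]]$schedule <- intervention_schedule(c(0, 10, 80), c(1, 1.75, 1), 120)
  rc <- run_cohort(co, dt = 1)
  expect_identical(rc[[1]]$trajectory$state, rc[[2]]$trajectory$state)
  sm <- summarize_cohort(rc)
  expect_true(all(sm$stats$sd < 1e-9))
})

test_that("individual classification follows the glucose-envelope rules", {
  spec <- sampling_spec("fig6", n = 25, seed = 7)
  co <- run_cohort(sample_cohort(spec), dt = 0.5)
  labs <- vapply(co, `[[`, character(1), "label")
  expect_true(all(labs %in% c("non-diabetic", "diabetic", "remission")))
  for (ind in co) {
    G <- ind$trajectory$state[, "G"]
    if (ind$label == "non-diabetic") expect_lte(max(G), 125)
    if (ind$label == "diabetic") expect_gt(G[length(G)], 125)
    if (ind$label == "remission") {
      expect_gt(max(G), 125); expect_lte(G[length(G)], 125)
    }
  }
  # trajectory ending before the intervention is rejected
  short <- simulate(co[[1]]$params, intervention_schedule(0, 1, 10), dt = 1)
  expect_error(classify_individual(short, 80), "intervention")
})

test_that("remission group shows healthier beta-cell state at intervention", {
  spec <- sampling_spec("fig6", n = 60, seed = 3)
  co <- run_cohort(sample_cohort(spec), dt = 0.5)
  sm <- summarize_cohort(co)
  at <- function(g, v, tt) {
    r <- sm$stats[sm$stats$group == g & sm$stats$variable == v &
                  sm$stats$time == tt, ]
    r$mean
  }
  t_int <- 80
  expect_gt(at("remission", "beta", t_int), at("diabetic", "beta", t_int))
  expect_gt(at("remission", "sigma", t_int), at("diabetic", "sigma", t_int))
  expect_lt(at("remission", "G", t_int), at("diabetic", "G", t_int))
  # BMI distributions are similar between the two groups at intervention
  bmi_test <- sm$tests[sm$tests$comparison == "between-groups" &
                       sm$tests$variable == "BMI" & sm$tests$time == t_int &
                       sm$tests$group1 %in% c("diabetic", "remission") &
                       sm$tests$group2 %in% c("diabetic", "remission"), ]
  if (nrow(bmi_test)) expect_gt(min(bmi_test$p), 0.01)
  # every individual gets exactly one label
  expect_equal(length(sm$labels), 60)
})

test_that("responders have shorter diabetes duration than non-responders", {
  spec <- sampling_spec("fig9", n = 60, seed = 9)
  co <- run_cohort(sample_cohort(spec), dt = 0.5)
  sm <- summarize_cohort(co)
  dur <- sm$duration
  resp <- dur$mean[dur$group == "remission"]
  nonr <- dur$mean[dur$group == "diabetic"]
  expect_gt(dur$n[dur$group == "remission"], 2)
  expect_gt(dur$n[dur$group == "diabetic"], 2)
  expect_lt(resp, nonr)
})
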