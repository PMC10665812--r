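# Shared fixtures, computed lazily and cached for the whole test run.

.fix <- new.env(parent = emptyenv())

fix_params <- function() {
  if (is.null(.fix$params)) .fix$params <- t2d_parameters()
  .fix$params
}

fix_baseline <- function() {
  if (is.null(.fix$baseline)) .fix$baseline <- baseline_state(fix_params())
  .fix$baseline
}

# coarse-but-sufficient diagram over the bistable interval, reused by the
# threshold/attractor/acceptance tests
fix_diagram <- function() {
  if (is.null(.fix$diagram))
    .fix$diagram <- continue_branches(fix_params(), bmi_range = c(23, 43),
                                      step = 1, fold_tol = 0.05)
  .fix$diagram
}

fix_threshold <- function() {
  if (is.null(.fix$threshold)) .fix$threshold <- threshold_curve(fix_diagram())
  .fix$threshold
}

# magenta weight-gain scenario, reused across event/scenario/acceptance tests
fix_fig2_175 <- function() {
  if (is.null(.fix$fig2_175))
    .fix$fig2_175 <- run_scenario("fig2-175", fix_params(), dt = 0.1)
  .fix$fig2_175
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
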