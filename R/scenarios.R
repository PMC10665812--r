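# Preset intake protocols.

.t2d_presets <- function() {
  list(
    # weight-gain scenarios: intake raised at month 5
    "fig2-130" = list(times = c(0, 5), levels = c(1, 1.30), horizon = 60),
    "fig2-155" = list(times = c(0, 5), levels = c(1, 1.55), horizon = 60),
    "fig2-175" = list(times = c(0, 5), levels = c(1, 1.75), horizon = 60),
    # remission scenarios: 175% gain phase, intake restored to baseline
    "fig4-64"  = list(times = c(0, 5, 64), levels = c(1, 1.75, 1), horizon = 144),
    "fig4-76"  = list(times = c(0, 5, 76), levels = c(1, 1.75, 1), horizon = 144),
    "fig4-88"  = list(times = c(0, 5, 88), levels = c(1, 1.75, 1), horizon = 144),
    # inflammation-sensitivity protocol (vary K_theta via overrides)
    "fig5-ktheta" = list(times = c(0, 5, 76), levels = c(1, 1.75, 1), horizon = 144),
    # weight-management trial protocol: gain from month 5, high-intensity
    # restriction at 60, low-intensity maintenance from 65
    "direct" = list(times = c(0, 5, 60, 65), levels = c(1, 1.40, 0.70, 1.25),
                    horizon = 85)
  )
}

#' Preset simulation scenarios
#'
#' Builds the intake schedule of a named preset, simulates from the
#' healthy baseline, and detects events.
#'
#' @param name one of `fig2-130`, `fig2-155`, `fig2-175`, `fig4-64`,
#'   `fig4-76`, `fig4-88`, `fig5-ktheta`, `direct`.
#' @param params a `t2d_parameters` object.
#' @param overrides named list of parameter overrides (e.g.
#'   `list(K_theta = 35)` for the inflammation presets).
#' @param threshold optional `t2d_threshold` for separatrix events.
#' @param dt output step, months.
#' @return list with `trajectory`, `events`, and `schedule`.
#' @export
#' @examples
#' sc <- run_scenario("fig2-130", t2d_parameters())
#' max(sc$trajectory$obs$BMI)
run_scenario <- function(name, params, overrides = NULL, threshold = NULL,
                         dt = 0.1) {
  presets <- .t2d_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; valid: ",
         paste(names(presets), collapse = ", "))
  if (!is.null(overrides)) {
    params <- unclass(params)
    params[names(overrides)] <- overrides
    params <- validate_parameters(params)
  }
  def <- presets[[name]]
  sch <- intervention_schedule(def$times, def$levels, def$horizon)
  tr <- simulate(params, sch, dt = dt)
  list(trajectory = tr, events = detect_events(tr, params, threshold),
       schedule = sch)
}
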