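#' Integrate the community model over time
#'
#' Integrates the 8-state community ODE with an adaptive stiff-capable
#' solver (`deSolve::ode`, lsoda) and records the trajectory on a uniform
#' output grid, together with the derived infection-prevalence series
#' `100 I / (H + I)`. States are clamped to be non-negative at output times;
#' inside the right-hand side all response functions are evaluated on
#' `max(state, 0)`, so transient tiny negative excursions of the stepper
#' cannot seed sign errors in the grazing-partition quotients.
#'
#' @param scenario a [scenario_spec()]; alternatively pass `initial`, `mask`
#'   and `horizon` directly.
#' @param params a [plankton_params()] object.
#' @param initial,mask,horizon used when `scenario` is `NULL`.
#' @param output_step output grid step in days (default 0.1; fine enough
#'   that peak-day identification is not grid-limited).
#' @param rtol relative integration tolerance.
#' @param atol_scale absolute tolerances are `atol_scale * max(|initial|, 1)`
#'   per variable.
#' @param options a [model_options()] object.
#' @return An object of class `plankton_sim`: a list with `trajectory`
#'   (tibble: `time`, the 8 state columns, `prevalence` in %), `scenario`,
#'   `params`, `options` and `solver` settings.
#' @examples
#' sim <- simulate_community(build_scenario(1, "eutro"))
#' dplyr::slice_max(sim$trajectory, prevalence)
#' @export
simulate_community <- function(scenario = NULL, params = plankton_params(),
                               initial = NULL, mask = community_mask(),
                               horizon = 30, output_step = 0.1,
                               rtol = 1e-8, atol_scale = 1e-8,
                               options = model_options()) {
  if (!is.null(scenario)) {
    stopifnot(inherits(scenario, "scenario_spec"))
    initial <- scenario$initial
    mask <- scenario$mask
    horizon <- scenario$horizon
  } else {
    stopifnot(!is.null(initial), horizon > 0)
    initial <- .apply_mask_state(initial[.state_names], mask)
    scenario <- scenario_spec("custom", mask, initial, horizon)
  }
  active <- .active_states(mask)
  frozen <- mask$frozen
  times <- seq(0, horizon, by = output_step)
  deriv <- function(t, y, parms) {
    terms <- .flux_terms(y, params, active, frozen, options)
    d <- .sum_terms(terms)
    .check_finite(d, terms)
    list(d)
  }
  out <- deSolve::ode(y = initial, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol,
                      atol = atol_scale * pmax(abs(initial), 1))
  if (attr(out, "istate")[1] < 0) {
    stop("integrator failure for '", scenario$label, "' at t = ",
         max(out[, 1]), " d (last successful output time)")
  }
  states <- pmax(out[, .state_names, drop = FALSE], 0)
  traj <- tibble::as_tibble(as.data.frame(states))
  traj <- dplyr::mutate(traj, time = out[, 1], .before = 1)
  traj$prevalence <- prevalence_series(traj)
  structure(list(trajectory = traj, scenario = scenario, params = params,
                 options = options,
                 solver = list(method = "lsoda", rtol = rtol,
                               atol_scale = atol_scale,
                               output_step = output_step)),
            class = "plankton_sim")
}

#' Infection prevalence series
#'
#' Percentage of the dinoflagellate population that is infected,
#' `100 I / (H + I)`, defined as 0 where `H + I = 0`.
#'
#' @param traj a data frame with columns `H` and `I` (e.g. the `trajectory`
#'   element of a [simulate_community()] result).
#' @return Numeric vector in \[0, 100\].
#' @export
prevalence_series <- function(traj) {
  tot <- traj$H + traj$I
  ifelse(tot > 0, 100 * traj$I / tot, 0)
}

#' Summarize a simulated trajectory
#'
#' Per-series maxima, times of (earliest) maximum, and final values for the
#' eight state variables and the prevalence series. Peak days are also
#' reported rounded to the nearest integer day.
#'
#' @param sim a `plankton_sim` object.
#' @return A tibble with columns `variable`, `max`, `t_max` (days, earliest
#'   attainment), `day_max` (nearest integer), `final`.
#' @export
summarize_trajectory <- function(sim) {
  stopifnot(inherits(sim, "plankton_sim"))
  traj <- sim$trajectory
  vars <- c(.state_names, "prevalence")
  purrr::map_dfr(vars, function(v) {
    x <- traj[[v]]
    i <- which.max(x)
    tibble::tibble(variable = v, max = x[i], t_max = traj$time[i],
                   day_max = as.integer(round(traj$time[i])),
                   final = x[length(x)])
  })
}

#' @export
print.plankton_sim <- function(x, ...) {
  cat("<plankton_sim>", x$scenario$label, "| horizon",
      x$scenario$horizon, "d |", nrow(x$trajectory), "output times\n")
  s <- summarize_trajectory(x)
  pv <- s[s$variable == "prevalence", ]
  cat(sprintf("  max prevalence %.1f%% on day %d\n", pv$max, pv$day_max))
  invisible(x)
}

#' @rdname simulate_community
#' @param x a `plankton_sim` object.
#' @param ... unused.
#' @method tidy plankton_sim
#' @export
tidy.plankton_sim <- function(x, ...) {
  tidyr::pivot_longer(x$trajectory, -"time",
                      names_to = "variable", values_to = "value")
}

#' @rdname simulate_community
#' @method glance plankton_sim
#' @export
glance.plankton_sim <- function(x, ...) {
  s <- summarize_trajectory(x)
  pv <- s[s$variable == "prevalence", ]
  hh <- s[s$variable == "H", ]
  pp <- s[s$variable == "P", ]
  tibble::tibble(
    label = x$scenario$label,
    horizon = x$scenario$horizon,
    max_prevalence = pv$max, day_max_prevalence = pv$day_max,
    max_H = hh$max, day_max_H = hh$day_max,
    max_P = pp$max, day_max_P = pp$day_max,
    final_N = x$trajectory$N[nrow(x$trajectory)]
  )
}
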