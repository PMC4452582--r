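# trapezoid rule on a (possibly non-uniform) grid
.trapz <- function(t, x) {
  n <- length(t)
  if (n < 2) return(0)
  sum(diff(t) * (x[-1] + x[-n]) / 2)
}

#' Flux terms along a trajectory
#'
#' Re-evaluates the exact flux decomposition ([decompose_fluxes()]) at every
#' output time of a simulation.
#'
#' @param sim a `plankton_sim` object.
#' @return A tibble with columns `time`, `variable`, `term`, `rate`.
#' @export
flux_series <- function(sim) {
  stopifnot(inherits(sim, "plankton_sim"))
  traj <- sim$trajectory
  active <- .active_states(sim$scenario$mask)
  frozen <- sim$scenario$mask$frozen
  purrr::map_dfr(seq_len(nrow(traj)), function(i) {
    y <- unlist(traj[i, .state_names])
    fx <- decompose_fluxes(y, sim$params, sim$scenario$mask, sim$options)
    fx$time <- traj$time[i]
    fx[, c("time", "variable", "term", "rate")]
  })
}

#' Demise window of a bloom
#'
#' The portion of a run used for loss attribution during bloom collapse:
#' from the (earliest) time at which the variable attains its maximum to the
#' end of the run. A monotonically increasing series yields an empty window
#' (`t_peak == horizon`).
#'
#' @param sim a `plankton_sim` object.
#' @param variable state variable name (e.g. `"P"`).
#' @return Numeric `c(t_peak, horizon)` in days.
#' @export
demise_window <- function(sim, variable = "P") {
  stopifnot(inherits(sim, "plankton_sim"), variable %in% .state_names)
  x <- sim$trajectory[[variable]]
  tt <- sim$trajectory$time
  c(tt[which.max(x)], tt[length(tt)])
}

#' Integrated loss shares of a state variable
#'
#' Integrates each loss term of one state equation over a time window by the
#' trapezoid rule on the output grid, and expresses every term as a
#' percentage of the summed losses — the cause-of-death breakdown used to
#' attribute bloom demise to parasites and grazers.
#'
#' @param sim a `plankton_sim` object.
#' @param variable state variable whose losses are attributed (default the
#'   dinospore pool `"P"`).
#' @param window `"demise"` (from the variable's earliest maximum to the end
#'   of the run, the default), `"full"`, or a numeric `c(t0, t1)`.
#' @param terms which loss terms enter the denominator: `"all"` (default) or
#'   a character vector of term names (e.g. excluding the infection
#'   attachment flux from the dinospore "mortality" total).
#' @return A tibble with columns `variable`, `term`, `integral` (state units
#'   lost over the window, >= 0) and `share` (%, summing to 100).
#' @examples
#' sim <- simulate_community(build_scenario(2, "eutro"))
#' integrated_loss_shares(sim, "P")
#' @export
integrated_loss_shares <- function(sim, variable = "P", window = "demise",
                                   terms = "all") {
  stopifnot(inherits(sim, "plankton_sim"), variable %in% .state_names)
  if (is.character(window)) {
    window <- switch(match.arg(window, c("demise", "full")),
                     demise = demise_window(sim, variable),
                     full = range(sim$trajectory$time))
  }
  stopifnot(length(window) == 2, window[1] <= window[2])
  structural_losses <- list(
    H = c("infection_loss", "ciliate_grazing"),
    I = c("maturation_loss", "ciliate_grazing"),
    P = c("infection_attachment_loss", "natural_mortality", "rotifer_grazing"),
    D = "ciliate_grazing", A = "rotifer_grazing",
    C = character(0), R = character(0),
    N = c("uptake_h", "uptake_d", "uptake_a")
  )
  loss_terms <- structural_losses[[variable]]
  if (!identical(terms, "all")) loss_terms <- intersect(loss_terms, terms)
  if (!length(loss_terms)) stop("variable '", variable, "' has no loss terms")
  losses <- dplyr::filter(flux_series(sim), .data$variable == !!variable)
  inside <- losses$time >= window[1] & losses$time <= window[2]
  out <- purrr::map_dfr(loss_terms, function(tm) {
    sel <- losses$term == tm & inside
    tibble::tibble(
      variable = variable, term = tm,
      integral = .trapz(losses$time[sel], -losses$rate[sel])
    )
  })
  total <- sum(out$integral)
  if (total <= 0) stop("total integrated loss is zero over the window; shares undefined")
  out$share <- 100 * out$integral / total
  out
}

#' Effect intensity of removing a community member
#'
#' Compares the maximum of a state variable between a baseline run and a run
#' with one community member removed. The intensity of the (growth-phase)
#' negative effect is `100 (max_removed - max_baseline) / max_removed` when
#' removal increases the maximum, else 0. Intensities below 1% are reported
#' but flagged as negligible.
#'
#' @param baseline,removed `plankton_sim` objects sharing grid and horizon.
#' @param variable affected state variable (e.g. `"H"` or `"P"`).
#' @return A one-row tibble: `variable`, `max_baseline`, `max_removed`,
#'   `intensity` (%), `negligible` (logical, < 1%).
#' @export
removal_effect_intensity <- function(baseline, removed, variable = "H") {
  stopifnot(inherits(baseline, "plankton_sim"), inherits(removed, "plankton_sim"),
            variable %in% .state_names)
  if (!isTRUE(all.equal(baseline$trajectory$time, removed$trajectory$time))) {
    stop("baseline and removed runs must share the output grid")
  }
  mb <- max(baseline$trajectory[[variable]])
  mr <- max(removed$trajectory[[variable]])
  if (mr == 0) stop("maximum of '", variable, "' in the removal run is zero; intensity undefined")
  intensity <- if (mr > mb) 100 * (mr - mb) / mr else 0
  tibble::tibble(variable = variable, max_baseline = mb, max_removed = mr,
                 intensity = intensity, negligible = intensity < 1)
}
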