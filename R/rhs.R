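# Core flux computation. All terms of every state equation are evaluated as
# named signed scalars; the right-hand side is their per-equation sum, so the
# flux decomposition and the derivative agree bitwise by construction.

# Returns a named list (one element per state variable) of named signed term
# vectors. `active`/`frozen` are logical(8) in canonical state order.
.flux_terms <- function(y, p, active, frozen, opts) {
  y <- pmax(y, 0)        # adaptive steppers may propose tiny negative states
  y[!active] <- 0
  H <- y[[1]]; I <- y[[2]]; P <- y[[3]]; D <- y[[4]]
  A <- y[[5]]; C <- y[[6]]; R <- y[[7]]; N <- y[[8]]

  fh <- N / (p$K_h + N); fd <- N / (p$K_d + N); fa <- N / (p$K_a + N)
  phi <- p$a * H / (1 + p$a * p$h * H)        # per-dinospore infection rate
  preyC <- H + I + D
  preyR <- A + P
  Gc <- p$G_cmax * preyC / (p$K_Gc + preyC)
  rc <- p$r_cmax * (preyC - p$x_c) / (p$K_rc + (preyC - p$x_c))
  rr <- p$r_rmax * (preyR - p$x_r) / (p$K_rr + (preyR - p$x_r))
  Gr <- p$G_rmax * preyR / (p$K_Gr + preyR) *
    (0.94 / (1 + 219000 * p$Temp^(-4.35))) * 24
  # grazing partition quotients, defined 0 at zero total prey
  qH <- if (preyC > 0) H / preyC else 0
  qI <- if (preyC > 0) I / preyC else 0
  qD <- if (preyC > 0) D / preyC else 0
  qP <- if (preyR > 0) P / preyR else 0
  qA <- if (preyR > 0) A / preyR else 0

  # nitrate uptake: printed form scales every producer term by H; the
  # self-scaled variant uses each producer's own abundance. A masked
  # producer's uptake term is dropped in either form.
  upt <- if (opts$nitrate_uptake == "printed") c(H, H, H) else c(H, D, A)
  dR_growth <- if (opts$rotifer_reproduction == "printed_ciliate") rr * C else rr * R

  terms <- list(
    H = c(growth = p$r_h * H * fh,
          infection_loss = -(phi * P),
          ciliate_grazing = -(C * Gc * qH)),
    I = c(infection_gain = phi * P,
          maturation_loss = -(I / p$h),
          ciliate_grazing = -(C * Gc * qI)),
    P = c(release_gain = p$eps * I / p$h,
          infection_attachment_loss = -(phi * P),
          natural_mortality = -(p$m * P),
          rotifer_grazing = -(R * Gr * qP)),
    D = c(growth = p$r_d * D * fd,
          ciliate_grazing = -(C * Gc * qD)),
    A = c(growth = p$r_a * A * fa,
          rotifer_grazing = -(R * Gr * qA)),
    C = c(net_growth = rc * C),
    R = c(net_growth = dR_growth),
    N = c(uptake_h = if (active[[1]]) -(upt[[1]] * p$r_h * fh * p$Q_h) else 0,
          uptake_d = if (active[[4]]) -(upt[[2]] * p$r_d * fd * p$Q_d) else 0,
          uptake_a = if (active[[5]]) -(upt[[3]] * p$r_a * fa * p$Q_a) else 0)
  )
  for (i in which(!active | frozen)) terms[[i]][] <- 0
  terms
}

# per-equation left-to-right sum; plain double additions so that
# sum-of-terms == derivative holds bitwise
.sum_terms <- function(terms) {
  vapply(terms, function(v) Reduce(`+`, v, accumulate = FALSE), numeric(1))
}

.check_finite <- function(d, terms) {
  if (all(is.finite(d))) return(invisible())
  bad <- names(d)[!is.finite(d)]
  detail <- vapply(bad, function(v) {
    tm <- terms[[v]]
    paste0(v, ": ", paste(names(tm)[!is.finite(tm)], collapse = "+"))
  }, character(1))
  stop("non-finite derivative in term(s): ", paste(detail, collapse = "; "))
}

#' Right-hand side of the community model
#'
#' Evaluates the time derivative of the 8 state variables: Monod-limited
#' growth of the three phytoplankton groups, Holling type-II infection of
#' dinoflagellate hosts by dinospores, maturation and dinospore release,
#' partitioned grazing by microciliates (on H, I, D) and rotifers (on A, P),
#' grazer numerical responses, and nitrate drawdown. Response functions are
#' evaluated on `max(state, 0)`; inactive members and frozen variables have
#' identically zero derivatives and contribute nothing to any term.
#'
#' @param state named state vector from [community_state()].
#' @param params a [plankton_params()] object.
#' @param mask a [community_mask()]; defaults to all members active.
#' @param options a [model_options()] object.
#' @return Named numeric vector of derivatives (state units per day).
#' @seealso [decompose_fluxes()] for the same quantity split into named
#'   gain/loss terms.
#' @examples
#' community_rhs(community_state(H = 1e5, P = 1e5, N = 36))
#' @export
community_rhs <- function(state, params = plankton_params(),
                          mask = community_mask(),
                          options = model_options()) {
  terms <- .flux_terms(state[.state_names], params,
                       .active_states(mask), mask$frozen, options)
  d <- .sum_terms(terms)
  .check_finite(d, terms)
  d
}

#' Decompose the model right-hand side into named flux terms
#'
#' Every state equation is split into its constituent signed gain and loss
#' terms (e.g. the dinospore equation into release, infection attachment,
#' natural mortality and rotifer grazing). The per-equation sum of terms
#' reproduces [community_rhs()] exactly — both are built from the same
#' scalar term values — which is the basis of the loss-attribution analyses.
#'
#' @inheritParams community_rhs
#' @return A tibble with columns `variable`, `term`, `rate` (signed, state
#'   units per day).
#' @examples
#' decompose_fluxes(community_state(H = 1e5, I = 3e3, P = 1e5, N = 36))
#' @export
decompose_fluxes <- function(state, params = plankton_params(),
                             mask = community_mask(),
                             options = model_options()) {
  terms <- .flux_terms(state[.state_names], params,
                       .active_states(mask), mask$frozen, options)
  .check_finite(.sum_terms(terms), terms)
  tibble::tibble(
    variable = rep(names(terms), lengths(terms)),
    term = unlist(lapply(terms, names), use.names = FALSE),
    rate = unlist(terms, use.names = FALSE)
  )
}
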