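#' Monod nutrient limitation factor
#'
#' Saturating Michaelis-Menten-Monod limitation `N / (K + N)` multiplying a
#' maximal growth rate. Strictly increasing in `N`, 0 at `N = 0`, and
#' approaches 1 as `N` grows.
#'
#' @param N nitrate concentration (uM), >= 0. Vectorized.
#' @param K half-saturation constant (uM), > 0.
#' @return Dimensionless fraction in \[0, 1).
#' @examples
#' monod_limitation(2.3, 2.3) # 0.5 at half-saturation
#' @export
monod_limitation <- function(N, K) {
  if (any(N < 0)) stop("N must be >= 0")
  if (any(K <= 0)) stop("K must be > 0")
  N / (K + N)
}

#' Per-dinospore infection rate (Holling type II)
#'
#' Attack rate of dinospores on uninfected hosts, `a H / (1 + a h H)`:
#' proportional to host abundance when hosts are rare and saturating at `1/h`
#' (the reciprocal handling/maturation time) when hosts are plentiful.
#'
#' @param H uninfected host abundance (cells per litre), >= 0. Vectorized.
#' @param a search rate (L per dinospore per day).
#' @param h handling/maturation time (days).
#' @return Infection rate per dinospore (per day).
#' @export
infection_attack_rate <- function(H, a, h) {
  if (any(H < 0)) stop("H must be >= 0")
  a * H / (1 + a * h * H)
}

#' Microciliate numerical response (growth rate)
#'
#' Growth rate of microciliates as a saturating function of their total prey
#' `H + I + D`, offset by a prey threshold `x_c` below which growth is
#' negative: `r_cmax (prey - x_c) / (K_rc + (prey - x_c))`. Zero exactly at
#' the threshold and approaching `r_cmax` at high prey.
#'
#' @param prey total ciliate prey abundance `H + I + D` (cells per litre).
#'   Vectorized.
#' @param params a [plankton_params()] object.
#' @return Growth rate (per day); may be negative.
#' @export
ciliate_growth_rate <- function(prey, params = plankton_params()) {
  if (any(prey < 0)) stop("prey must be >= 0")
  if (params$K_rc <= params$x_c) stop("K_rc must exceed x_c")
  params$r_cmax * (prey - params$x_c) / (params$K_rc + (prey - params$x_c))
}

#' Microciliate functional response (ingestion rate)
#'
#' Per-capita ingestion of microciliates, `G_cmax prey / (K_Gc + prey)`.
#'
#' @inheritParams ciliate_growth_rate
#' @return Ingestion rate (prey per ciliate per day).
#' @export
ciliate_ingestion_rate <- function(prey, params = plankton_params()) {
  if (any(prey < 0)) stop("prey must be >= 0")
  params$G_cmax * prey / (params$K_Gc + prey)
}

#' Rotifer numerical response (growth rate)
#'
#' Growth rate of rotifers on their combined prey `A + P`, with threshold
#' `x_r`: `r_rmax (prey - x_r) / (K_rr + (prey - x_r))`.
#'
#' @param prey total rotifer prey abundance `A + P` (cells per litre).
#'   Vectorized.
#' @inheritParams ciliate_growth_rate
#' @return Growth rate (per day); may be negative.
#' @export
rotifer_growth_rate <- function(prey, params = plankton_params()) {
  if (any(prey < 0)) stop("prey must be >= 0")
  if (params$K_rr <= params$x_r) stop("K_rr must exceed x_r")
  params$r_rmax * (prey - params$x_r) / (params$K_rr + (prey - params$x_r))
}

#' Temperature factor of the rotifer functional response
#'
#' Empirical temperature dependence `0.94 / (1 + 219000 T^(-4.35))` applied
#' to the rotifer ingestion rate; about 0.635 at 20 degrees C.
#'
#' @param Temp temperature (degrees C), > 0. Vectorized.
#' @return Dimensionless factor in (0, 0.94).
#' @export
rotifer_temperature_factor <- function(Temp) {
  if (any(Temp <= 0)) stop("Temp must be > 0")
  0.94 / (1 + 219000 * Temp^(-4.35))
}

#' Rotifer functional response (ingestion rate)
#'
#' Per-capita rotifer ingestion `G_rmax prey / (K_Gr + prey)` modulated by
#' the temperature factor and converted from an hourly to a daily rate
#' (factor 24): at 20 degrees C the combined multiplier on the hourly
#' Michaelis-Menten term is about 15.25.
#'
#' @param prey total rotifer prey abundance `A + P` (cells per litre).
#'   Vectorized.
#' @param Temp temperature (degrees C); defaults to the value in `params`.
#' @inheritParams ciliate_growth_rate
#' @return Ingestion rate (prey per rotifer per day).
#' @export
rotifer_ingestion_rate <- function(prey, Temp = params$Temp,
                                   params = plankton_params()) {
  if (any(prey < 0)) stop("prey must be >= 0")
  params$G_rmax * prey / (params$K_Gr + prey) *
    rotifer_temperature_factor(Temp) * 24
}
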