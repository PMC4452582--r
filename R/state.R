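#' Community state vector
#'
#' The instantaneous state of the modeled plankton community: abundances of
#' uninfected (`H`) and infected (`I`) dinoflagellates, free-living parasite
#' dinospores (`P`), diatoms (`D`), nanophytoplankton (`A`), microciliates
#' (`C`) (all cells per litre), rotifers (`R`, individuals per litre) and the
#' nitrate concentration (`N`, uM).
#'
#' @param H,I,P,D,A,C,R abundances (>= 0).
#' @param N nitrate concentration in uM (>= 0).
#' @return A named numeric vector of length 8 in canonical order.
#' @examples
#' community_state(H = 1.48e5, I = 3e3, P = 1.16e5, N = 36)
#' @export
community_state <- function(H = 0, I = 0, P = 0, D = 0, A = 0,
                            C = 0, R = 0, N = 0) {
  y <- c(H = H, I = I, P = P, D = D, A = A, C = C, R = R, N = N)
  if (any(!is.finite(y))) stop("state values must be finite")
  if (any(y < 0)) stop("state values must be >= 0")
  y
}

#' Community membership mask
#'
#' Declares which community members take part in a simulation, and optionally
#' which state variables are frozen (their derivative forced to zero).
#' Inactive members have their state variables held at exactly zero and
#' contribute nothing to any flux term. Freezing is a design facility used by
#' the 24-h grazing assay (nanophytoplankton held constant) and by test
#' hooks (e.g. a constant-nitrate chemostat limit).
#'
#' Infected dinoflagellates (`I`) exist only when both dinoflagellates and
#' parasites are active. Parasites may be active without dinoflagellates
#' (dinospores then simply decay), as in the host-free grazing assay and the
#' host-removal experiment.
#'
#' @param dinoflagellates,parasites,diatoms,nanophytoplankton,microciliates,rotifers
#'   logical flags; `TRUE` activates the member.
#' @param frozen character vector of state variable names (among
#'   `r paste0('"', paste(c("H","I","P","D","A","C","R","N"), collapse='", "'), '"')`)
#'   whose derivative is forced to zero.
#' @return A list of class `community_mask` with elements `members` (named
#'   logical) and `frozen` (named logical over the 8 state variables).
#' @examples
#' community_mask(diatoms = FALSE, nanophytoplankton = FALSE)
#' community_mask(frozen = "N") # chemostat test hook
#' @export
community_mask <- function(dinoflagellates = TRUE, parasites = TRUE,
                           diatoms = TRUE, nanophytoplankton = TRUE,
                           microciliates = TRUE, rotifers = TRUE,
                           frozen = character(0)) {
  members <- c(
    dinoflagellates = isTRUE(dinoflagellates),
    parasites = isTRUE(parasites),
    diatoms = isTRUE(diatoms),
    nanophytoplankton = isTRUE(nanophytoplankton),
    microciliates = isTRUE(microciliates),
    rotifers = isTRUE(rotifers)
  )
  if (!all(frozen %in% .state_names)) {
    stop("frozen must name state variables among: ",
         paste(.state_names, collapse = ", "))
  }
  structure(list(
    members = members,
    frozen = setNames(.state_names %in% frozen, .state_names)
  ), class = "community_mask")
}

# logical(8): which state variables are carried by active members
.active_states <- function(mask) {
  m <- mask$members
  c(H = m[["dinoflagellates"]],
    I = m[["dinoflagellates"]] && m[["parasites"]],
    P = m[["parasites"]],
    D = m[["diatoms"]],
    A = m[["nanophytoplankton"]],
    C = m[["microciliates"]],
    R = m[["rotifers"]],
    N = TRUE)
}

#' @export
print.community_mask <- function(x, ...) {
  act <- names(x$members)[x$members]
  frz <- names(x$frozen)[x$frozen]
  cat("<community_mask> active:", paste(act, collapse = ", "), "\n")
  if (length(frz)) cat("  frozen:", paste(frz, collapse = ", "), "\n")
  invisible(x)
}

# zero the state variables of inactive members; error on inconsistency
.apply_mask_state <- function(state, mask, enforce = TRUE) {
  active <- .active_states(mask)
  if (enforce && any(state[!active] != 0)) {
    stop("initial state has non-zero values for inactive members: ",
         paste(names(state)[!active & state != 0], collapse = ", "))
  }
  state[!active] <- 0
  state
}
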