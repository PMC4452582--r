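#' Scenario specification
#'
#' Bundles everything a simulation run needs: a label, the community mask,
#' the initial state, and the horizon. Generated by the experiment-design
#' helpers ([build_scenario()], [nutrient_competition_grid()],
#' [removal_designs()], [grazing_assay_design()]) or constructed directly.
#'
#' @param label short run identifier.
#' @param mask a [community_mask()].
#' @param initial a [community_state()] consistent with the mask (inactive
#'   members at zero).
#' @param horizon run length in days (> 0).
#' @param notes free-text annotation.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(label, mask, initial, horizon = 30, notes = "") {
  stopifnot(inherits(mask, "community_mask"), horizon > 0)
  initial <- .apply_mask_state(community_state(
    initial[["H"]], initial[["I"]], initial[["P"]], initial[["D"]],
    initial[["A"]], initial[["C"]], initial[["R"]], initial[["N"]]), mask)
  structure(list(label = label, mask = mask, initial = initial,
                 horizon = horizon, notes = notes),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("<scenario_spec>", x$label, "| horizon", x$horizon, "d\n")
  print(x$initial)
  print(x$mask)
  invisible(x)
}

#' Published default parameters and initial state
#'
#' The literature-derived parameter values and the initial plankton
#' composition observed at the onset of a *Prorocentrum triestinum* bloom
#' (the template community for all experiments): H = 1.48e5, I = 3e3,
#' P = 1.16e5, D = 2.5e4, A = 1.9e6, C = 3.2e3 cells/L, R = 20 ind/L.
#' Nitrate is left at 0 because each experiment sets its own forcing (1 uM
#' oligotrophic, 36 uM eutrophic, or a grid level).
#'
#' @return A list with elements `params` ([plankton_params()]) and `initial`
#'   ([community_state()]).
#' @export
table1_defaults <- function() {
  list(
    params = plankton_params(),
    initial = community_state(H = 1.48e5, I = 3e3, P = 1.16e5, D = 2.5e4,
                              A = 1.9e6, C = 3.2e3, R = 20, N = 0)
  )
}

.nitrate_for <- function(trophic) {
  switch(match.arg(trophic, c("oligo", "eutro")), oligo = 1, eutro = 36)
}

#' Community-complexity scenarios
#'
#' The three nested community configurations used to probe how community
#' structure modulates parasitic control, each run for 30 days: level 1 has
#' hosts and parasites only; level 2 adds both grazer guilds; level 3 adds
#' the competing phytoplankton (diatoms and nanophytoplankton) — the full
#' community. `trophic` selects the nitrate forcing: 1 uM ("oligo") or
#' 36 uM ("eutro").
#'
#' @param level 1, 2 or 3.
#' @param trophic `"oligo"` or `"eutro"`.
#' @return A [scenario_spec()].
#' @examples
#' build_scenario(3, "eutro")
#' @export
build_scenario <- function(level, trophic = c("eutro", "oligo")) {
  if (!(length(level) == 1 && level %in% 1:3)) stop("level must be 1, 2 or 3")
  trophic <- match.arg(trophic)
  defs <- table1_defaults()
  mask <- community_mask(
    diatoms = level >= 3, nanophytoplankton = level >= 3,
    microciliates = level >= 2, rotifers = level >= 2
  )
  init <- defs$initial
  init[["N"]] <- .nitrate_for(trophic)
  init <- .apply_mask_state(init, mask, enforce = FALSE)
  scenario_spec(sprintf("scenario%d_%s", level, trophic), mask, init,
                horizon = 30,
                notes = sprintf("community complexity level %d, %s uM nitrate",
                                level, init[["N"]]))
}

# shared initial layout of the competition-grid / removal experiments
.grid_initial <- function(total, nitrate, parasites, ratio = c(99, 1)) {
  ratio <- ratio / sum(ratio)
  community_state(H = 2.5e5, I = 0, P = if (parasites) 1.25e5 else 0,
                  D = ratio[2] * total, A = ratio[1] * total,
                  C = 3.2e3, R = 20, N = nitrate)
}

#' Nutrient x competitor grid of scenarios
#'
#' Crosses initial abundances of phytoplankton other than dinoflagellates
#' with nitrate concentrations, in the presence and absence of parasites
#' (the bloom-window experiment). Other phytoplankton are split
#' nanophytoplankton:diatoms = 99:1 by default; dinoflagellates start at
#' 2.5e5 cells/L, microciliates at 3.2e3 cells/L, rotifers at 20 ind/L,
#' and runs with parasites start with no infected cells and 1.25e5
#' dinospores/L.
#'
#' @param totals other-phytoplankton totals (cells per litre).
#' @param nitrate_levels nitrate concentrations (uM).
#' @param parasites logical vector of parasite-presence settings to cross.
#' @param ratio nanophytoplankton:diatom split (length 2).
#' @return A tibble with one row per scenario: `total`, `nitrate`,
#'   `parasites` and a `spec` list-column of [scenario_spec()] objects
#'   (6 x 8 x 2 = 96 rows for the defaults).
#' @export
nutrient_competition_grid <- function(totals = 10^(4:9),
                                      nitrate_levels = c(0.5, 1, 5, 10, 20, 30, 40, 50),
                                      parasites = c(TRUE, FALSE),
                                      ratio = c(99, 1)) {
  stopifnot(all(totals > 0), all(nitrate_levels > 0), length(ratio) == 2)
  grid <- tidyr::expand_grid(total = totals, nitrate = nitrate_levels,
                             parasites = parasites)
  grid$spec <- purrr::pmap(grid, function(total, nitrate, parasites) {
    mask <- community_mask(parasites = parasites)
    scenario_spec(
      sprintf("grid_T%.0e_N%g_%s", total, nitrate,
              if (parasites) "par" else "nopar"),
      mask, .grid_initial(total, nitrate, parasites, ratio), horizon = 30)
  })
  grid
}

#' Component-removal experiment designs
#'
#' A full-community eutrophic (36 uM) baseline plus one design per community
#' member excluded one at a time, used to separate growth-limiting from
#' demise-driving interactions. Initial layout as in
#' [nutrient_competition_grid()] with parasites present.
#'
#' @param other_phyto_total total other-phytoplankton abundance, 1e4 (host
#'   dominated) or 1e8 (competitor dominated) cells per litre.
#' @return A tibble with columns `removed` (`"none"` for the baseline) and a
#'   `spec` list-column (7 rows).
#' @export
removal_designs <- function(other_phyto_total = c(1e4, 1e8)) {
  total <- other_phyto_total[1]
  if (!total %in% c(1e4, 1e8)) stop("other_phyto_total must be 1e4 or 1e8")
  removed <- c("none", .members)
  specs <- purrr::map(removed, function(rm) {
    flags <- setNames(!(.members %in% rm), .members)
    mask <- do.call(community_mask, as.list(flags))
    init <- .grid_initial(total, 36, parasites = flags[["parasites"]])
    init <- .apply_mask_state(init, mask, enforce = FALSE)
    scenario_spec(sprintf("removal_T%.0e_%s", total, rm), mask, init,
                  horizon = 30, notes = paste("excluded:", rm))
  })
  tibble::tibble(removed = removed, spec = specs)
}

#' Rotifer grazing assay designs
#'
#' Two designs probing rotifer predation on dinospores under varying
#' nanophytoplankton (alternative prey) abundance. The 24-h mode removes
#' both interferences the short assay is meant to exclude: hosts are absent
#' (no dinospore release) and nanophytoplankton is frozen (no alternative
#' prey growth); dinospores start at 1.25e5 cells/L with 20 rotifers/L.
#' Natural dinospore mortality remains active; consumption is therefore
#' reported from the integrated rotifer-grazing flux only (see
#' [grazing_assay()]). The 30-d mode embeds the same question in the full
#' eutrophic community (diatoms at 2.9e4 cells/L).
#'
#' @param nano_level initial nanophytoplankton abundance (cells per litre).
#' @param mode `"24h"` or `"30d"`.
#' @return A [scenario_spec()].
#' @export
grazing_assay_design <- function(nano_level, mode = c("24h", "30d")) {
  mode <- match.arg(mode)
  stopifnot(nano_level > 0)
  if (mode == "24h") {
    mask <- community_mask(dinoflagellates = FALSE, diatoms = FALSE,
                           microciliates = FALSE, frozen = "A")
    init <- community_state(P = 1.25e5, A = nano_level, R = 20, N = 36)
    scenario_spec(sprintf("assay24h_A%.0e", nano_level), mask, init,
                  horizon = 1, notes = "host-free 24-h grazing assay; A frozen")
  } else {
    mask <- community_mask()
    init <- community_state(H = 2.5e5, I = 0, P = 1.25e5, D = 2.9e4,
                            A = nano_level, C = 3.2e3, R = 20, N = 36)
    scenario_spec(sprintf("assay30d_A%.0e", nano_level), mask, init,
                  horizon = 30, notes = "30-d eutrophic grazing assay")
  }
}
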