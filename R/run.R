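#' Run a configured simulation and write its outputs
#'
#' Executes one simulation described by a configuration list and writes a
#' time-series table (CSV with columns `time_d`, the 8 state variables and
#' `prevalence_pct`) plus a JSON summary (peaks, peak days, final values).
#' An empty configuration runs the full community (scenario 3) under
#' eutrophic forcing with the published defaults.
#'
#' @param config a list with optional entries: `scenario` (list with `level`
#'   and `trophic`, or a [scenario_spec()] under `spec`), `params` (named
#'   overrides), `solver` (`output_step`, `rtol`), `options` (arguments of
#'   [model_options()]).  Unknown keys are rejected.
#' @param out_dir output directory (created if missing).
#' @return Invisibly, a list with the `plankton_sim`, the summary tibble and
#'   the paths written.
#' @export
run_simulate <- function(config = list(), out_dir = ".") {
  known <- c("scenario", "params", "solver", "options")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  params <- do.call(plankton_params, config$params %||% list())
  options <- do.call(model_options, config$options %||% list())
  solver <- modifyList(list(output_step = 0.1, rtol = 1e-8),
                       config$solver %||% list())
  spec <- if (!is.null(config$scenario$spec)) {
    config$scenario$spec
  } else {
    build_scenario(config$scenario$level %||% 3,
                   config$scenario$trophic %||% "eutro")
  }
  sim <- simulate_community(spec, params = params,
                            output_step = solver$output_step,
                            rtol = solver$rtol, options = options)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  ts_path <- file.path(out_dir, paste0(spec$label, "_timeseries.csv"))
  sm_path <- file.path(out_dir, paste0(spec$label, "_summary.json"))
  ts <- dplyr::rename(sim$trajectory, time_d = "time",
                      prevalence_pct = "prevalence")
  readr::write_csv(ts, ts_path)
  summary <- summarize_trajectory(sim)
  jsonlite::write_json(
    list(label = spec$label, horizon_d = spec$horizon,
         options = unclass(options), summary = summary),
    sm_path, auto_unbox = TRUE, digits = NA)
  invisible(list(sim = sim, summary = summary, paths = c(ts_path, sm_path)))
}

#' Reproduce a full experiment family
#'
#' Runs one of the study's experiment designs end to end and writes tidy
#' result tables (CSV) plus a machine-readable JSON summary of the headline
#' quantities (peak days, maximal prevalences, loss shares, sensitivity
#' rankings) into `out_dir`.
#'
#' Experiments: `"fig1"` — the 3 community-complexity scenarios under both
#' trophic conditions (6 trajectories); `"fig2grid"` — the 96-run nutrient x
#' competitor grid; `"fig2removal"` — component-removal designs and
#' demise-phase loss attribution at 1e4 and 1e8 other phytoplankton;
#' `"fig3"` — the 24-h host-free grazing assays and the two 30-d assays;
#' `"fig4"` — Sobol' sensitivity analysis under both trophic conditions.
#'
#' @param experiment one of `"fig1"`, `"fig2grid"`, `"fig2removal"`,
#'   `"fig3"`, `"fig4"`.
#' @param out_dir output directory.
#' @param seed seed for the sensitivity analysis (other experiments are
#'   deterministic).
#' @param n_base Saltelli base sample size for `"fig4"`.
#' @return Invisibly, the summary object written as JSON.
#' @export
run_reproduce <- function(experiment = c("fig1", "fig2grid", "fig2removal",
                                         "fig3", "fig4"),
                          out_dir = ".", seed = 20090101L, n_base = 128) {
  experiment <- match.arg(experiment)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- switch(
    experiment,
    fig1 = {
      runs <- tidyr::expand_grid(level = 1:3, trophic = c("eutro", "oligo"))
      sims <- purrr::pmap(runs, function(level, trophic) {
        sim <- simulate_community(build_scenario(level, trophic))
        ts <- dplyr::rename(sim$trajectory, time_d = "time",
                            prevalence_pct = "prevalence")
        readr::write_csv(ts, file.path(out_dir,
          paste0(sim$scenario$label, "_timeseries.csv")))
        sim
      })
      purrr::map_dfr(sims, glance)
    },
    fig2grid = {
      grid <- nutrient_competition_grid()
      res <- purrr::map_dfr(seq_len(nrow(grid)), function(i) {
        sim <- simulate_community(grid$spec[[i]])
        g <- glance(sim)
        tibble::tibble(total = grid$total[i], nitrate = grid$nitrate[i],
                       parasites = grid$parasites[i],
                       max_H = g$max_H, day_max_H = g$day_max_H,
                       bloom = g$max_H >= 10 * 2.5e5)
      })
      readr::write_csv(res, file.path(out_dir, "fig2grid.csv"))
      res
    },
    fig2removal = {
      purrr::map_dfr(c(1e4, 1e8), function(total) {
        designs <- removal_designs(total)
        sims <- purrr::map(designs$spec, simulate_community)
        base <- sims[[which(designs$removed == "none")]]
        eff <- purrr::map_dfr(which(designs$removed != "none"), function(i) {
          purrr::map_dfr(c("H", "P"), function(v) {
            # the affected pool must exist in the removal run
            if (max(sims[[i]]$trajectory[[v]]) == 0) return(NULL)
            dplyr::mutate(removal_effect_intensity(base, sims[[i]], v),
                          removed = designs$removed[i])
          })
        })
        shares <- dplyr::mutate(integrated_loss_shares(base, "P", "demise"),
                                total = total)
        readr::write_csv(eff, file.path(out_dir,
          sprintf("fig2removal_T%.0e_intensity.csv", total)))
        readr::write_csv(shares, file.path(out_dir,
          sprintf("fig2removal_T%.0e_loss_shares.csv", total)))
        dplyr::mutate(shares, experiment = sprintf("T%.0e", total))
      })
    },
    fig3 = {
      a24 <- purrr::map_dfr(10^(4:9), function(a)
        dplyr::select(grazing_assay(a, "24h"), -"sim"))
      a30 <- purrr::map_dfr(c(1e5, 1e7), function(a)
        dplyr::select(grazing_assay(a, "30d"), -"sim"))
      res <- dplyr::bind_rows(a24, a30)
      readr::write_csv(res, file.path(out_dir, "fig3_assays.csv"))
      res
    },
    fig4 = {
      purrr::map_dfr(c("oligo", "eutro"), function(tr) {
        res <- sobol_community(tr, n_base = n_base, seed = seed)
        readr::write_csv(tidy(res), file.path(out_dir,
          paste0("fig4_sobol_", tr, ".csv")))
        top <- purrr::map_dfr(unique(res$output), function(v) {
          r <- rank_top_k(res[res$output == v, ], 5)
          tibble::tibble(trophic = tr, output = v,
                         rank = seq_len(nrow(r)), parameter = r$parameter,
                         S1 = r$S1)
        })
        top
      })
    }
  )
  jsonlite::write_json(summary,
                       file.path(out_dir, paste0(experiment, "_summary.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(summary)
}
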